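test_that("pairwise coancestry rate follows its closed form", {
  expect_equal(delta_coancestry(0, 3, 5), 0)
  expect_equal(delta_coancestry(0.25, 1, 1), 0.25)
  expect_equal(delta_coancestry(0.25, 4, 4), 1 - 0.75^(1 / 4))
  # elementwise over vectors, symmetric in g
  expect_equal(delta_coancestry(c(0.1, 0.2), c(2, 3), c(4, 1)),
               c(1 - 0.9^(1 / 3), 1 - 0.8^(1 / 2)))
  expect_equal(delta_coancestry(0.3, 2, 6), delta_coancestry(0.3, 6, 2))
  expect_error(delta_coancestry(0.1, 0, 0), "undefined")
  expect_error(delta_coancestry(1.2, 1, 1), "0, 1")
})

test_that("Ne estimation handles the limit cases", {
  # unrelated members with known depth: mean dC = 0, Ne infinite
  ped <- pedigree(id = c("S1", "D1", "S2", "D2", "A", "B"),
                  sire = c(NA, NA, NA, NA, "S1", "S2"),
                  dam = c(NA, NA, NA, NA, "D1", "D2"),
                  birth_year = c(rep(2000, 4), 2005, 2005))
  est <- ne_estimate(ped, c("A", "B"))
  expect_identical(est$ne, Inf)
  expect_equal(est$mean_delta_c, 0)
  # two full sibs: C = 0.25, g = 1 each -> Ne = 2
  fs <- pedigree(id = c("S", "D", "A", "B"),
                 sire = c(NA, NA, "S", "S"), dam = c(NA, NA, "D", "D"),
                 birth_year = c(2000, 2000, 2005, 2005))
  est2 <- ne_estimate(fs, c("A", "B"))
  expect_equal(est2$ne, 2)
  expect_error(ne_estimate(fs, "A"), "at least 2")
  # members with zero traced depth carry no pairs
  expect_error(ne_estimate(ped, c("S1", "D1")), "positive equivalent")
})

test_that("Ne is invariant to member order and decreases with kinship", {
  ped <- random_pedigree(80, p_known = 0.9, seed = 13)
  rp <- reference_population(ped, 2005, 2013)
  ids <- rp$ids
  e1 <- ne_estimate(ped, ids)
  e2 <- ne_estimate(ped, sample(ids))
  expect_equal(e1$ne, e2$ne, tolerance = 1e-12)
  # raising every pairwise kinship (same depths) strictly lowers Ne:
  # compare a population of unrelated pairs vs half-sib pairs
  q <- pedigree_quality(ped)
  g <- q$neg[match(ids, q$id)]
  C <- kinship(ped, ids)
  raise <- function(C) {
    ut <- upper.tri(C)
    gi <- matrix(g, length(g), length(g))
    mean(delta_coancestry(C[ut], gi[ut], t(gi)[ut]))
  }
  C2 <- C; C2[upper.tri(C2)] <- pmin(C2[upper.tri(C2)] + 0.05, 0.99)
  expect_gt(raise(C2), raise(C))   # mean dC up means Ne down
})

test_that("reference populations apply window and quality gates", {
  sim <- simulate_flock_population(sim_flock_config(
    n_flocks = 5, ewes_per_flock = 12, n_years = 10, seed = 17))
  ped <- sim$pedigree
  q <- pedigree_quality(ped)
  rp <- reference_population(ped, 5, 10, min_neg = 2, quality = q)
  expect_gt(rp$nt, 0)
  yr <- ped$birth_year[match(rp$ids, ped$id)]
  expect_true(all(yr >= 5 & yr <= 10))
  expect_true(all(q$neg[match(rp$ids, q$id)] >= 2))
  rp2 <- reference_population(ped, 5, 10, quality = q)
  expect_gte(rp2$nt, rp$nt)
  # infeasible gate empties the population
  rp3 <- reference_population(ped, 5, 10, min_nfg = 50, quality = q)
  expect_identical(rp3$nt, 0L)
})

test_that("sliding windows reproduce the 4-year overlapping layout", {
  w <- sliding_windows(2012, 2018, window_len = 4, step = 1)
  expect_identical(nrow(w), 4L)
  expect_equal(w$from, 2012:2015)
  expect_equal(w$to, 2015:2018)
  expect_equal(w$generation, 1:4)
  expect_identical(w$label[1], "2012-2015")
  # step equal to span: disjoint windows
  w2 <- sliding_windows(2000, 2007, window_len = 4, step = 4)
  expect_equal(w2$from, c(2000, 2004))
  expect_true(all(w2$to - w2$from + 1 == 4))
  # single window covering all years
  w3 <- sliding_windows(2010, 2018, window_len = 9)
  expect_identical(nrow(w3), 1L)
  expect_error(sliding_windows(2018, 2010), "empty")
})

test_that("trend regression matches closed-form least squares", {
  # exact line
  t1 <- trend(c(92, 85, 78, 71))
  expect_equal(t1$slope, -7)
  expect_equal(t1$se, 0)
  expect_lt(t1$p_value, 1e-10)
  # constant values: slope 0, p = 1
  t2 <- trend(c(5, 5, 5, 5, 5))
  expect_equal(t2$slope, 0)
  expect_equal(t2$p_value, 1)
  # hand OLS on 4 points
  y <- c(92, 85, 78, 73); x <- 1:4
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se <- sqrt(rss / 2 / sum((x - mean(x))^2))
  p <- 2 * pt(abs(b / se), df = 2, lower.tail = FALSE)
  t3 <- trend(y)
  expect_equal(t3$slope, b, tolerance = 1e-10)
  expect_equal(t3$slope, -6.4, tolerance = 1e-10)
  expect_equal(t3$se, se, tolerance = 1e-10)
  expect_equal(t3$p_value, p, tolerance = 1e-10)
  expect_error(trend(c(1, 2)), "at least 3")
})

test_that("windowed Ne table and trends assemble end to end", {
  sim <- simulate_flock_population(sim_flock_config(
    n_flocks = 6, ewes_per_flock = 15, n_years = 12, seed = 19))
  nw <- ne_windows(sim$pedigree, from = 5, to = 12, window_len = 4,
                   step = 1, min_neg = 1)
  expect_identical(nrow(nw$table), 5L)
  expect_true(all(nw$table$ne > 0))
  expect_true(all(nw$table$ratio == nw$table$ne / nw$table$nt))
  expect_s3_class(nw$trend_f, "trend_estimate")
  expect_identical(nw$trend_f$n, 5L)
})

test_that("idealized populations recover their census size", {
  med_ne <- function(N, seeds) {
    median(vapply(seeds, function(s) {
      ped <- simulate_idealized(N, 8, seed = s)
      q <- pedigree_quality(ped)
      ne_estimate(ped, reference_population(ped, 8, 8, quality = q),
                  quality = q)$ne
    }, 0))
  }
  ne50 <- med_ne(50, 1:3)
  expect_gt(ne50, 0.8 * 50)
  expect_lt(ne50, 1.25 * 50)
})

test_that("coancestry-rate Ne agrees with the inbreeding-trend route", {
  # in the idealized case, the slope of mean F per generation implies
  # Ne_F = 1 / (2 dF / (1 - F)); compare at N = 50 after 10 generations
  ped <- simulate_idealized(50, 10, seed = 5)
  q <- pedigree_quality(ped)
  fbar <- vapply(1:10, function(t)
    mean(inbreeding(ped)[ped$birth_year == t]), 0)
  dF <- mean(diff(fbar) / (1 - fbar[-length(fbar)]))
  ne_f <- 1 / (2 * dF)
  ne_c <- ne_estimate(ped, reference_population(ped, 10, 10, quality = q),
                      quality = q)$ne
  expect_lt(abs(ne_c - ne_f) / ne_f, 0.25)
})
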