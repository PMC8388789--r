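#' Configuration for the multi-flock pedigree simulator
#'
#' Defaults describe a desk-scale, performance-recorded dairy-sheep
#' population: 14 flocks of 30 breeding ewes and 2 service rams run for
#' 12 years with overlapping generations. Rams service their own flock,
#' but each mating's sire is drawn from a uniformly chosen other flock
#' with probability `migration_rate` (breeding-ram exchange). Parent
#' links of early cohorts are deleted at a rate decaying with calendar
#' year, mimicking the incomplete ancestry of historic records. Breeding
#' animals enter service at age 2 and are replaced at rate
#' `replacement_rate` per year; with the default turnover, the mean
#' parent age is about `mean_parent_age` years.
#'
#' @param n_flocks Number of flocks.
#' @param ewes_per_flock,rams_per_flock Breeding roster sizes per flock.
#' @param n_years Years of lambing simulated.
#' @param migration_rate Probability that a mating's sire comes from
#'   another flock.
#' @param missing_parent_rate Numeric vector of per-year parent-link
#'   deletion probabilities (recycled/truncated to `n_years`), or a
#'   function of the year index 1..n_years. The default decays linearly
#'   from 0.5 to 0 over the first 60% of the horizon.
#' @param lambing_rate Probability a breeding ewe produces a recorded
#'   lamb in a given year.
#' @param mean_parent_age Target mean parent age (years); used to derive
#'   `replacement_rate` when that is `NULL` (entry at age 2, geometric
#'   survival).
#' @param replacement_rate Fraction of the breeding roster replaced per
#'   year, or `NULL` to derive it from `mean_parent_age`.
#' @param recorded_flocks Flock labels receiving phenotype records
#'   (default: all flocks).
#' @param seed Integer seed; the same configuration and seed give an
#'   identical pedigree.
#' @return A list of class `sim_flock_config`.
#' @export
sim_flock_config <- function(n_flocks = 14L, ewes_per_flock = 30L,
                             rams_per_flock = 2L, n_years = 12L,
                             migration_rate = 0.1,
                             missing_parent_rate = NULL,
                             lambing_rate = 0.7,
                             mean_parent_age = 3.8,
                             replacement_rate = NULL,
                             recorded_flocks = NULL, seed = 1L) {
  if (n_flocks < 1L || ewes_per_flock < 1L || rams_per_flock < 1L)
    stop("infeasible configuration: need at least one flock with breeders")
  if (migration_rate < 0 || migration_rate > 1)
    stop("migration_rate must lie in [0, 1]")
  if (is.null(replacement_rate))
    replacement_rate <- 1 / (mean_parent_age - 2 + 1)
  if (replacement_rate <= 0 || replacement_rate > 1)
    stop("replacement_rate must lie in (0, 1]")
  if (is.null(missing_parent_rate))
    missing_parent_rate <- function(yr)
      pmax(0, 0.5 * (1 - (yr - 1) / max(1, 0.6 * n_years)))
  mpr <- if (is.function(missing_parent_rate))
    missing_parent_rate(seq_len(n_years)) else
      rep_len(missing_parent_rate, n_years)
  if (any(mpr < 0 | mpr > 1)) stop("missing_parent_rate outside [0, 1]")
  if (is.null(recorded_flocks))
    recorded_flocks <- paste0("F", seq_len(n_flocks))
  structure(list(n_flocks = as.integer(n_flocks),
                 ewes_per_flock = as.integer(ewes_per_flock),
                 rams_per_flock = as.integer(rams_per_flock),
                 n_years = as.integer(n_years),
                 migration_rate = migration_rate,
                 missing_parent_rate = mpr,
                 lambing_rate = lambing_rate,
                 mean_parent_age = mean_parent_age,
                 replacement_rate = replacement_rate,
                 recorded_flocks = as.character(recorded_flocks),
                 seed = as.integer(seed)),
            class = "sim_flock_config")
}

#' Simulate a multi-flock sheep population with overlapping generations
#'
#' See [sim_flock_config()] for the generative model. Founder breeders
#' are unrelated and carry staggered birth years (so founders differ in
#' age at the start); all subsequent animals descend from recorded
#' matings, with parent links then deleted per the missing-parent
#' schedule. Phenotype records (one per ewe) are assigned when a ewe
#' born in a recorded flock is recruited into its breeding roster.
#'
#' @param cfg A [sim_flock_config()].
#' @return A list with `pedigree` (a [pedigree()]), `design` (a
#'   [records_design()]) and `config`.
#' @examples
#' sim <- simulate_flock_population(sim_flock_config(
#'   n_flocks = 3, ewes_per_flock = 8, n_years = 6, seed = 42))
#' sim$pedigree
#' @export
simulate_flock_population <- function(cfg = sim_flock_config()) {
  stopifnot(inherits(cfg, "sim_flock_config"))
  set.seed(cfg$seed)
  nf <- cfg$n_flocks
  flocks <- paste0("F", seq_len(nf))
  id <- sire <- dam <- sex <- flock <- character(0)
  year <- integer(0)
  next_id <- 0L
  new_animal <- function(sx, fl, yr, s = NA_character_,
                         d = NA_character_) {
    next_id <<- next_id + 1L
    aid <- sprintf("A%05d", next_id)
    id <<- c(id, aid); sire <<- c(sire, s); dam <<- c(dam, d)
    sex <<- c(sex, sx); flock <<- c(flock, fl); year <<- c(year, yr)
    aid
  }
  # founder rosters, entry ages staggered over 2..6 years before year 1
  ewes <- rams <- vector("list", nf)
  young_f <- young_m <- lapply(seq_len(nf), function(i)
    list(id = character(0), year = integer(0)))
  for (f in seq_len(nf)) {
    ewes[[f]] <- vapply(seq_len(cfg$ewes_per_flock), function(k)
      new_animal("F", flocks[f], 1L - sample(2:6, 1)), "")
    rams[[f]] <- vapply(seq_len(cfg$rams_per_flock), function(k)
      new_animal("M", flocks[f], 1L - sample(2:6, 1)), "")
  }
  rec_animal <- rec_unit <- character(0)
  for (yr in seq_len(cfg$n_years)) {
    pmiss <- cfg$missing_parent_rate[yr]
    # lambing
    for (f in seq_len(nf)) {
      for (e in ewes[[f]]) {
        if (runif(1) > cfg$lambing_rate) next
        src <- if (nf > 1L && runif(1) < cfg$migration_rate)
          sample(setdiff(seq_len(nf), f), 1L) else f
        sr <- sample(rams[[src]], 1L)
        s_rec <- if (runif(1) < pmiss) NA_character_ else sr
        d_rec <- if (runif(1) < pmiss) NA_character_ else e
        sx <- if (runif(1) < 0.5) "M" else "F"
        lamb <- new_animal(sx, flocks[f], yr, s_rec, d_rec)
        if (sx == "F") {
          young_f[[f]]$id <- c(young_f[[f]]$id, lamb)
          young_f[[f]]$year <- c(young_f[[f]]$year, yr)
        } else {
          young_m[[f]]$id <- c(young_m[[f]]$id, lamb)
          young_m[[f]]$year <- c(young_m[[f]]$year, yr)
        }
      }
    }
    # replacement: cull at replacement_rate, recruit local youngstock
    for (f in seq_len(nf)) {
      for (side in c("f", "m")) {
        roster0 <- if (side == "f") ewes[[f]] else rams[[f]]
        cull <- runif(length(roster0)) < cfg$replacement_rate
        roster <- roster0[!cull]
        pool <- if (side == "f") young_f[[f]] else young_m[[f]]
        # recruited as yearlings after this year's lambing, so first
        # service is at age 2
        ready <- which(yr - pool$year >= 1L)
        # a breeder is retained until a replacement exists
        if (!length(roster) && !length(ready)) roster <- roster0[1L]
        want <- (if (side == "f") cfg$ewes_per_flock else
                   cfg$rams_per_flock) - length(roster)
        # replacements are the youngest eligible animals (enter at ~2 y)
        take <- if (want > 0L && length(ready)) {
          ready <- ready[order(-pool$year[ready])]
          ready[seq_len(min(want, length(ready)))]
        } else integer(0)
        if (length(take)) {
          recruits <- pool$id[take]
          roster <- c(roster, recruits)
          pool$id <- pool$id[-take]; pool$year <- pool$year[-take]
          if (side == "f" && flocks[f] %in% cfg$recorded_flocks) {
            rec_animal <- c(rec_animal, recruits)
            rec_unit <- c(rec_unit, rep(flocks[f], length(recruits)))
          }
        }
        if (side == "f") { ewes[[f]] <- roster; young_f[[f]] <- pool }
        else { rams[[f]] <- roster; young_m[[f]] <- pool }
      }
    }
  }
  ped <- pedigree(id = id, sire = sire, dam = dam, sex = sex,
                  birth_year = year, flock = flock)
  if (!length(rec_animal))
    stop("no records generated; lengthen the simulation or raise rates")
  list(pedigree = ped,
       design = records_design(rec_animal, rec_unit),
       config = cfg)
}

#' Simulate an idealized random-mating population
#'
#' Discrete, non-overlapping generations of constant census size N: each
#' offspring draws its sire uniformly at random from the previous
#' generation's males and its dam from its females (Wright-Fisher
#' style multinomial family sizes). Founders (generation 0) are
#' unrelated. The pedigree-derived effective size of this population is
#' approximately N (equal sex ratio), which makes it the ground-truth
#' scenario for the coancestry-rate estimator.
#'
#' @param N Census size per generation (>= 4).
#' @param n_generations Number of offspring generations.
#' @param sex_ratio Proportion of males per generation.
#' @param seed Integer seed.
#' @return A [pedigree()] with `birth_year` equal to the generation
#'   number (founders 0).
#' @export
simulate_idealized <- function(N, n_generations, sex_ratio = 0.5,
                               seed = 1L) {
  if (N < 4L) stop("N must be >= 4")
  n_m <- max(1L, round(N * sex_ratio)); n_f <- N - n_m
  if (n_f < 1L) stop("sex_ratio leaves no females")
  set.seed(seed)
  id <- sprintf("G0_%03d", seq_len(N))
  sire <- dam <- rep(NA_character_, N)
  sex <- c(rep("M", n_m), rep("F", n_f))
  year <- rep(0L, N)
  males <- id[sex == "M"]; females <- id[sex == "F"]
  for (t in seq_len(n_generations)) {
    ids_t <- sprintf("G%d_%03d", t, seq_len(N))
    sex_t <- c(rep("M", n_m), rep("F", n_f))
    sire_t <- sample(males, N, replace = TRUE)
    dam_t <- sample(females, N, replace = TRUE)
    id <- c(id, ids_t); sire <- c(sire, sire_t); dam <- c(dam, dam_t)
    sex <- c(sex, sex_t); year <- c(year, rep(t, N))
    males <- ids_t[sex_t == "M"]; females <- ids_t[sex_t == "F"]
  }
  pedigree(id = id, sire = sire, dam = dam, sex = sex, birth_year = year,
           flock = rep("F1", length(id)))
}
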