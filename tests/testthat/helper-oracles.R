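# Independent oracles and fixture generators used across the suite.

# Wright's path-counting coancestry: enumerate all ancestor paths of i
# and j; paths meeting only in their common ancestor A contribute
# 0.5^(n1 + n2 + 1) * (1 + F_A). F_A is itself the path-counting
# kinship of A's parents. Exponential, for tiny pedigrees only.
path_kinship <- function(ped, a, b) {
  ia <- match(a, ped$id); ib <- match(b, ped$id)
  paths_up <- function(i) {
    # list of integer vectors: i, then successive ancestors
    out <- list(i)
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    for (p in c(s, d)) if (p > 0L)
      out <- c(out, lapply(paths_up(p), function(pt) c(i, pt)))
    out
  }
  f_of <- function(i) {
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    if (s == 0L || d == 0L) return(0)
    path_kinship(ped, ped$id[s], ped$id[d])
  }
  if (ia == ib) return(0.5 * (1 + f_of(ia)))
  pa <- paths_up(ia); pb <- paths_up(ib)
  tot <- 0
  for (p in pa) for (q in pb) {
    anc <- p[length(p)]
    if (q[length(q)] != anc) next
    # share only the terminal common ancestor
    if (length(intersect(p[-length(p)], q[-length(q)]))) next
    tot <- tot + 0.5^(length(p) + length(q) - 1) * (1 + f_of(anc))
  }
  tot
}

path_kinship_matrix <- function(ped, ids = ped$id) {
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(i))
    K[i, j] <- K[j, i] <- path_kinship(ped, ids[i], ids[j])
  K
}

# Dense mixed-model oracle: assemble the full coefficient matrix from a
# dense tabular relationship matrix inverted with base::solve, invert
# the whole system with base::solve, and read the animal block.
dense_pev_oracle <- function(ped, design, h2, sigma_e = 1,
                             animals = unique(design$animal)) {
  lambda <- (1 - h2) / h2
  units <- sort(unique(design$unit))
  m <- nrow(design); p <- length(units); n <- n_animals(ped)
  X <- matrix(0, m, p); Z <- matrix(0, m, n)
  X[cbind(seq_len(m), match(design$unit, units))] <- 1
  Z[cbind(seq_len(m), match(design$animal, ped$id))] <- 1
  A <- relationship_matrix(ped)          # dense tabular A
  M <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * solve(A)))
  Minv <- solve(M)
  ix <- p + match(animals, ped$id)
  out <- Minv[ix, ix, drop = FALSE] * sigma_e
  dimnames(out) <- list(animals, animals)
  out
}

# Random acyclic pedigree: animals arrive in order; each picks a sire
# among earlier males and a dam among earlier females with probability
# p_known per side.
random_pedigree <- function(n = 30, p_known = 0.8, n_founders = 6,
                            n_flocks = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  id <- paste0("R", seq_len(n))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")   # guarantee both sexes among founders
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i <= n_founders) next
    males <- which(sex[seq_len(i - 1)] == "M")
    females <- which(sex[seq_len(i - 1)] == "F")
    if (length(males) && runif(1) < p_known)
      sire[i] <- id[sample(males, 1)]
    if (length(females) && runif(1) < p_known)
      dam[i] <- id[sample(females, 1)]
  }
  pedigree(id = id, sire = sire, dam = dam, sex = sex,
           birth_year = 2000L + (seq_len(n) %/% 3L),
           flock = paste0("U", 1 + (seq_len(n) %% n_flocks)))
}

# Records design putting every non-founder with a flock label into its
# flock as one record.
design_from_flocks <- function(ped, only = NULL) {
  keep <- !is.na(ped$flock) & (ped$sire_idx > 0L | ped$dam_idx > 0L)
  if (!is.null(only)) keep <- keep & ped$flock %in% only
  records_design(ped$id[keep], ped$flock[keep])
}

write_ped_csv <- function(ped, path = tempfile(fileext = ".csv")) {
  write_pedigree(ped, path)
  path
}
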