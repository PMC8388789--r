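#' Inbreeding coefficients
#'
#' Computes F for every animal with the Meuwissen & Luo recursion on the
#' topologically ordered pedigree. An unknown parent is treated as an
#' unrelated, non-inbred founder, so F accrues only through fully known
#' parental paths; F of a non-founder with both parents known equals the
#' kinship of its parents.
#'
#' @param ped A validated, acyclic [pedigree()] object.
#' @return Named numeric vector of F values in \[0, 1).
#' @examples
#' # offspring of full sibs: F = 0.25
#' ped <- pedigree(id = c("S", "D", "A", "B", "X"),
#'                 sire = c(NA, NA, "S", "S", "A"),
#'                 dam = c(NA, NA, "D", "D", "B"))
#' inbreeding(ped)["X"]
#' @export
inbreeding <- function(ped) {
  stop_if_cyclic(ped)
  setNames(ml_inbreeding(ped$sire_idx, ped$dam_idx), ped$id)
}

# dense numerator relationship matrix over a topologically ordered
# index subset (must be ancestor-closed); classic tabular recursion
tabular_A <- function(sire_idx, dam_idx) {
  n <- length(sire_idx)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire_idx[i]; d <- dam_idx[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (s > 0L) A[j, s] else 0) +
                    (if (d > 0L) A[j, d] else 0))
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + (if (s > 0L && d > 0L) 0.5 * A[s, d] else 0)
  }
  A
}

# ancestor closure of a set of positions, with parent indices remapped
# into the reduced (still topological) ordering
ancestor_closure <- function(ped, ix) {
  keep <- logical(n_animals(ped))
  keep[ix] <- TRUE
  for (i in rev(seq_len(n_animals(ped)))) {
    if (!keep[i]) next
    if (ped$sire_idx[i] > 0L) keep[ped$sire_idx[i]] <- TRUE
    if (ped$dam_idx[i] > 0L) keep[ped$dam_idx[i]] <- TRUE
  }
  sub <- which(keep)
  pos <- integer(n_animals(ped)); pos[sub] <- seq_along(sub)
  remap <- function(p) ifelse(p > 0L, pos[pmax(p, 1L)], 0L)
  list(sub = sub,
       sire = as.integer(remap(ped$sire_idx[sub])),
       dam = as.integer(remap(ped$dam_idx[sub])))
}

#' Pairwise kinship (coancestry) matrix
#'
#' Kinship C_ij is the probability that two alleles drawn at random, one
#' from each animal, are identical by descent; the self-kinship is
#' 0.5 (1 + F_i). Computed by the exact tabular recursion on the
#' numerator relationship matrix A = 2 C, restricted to the ancestor
#' closure of the requested animals (no approximation, bounded memory).
#'
#' @param ped A validated, acyclic [pedigree()] object.
#' @param ids Animals to include (default: all).
#' @return Symmetric numeric matrix of kinships with `ids` as dimnames.
#' @seealso [relationship_matrix()] for A = 2 C.
#' @export
kinship <- function(ped, ids = ped$id) {
  relationship_matrix(ped, ids) / 2
}

#' Numerator relationship matrix
#'
#' @inheritParams kinship
#' @return Symmetric matrix A with A_ii = 1 + F_i; equals twice the
#'   kinship matrix.
#' @export
relationship_matrix <- function(ped, ids = ped$id) {
  stop_if_cyclic(ped)
  if (!length(ids)) stop("ids must be non-empty")
  ix <- ped_index(ped, ids)
  cl <- ancestor_closure(ped, ix)
  A <- tabular_A(cl$sire, cl$dam)
  at <- match(ix, cl$sub)
  out <- A[at, at, drop = FALSE]
  dimnames(out) <- list(as.character(ids), as.character(ids))
  out
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A^-1 directly from the pedigree by the Henderson/Quaas
#' rules, with the Mendelian sampling variance adjusted for parental
#' inbreeding (d_i = 0.5 - 0.25 (F_s + F_d) with both parents known,
#' 0.75 - 0.25 F_p with one, 1 with none).
#'
#' @param ped A validated, acyclic [pedigree()] object.
#' @return A sparse symmetric [Matrix::Matrix()] with dimnames `ped$id`.
#' @export
a_inverse <- function(ped) {
  stop_if_cyclic(ped)
  n <- n_animals(ped)
  F <- unname(inbreeding(ped))
  s <- ped$sire_idx; d <- ped$dam_idx
  fs <- ifelse(s > 0L, F[pmax(s, 1L)], 0)
  fd <- ifelse(d > 0L, F[pmax(d, 1L)], 0)
  di <- ifelse(s > 0L & d > 0L, 0.5 - 0.25 * (fs + fd),
        ifelse(s > 0L | d > 0L, 0.75 - 0.25 * (fs + fd), 1))
  alpha <- 1 / di
  i <- seq_len(n)
  ii <- c(i); jj <- c(i); xx <- c(alpha)                    # (i,i)
  ks <- which(s > 0L); kd <- which(d > 0L)
  ii <- c(ii, ks, s[ks], kd, d[kd])
  jj <- c(jj, s[ks], ks, d[kd], kd)
  xx <- c(xx, rep(-alpha[ks] / 2, 2), rep(-alpha[kd] / 2, 2))
  ii <- c(ii, s[ks], d[kd])                                 # (p,p)
  jj <- c(jj, s[ks], d[kd])
  xx <- c(xx, alpha[ks] / 4, alpha[kd] / 4)
  kb <- which(s > 0L & d > 0L)                              # (s,d) cross
  ii <- c(ii, s[kb], d[kb]); jj <- c(jj, d[kb], s[kb])
  xx <- c(xx, rep(alpha[kb] / 4, 2))
  out <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                              dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(out)
}

#' Generation interval from mid-parent ages
#'
#' For every offspring with both parental birth years known, the
#' mid-parent age is the mean of (offspring year - sire year) and
#' (offspring year - dam year); the generation interval is the mean
#' mid-parent age over all eligible offspring. As a secondary estimate,
#' the mean over the four parent-sex pathways (sire/dam age at birth of
#' male/female offspring) is also reported.
#'
#' @param ped A [pedigree()] object with birth years.
#' @return A list: `gi` (mean mid-parent age), `gi_pathway` (mean of the
#'   four pathway means), `mid_parent_age` (named vector per eligible
#'   offspring) and `n` (number of eligible offspring).
#' @export
generation_interval <- function(ped) {
  s <- ped$sire_idx; d <- ped$dam_idx; y <- ped$birth_year
  ok <- s > 0L & d > 0L & !is.na(y)
  ok[ok] <- !is.na(y[s[ok]]) & !is.na(y[d[ok]])
  if (!any(ok)) stop("no offspring with both parental birth years known")
  mpa <- ((y[ok] - y[s[ok]]) + (y[ok] - y[d[ok]])) / 2
  male <- ok & !is.na(ped$sex) & ped$sex == "M"
  female <- ok & !is.na(ped$sex) & ped$sex == "F"
  path <- c(
    sire_male = mean((y - y[pmax(s, 1L)])[male]),
    sire_female = mean((y - y[pmax(s, 1L)])[female]),
    dam_male = mean((y - y[pmax(d, 1L)])[male]),
    dam_female = mean((y - y[pmax(d, 1L)])[female]))
  list(gi = mean(mpa),
       gi_pathway = mean(path, na.rm = TRUE),
       mid_parent_age = setNames(mpa, ped$id[ok]),
       n = sum(ok))
}
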