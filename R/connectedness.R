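#' Records design for connectedness analysis
#'
#' Pairs phenotype records with the management unit (flock) in which
#' they were made. Repeated rows represent repeated records on the same
#' animal; no permanent-environment effect is fitted.
#'
#' @param animal Character vector of animal ids (must exist in the
#'   pedigree when the design is used).
#' @param unit Character vector of unit labels, same length.
#' @return An object of class `records_design`: data frame with columns
#'   `animal`, `unit`, plus attribute `units` (sorted unique labels).
#' @export
records_design <- function(animal, unit) {
  if (length(animal) != length(unit)) stop("animal and unit lengths differ")
  if (!length(animal)) stop("design has no records")
  df <- data.frame(animal = as.character(animal), unit = as.character(unit),
                   stringsAsFactors = FALSE)
  structure(df, units = sort(unique(df$unit)), class =
              c("records_design", "data.frame"))
}

#' Build Henderson's mixed-model equations for an animal model
#'
#' Single-trait animal model y = Xb + Zu + e with one fixed-effect level
#' per management unit (no separate intercept) and a random animal
#' effect for every pedigree animal, u ~ N(0, A sigma_u^2). The
#' coefficient matrix is
#' \deqn{M = [X'X, X'Z; Z'X, Z'Z + \lambda A^{-1}]}
#' with \eqn{\lambda = \sigma_e^2/\sigma_u^2 = (1 - h^2)/h^2}. Under
#' this parameterization M is nonsingular, so prediction error
#' (co)variances come from a plain inverse.
#'
#' @param ped A validated, acyclic [pedigree()] object.
#' @param design A [records_design()]; every animal must be in `ped`.
#' @param h2 Heritability in (0, 1); sets the variance ratio.
#' @param sigma_e Residual variance (default 1, so PEV/PEVD are reported
#'   in residual-variance units).
#' @return An object of class `mme_system`: list with the sparse
#'   coefficient matrix `M`, `lambda`, `sigma_e`, `sigma_u`, `units`,
#'   `animal_ids`, the design, and index offsets.
#' @export
build_mme <- function(ped, design, h2 = 0.3, sigma_e = 1) {
  stop_if_cyclic(ped)
  if (!inherits(design, "records_design"))
    design <- records_design(design$animal, design$unit)
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)")
  if (sigma_e <= 0) stop("sigma_e must be positive")
  units <- attr(design, "units")
  if (any(!table(factor(design$unit, levels = units))))
    stop("every unit must have at least one record")
  aidx <- ped_index(ped, design$animal)
  lambda <- (1 - h2) / h2
  m <- nrow(design); p <- length(units); n <- n_animals(ped)
  X <- Matrix::sparseMatrix(i = seq_len(m),
                            j = match(design$unit, units),
                            x = 1, dims = c(m, p))
  Z <- Matrix::sparseMatrix(i = seq_len(m), j = aidx, x = 1,
                            dims = c(m, n))
  Ainv <- a_inverse(ped)
  M <- rbind(cbind(Matrix::crossprod(X), Matrix::crossprod(X, Z)),
             cbind(Matrix::crossprod(Z, X),
                   Matrix::crossprod(Z) + lambda * Ainv))
  structure(list(M = M, lambda = lambda, sigma_e = sigma_e,
                 sigma_u = sigma_e / lambda, units = units,
                 animal_ids = ped$id, design = design,
                 n_units = p, n_animals = n),
            class = "mme_system")
}

#' Prediction error (co)variances of estimated breeding values
#'
#' Extracts PEV (diagonal) and PEC (off-diagonal) for the requested
#' animals: the animal block C22 of the inverse coefficient matrix,
#' scaled by the residual variance. The sparse symmetric system is
#' factorized once (Cholesky) and solved for the requested columns only.
#'
#' @param mme An [build_mme()] system.
#' @param animals Animal ids (default: all recorded animals).
#' @return Symmetric matrix with `animals` as dimnames; entries in
#'   residual-variance units.
#' @export
pev_pec <- function(mme, animals = unique(mme$design$animal)) {
  animals <- as.character(animals)
  ix <- match(animals, mme$animal_ids)
  if (anyNA(ix)) stop("unknown animal id(s): ",
                      paste(animals[is.na(ix)], collapse = ", "))
  cols <- mme$n_units + ix
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(mme$M),
                                  LDL = FALSE, perm = TRUE),
                 error = function(e)
                   stop("coefficient matrix is singular: ",
                        conditionMessage(e)))
  rhs <- Matrix::sparseMatrix(i = cols, j = seq_along(cols), x = 1,
                              dims = c(nrow(mme$M), length(cols)))
  sol <- Matrix::solve(ch, rhs)
  out <- as.matrix(sol[cols, , drop = FALSE]) * mme$sigma_e
  out <- (out + t(out)) / 2
  dimnames(out) <- list(animals, animals)
  out
}

# animal -> unit membership of the *distinct* recorded animals;
# aggregation runs over recorded animals per unit
unit_membership <- function(design) {
  d <- unique(data.frame(animal = design$animal, unit = design$unit,
                         stringsAsFactors = FALSE))
  split(d$animal, factor(d$unit, levels = attr(design, "units")))
}

#' Individual-average PEVD between management units
#'
#' Pairwise prediction error variance of EBV differences,
#' PEVD(u_i - u_j) = PEV_i + PEV_j - 2 PEC_ij, averaged over all
#' animal pairs crossing two units (weight 1/(n_i' n_j')). The diagonal
#' holds the within-unit pair average for reference; summaries exclude
#' it.
#'
#' @param pp A [pev_pec()] matrix covering all recorded animals.
#' @param design The [records_design()].
#' @return Symmetric unit x unit matrix.
#' @export
pevd_ind <- function(pp, design) {
  mem <- unit_membership(design)
  u <- names(mem); p <- length(u)
  out <- matrix(0, p, p, dimnames = list(u, u))
  for (a in seq_len(p)) for (b in seq_len(a)) {
    ia <- mem[[a]]; ib <- mem[[b]]
    if (a == b) {
      if (length(ia) < 2L) { out[a, a] <- 0; next }
      blk <- pp[ia, ia, drop = FALSE]
      pr <- upper.tri(blk)
      pv <- diag(blk)
      out[a, a] <- mean(outer(pv, pv, "+")[pr] - 2 * blk[pr])
    } else {
      blk <- pp[ia, ib, drop = FALSE]
      val <- mean(outer(diag(pp)[ia], diag(pp)[ib], "+") - 2 * blk)
      out[a, b] <- out[b, a] <- val
    }
  }
  out
}

#' Group-average PEVD between management units
#'
#' Prediction error variance of the difference between unit-mean EBVs:
#' PEV of the mean of unit i plus PEV of the mean of unit j minus twice
#' their prediction error covariance, each term a full-block average of
#' the animal-level PEV/PEC (within-unit covariances included).
#' Equivalently the quadratic form w' C22 w sigma_e^2 with contrast
#' weights 1/n_i' and -1/n_j'.
#'
#' @inheritParams pevd_ind
#' @return Symmetric unit x unit matrix (diagonal 0).
#' @export
pevd_group <- function(pp, design) {
  mem <- unit_membership(design)
  u <- names(mem); p <- length(u)
  bm <- function(a, b) mean(pp[mem[[a]], mem[[b]], drop = FALSE])
  out <- matrix(0, p, p, dimnames = list(u, u))
  for (a in seq_len(p)) for (b in seq_len(a)) {
    val <- bm(a, a) + bm(b, b) - 2 * bm(a, b)
    out[a, b] <- out[b, a] <- val
  }
  out
}

#' Coefficient of determination of EBV differences between units
#'
#' Individual-level CD for animals i, j is
#' \deqn{CD_{ij} = 1 - \lambda (C^{22}_{ii} + C^{22}_{jj} - 2 C^{22}_{ij})
#'   / (K_{ii} + K_{jj} - 2 K_{ij})}
#' with K the numerator relationship matrix. The unit-level statistic
#' aggregates numerator and denominator over all cross-unit pairs
#' (ratio of the summed PEVD to sigma_u^2 times the summed relationship
#' contrast), so it equals 1 minus summed-PEVD / (sigma_u^2 * summed K
#' contrast).
#'
#' @inheritParams pevd_ind
#' @param K Numerator relationship submatrix over the recorded animals
#'   (see [relationship_matrix()]), same ordering as `pp`.
#' @param lambda,sigma_e Variance ratio and residual variance of the
#'   system (take them from the `mme_system`).
#' @return Symmetric unit x unit matrix. The diagonal holds the
#'   within-unit aggregate (self-pairs contribute zero to both sums;
#'   `NA` for single-animal units, whose contrast sum is empty).
#' @export
cd_ind <- function(pp, K, design, lambda, sigma_e = 1) {
  mem <- unit_membership(design)
  u <- names(mem); p <- length(u)
  sigma_u <- sigma_e / lambda
  out <- matrix(0, p, p, dimnames = list(u, u))
  for (a in seq_len(p)) for (b in seq_len(a)) {
    ia <- mem[[a]]; ib <- mem[[b]]
    num <- sum(outer(diag(pp)[ia], diag(pp)[ib], "+") -
               2 * pp[ia, ib, drop = FALSE])
    den <- sum(outer(diag(K)[ia], diag(K)[ib], "+") -
               2 * K[ia, ib, drop = FALSE]) * sigma_u
    if (a == b && (length(ia) < 2L || den <= 0)) {
      out[a, a] <- NA_real_
      next
    }
    if (den <= 0)
      stop("degenerate relationship structure between units ", u[a],
           " and ", u[b], " (zero relationship contrast: units of clones)")
    val <- 1 - num / den
    out[a, b] <- out[b, a] <- val
  }
  out
}

#' Prediction error correlation between management units
#'
#' Flock-level correlation of EBV prediction errors:
#' \deqn{r_{i'j'} = \sum PEC_{i'j'} /
#'   \sqrt{\sum PEV_{i'i'} \cdot \sum PEV_{j'j'}}}
#' where the numerator sums the full cross-unit PEC block and each
#' denominator term sums the full within-unit block (PEV and within-unit
#' PEC alike), so a unit has correlation 1 with itself.
#'
#' @inheritParams pevd_ind
#' @return Symmetric unit x unit matrix with unit diagonal; entries in
#'   \[-1, 1\].
#' @export
r_stat <- function(pp, design) {
  mem <- unit_membership(design)
  u <- names(mem); p <- length(u)
  ssum <- vapply(seq_len(p), function(a)
    sum(pp[mem[[a]], mem[[a]], drop = FALSE]), 0)
  if (any(ssum <= 0)) stop("unit with non-positive summed PEV block")
  out <- matrix(0, p, p, dimnames = list(u, u))
  for (a in seq_len(p)) for (b in seq_len(a)) {
    val <- sum(pp[mem[[a]], mem[[b]], drop = FALSE]) /
      sqrt(ssum[a] * ssum[b])
    out[a, b] <- out[b, a] <- val
  }
  out
}

#' Individual-level prediction error correlation
#'
#' r_ij = PEC_ij / sqrt(PEV_i PEV_j) for every pair of recorded animals.
#'
#' @inheritParams pevd_ind
#' @return Symmetric animal x animal correlation matrix.
#' @export
r_ind <- function(pp) {
  s <- sqrt(diag(pp))
  pp / outer(s, s)
}

#' Summarize connectedness matrices
#'
#' Per-unit means (mean over the other units, off-diagonal only),
#' overall means over unit pairs, the 4 x 4 Pearson correlation matrix
#' of the vectorized off-diagonal statistics, and a benchmark
#' classification of the overall prediction error correlation
#' (>= 0.10 "superior", >= 0.05 "good", otherwise "insufficient").
#'
#' @param matrices Named list with elements `pevd_ind`, `pevd_group`,
#'   `cd`, `r`: symmetric unit x unit matrices on identical unit sets.
#' @return An object of class `connectedness_summary`: list with
#'   `unit_means` (data frame), `overall` (named numeric),
#'   `cross_correlation` (4 x 4 matrix) and `r_benchmark`.
#' @export
summarize_connectedness <- function(matrices) {
  stopifnot(all(c("pevd_ind", "pevd_group", "cd", "r") %in%
                names(matrices)))
  u <- rownames(matrices$pevd_ind)
  if (length(u) < 2L) stop("at least 2 units are required")
  off <- function(m) m[upper.tri(m)]
  unit_mean <- function(m)
    vapply(seq_along(u), function(k) mean(m[k, -k]), 0)
  um <- data.frame(unit = u,
                   pevd_ind = unit_mean(matrices$pevd_ind),
                   pevd_group = unit_mean(matrices$pevd_group),
                   cd = unit_mean(matrices$cd),
                   r = unit_mean(matrices$r), stringsAsFactors = FALSE)
  overall <- c(pevd_ind = mean(off(matrices$pevd_ind)),
               pevd_group = mean(off(matrices$pevd_group)),
               cd = mean(off(matrices$cd)),
               r = mean(off(matrices$r)))
  V <- cbind(pevd_ind = off(matrices$pevd_ind),
             pevd_group = off(matrices$pevd_group),
             cd = off(matrices$cd), r = off(matrices$r))
  cc <- suppressWarnings(cor(V))
  structure(list(unit_means = um, overall = overall,
                 cross_correlation = cc,
                 r_benchmark = r_benchmark(overall[["r"]])),
            class = "connectedness_summary")
}

#' Benchmark classification of prediction error correlation
#'
#' @param r_bar Overall prediction error correlation.
#' @return `"superior"` (>= 0.10), `"good"` (>= 0.05) or
#'   `"insufficient"`.
#' @export
r_benchmark <- function(r_bar) {
  if (r_bar >= 0.10) "superior" else if (r_bar >= 0.05) "good" else
    "insufficient"
}

#' Full connectedness analysis
#'
#' Builds the mixed-model equations, extracts PEV/PEC for all recorded
#' animals, computes the four unit x unit connectedness statistics and
#' their summaries.
#'
#' @inheritParams build_mme
#' @return A list of class `connectedness_result`: `matrices` (the four
#'   unit x unit matrices), `summary` (a [summarize_connectedness()]
#'   object), `n_per_unit`, `h2`, `lambda`, `sigma_e`.
#' @export
connectedness <- function(ped, design, h2 = 0.3, sigma_e = 1) {
  mme <- build_mme(ped, design, h2 = h2, sigma_e = sigma_e)
  rec <- unique(mme$design$animal)
  pp <- pev_pec(mme, rec)
  K <- relationship_matrix(ped, rec)
  mats <- list(pevd_ind = pevd_ind(pp, mme$design),
               pevd_group = pevd_group(pp, mme$design),
               cd = cd_ind(pp, K, mme$design, mme$lambda, mme$sigma_e),
               r = r_stat(pp, mme$design))
  structure(list(matrices = mats,
                 summary = summarize_connectedness(mats),
                 n_per_unit = vapply(unit_membership(mme$design),
                                     length, 0L),
                 h2 = h2, lambda = mme$lambda, sigma_e = sigma_e),
            class = "connectedness_result")
}

#' @export
print.connectedness_result <- function(x, ...) {
  ov <- x$summary$overall
  cat("<connectedness> ", length(x$n_per_unit), " units, h2 = ", x$h2,
      "\n  overall: PEVD_ind = ", format(ov[["pevd_ind"]], digits = 4),
      ", PEVD_group = ", format(ov[["pevd_group"]], digits = 4),
      ", CD = ", format(ov[["cd"]], digits = 4),
      ", r = ", format(ov[["r"]], digits = 4),
      " (", x$summary$r_benchmark, ")\n", sep = "")
  invisible(x)
}
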