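#' Pairwise rate of increase in coancestry
#'
#' For a pair of animals with kinship C_ij and equivalent complete
#' generations g_i and g_j, the per-generation rate of increase in
#' coancestry is
#' \deqn{\Delta C_{ij} = 1 - (1 - C_{ij})^{2/(g_i + g_j)}}
#' i.e. the accumulated coancestry annualized over the mean traced depth
#' (g_i + g_j)/2 of the pair.
#'
#' @param c_ij Kinship value(s) in \[0, 1).
#' @param g_i,g_j Equivalent complete generations of the two animals
#'   (both > 0). Vectors are recycled elementwise.
#' @return Numeric vector of rates in \[0, 1).
#' @examples
#' delta_coancestry(0.25, 1, 1)   # 0.25
#' delta_coancestry(0.25, 4, 4)   # 1 - 0.75^(1/4)
#' @export
delta_coancestry <- function(c_ij, g_i, g_j) {
  if (any(g_i + g_j <= 0))
    stop("g_i + g_j must be positive: the per-generation rate is undefined")
  if (any(c_ij < 0 | c_ij >= 1)) stop("c_ij must lie in [0, 1)")
  1 - (1 - c_ij)^(2 / (g_i + g_j))
}

#' Define a reference population
#'
#' Selects the animals entering the effective-size and inbreeding
#' estimation: a birth-year window, optionally intersected with pedigree
#' quality constraints (minimum PCI, NEG and/or NFG). Animals with an
#' unknown birth year are always excluded.
#'
#' @param ped A [pedigree()] object.
#' @param from,to First and last birth year (inclusive).
#' @param min_pci,min_neg,min_nfg Optional quality thresholds; `NULL`
#'   disables the corresponding constraint.
#' @param quality Optional precomputed [pedigree_quality()] table (saves
#'   recomputation across sliding windows).
#' @return An object of class `reference_population`: list with `ids`,
#'   `nt` (member count), `window = c(from, to)` and the constraints.
#' @export
reference_population <- function(ped, from, to, min_pci = NULL,
                                 min_neg = NULL, min_nfg = NULL,
                                 quality = NULL) {
  if (is.null(quality)) quality <- pedigree_quality(ped)
  keep <- !is.na(ped$birth_year) & ped$birth_year >= from &
    ped$birth_year <= to
  if (!is.null(min_pci)) keep <- keep & quality$pci >= min_pci
  if (!is.null(min_neg)) keep <- keep & quality$neg >= min_neg
  if (!is.null(min_nfg)) keep <- keep & quality$nfg >= min_nfg
  structure(list(ids = ped$id[keep], nt = sum(keep),
                 window = c(from = from, to = to),
                 constraints = list(min_pci = min_pci, min_neg = min_neg,
                                    min_nfg = min_nfg)),
            class = "reference_population")
}

#' Effective population size from the mean coancestry rate
#'
#' Computes the mean of [delta_coancestry()] over all unordered pairs of
#' reference-population members (self-pairs excluded) and estimates
#' \deqn{N_e = 1 / (2 \bar{\Delta C})}
#' Pairs require positive traced depth, so members with NEG = 0 are
#' excluded from the pair set (they carry no coancestry information);
#' the reported mean F averages over all members of the reference
#' population. If the mean rate is zero (all members unrelated), Ne is
#' reported as `Inf`.
#'
#' @param ped A validated, acyclic [pedigree()] object.
#' @param refpop A [reference_population()], or a character vector of
#'   member ids.
#' @param quality Optional precomputed [pedigree_quality()] table.
#' @return An object of class `ne_estimate`: list with `ne`,
#'   `mean_delta_c`, `nt`, `ratio` (Ne/Nt), `mean_f`, `n_pairs` and
#'   `window` (if known).
#' @export
ne_estimate <- function(ped, refpop, quality = NULL) {
  ids <- if (inherits(refpop, "reference_population")) refpop$ids else
    as.character(refpop)
  nt <- length(ids)
  if (nt < 2L) stop("reference population must have at least 2 members")
  if (is.null(quality)) quality <- pedigree_quality(ped)
  g <- quality$neg[match(ids, quality$id)]
  f_all <- inbreeding(ped)[ids]
  use <- g > 0
  if (sum(use) < 2L)
    stop("fewer than 2 members with positive equivalent generations")
  ids_u <- ids[use]; g_u <- g[use]
  C <- kinship(ped, ids_u)
  ut <- upper.tri(C)
  gi <- matrix(g_u, length(g_u), length(g_u))
  dC <- delta_coancestry(pmin(C[ut], 1 - 1e-12), t(gi)[ut], gi[ut])
  mdc <- mean(dC)
  structure(list(ne = if (mdc > 0) 1 / (2 * mdc) else Inf,
                 mean_delta_c = mdc, nt = nt,
                 ratio = if (mdc > 0) 1 / (2 * mdc) / nt else Inf,
                 mean_f = mean(f_all), n_pairs = length(dC),
                 window = if (inherits(refpop, "reference_population"))
                   refpop$window else NULL),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat("<Ne estimate> Ne = ", format(x$ne, digits = 4),
      " (mean dC = ", format(x$mean_delta_c, digits = 4),
      ", Nt = ", x$nt, ", Ne/Nt = ", format(x$ratio, digits = 3),
      ", mean F = ", format(x$mean_f, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Sliding birth-year windows
#'
#' Generates the window templates used for trend analysis: windows of
#' `window_len` consecutive years (inclusive span), advanced by `step`
#' years, each labelled with a 1-based generation number that serves as
#' the regressor in [trend()].
#'
#' @param from,to First and last birth year of the full range.
#' @param window_len Window span in years (a window covers
#'   `start .. start + window_len - 1`).
#' @param step Years between successive window starts.
#' @return A data frame with columns `generation`, `from`, `to`,
#'   `label`.
#' @examples
#' sliding_windows(2012, 2018, window_len = 4)  # 2012-2015 ... 2015-2018
#' @export
sliding_windows <- function(from, to, window_len = 4L, step = 1L) {
  if (window_len < 1L) stop("window_len must be >= 1")
  if (to < from) stop("empty year range")
  starts <- seq(from, to - window_len + 1L, by = step)
  if (!length(starts)) stop("range shorter than one window")
  ends <- starts + window_len - 1L
  data.frame(generation = seq_along(starts), from = starts, to = ends,
             label = paste0(starts, "-", ends), stringsAsFactors = FALSE)
}

#' Per-generation trend by ordinary least squares
#'
#' Regresses a per-window quantity (window-mean F, window Ne, ...) on
#' the 1-based window generation number, so the slope is a
#' per-generation rate.
#'
#' @param values Numeric vector, one value per window, in window order
#'   (>= 3 values; the standard error is undefined at 2).
#' @return An object of class `trend_estimate`: list with `slope`, `se`,
#'   `p_value` (two-sided t test on n - 2 df), `intercept` and `n`.
#' @examples
#' trend(c(92, 85, 78, 73))
#' @export
trend <- function(values) {
  n <- length(values)
  if (n < 3L) stop("at least 3 windows are required for a trend")
  fit <- lm(values ~ x, data = data.frame(values = values, x = seq_len(n)))
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["x", "Estimate"]; se <- sm["x", "Std. Error"]
  # an exact or constant fit leaves only floating-point noise; snap it
  tol <- 1e-10 * max(abs(values), 1)
  if (se < tol) se <- 0
  if (abs(slope) < tol) slope <- 0
  p <- if (se == 0) (if (slope == 0) 1 else 0) else sm["x", "Pr(>|t|)"]
  structure(list(slope = unname(slope), se = unname(se),
                 p_value = unname(p),
                 intercept = unname(coef(fit)["(Intercept)"]), n = n),
            class = "trend_estimate")
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat("<trend> slope = ", format(x$slope, digits = 4), " +/- ",
      format(x$se, digits = 3), " (p = ", format(x$p_value, digits = 3),
      ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Effective size over sliding windows, with trends
#'
#' Applies [ne_estimate()] to each sliding birth-year window under the
#' given quality constraints and regresses both Ne and the window-mean F
#' on the window generation number.
#'
#' @inheritParams reference_population
#' @inheritParams sliding_windows
#' @return A list with `table` (one row per window: generation, years,
#'   ne, nt, ratio, mean_f), `trend_ne` and `trend_f` (each a [trend()]
#'   result, or `NULL` with fewer than 3 windows).
#' @export
ne_windows <- function(ped, from, to, window_len = 4L, step = 1L,
                       min_pci = NULL, min_neg = NULL, min_nfg = NULL,
                       quality = NULL) {
  if (is.null(quality)) quality <- pedigree_quality(ped)
  w <- sliding_windows(from, to, window_len, step)
  rows <- lapply(seq_len(nrow(w)), function(k) {
    rp <- reference_population(ped, w$from[k], w$to[k], min_pci = min_pci,
                               min_neg = min_neg, min_nfg = min_nfg,
                               quality = quality)
    est <- ne_estimate(ped, rp, quality = quality)
    data.frame(generation = w$generation[k], label = w$label[k],
               ne = est$ne, nt = est$nt, ratio = est$ratio,
               mean_f = est$mean_f, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       trend_ne = if (nrow(tab) >= 3L && all(is.finite(tab$ne)))
         trend(tab$ne) else NULL,
       trend_f = if (nrow(tab) >= 3L) trend(tab$mean_f) else NULL)
}
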