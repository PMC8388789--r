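#' Per-generation pedigree completeness
#'
#' For each animal, the proportion of known ancestors in each ancestral
#' generation: generation g has 2^g ancestor slots (2 parents, 4
#' grandparents, ...) and a_g is the fraction of those slots occupied by
#' a known animal. An ancestor appearing in several slots (inbred loops)
#' counts once per slot.
#'
#' @param ped A [pedigree()] object.
#' @param ids Animal ids to report (default: all animals).
#' @param depth Number of ancestral generations d (>= 1).
#' @return A numeric matrix (length(ids) x depth) with rownames `ids`
#'   and columns `g1..gd`; entries in \[0, 1\].
#' @examples
#' ped <- pedigree(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
#'                 dam = c(NA, NA, "B"))
#' completeness(ped, "C", depth = 3)
#' @export
completeness <- function(ped, ids = ped$id, depth = 5L) {
  stop_if_cyclic(ped)
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  n <- n_animals(ped)
  # known-ancestor slot counts, one topological pass per generation
  K <- matrix(0, n, depth)
  s <- ped$sire_idx; d <- ped$dam_idx
  K[, 1L] <- (s > 0L) + (d > 0L)
  if (depth > 1L) for (g in 2:depth) {
    prev <- K[, g - 1L]
    K[, g] <- ifelse(s > 0L, prev[pmax(s, 1L)], 0) +
      ifelse(d > 0L, prev[pmax(d, 1L)], 0)
  }
  A <- sweep(K, 2L, 2^seq_len(depth), "/")
  dimnames(A) <- list(ped$id, paste0("g", seq_len(depth)))
  A[ped_index(ped, ids), , drop = FALSE]
}

# depth-aware internal recursions shared by the per-animal metrics;
# all run in one pass over the topologically ordered pedigree
quality_vectors <- function(ped, pci_depth = 5L) {
  stop_if_cyclic(ped)
  n <- n_animals(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  neg <- nfg <- nmg <- numeric(n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    neg[i] <- (if (si > 0L) 0.5 + 0.5 * neg[si] else 0) +
      (if (di > 0L) 0.5 + 0.5 * neg[di] else 0)
    nmg[i] <- max(if (si > 0L) 1 + nmg[si] else 0,
                  if (di > 0L) 1 + nmg[di] else 0)
    nfg[i] <- if (si > 0L && di > 0L) 1 + min(nfg[si], nfg[di]) else 0
  }
  # PCI: side completeness over pci_depth generations; the parent itself
  # is generation 1 of its side, the parent's a_g shift to g + 1
  A <- completeness(ped, depth = max(pci_depth - 1L, 1L))
  cum <- if (pci_depth > 1L)
    rowSums(A[, seq_len(pci_depth - 1L), drop = FALSE]) else numeric(n)
  side <- function(p) ifelse(p > 0L, (1 + cum[pmax(p, 1L)]) / pci_depth, 0)
  cf <- side(s); cm <- side(d)
  pci <- ifelse(cf + cm > 0, 2 * cf * cm / (cf + cm), 0)
  list(neg = neg, nfg = as.integer(nfg), nmg = as.integer(nmg),
       pci = pci, cf = cf, cm = cm)
}

#' Equivalent complete generations (NEG)
#'
#' Sum over all known ancestor slots of (1/2)^g, where g is the slot's
#' generation: 1/2 per known parent, 1/4 per known grandparent, and so
#' on, over all traced generations (no depth cap).
#'
#' @inheritParams completeness
#' @return Named numeric vector of NEG values.
#' @export
neg <- function(ped, ids = ped$id) {
  v <- quality_vectors(ped)$neg
  setNames(v[ped_index(ped, ids)], as.character(ids))
}

#' Number of fully traced generations (NFG)
#'
#' The largest g such that every ancestor slot in every generation up to
#' g is known (0 for a founder).
#'
#' @inheritParams completeness
#' @return Named integer vector.
#' @export
nfg <- function(ped, ids = ped$id) {
  v <- quality_vectors(ped)$nfg
  setNames(v[ped_index(ped, ids)], as.character(ids))
}

#' Number of maximum generations traced (NMG)
#'
#' Length of the longest known ancestral path (0 for a founder).
#'
#' @inheritParams completeness
#' @return Named integer vector.
#' @export
nmg <- function(ped, ids = ped$id) {
  v <- quality_vectors(ped)$nmg
  setNames(v[ped_index(ped, ids)], as.character(ids))
}

#' Pedigree completeness index (PCI)
#'
#' Harmonic mean of the paternal- and maternal-side pedigree
#' completeness, each the mean over `depth` generations of the
#' per-generation proportion of known ancestors on that side (the parent
#' itself counting as generation 1 of its side). The harmonic mean
#' weights the less complete side more heavily, so PCI is zero whenever
#' either parent is unknown.
#'
#' @inheritParams completeness
#' @param depth Number of generations d over which each side's
#'   completeness is averaged (default 5).
#' @return Named numeric vector in \[0, 1\].
#' @export
pci <- function(ped, ids = ped$id, depth = 5L) {
  v <- quality_vectors(ped, pci_depth = depth)$pci
  setNames(v[ped_index(ped, ids)], as.character(ids))
}

#' Per-animal pedigree quality table
#'
#' @inheritParams pci
#' @param pci_depth Generations used for the PCI side means.
#' @return A data frame with columns `id`, `pci`, `neg`, `nfg`, `nmg`.
#' @export
pedigree_quality <- function(ped, pci_depth = 5L) {
  q <- quality_vectors(ped, pci_depth = pci_depth)
  data.frame(id = ped$id, pci = q$pci, neg = q$neg, nfg = q$nfg,
             nmg = q$nmg, stringsAsFactors = FALSE)
}

#' Summary statistics of the pedigree quality metrics
#'
#' @inheritParams pedigree_quality
#' @return A data frame with one row per metric (NEG, NFG, NMG, PCI) and
#'   columns `min`, `max`, `median`, `mean`.
#' @export
quality_summary <- function(ped, pci_depth = 5L) {
  q <- pedigree_quality(ped, pci_depth = pci_depth)
  m <- q[, c("neg", "nfg", "nmg", "pci")]
  out <- data.frame(
    metric = c("NEG", "NFG", "NMG", "PCI"),
    min = vapply(m, min, 0), max = vapply(m, max, 0),
    median = vapply(m, median, 0), mean = vapply(m, mean, 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Frequency distribution table
#'
#' Bins values and reports frequency, percentage and cumulative
#' percentage per bin, the layout used for reporting the distribution of
#' completeness and inbreeding metrics across a population. Bins are
#' closed on the right (lowest bin closed on both sides).
#'
#' @param values Numeric vector (non-empty).
#' @param bin_edges Increasing numeric vector of bin edges covering the
#'   data range.
#' @param digits Rounding applied to the percentage columns.
#' @return A data frame with columns `lower`, `upper`, `frequency`,
#'   `pct`, `cum_pct`. Frequencies sum to `length(values)`.
#' @examples
#' distribution_table(c(0.1, 0.3, 0.5, 0.7, 0.9), seq(0, 1, by = 0.2))
#' @export
distribution_table <- function(values, bin_edges, digits = 2L) {
  if (!length(values)) stop("no values to tabulate")
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  if (min(values) < bin_edges[1L] || max(values) > bin_edges[length(bin_edges)])
    stop("bin_edges do not cover the data range")
  b <- cut(values, breaks = bin_edges, include.lowest = TRUE, right = TRUE)
  freq <- as.integer(table(b))
  pct <- 100 * freq / length(values)
  data.frame(lower = bin_edges[-length(bin_edges)],
             upper = bin_edges[-1L],
             frequency = freq,
             pct = round(pct, digits),
             cum_pct = round(cumsum(pct), digits))
}
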