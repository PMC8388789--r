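#' Configuration for the full analysis pipeline
#'
#' @param pedigree A [pedigree()] object or path to a pedigree CSV.
#' @param records Optional [records_design()], or path to a CSV with
#'   columns `animal_id`, `unit`; `NULL` skips the connectedness stage.
#' @param out_dir Output directory (created if absent).
#' @param dialect A [pedigree_dialect()] used when `pedigree` is a path.
#' @param from,to Birth-year range of the sliding-window analysis;
#'   defaults to the observed range of known birth years.
#' @param window_len,step Sliding-window span and step in years.
#' @param min_pci,min_neg,min_nfg Reference-population quality gates
#'   (each `NULL` to disable).
#' @param pci_depth Generations for the PCI side means.
#' @param h2,sigma_e Variance parameters of the connectedness model.
#' @param digits Decimals used in the CSV outputs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(pedigree, records = NULL, out_dir = "pedconnect_out",
                       dialect = pedigree_dialect(), from = NULL, to = NULL,
                       window_len = 4L, step = 1L, min_pci = NULL,
                       min_neg = NULL, min_nfg = NULL, pci_depth = 5L,
                       h2 = 0.3, sigma_e = 1, digits = 4L) {
  structure(list(pedigree = pedigree, records = records, out_dir = out_dir,
                 dialect = dialect, from = from, to = to,
                 window_len = window_len, step = step, min_pci = min_pci,
                 min_neg = min_neg, min_nfg = min_nfg,
                 pci_depth = pci_depth, h2 = h2, sigma_e = sigma_e,
                 digits = digits),
            class = "run_config")
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  df
}

#' Run the full pedigree diversity and connectedness pipeline
#'
#' Orchestrates the complete analysis: pedigree reading and validation
#' (a pedigree with validation errors is rejected), per-animal quality
#' metrics with summary and distribution tables, inbreeding and
#' generation interval, effective size over sliding birth-year windows
#' with per-generation trends, and (when records are supplied) the four
#' connectedness statistics with summaries. All outputs are CSV files in
#' `cfg$out_dir` plus a machine-readable JSON manifest; repeated runs
#' with an identical configuration produce byte-identical files.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory results and the
#'   manifest; side effect: files under `cfg$out_dir`.
#' @export
run_full_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  dg <- cfg$digits
  out <- function(name) file.path(cfg$out_dir, name)
  manifest <- list(parameters = cfg[setdiff(names(cfg),
                                            c("pedigree", "records",
                                              "dialect"))],
                   stages = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", force = TRUE)
  }
  fail <- function(stage, msg) {
    manifest$stages[[stage]] <<- list(status = "FAILED", message = msg)
    write_manifest()
    stop("pipeline stage '", stage, "' failed: ", msg, call. = FALSE)
  }

  # --- stage: pedigree ---
  ped <- if (inherits(cfg$pedigree, "pedigree")) cfg$pedigree else
    read_pedigree(cfg$pedigree, cfg$dialect)
  vr <- validate_pedigree(ped)
  if (nrow(vr$errors))
    fail("validate", paste0(nrow(vr$errors), " validation error(s); first: ",
                            vr$errors$id[1], " [", vr$errors$rule[1], "]"))
  write_pedigree(ped, out("pedigree_normalized.csv"))
  manifest$stages$pedigree <- c(vr$counts,
                                list(warnings = nrow(vr$warnings),
                                     status = "OK"))

  # --- stage: quality ---
  qual <- pedigree_quality(ped, pci_depth = cfg$pci_depth)
  write.csv(round_df(qual, dg), out("quality_per_animal.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(round_df(quality_summary(ped, pci_depth = cfg$pci_depth), dg),
            out("quality_summary.csv"), row.names = FALSE, quote = FALSE)
  write.csv(distribution_table(qual$pci, seq(0, 1, by = 0.2)),
            out("distribution_pci.csv"), row.names = FALSE, quote = FALSE)
  write.csv(distribution_table(qual$nfg,
                               seq(-0.5, max(qual$nfg) + 0.5, by = 1)),
            out("distribution_nfg.csv"), row.names = FALSE, quote = FALSE)
  manifest$stages$quality <- list(n = nrow(qual), status = "OK")

  # --- stage: relatedness ---
  f <- inbreeding(ped)
  write.csv(round_df(data.frame(id = names(f), f = unname(f)), dg),
            out("inbreeding.csv"), row.names = FALSE, quote = FALSE)
  write.csv(distribution_table(f, seq(0, 1, by = 0.1)),
            out("distribution_f.csv"), row.names = FALSE, quote = FALSE)
  gi <- tryCatch(generation_interval(ped), error = function(e) NULL)
  manifest$stages$relatedness <-
    list(mean_f = mean(f),
         generation_interval = if (is.null(gi)) NA else gi$gi,
         status = "OK")

  # --- stage: effective size ---
  yrs <- ped$birth_year[!is.na(ped$birth_year)]
  from <- if (is.null(cfg$from)) min(yrs) else cfg$from
  to <- if (is.null(cfg$to)) max(yrs) else cfg$to
  nw <- tryCatch(
    ne_windows(ped, from, to, cfg$window_len, cfg$step,
               min_pci = cfg$min_pci, min_neg = cfg$min_neg,
               min_nfg = cfg$min_nfg, quality = qual),
    error = function(e) conditionMessage(e))
  if (is.character(nw)) fail("effective_size", nw)
  write.csv(round_df(nw$table, dg), out("ne_windows.csv"),
            row.names = FALSE, quote = FALSE)
  tr <- function(t) if (is.null(t)) list(slope = NA, se = NA,
                                         p_value = NA) else
    t[c("slope", "se", "p_value")]
  trend_tab <- rbind(data.frame(quantity = "ne", tr(nw$trend_ne)),
                     data.frame(quantity = "mean_f", tr(nw$trend_f)))
  write.csv(round_df(trend_tab, dg), out("ne_trend.csv"),
            row.names = FALSE, quote = FALSE)
  manifest$stages$effective_size <-
    list(windows = nrow(nw$table), from = from, to = to,
         ne_slope = if (is.null(nw$trend_ne)) NA else nw$trend_ne$slope,
         status = "OK")

  conn <- NULL
  if (!is.null(cfg$records)) {
    design <- if (inherits(cfg$records, "records_design")) cfg$records
    else {
      df <- read.table(cfg$records, header = TRUE, sep = ",",
                       colClasses = "character")
      nm <- if ("animal_id" %in% names(df)) "animal_id" else "animal"
      records_design(df[[nm]], df$unit)
    }
    conn <- tryCatch(connectedness(ped, design, h2 = cfg$h2,
                                   sigma_e = cfg$sigma_e),
                     error = function(e) conditionMessage(e))
    if (is.character(conn)) fail("connectedness", conn)
    for (nm in names(conn$matrices))
      write.csv(round(conn$matrices[[nm]], dg),
                out(paste0("connectedness_", nm, ".csv")), quote = FALSE)
    write.csv(round_df(conn$summary$unit_means, dg),
              out("connectedness_unit_means.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(round(conn$summary$cross_correlation, dg),
              out("connectedness_cross_correlation.csv"), quote = FALSE)
    manifest$stages$connectedness <-
      list(units = length(conn$n_per_unit),
           overall = as.list(conn$summary$overall),
           r_benchmark = conn$summary$r_benchmark, status = "OK")
  }
  write_manifest()
  invisible(list(pedigree = ped, validation = vr, quality = qual,
                 inbreeding = f, generation_interval = gi,
                 ne = nw, connectedness = conn, manifest = manifest))
}
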