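#' Column dialect for pedigree files
#'
#' Describes how the columns of a delimited pedigree file map onto the
#' canonical fields (id, sire, dam, sex, birth year, flock) and which
#' tokens denote a missing value. Livestock pedigree files vary widely in
#' both respects, so the mapping is explicit rather than guessed.
#'
#' @param id,sire,dam Column names holding the animal and parent labels.
#' @param sex,birth_year,flock Column names for the optional fields, or
#'   `NULL` if the file has no such column.
#' @param missing Character vector of tokens treated as "unknown"
#'   (applied to parents, sex, birth year and flock alike). `NA` and
#'   empty strings are always treated as missing.
#' @param sep Field separator passed to the reader.
#' @return An object of class `pedigree_dialect`.
#' @examples
#' pedigree_dialect(id = "animal", sire = "father", dam = "mother")
#' @export
pedigree_dialect <- function(id = "id", sire = "sire", dam = "dam",
                             sex = "sex", birth_year = "birth_year",
                             flock = "flock", missing = c("0", ".", "NA"),
                             sep = ",") {
  structure(list(id = id, sire = sire, dam = dam, sex = sex,
                 birth_year = birth_year, flock = flock,
                 missing = as.character(missing), sep = sep),
            class = "pedigree_dialect")
}

norm_sex <- function(x) {
  x <- tolower(as.character(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("m", "male", "ram", "sire", "1")] <- "M"
  out[x %in% c("f", "female", "ewe", "dam", "2")] <- "F"
  out
}

#' Construct a pedigree
#'
#' Builds the canonical pedigree object used throughout the package: one
#' record per animal, parents referenced but absent added as founder
#' placeholders, and records placed in topological order (every parent
#' precedes its offspring). Unknown values are `NA`.
#'
#' Placeholder founders get `NA` parents and birth year; their sex is
#' inferred from the role in which they were referenced (sire implies
#' male, dam implies female).
#'
#' If the parent links contain a cycle the affected animals cannot be
#' ordered; they are appended after all orderable animals and their ids
#' are retained (see [validate_pedigree()]). Most downstream operations
#' refuse cyclic pedigrees.
#'
#' @param id Character vector of unique animal labels.
#' @param sire,dam Parent labels (`NA` or missing token for unknown).
#' @param sex Optional sex labels; normalized to `"M"`/`"F"`/`NA`.
#' @param birth_year Optional integer birth years.
#' @param flock Optional flock (management unit) labels.
#' @return An object of class `pedigree`: a list with character fields
#'   `id`, `sire`, `dam`, `sex`, `flock`, integer `birth_year`, integer
#'   parent indices `sire_idx`/`dam_idx` (0 = unknown) and `cyclic_ids`.
#' @seealso [read_pedigree()], [validate_pedigree()], [recode_pedigree()]
#' @export
pedigree <- function(id, sire, dam, sex = NULL, birth_year = NULL,
                     flock = NULL) {
  id <- as.character(id)
  if (anyNA(id) || any(!nzchar(id)))
    stop("animal ids must be non-empty and non-missing")
  if (anyDuplicated(id))
    stop("duplicate animal id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  sire <- as.character(sire); dam <- as.character(dam)
  sire[!is.na(sire) & !nzchar(sire)] <- NA
  dam[!is.na(dam) & !nzchar(dam)] <- NA
  n0 <- length(id)
  sex <- if (is.null(sex)) rep(NA_character_, n0) else norm_sex(sex)
  birth_year <- if (is.null(birth_year)) rep(NA_integer_, n0) else
    suppressWarnings(as.integer(birth_year))
  flock <- if (is.null(flock)) rep(NA_character_, n0) else as.character(flock)

  # founder placeholders for referenced-but-absent parents
  miss_s <- setdiff(stats::na.omit(unique(sire)), id)
  miss_d <- setdiff(stats::na.omit(unique(dam)), id)
  miss_d <- setdiff(miss_d, miss_s)  # dual-role ids flagged by validate()
  if (length(miss_s) || length(miss_d)) {
    ph <- c(miss_s, miss_d)
    id <- c(id, ph)
    sire <- c(sire, rep(NA_character_, length(ph)))
    dam <- c(dam, rep(NA_character_, length(ph)))
    sex <- c(sex, rep("M", length(miss_s)), rep("F", length(miss_d)))
    birth_year <- c(birth_year, rep(NA_integer_, length(ph)))
    flock <- c(flock, rep(NA_character_, length(ph)))
  }
  n <- length(id)
  pos <- setNames(seq_len(n), id)
  si <- ifelse(is.na(sire), 0L, pos[sire])
  di <- ifelse(is.na(dam), 0L, pos[dam])
  si[is.na(si)] <- 0L; di[is.na(di)] <- 0L

  # Kahn's algorithm over parent -> offspring edges
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (k in seq_len(n)) {
    if (si[k] > 0L) children[[si[k]]] <- c(children[[si[k]]], k)
    if (di[k] > 0L) children[[di[k]]] <- c(children[[di[k]]], k)
  }
  order_out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order_out <- c(order_out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  cyclic <- setdiff(seq_len(n), order_out)
  ord <- c(order_out, cyclic)

  newpos <- integer(n); newpos[ord] <- seq_len(n)
  remap <- function(ix) ifelse(ix > 0L, newpos[pmax(ix, 1L)], 0L)
  structure(list(
    id = id[ord], sire = sire[ord], dam = dam[ord], sex = sex[ord],
    birth_year = birth_year[ord], flock = flock[ord],
    sire_idx = as.integer(remap(si)[ord]), dam_idx = as.integer(remap(di)[ord]),
    cyclic_ids = id[cyclic]
  ), class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree> ", n_animals(x), " animals (",
      sum(x$sire_idx == 0L & x$dam_idx == 0L), " founders, ",
      length(unique(stats::na.omit(x$flock))), " flocks)\n", sep = "")
  if (length(x$cyclic_ids))
    cat("  ! contains parentage cycles involving:",
        paste(x$cyclic_ids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.pedigree <- function(x, ...) {
  data.frame(id = x$id, sire = x$sire, dam = x$dam, sex = x$sex,
             birth_year = x$birth_year, flock = x$flock,
             stringsAsFactors = FALSE)
}

#' Number of animals in a pedigree
#' @param ped A [pedigree()] object.
#' @return Integer count including placeholder founders.
#' @export
n_animals <- function(ped) length(ped$id)

ped_index <- function(ped, ids) {
  ix <- match(as.character(ids), ped$id)
  if (anyNA(ix))
    stop("unknown animal id(s): ",
         paste(ids[is.na(ix)], collapse = ", "))
  ix
}

stop_if_cyclic <- function(ped) {
  if (length(ped$cyclic_ids))
    stop("pedigree contains parentage cycles (",
         paste(ped$cyclic_ids, collapse = ", "),
         "); fix the input before analysis")
  invisible(ped)
}

#' Read a pedigree from a delimited text file
#'
#' @param path Path to a delimited file with a header row.
#' @param dialect A [pedigree_dialect()] mapping columns and missing codes.
#' @return A [pedigree()] object in topological order, with founder
#'   placeholders for any parent referenced without its own row.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,sire,dam,sex,birth_year,flock",
#'              "A,0,0,M,2010,1", "B,0,0,F,2010,1", "C,A,B,F,2013,1"), f)
#' read_pedigree(f)
#' @export
read_pedigree <- function(path, dialect = pedigree_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = dialect$sep,
                   colClasses = "character", check.names = FALSE,
                   quote = "\"", comment.char = "", strip.white = TRUE)
  need <- c(dialect$id, dialect$sire, dialect$dam)
  if (!all(need %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  getcol <- function(nm) {
    if (is.null(nm) || !nm %in% names(df)) return(NULL)
    v <- df[[nm]]
    v[v %in% dialect$missing | !nzchar(v)] <- NA
    v
  }
  idv <- df[[dialect$id]]
  bad <- which(is.na(idv) | !nzchar(idv) | idv %in% dialect$missing)
  if (length(bad))
    stop("unparseable row(s) with empty/missing id at line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for header
  if (anyDuplicated(idv))
    stop("duplicate animal id(s): ",
         paste(unique(idv[duplicated(idv)]), collapse = ", "))
  pedigree(id = idv, sire = getcol(dialect$sire), dam = getcol(dialect$dam),
           sex = getcol(dialect$sex), birth_year = getcol(dialect$birth_year),
           flock = getcol(dialect$flock))
}

#' Write a pedigree to CSV in the normalized column layout
#'
#' Columns are always `id,sire,dam,sex,birth_year,flock`; unknown parents
#' are written as `"0"`, other unknown fields as empty strings.
#'
#' @param ped A [pedigree()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  df$sex[is.na(df$sex)] <- ""
  df$flock[is.na(df$flock)] <- ""
  yr <- ifelse(is.na(df$birth_year), "", as.character(df$birth_year))
  df$birth_year <- yr
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a pedigree
#'
#' Checks structural rules and returns a report rather than stopping.
#' Errors: parentage cycles, an animal being its own parent, sire equal
#' to dam (selfing; sheep are dioecious), ids used both as sire and as
#' dam, and sex-inconsistent parents (recorded female used as sire or
#' vice versa). Warnings: offspring born in or before a parent's birth
#' year (historic records commonly contain such gaps, and birth-year
#' windows simply exclude animals with unknown year).
#'
#' @param ped A [pedigree()] object.
#' @return A `pedigree_validation` object: data frames `errors` and
#'   `warnings` (columns `id`, `rule`, `detail`) and a list `counts`
#'   (animals, founders, sires, dams, flocks).
#' @export
validate_pedigree <- function(ped) {
  err <- list(); wrn <- list()
  add <- function(lst, id, rule, detail = "") {
    c(lst, list(data.frame(id = id, rule = rule, detail = detail,
                           stringsAsFactors = FALSE)))
  }
  if (length(ped$cyclic_ids))
    err <- add(err, ped$cyclic_ids, "cycle",
               "animal is its own ancestor")
  self_par <- which(!is.na(ped$sire) & ped$sire == ped$id |
                    !is.na(ped$dam) & ped$dam == ped$id)
  if (length(self_par))
    err <- add(err, ped$id[self_par], "self-parent",
               "animal listed as its own parent")
  selfing <- which(!is.na(ped$sire) & !is.na(ped$dam) & ped$sire == ped$dam)
  if (length(selfing))
    err <- add(err, ped$id[selfing], "selfing",
               paste0("sire equals dam (", ped$sire[selfing], ")"))
  sires <- unique(stats::na.omit(ped$sire))
  dams <- unique(stats::na.omit(ped$dam))
  dual <- intersect(sires, dams)
  if (length(dual))
    err <- add(err, dual, "dual-role", "used both as sire and as dam")
  bad_sire <- sires[!is.na(ped$sex[match(sires, ped$id)]) &
                    ped$sex[match(sires, ped$id)] == "F"]
  if (length(bad_sire))
    err <- add(err, bad_sire, "sex-inconsistency",
               "recorded female but used as sire")
  bad_dam <- dams[!is.na(ped$sex[match(dams, ped$id)]) &
                  ped$sex[match(dams, ped$id)] == "M"]
  if (length(bad_dam))
    err <- add(err, bad_dam, "sex-inconsistency",
               "recorded male but used as dam")
  for (side in c("sire_idx", "dam_idx")) {
    p <- ped[[side]]
    ok <- p > 0L & !is.na(ped$birth_year)
    ok[ok] <- !is.na(ped$birth_year[p[ok]]) &
      ped$birth_year[ok] <= ped$birth_year[p[ok]]
    if (any(ok))
      wrn <- add(wrn, ped$id[ok], "birth-year",
                 paste0("born ", ped$birth_year[ok], ", ",
                        sub("_idx", "", side), " born ",
                        ped$birth_year[p[ok]]))
  }
  empty <- data.frame(id = character(0), rule = character(0),
                      detail = character(0), stringsAsFactors = FALSE)
  structure(list(
    errors = if (length(err)) do.call(rbind, err) else empty,
    warnings = if (length(wrn)) do.call(rbind, wrn) else empty,
    counts = list(animals = n_animals(ped),
                  founders = sum(ped$sire_idx == 0L & ped$dam_idx == 0L),
                  sires = length(sires), dams = length(dams),
                  flocks = length(unique(stats::na.omit(ped$flock))))
  ), class = "pedigree_validation")
}

#' @export
print.pedigree_validation <- function(x, ...) {
  cat("<pedigree validation> ", x$counts$animals, " animals, ",
      x$counts$founders, " founders, ", x$counts$sires, " sires, ",
      x$counts$dams, " dams, ", x$counts$flocks, " flocks\n", sep = "")
  cat("  errors: ", nrow(x$errors), ", warnings: ", nrow(x$warnings),
      "\n", sep = "")
  invisible(x)
}

#' Recode animal labels to consecutive integers
#'
#' Assigns integer codes 1..n in topological order (so every parent's
#' code is smaller than its offspring's). The mapping is a bijection;
#' applying it in reverse recovers the original labels.
#'
#' @param ped A validated, acyclic [pedigree()] object.
#' @return A list with `pedigree` (the recoded pedigree) and `map`
#'   (named integer vector, original id -> code).
#' @export
recode_pedigree <- function(ped) {
  stop_if_cyclic(ped)
  n <- n_animals(ped)
  map <- setNames(seq_len(n), ped$id)
  code <- as.character(seq_len(n))
  par <- function(ix) ifelse(ix > 0L, code[pmax(ix, 1L)], NA_character_)
  list(pedigree = pedigree(id = code, sire = par(ped$sire_idx),
                           dam = par(ped$dam_idx), sex = ped$sex,
                           birth_year = ped$birth_year, flock = ped$flock),
       map = map)
}
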