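MEASUREMENT_CHARS <- c("SVL", "HL", "HW", "SL", "IND", "IOD", "ED",
                       "TD", "TED", "HNL", "FAL", "TL", "FTL")

#' Read a specimen measurement table
#'
#' Reads a table of the 13 standard linear measurements (mm, 0.1 mm
#' precision): snout--vent length (SVL), head length (HL), head width (HW),
#' snout length (SL), internasal distance (IND), interorbital distance
#' (IOD), eye diameter (ED), tympanum diameter (TD), tympanum--eye distance
#' (TED), hand length (HNL), forearm length (FAL), tibial length (TL) and
#' foot length (FTL). Both orientations are auto-detected: one row per
#' specimen (columns `specimen_id`, `sex`, then the characters) or one
#' column per specimen (rows `Sex`, then the characters; header row of
#' specimen IDs).
#'
#' @param path delimited text file (TSV or CSV; the delimiter is sniffed).
#' @return a data.frame of class `specimen_table`, one row per specimen,
#'   with columns `specimen_id`, `sex` (`male`/`female`/`unknown`) and the
#'   13 measurements. Missing cells are `NA` and reported in attribute
#'   `missing_cells`.
#' @export
read_measurements <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0 && ncol(raw) <= 1) return(empty_specimen_table())
  wide <- any(MEASUREMENT_CHARS %in% names(raw))
  if (!wide) {
    labels <- trimws(raw[[1]])
    known <- c("Sex", MEASUREMENT_CHARS)
    bad <- setdiff(labels, known)
    if (length(bad))
      stopf("unknown character name(s): %s (expected: %s)",
            paste(bad, collapse = ", "), paste(known, collapse = ", "))
    ids <- names(raw)[-1]
    df <- as.data.frame(t(raw[, -1, drop = FALSE]),
                        stringsAsFactors = FALSE)
    names(df) <- labels
    df <- cbind(specimen_id = ids, df, stringsAsFactors = FALSE)
    names(df)[names(df) == "Sex"] <- "sex"
    raw <- df
  } else {
    names(raw)[tolower(names(raw)) == "sex"] <- "sex"
    id_col <- which(tolower(names(raw)) %in% c("specimen_id", "id",
                                               "specimen"))[1]
    if (is.na(id_col)) stopf("no specimen id column found")
    names(raw)[id_col] <- "specimen_id"
    bad <- setdiff(names(raw), c("specimen_id", "sex", MEASUREMENT_CHARS))
    if (length(bad))
      stopf("unknown character name(s): %s (expected: %s)",
            paste(bad, collapse = ", "),
            paste(MEASUREMENT_CHARS, collapse = ", "))
  }
  if (anyDuplicated(raw$specimen_id))
    stopf("duplicate specimen ID: %s",
          raw$specimen_id[duplicated(raw$specimen_id)][1])
  missing_chars <- setdiff(MEASUREMENT_CHARS, names(raw))
  if (length(missing_chars))
    stopf("measurement column(s) absent: %s",
          paste(missing_chars, collapse = ", "))
  missing_cells <- character(0)
  for (ch in MEASUREMENT_CHARS) {
    v <- trimws(raw[[ch]])
    v[v %in% c("", "/", "NA")] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stopf("non-numeric cell: specimen '%s', character %s, value '%s'",
            raw$specimen_id[bad[1]], ch, v[bad[1]])
    if (any(is.na(num)))
      missing_cells <- c(missing_cells,
                         sprintf("%s:%s", raw$specimen_id[is.na(num)], ch))
    if (any(num[!is.na(num)] <= 0))
      stopf("non-positive measurement: character %s", ch)
    raw[[ch]] <- num
  }
  raw$sex <- normalize_sex(raw$sex)
  out <- raw[, c("specimen_id", "sex", MEASUREMENT_CHARS)]
  viol <- which(out$SVL < pmax(out$HL, out$HW))
  if (length(viol))
    warnf("SVL smaller than head dimensions for: %s",
          paste(out$specimen_id[viol], collapse = ", "))
  attr(out, "missing_cells") <- missing_cells
  class(out) <- c("specimen_table", "data.frame")
  out
}

empty_specimen_table <- function() {
  out <- data.frame(specimen_id = character(0), sex = character(0))
  for (ch in MEASUREMENT_CHARS) out[[ch]] <- numeric(0)
  class(out) <- c("specimen_table", "data.frame")
  out
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- ifelse(x %in% c("m", "male"), "male",
         ifelse(x %in% c("f", "female"), "female", "unknown"))
  out
}

#' Write a specimen measurement table
#'
#' Writes the row-per-specimen orientation at 0.1 mm precision, the inverse
#' of [read_measurements()].
#'
#' @param tab a `specimen_table`.
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(tab, path, sep = "\t") {
  out <- as.data.frame(tab)
  for (ch in MEASUREMENT_CHARS)
    out[[ch]] <- formatC(round_half_up(out[[ch]], 1), format = "f",
                         digits = 1)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

get_record <- function(tab, specimen_id) {
  i <- match(specimen_id, tab$specimen_id)
  if (is.na(i)) stopf("specimen '%s' not in table", specimen_id)
  tab[i, ]
}

#' Measurement ratio for one specimen
#'
#' @param record one row of a `specimen_table` (or a named list/vector of
#'   measurements).
#' @param numerator,denominator measurement character names, e.g. `"HW"`,
#'   `"HL"`.
#' @return the ratio rounded half-up to 2 decimals.
#' @export
morpho_ratio <- function(record, numerator, denominator) {
  for (ch in c(numerator, denominator)) {
    if (is.null(record[[ch]]) || is.na(record[[ch]]))
      stopf("measurement '%s' missing from record", ch)
  }
  if (record[[denominator]] <= 0)
    stopf("denominator %s must be > 0", denominator)
  round_half_up(record[[numerator]] / record[[denominator]], 2)
}

HOLOTYPE_RATIOS <- list(
  c("HW", "HL"), c("ED", "HL"), c("TD", "ED"), c("FAL", "SVL"),
  c("HNL", "SVL"), c("TL", "SVL"), c("FTL", "SVL"))

#' Diagnostic ratio report for one specimen
#'
#' Computes the seven ratios conventionally quoted in a horned-toad species
#' description: HW/HL, ED/HL, TD/ED, FAL/SVL, HNL/SVL, TL/SVL and FTL/SVL,
#' each rounded half-up to 2 decimals.
#'
#' @param record one row of a `specimen_table`; all 13 measurements must be
#'   present.
#' @return named numeric vector of class `ratio_report`.
#' @export
holotype_report <- function(record) {
  vals <- vapply(HOLOTYPE_RATIOS, function(r)
    morpho_ratio(record, r[1], r[2]), numeric(1))
  names(vals) <- vapply(HOLOTYPE_RATIOS, paste, character(1), collapse = "/")
  if (is.finite(vals[["TD/ED"]]) && vals[["TD/ED"]] >= 1)
    warnf("TD/ED >= 1 is unusual for this group")
  structure(vals, class = c("ratio_report", "numeric"))
}

#' Sex-grouped size summary
#'
#' @param tab a `specimen_table`.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param character one of the 13 measurement names (default `"SVL"`).
#' @return list with `sex`, `character`, `n`, `min`, `max` (mm at 1
#'   decimal), as quoted in diagnoses such as "adult males, SVL 40.5--44.7
#'   mm (n = 5)".
#' @export
group_summary <- function(tab, sex, character = "SVL") {
  if (!character %in% MEASUREMENT_CHARS)
    stopf("unknown measurement character '%s'", character)
  v <- tab[[character]][tab$sex == sex]
  v <- v[!is.na(v)]
  if (!length(v)) stopf("no '%s' specimens with %s recorded", sex, character)
  list(sex = sex, character = character, n = length(v),
       min = round_half_up(min(v), 1), max = round_half_up(max(v), 1))
}

#' Path to a packaged example data file
#'
#' @param file file name under the package's `extdata` (e.g.
#'   `"table1_lushanensis.tsv"`); with no argument, lists available files.
#' @return a file path, or a vector of file names.
#' @export
toadcall_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "toadcall")))
  path <- system.file("extdata", file, package = "toadcall")
  if (path == "") stopf("no packaged file '%s'", file)
  path
}
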