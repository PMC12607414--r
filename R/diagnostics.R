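TRAIT_CHARS <- c("eyelid_tubercle_large", "vomerine_teeth", "tongue_notched",
                 "heels", "toe_fringes", "toe_webbing")
TRAIT_ATOMS <- c("T", "N", "F")

# "T/N" -> c("T","N"); "/" or "" -> character(0) (missing)
parse_state <- function(cell) {
  cell <- trimws(cell)
  if (is.na(cell) || cell %in% c("", "/", "?")) return(character(0))
  atoms <- unique(trimws(strsplit(cell, "/", fixed = TRUE)[[1]]))
  atoms[atoms != ""]
}

state_label <- function(atoms) {
  if (!length(atoms)) "/" else paste(atoms, collapse = "/")
}

# "40.5–44.7" / "40.5-44.7" / "81.3" -> c(min, max); "/" -> c(NA, NA)
parse_range <- function(cell) {
  cell <- trimws(cell)
  if (is.na(cell) || cell %in% c("", "/")) return(c(NA_real_, NA_real_))
  parts <- strsplit(cell, "–|—|-")[[1]]
  v <- suppressWarnings(as.numeric(trimws(parts)))
  if (any(is.na(v))) stopf("unparseable size range '%s'", cell)
  if (length(v) == 1) v <- c(v, v)
  if (v[1] > v[2]) stopf("size range min exceeds max: '%s'", cell)
  v[1:2]
}

normalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  x <- sub("\\s*sp\\. nov\\.$", "", x)
  sub("^B\\.(?=\\S)", "B. ", x, perl = TRUE)   # "B.hengshanensis" style
}

#' Load a species-by-character diagnostic trait matrix
#'
#' Reads a delimited table with one row per species and the columns
#' `species`, `svl_male_mm`, `svl_female_mm` and six categorical
#' characters: `eyelid_tubercle_large`, `vomerine_teeth`, `tongue_notched`,
#' `heels`, `toe_fringes`, `toe_webbing`. States are coded `T`/`N`/`F`
#' (their meaning differs per character, e.g. for heels: overlapping / just
#' meeting / not meeting); `X/Y` denotes a polymorphic state set and a bare
#' `/` missing data.
#'
#' @param path TSV/CSV path.
#' @param aliases optional named character vector mapping alternate
#'   spellings to the spelling used in the matrix.
#' @return an object of class `trait_matrix`: list with `species`,
#'   `svl_male_mm` / `svl_female_mm` (2-column matrices), `states` (list
#'   per character of state-set lists) and a `parse_report` data.frame of
#'   polymorphic and missing cells.
#' @export
load_trait_matrix <- function(path, aliases = NULL) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  need <- c("species", "svl_male_mm", "svl_female_mm", TRAIT_CHARS)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stopf("trait matrix lacks column(s): %s", paste(miss, collapse = ", "))
  species <- normalize_species(raw$species)
  if (anyDuplicated(species))
    stopf("duplicate species: %s", species[duplicated(species)][1])
  svl_m <- t(vapply(raw$svl_male_mm, parse_range, numeric(2)))
  svl_f <- t(vapply(raw$svl_female_mm, parse_range, numeric(2)))
  dimnames(svl_m) <- dimnames(svl_f) <- list(species, c("min", "max"))
  states <- list()
  report <- data.frame(species = character(0), character = character(0),
                       state = character(0), kind = character(0))
  for (ch in TRAIT_CHARS) {
    sets <- lapply(raw[[ch]], parse_state)
    bad <- which(vapply(sets, function(s) any(!s %in% TRAIT_ATOMS),
                        logical(1)))
    if (length(bad))
      stopf("unknown state symbol '%s' (species '%s', character %s)",
            raw[[ch]][bad[1]], species[bad[1]], ch)
    names(sets) <- species
    states[[ch]] <- sets
    n_atoms <- vapply(sets, length, integer(1))
    flag <- which(n_atoms != 1)
    if (length(flag))
      report <- rbind(report, data.frame(
        species = species[flag], character = ch,
        state = vapply(sets[flag], state_label, character(1)),
        kind = ifelse(n_atoms[flag] == 0, "missing", "polymorphic")))
  }
  structure(list(species = species, svl_male_mm = svl_m,
                 svl_female_mm = svl_f, states = states,
                 aliases = aliases, parse_report = report),
            class = "trait_matrix")
}

resolve_species <- function(m, name) {
  name <- normalize_species(name)
  if (!is.null(m$aliases) && name %in% names(m$aliases))
    name <- unname(m$aliases[name])
  name
}

trait_state <- function(m, species, character) {
  species <- resolve_species(m, species)
  if (!species %in% m$species) stopf("species '%s' not in matrix", species)
  m$states[[character]][[species]]
}

ranges_disjoint <- function(a, b) {
  if (any(is.na(a)) || any(is.na(b))) return(FALSE)
  a[2] < b[1] || b[2] < a[1]
}

#' Characters distinguishing two species
#'
#' A categorical character distinguishes two species only if their state
#' sets are disjoint — overlapping polymorphism is not diagnostic — and
#' missing states never distinguish. Male and female SVL ranges each count
#' only when strictly disjoint within sex.
#'
#' @param m a [load_trait_matrix()] result.
#' @param focal,other species names (aliases are resolved).
#' @return data.frame with columns `character`, `focal_state`,
#'   `other_state`; zero rows when nothing is diagnostic (e.g. a species
#'   against itself).
#' @export
distinguishing_characters <- function(m, focal, other) {
  focal <- resolve_species(m, focal)
  other <- resolve_species(m, other)
  out <- data.frame(character = character(0), focal_state = character(0),
                    other_state = character(0))
  for (sexcol in c("svl_male_mm", "svl_female_mm")) {
    a <- m[[sexcol]][match(focal, m$species), ]
    b <- m[[sexcol]][match(other, m$species), ]
    if (is.na(match(focal, m$species)) || is.na(match(other, m$species)))
      stopf("species not in matrix")
    if (ranges_disjoint(a, b))
      out <- rbind(out, data.frame(
        character = sexcol,
        focal_state = sprintf("%.1f–%.1f", a[1], a[2]),
        other_state = sprintf("%.1f–%.1f", b[1], b[2])))
  }
  for (ch in TRAIT_CHARS) {
    sa <- trait_state(m, focal, ch)
    sb <- trait_state(m, other, ch)
    if (length(sa) && length(sb) && !length(intersect(sa, sb)))
      out <- rbind(out, data.frame(character = ch,
                                   focal_state = state_label(sa),
                                   other_state = state_label(sb)))
  }
  out
}

#' Partition congeners by their state of one character
#'
#' Groups every non-focal species by its state set for `character`.
#' Congeners whose state set intersects the focal species' set (and those
#' with missing data) go into the `not_distinguished` bucket; the remaining
#' buckets are keyed by state label (`"F"`, `"T"`, `"T/N"`, ...), the
#' structure of a comparison paragraph ("distinguished from ... by its
#' vomerine teeth present (vs. absent)").
#'
#' @param m a `trait_matrix`.
#' @param character one of the six categorical characters.
#' @param focal focal species name.
#' @return named list of species-name vectors; every congener appears in
#'   exactly one bucket.
#' @export
partition_by_state <- function(m, character, focal) {
  if (!character %in% TRAIT_CHARS)
    stopf("unknown character '%s'", character)
  focal <- resolve_species(m, focal)
  fs <- trait_state(m, focal, character)
  buckets <- list(not_distinguished = character(0))
  for (sp in setdiff(m$species, focal)) {
    ss <- m$states[[character]][[sp]]
    if (!length(fs) || !length(ss) || length(intersect(fs, ss))) {
      buckets$not_distinguished <- c(buckets$not_distinguished, sp)
    } else {
      lab <- state_label(ss)
      buckets[[lab]] <- c(buckets[[lab]], sp)
    }
  }
  buckets
}

#' Audit published comparison lists against the trait matrix
#'
#' For every species in every claim list (each list asserting "these
#' congeners have state X for character Y"), checks that the matrix state
#' implies that placement: the species must be present in the matrix, its
#' state must not be missing, and its state set must be contained in the
#' claimed state set. Mismatches are findings, not errors: the report is
#' returned for inspection and the function never fails.
#'
#' @param m a `trait_matrix`.
#' @param claims a list with element `claims`, each entry a list with
#'   `character`, `claimed_state` (possibly polymorphic, `"X/Y"`), and
#'   `species` (character vector); see [read_claims()].
#' @return data.frame with columns `species`, `character`, `table_state`,
#'   `claimed_state`, `note`; zero rows when fully consistent.
#' @export
audit_consistency <- function(m, claims) {
  out <- data.frame(species = character(0), character = character(0),
                    table_state = character(0), claimed_state = character(0),
                    note = character(0))
  for (cl in claims$claims) {
    claimed <- parse_state(cl$claimed_state)
    for (sp in cl$species) {
      rsp <- resolve_species(m, sp)
      if (!rsp %in% m$species) {
        out <- rbind(out, data.frame(
          species = sp, character = cl$character, table_state = NA,
          claimed_state = cl$claimed_state, note = "not in matrix"))
        next
      }
      ss <- m$states[[cl$character]][[rsp]]
      if (!length(ss)) {
        out <- rbind(out, data.frame(
          species = sp, character = cl$character, table_state = "/",
          claimed_state = cl$claimed_state, note = "state missing in matrix"))
      } else if (!all(ss %in% claimed)) {
        out <- rbind(out, data.frame(
          species = sp, character = cl$character,
          table_state = state_label(ss), claimed_state = cl$claimed_state,
          note = "matrix state incompatible with list placement"))
      }
    }
  }
  out
}

#' Read a claim-list fixture (JSON or YAML)
#'
#' @param path path to a claims file: an object with `focal`, optional
#'   `aliases` (map of alternate to canonical spellings) and `claims` as
#'   described in [audit_consistency()].
#' @return the parsed list, with `aliases` as a named character vector.
#' @export
read_claims <- function(path) {
  cl <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
        else jsonlite::read_json(path, simplifyVector = FALSE)
  cl$claims <- lapply(cl$claims, function(x) {
    x$species <- as.character(unlist(x$species))
    x
  })
  if (!is.null(cl$aliases)) cl$aliases <- unlist(cl$aliases)
  cl
}

#' Full diagnosability report for a focal species
#'
#' @param m a `trait_matrix`.
#' @param focal focal species name.
#' @return list of class `diagnosis_report`: `focal`, `per_congener` (named
#'   list of [distinguishing_characters()] tables) and `per_character`
#'   (named list of [partition_by_state()] buckets).
#' @export
diagnosis_report <- function(m, focal) {
  focal_r <- resolve_species(m, focal)
  congeners <- setdiff(m$species, focal_r)
  per_congener <- lapply(congeners, function(sp)
    distinguishing_characters(m, focal_r, sp))
  names(per_congener) <- congeners
  per_character <- lapply(TRAIT_CHARS, function(ch)
    partition_by_state(m, ch, focal_r))
  names(per_character) <- TRAIT_CHARS
  structure(list(focal = focal_r, per_congener = per_congener,
                 per_character = per_character),
            class = "diagnosis_report")
}
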