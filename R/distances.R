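#' Aligned sequence sets
#'
#' A light container for a multiple sequence alignment with optional group
#' (species/population) labels. Sequences are stored upper-case with RNA `U`
#' mapped to `T`.
#'
#' @param taxa character vector of unique taxon names.
#' @param sequences character vector of equal-length aligned sequences over
#'   nucleotides, IUPAC ambiguity codes, `N` and `-`.
#' @param group_of named character vector mapping taxon name to group label;
#'   optional.
#' @return an object of class `alignment` with elements `taxa`, `sequences`
#'   (named by taxon) and `group_of`.
#' @export
alignment <- function(taxa, sequences, group_of = NULL) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stopf("duplicate taxon names")
  sequences <- toupper(as.character(sequences))
  sequences <- gsub("U", "T", sequences, fixed = TRUE)
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1)
    stopf("unequal sequence lengths (taxon '%s' has %d bp, expected %d)",
          taxa[which(lens != lens[1])[1]], lens[lens != lens[1]][1], lens[1])
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_OK, collapse = "")), sequences)
  if (any(bad))
    stopf("unknown symbol in sequence of taxon '%s'", taxa[which(bad)[1]])
  names(sequences) <- taxa
  if (!is.null(group_of)) group_of <- group_of[taxa]
  structure(list(taxa = taxa, sequences = sequences, group_of = group_of),
            class = "alignment")
}

# "-" kept last so the set can be spliced into a regex character class
IUPAC_OK <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "?", "-")

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d taxa x %d bp%s\n", length(x$taxa),
              nchar(x$sequences[1]),
              if (is.null(x$group_of)) ""
              else sprintf(", %d groups", length(unique(x$group_of)))))
  invisible(x)
}

#' Read an aligned FASTA file (with optional group labels)
#'
#' @param path FASTA file of equal-length aligned records.
#' @param groups_path optional two-column TSV (`taxon`, `group`), no header
#'   required if exactly two columns.
#' @return an [alignment()].
#' @export
read_fasta_alignment <- function(path, groups_path = NULL) {
  dna <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(dna), names(dna))
  names(seqs) <- sub("\\s.*$", "", names(seqs))  # FASTA id = first token
  grp <- NULL
  if (!is.null(groups_path)) {
    tab <- utils::read.table(groups_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (identical(tolower(unlist(tab[1, ])), c("taxon", "group")))
      tab <- tab[-1, , drop = FALSE]
    grp <- stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
  }
  alignment(names(seqs), seqs, grp)
}

#' Write an alignment to FASTA (and optionally its group table)
#'
#' @param aln an [alignment()].
#' @param path output FASTA path.
#' @param groups_path optional TSV path for the `taxon, group` table.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path, groups_path = NULL) {
  writeLines(paste0(">", aln$taxa, "\n", aln$sequences), path)
  if (!is.null(groups_path) && !is.null(aln$group_of)) {
    utils::write.table(
      data.frame(taxon = aln$taxa, group = unname(aln$group_of[aln$taxa])),
      groups_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  invisible(path)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' The proportion of differing sites among comparable sites. A site is
#' comparable only if both sequences carry an unambiguous base (`A`, `C`,
#' `G`, `T`) there; gaps, `N` and IUPAC ambiguity codes are excluded
#' per pair (pairwise deletion). Under complete deletion the caller is
#' expected to have pruned such columns beforehand via
#' [complete_deletion()].
#'
#' @param a,b aligned sequences of equal length (character strings).
#' @return the distance as a proportion in \[0, 1\], with attribute
#'   `comparable_sites`; `NA` (flagged via the attribute being 0) when no
#'   site is comparable.
#' @export
p_distance <- function(a, b) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  if (length(va) != length(vb))
    stopf("sequence length mismatch: %d vs %d", length(va), length(vb))
  ok <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  n_comp <- sum(ok)
  d <- if (n_comp == 0) NA_real_ else sum(va[ok] != vb[ok]) / n_comp
  structure(d, comparable_sites = n_comp)
}

#' Drop alignment columns containing any gap or ambiguity
#'
#' Complete-deletion preprocessing: removes every column where any taxon has
#' a non-`ACGT` symbol, so that all pairwise distances afterwards are
#' computed over the same site set.
#'
#' @param aln an [alignment()].
#' @return a pruned [alignment()].
#' @export
complete_deletion <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequences, ""))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  alignment(aln$taxa, apply(m[, keep, drop = FALSE], 1, paste, collapse = ""),
            aln$group_of)
}

#' Pairwise uncorrected p-distance matrix
#'
#' @param aln an [alignment()].
#' @param deletion `"pairwise"` (default; sites excluded per pair) or
#'   `"complete"` (columns with any gap/ambiguity removed once, up front).
#' @return an object of class `p_distance_matrix`: list with `taxa`, `d`
#'   (symmetric proportion matrix, zero diagonal), `comparable_sites`
#'   (symmetric count matrix) and `group_of`.
#' @export
p_distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (deletion == "complete") aln <- complete_deletion(aln)
  n <- length(aln$taxa)
  d <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  cs <- matrix(nchar(aln$sequences[1]), n, n,
               dimnames = list(aln$taxa, aln$taxa))
  chars <- strsplit(aln$sequences, "")
  acgt <- c("A", "C", "G", "T")
  valid <- lapply(chars, function(v) v %in% acgt)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ok <- valid[[i]] & valid[[j]]
      nc <- sum(ok)
      dij <- if (nc == 0) NA_real_
             else sum(chars[[i]][ok] != chars[[j]][ok]) / nc
      d[i, j] <- d[j, i] <- dij
      cs[i, j] <- cs[j, i] <- nc
    }
  }
  structure(list(taxa = aln$taxa, d = d, comparable_sites = cs,
                 group_of = aln$group_of), class = "p_distance_matrix")
}

#' Range of p-distances between (or within) groups
#'
#' Summarizes a distance matrix as the minimum and maximum percent distance
#' over all cross-group pairs (`g1 != g2`) or within-group pairs
#' (`g1 == g2`), the form in which interspecific divergences are reported
#' in species descriptions (e.g. "3.4--3.7%").
#'
#' @param m a [p_distance_matrix()] whose alignment carried group labels.
#' @param g1,g2 group labels; equal labels request the within-group range.
#' @param digits decimal places for the percent values (default 1).
#' @return named numeric `c(min, max)` in percent; both `NA` when a
#'   within-group range is requested for a group of fewer than two taxa.
#' @export
group_range <- function(m, g1, g2 = g1, digits = 1) {
  if (is.null(m$group_of)) stopf("distance matrix has no group labels")
  i <- which(m$group_of == g1)
  j <- which(m$group_of == g2)
  if (length(i) == 0) stopf("group '%s' is empty", g1)
  if (length(j) == 0) stopf("group '%s' is empty", g2)
  if (g1 == g2) {
    if (length(i) < 2) {
      warnf("within-group range undefined for singleton group '%s'", g1)
      return(c(min = NA_real_, max = NA_real_))
    }
    vals <- m$d[i, i][upper.tri(m$d[i, i])]
  } else {
    vals <- as.vector(m$d[i, j, drop = FALSE])
  }
  pct <- round_half_up(100 * vals, digits)
  c(min = min(pct), max = max(pct))
}

#' Write a p-distance matrix as TSV
#'
#' @param m a [p_distance_matrix()].
#' @param path output path for the square matrix.
#' @param long_path optional path for a long-format table
#'   (`taxon_a, taxon_b, distance, comparable_sites`).
#' @return `path`, invisibly.
#' @export
write_p_distance_matrix <- function(m, path, long_path = NULL) {
  utils::write.table(m$d, path, sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(long_path)) {
    idx <- which(upper.tri(m$d), arr.ind = TRUE)
    long <- data.frame(taxon_a = m$taxa[idx[, 1]], taxon_b = m$taxa[idx[, 2]],
                       distance = m$d[idx],
                       comparable_sites = m$comparable_sites[idx])
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
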