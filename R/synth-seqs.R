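#' Specification for a synthetic aligned sequence set
#'
#' Builds groups of aligned DNA sequences with controlled uncorrected
#' p-distances, emulating short mitochondrial barcode fragments (e.g. a
#' 632 bp COI or 536 bp 16S alignment) diverged at interspecific levels of a
#' few percent.
#'
#' @param n_taxa_per_group integer vector, taxa per group; names, if given,
#'   become group labels (otherwise `g1`, `g2`, ...).
#' @param seq_length_bp alignment length in base pairs (>= 1).
#' @param target_between_p target between-group uncorrected p-distance, in
#'   \[0, 0.75\].
#' @param target_within_p target within-group p-distance; must not exceed
#'   `target_between_p`.
#' @param gap_frac fraction of alignment columns carrying a gap in at least
#'   one sequence.
#' @param seed RNG seed.
#' @return an object of class `seq_sim_spec`.
#' @seealso [generate_alignment()]
#' @export
seq_sim_spec <- function(n_taxa_per_group = c(3, 3),
                         seq_length_bp = 632,
                         target_between_p = 0.037,
                         target_within_p = 0,
                         gap_frac = 0,
                         seed = 1L) {
  spec <- structure(list(
    n_taxa_per_group = as.integer(n_taxa_per_group),
    seq_length_bp = as.integer(seq_length_bp),
    target_between_p = target_between_p,
    target_within_p = target_within_p,
    gap_frac = gap_frac,
    seed = as.integer(seed)), class = "seq_sim_spec")
  if (spec$seq_length_bp < 1) stopf("seq_length_bp must be >= 1")
  if (spec$target_between_p > 0.75)
    stopf("target_between_p above 0.75: p-distance saturates")
  if (spec$target_within_p < 0 ||
      spec$target_within_p > spec$target_between_p)
    stopf("need 0 <= target_within_p <= target_between_p")
  if (spec$gap_frac < 0 || spec$gap_frac >= 1)
    stopf("gap_frac must lie in [0, 1)")
  spec
}

#' Generate an aligned sequence set with target p-distances
#'
#' With two groups, group 1 carries the reference sequence and group 2 differs
#' from it at exactly `round(target_between_p * seq_length_bp)` ungapped
#' sites, so the realized between-group distance on a gap-free alignment is
#' exact to the nearest site. With more groups, each group consensus is
#' mutated at its own disjoint site set of half that size, giving pairwise
#' between-group distances within one site of the target. Within-group
#' variation mutates each taxon at `round(target_within_p * L / 2)` random
#' sites. Gap columns, if requested, are drawn from the unmutated sites and
#' placed in one random taxon each.
#'
#' @param spec a [seq_sim_spec()].
#' @return an `alignment` object (see [alignment()]).
#' @export
generate_alignment <- function(spec) {
  stopifnot(inherits(spec, "seq_sim_spec"))
  L <- spec$seq_length_bp
  bases <- c("A", "C", "G", "T")
  groups <- spec$n_taxa_per_group
  g_names <- names(groups) %||% paste0("g", seq_along(groups))
  names(groups) <- g_names
  with_seed(spec$seed, {
    ref <- sample(bases, L, replace = TRUE)
    m_b <- round(spec$target_between_p * L)
    k <- length(groups)
    # disjoint mutated site sets per group consensus
    if (k == 2) {
      site_sets <- list(integer(0), sample.int(L, m_b))
    } else {
      half <- ceiling(m_b / 2)
      pool <- sample.int(L, min(L, half * k))
      site_sets <- split(pool, rep(seq_len(k), each = half)[seq_along(pool)])
    }
    mutate_at <- function(seq, sites) {
      for (s in sites) seq[s] <- sample(setdiff(bases, seq[s]), 1)
      seq
    }
    consensus <- lapply(seq_len(k), function(i) mutate_at(ref, site_sets[[i]]))
    m_w <- round(spec$target_within_p * L / 2)
    taxa <- character(0); seqs <- list(); grp <- character(0)
    for (i in seq_len(k)) {
      for (j in seq_len(groups[i])) {
        s <- mutate_at(consensus[[i]],
                       if (m_w > 0) sample.int(L, m_w) else integer(0))
        taxa <- c(taxa, sprintf("%s_t%d", g_names[i], j))
        grp <- c(grp, g_names[i])
        seqs <- c(seqs, list(s))
      }
    }
    mat <- do.call(rbind, seqs)
    if (spec$gap_frac > 0) {
      mutated <- unique(unlist(site_sets))
      candidates <- setdiff(seq_len(L), mutated)
      n_gap <- round(spec$gap_frac * L)
      gap_cols <- sample(candidates, min(n_gap, length(candidates)))
      for (cc in gap_cols) mat[sample.int(nrow(mat), 1), cc] <- "-"
    }
    rownames(mat) <- taxa
    alignment(taxa, apply(mat, 1, paste, collapse = ""),
              stats::setNames(grp, taxa))
  })
}
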