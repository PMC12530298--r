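#' Gap-threshold column trimming
#'
#' Removes poorly occupied alignment columns, mirroring gap-threshold
#' trimming as done by trimAl's `-gt` option. Under the default rule
#' (`"min_residue_fraction"`) a column is retained iff the fraction of
#' sequences bearing a residue (non-gap) in that column is at least
#' `gap_threshold`; the boundary case is retained. The alternative reading
#' of a "40% gap threshold" — a column may contain at most `gap_threshold`
#' gaps — is available as `gap_rule = "max_gap_fraction"`. Column order is
#' preserved.
#'
#' @param aln An [aa_alignment()].
#' @param gap_threshold Fraction in `[0, 1]`; default 0.40.
#' @param gap_rule `"min_residue_fraction"` (default) or
#'   `"max_gap_fraction"`.
#' @return A list with elements `alignment` (trimmed `aa_alignment`) and
#'   `report` (one-row tibble: `columns_removed`, `columns_kept`,
#'   `gap_threshold`, `gap_rule`).
#' @export
#' @examples
#' aln <- aa_alignment(c(a = "MK-", b = "M--", c = "MR-"), id = "og")
#' trim_columns(aln)$alignment
trim_columns <- function(aln, gap_threshold = 0.40,
                         gap_rule = c("min_residue_fraction",
                                      "max_gap_fraction")) {
  stopifnot(inherits(aln, "aa_alignment"))
  gap_rule <- match.arg(gap_rule)
  if (n_species(aln) == 0) stop("alignment has zero sequences")
  res <- !is.na(encode_alignment(aln))
  frac_res <- colMeans(res)
  keep <- if (gap_rule == "min_residue_fraction") {
    frac_res >= gap_threshold
  } else {
    (1 - frac_res) <= gap_threshold
  }
  out <- aa_alignment(aln$seq[, keep, drop = FALSE], id = aln$id)
  report <- tibble::tibble(
    orthogroup_id = aln$id,
    columns_removed = sum(!keep),
    columns_kept = sum(keep),
    gap_threshold = gap_threshold,
    gap_rule = gap_rule
  )
  list(alignment = out, report = report)
}

#' Remove spuriously aligned sequences
#'
#' Single-pass analogue of trimAl's `-resoverlap`/`-seqoverlap` filter. A
#' residue position of a sequence is "good" iff at least `res_overlap` of
#' the other sequences carry a residue in that column; a sequence is removed
#' iff fewer than `seq_overlap` percent of its residue positions are good.
#' All removals are decided on the original alignment in one pass (not
#' iteratively). Residue identity is not consulted: any residue counts as
#' overlap.
#'
#' @param aln An [aa_alignment()] with at least 2 sequences.
#' @param res_overlap Fraction of other sequences that must carry a residue
#'   for a position to count as good (default 0.5).
#' @param seq_overlap Minimum percentage of good positions a sequence needs
#'   to be kept (default 50).
#' @return A list with `alignment` (filtered) and `report` (one-row tibble
#'   listing `sequences_removed` as a comma-separated string).
#' @export
remove_spurious_sequences <- function(aln, res_overlap = 0.5,
                                      seq_overlap = 50) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (n_species(aln) < 2) stop("need at least 2 sequences")
  res <- !is.na(encode_alignment(aln))          # species x sites
  n <- nrow(res)
  col_res <- colSums(res)
  # for sequence i, a column is good iff (col_res - res[i,]) / (n - 1) >= res_overlap
  good_frac <- vapply(seq_len(n), function(i) {
    own <- res[i, ]
    if (!any(own)) return(0)
    others <- (col_res[own] - 1) / (n - 1)
    mean(others >= res_overlap)
  }, numeric(1))
  keep <- good_frac * 100 >= seq_overlap
  out <- aa_alignment(aln$seq[keep, , drop = FALSE], id = aln$id)
  report <- tibble::tibble(
    orthogroup_id = aln$id,
    n_removed = sum(!keep),
    sequences_removed = paste(rownames(aln$seq)[!keep], collapse = ","),
    res_overlap = res_overlap,
    seq_overlap = seq_overlap
  )
  list(alignment = out, report = report)
}

#' Species-occupancy filter
#'
#' Keep an orthogroup iff it retains at least `min_species` sequences after
#' trimming and spurious-sequence removal. The canonical choice is half the
#' study's species set, rounded up (e.g., 17 of 34 species).
#'
#' @param aln An [aa_alignment()].
#' @param min_species Minimum number of species (>= 2).
#' @return Logical: keep (`TRUE`) or drop (`FALSE`).
#' @export
#' @examples
#' occupancy_min(34)
occupancy_filter <- function(aln, min_species) {
  stopifnot(inherits(aln, "aa_alignment"), min_species >= 2)
  n_species(aln) >= min_species
}

#' @rdname occupancy_filter
#' @param n_study_species Total number of species in the study.
#' @export
occupancy_min <- function(n_study_species) {
  as.integer(ceiling(0.5 * n_study_species))
}
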