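#' Exclude poor-quality alignment regions (relaxed block filtering)
#'
#' Retains maximal runs of alignment columns that are simultaneously
#' (i) conserved — the majority residue among non-gap residues reaches at
#' least `b2_flank_fraction` of the non-gap count, (ii) not gap-ridden — the
#' fraction of sequences with a gap is at most `b5_max_gap_fraction` — and
#' (iii) part of a run of at least `b4_min_block` consecutive such columns.
#' This is a relaxed, single-tier variant of the Gblocks criteria; the
#' defaults correspond to the relaxed settings b2 = 50%, b4 = 5, b5 = 50%.
#'
#' `N` is treated as missing (excluded from the conservation count, not a
#' gap). An empty result is returned rather than an error when nothing
#' survives.
#'
#' @param aln A `gene_alignment`.
#' @param b2_flank_fraction Minimum majority-residue fraction among non-gap
#'   residues for a column to count as conserved (default 0.5).
#' @param b4_min_block Minimum run length in columns (default 5).
#' @param b5_max_gap_fraction Maximum fraction of sequences gapped in a kept
#'   column (default 0.5).
#' @return A list with `alignment` (the filtered `gene_alignment`, possibly
#'   zero columns) and `column_map`, a tibble with strictly increasing
#'   1-based `new` and `original` column indices.
#' @export
filter_blocks <- function(aln, b2_flank_fraction = 0.5, b4_min_block = 5,
                          b5_max_gap_fraction = 0.5) {
  stopifnot(b2_flank_fraction > 0, b2_flank_fraction <= 1,
            b4_min_block >= 1,
            b5_max_gap_fraction >= 0, b5_max_gap_fraction <= 1)
  L <- aln_length(aln)
  n <- nrow(aln$seqs)
  good <- vapply(seq_len(L), function(j) {
    col <- aln$seqs[, j]
    gap_frac <- mean(col == "-")
    if (gap_frac > b5_max_gap_fraction) return(FALSE)
    bases <- col[col %in% c("A", "C", "G", "T")]
    if (length(bases) == 0L) return(FALSE)
    max(table(bases)) / length(bases) >= b2_flank_fraction
  }, logical(1))
  keep <- keep_runs(good, b4_min_block)
  kept <- which(keep)
  column_map <- tibble::tibble(new = seq_along(kept), original = kept)
  alignment <- if (length(kept) > 0) {
    aln_subset(aln, columns = kept)
  } else {
    out <- aln
    out$seqs <- aln$seqs[, 0, drop = FALSE]
    out
  }
  list(alignment = alignment, column_map = column_map)
}

# keep only runs of TRUE with length >= min_len
keep_runs <- function(good, min_len) {
  r <- rle(good)
  r$values <- r$values & r$lengths >= min_len
  inverse.rle(r)
}
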