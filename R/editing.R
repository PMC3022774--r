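#' Build or read an edit-evidence table
#'
#' Edit evidence lists C-to-U RNA edit sites per reference sequence as
#' 1-based alignment columns, with the evidence class (`experimental` for
#' sites known from cDNA studies, `predicted` for sites called by
#' [predict_edit_sites()]) and the codon position of the site. The reference
#' genomic sequence carries `C` at every listed column.
#'
#' @param reference_id,gene,column,evidence,codon_position Vectors (recycled
#'   to a common length) or a single data frame passed as `reference_id`.
#' @return A tibble of class `edit_evidence`.
#' @export
edit_evidence <- function(reference_id, gene = NA_character_, column = integer(),
                          evidence = "experimental", codon_position = NA_integer_) {
  if (is.data.frame(reference_id)) {
    out <- tibble::as_tibble(reference_id)
  } else {
    out <- tibble::tibble(reference_id = reference_id, gene = gene,
                          column = as.integer(column), evidence = evidence,
                          codon_position = as.integer(codon_position))
  }
  need <- c("reference_id", "gene", "column", "evidence", "codon_position")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("edit evidence missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(out$evidence %in% c("experimental", "predicted")))
    stop("evidence must be 'experimental' or 'predicted'", call. = FALSE)
  class(out) <- c("edit_evidence", setdiff(class(out), "edit_evidence"))
  out
}

#' Read / write edit evidence TSV
#' @param path TSV path with columns reference_id, gene, column, evidence,
#'   codon_position.
#' @return An `edit_evidence` tibble.
#' @export
read_edit_evidence <- function(path) {
  edit_evidence(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' @rdname read_edit_evidence
#' @param evidence An `edit_evidence` tibble.
#' @export
write_edit_evidence <- function(evidence, path) {
  utils::write.table(evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Predict C-to-U edit sites in a target sequence from reference evidence
#'
#' A conservation-based predictor in the spirit of PREP-Aln: for every
#' target `C` at a column homologous to at least one reference edit site,
#' the score is the fraction of assessable reference sequences for which the
#' target codon, after the hypothetical C-to-U edit, encodes the same amino
#' acid as that reference's edited codon. References without evidence at the
#' column, or unedited there, count against the score, so unanimous evidence
#' with a restored conserved amino acid scores 1. Sites scoring at least
#' `cutoff` (default 0.2) are predicted edited. Sites where the target lacks
#' `C` are never predicted.
#'
#' @param aln A `gene_alignment` containing target and references.
#' @param target Target record id.
#' @param references An `edit_evidence` tibble over one or more reference
#'   ids present in `aln`.
#' @param codon_map Codon map defining the reading frame (see
#'   [restore_reading_frame()]); required for amino-acid scoring.
#' @param cutoff Prediction threshold on the score (default 0.2).
#' @return An `edit_evidence` tibble for the target (`evidence =
#'   "predicted"`), with a `score` column.
#' @export
predict_edit_sites <- function(aln, target, references, codon_map,
                               cutoff = 0.2) {
  if (is.null(codon_map)) stop("codon frame unavailable: amino-acid scoring ",
                               "is impossible without a codon_map", call. = FALSE)
  tgt <- aln_seq(aln, target)
  ref_ids <- unique(references$reference_id)
  if (!length(ref_ids)) stop("no reference evidence provided", call. = FALSE)
  cols <- sort(unique(references$column))
  res <- list()
  for (jj in cols) {
    if (tgt[jj] != "C") next
    ci <- which(codon_map$col1 <= jj & codon_map$col3 >= jj)
    if (!length(ci)) next
    ci <- ci[1]
    ccols <- c(codon_map$col1[ci], codon_map$col2[ci], codon_map$col3[ci])
    cpos <- match(jj, ccols)
    tcod <- tgt[ccols]
    if (!all(tcod %in% c("A", "C", "G", "T"))) next
    ecod <- tcod; ecod[cpos] <- "T"
    aa_t <- translate_codons(paste(ecod, collapse = ""))
    n_match <- 0L; n_assess <- 0L
    for (rid in ref_ids) {
      rseq <- aln_seq(aln, rid)
      rcod <- rseq[ccols]
      if (!all(rcod %in% c("A", "C", "G", "T"))) next
      n_assess <- n_assess + 1L
      edited_here <- any(references$reference_id == rid &
                           references$column == jj)
      if (!edited_here) next
      recod <- rcod; recod[cpos] <- "T"
      if (identical(translate_codons(paste(recod, collapse = "")), aa_t))
        n_match <- n_match + 1L
    }
    if (n_assess == 0L) next
    score <- n_match / n_assess
    if (score >= cutoff) {
      res[[length(res) + 1L]] <- tibble::tibble(
        reference_id = target, gene = aln$meta$gene[aln$meta$id == target][1],
        column = jj, evidence = "predicted", codon_position = cpos,
        score = score)
    }
  }
  out <- if (length(res)) dplyr::bind_rows(res) else
    tibble::tibble(reference_id = character(), gene = character(),
                   column = integer(), evidence = character(),
                   codon_position = integer(), score = numeric())
  class(out) <- c("edit_evidence", setdiff(class(out), "edit_evidence"))
  out
}

#' Tally C/T retention at donor edit sites in a foreign copy
#'
#' Counts the foreign record's residue at every assessable donor edit-site
#' column (non-gap, non-`N` in the foreign record). A DNA-mediated transfer
#' retains the genomic `C` at these sites up to background substitution; a
#' transfer through an edited RNA/cDNA intermediate carries `T` at most
#' sites.
#'
#' @param aln A `gene_alignment`.
#' @param foreign Foreign record id.
#' @param donor_sites `edit_evidence` for the donor-lineage reference
#'   (columns give the homologous edit-site positions).
#' @return A one-row tibble of class `retention_tally`: `target_id`,
#'   `n_sites_assessed`, `n_C`, `n_T`, `n_other`, `n_outside_span`,
#'   `verdict` (`NA` until [classify_mechanism()]), `verdict_p`. Per-site
#'   detail in attribute `"sites"`.
#' @export
tally_retention <- function(aln, foreign, donor_sites) {
  f <- aln_seq(aln, foreign)
  cols <- sort(unique(donor_sites$column))
  res <- f[cols]
  assessable <- res %in% c("A", "C", "G", "T")
  if (!any(assessable))
    stop("untestable: no donor edit site falls in the sequenced span of '",
         foreign, "'", call. = FALSE)
  rr <- res[assessable]
  out <- tibble::tibble(
    target_id = foreign,
    n_sites_assessed = sum(assessable),
    n_C = sum(rr == "C"), n_T = sum(rr == "T"),
    n_other = sum(!rr %in% c("C", "T")),
    n_outside_span = sum(!assessable),
    verdict = NA_character_, verdict_p = NA_real_)
  class(out) <- c("retention_tally", class(out))
  attr(out, "sites") <- tibble::tibble(column = cols, residue = res,
                                       assessable = assessable)
  out
}

#' Classify the transfer mechanism from an edit-site retention tally
#'
#' Compares the observed thymidine count against two binomial models: the
#' RNA-mediated expectation (a cDNA of an edited transcript carries `T` at
#' the fully-edited fraction of sites, default 0.9) and the DNA-mediated
#' expectation (`T` only from background C-to-T substitution). The verdict
#' is the model that is not rejected at `alpha`; `verdict_p` is the tail
#' probability under the rejected model. When both or neither model is
#' rejected the call is ambiguous.
#'
#' @param tally A `retention_tally`.
#' @param background_CtoT_rate Background C-to-T substitution probability
#'   per site (e.g. estimated from non-edit-site `C` columns).
#' @param edited_fraction Expected fully-edited fraction under an RNA
#'   intermediate (default 0.9).
#' @param alpha Rejection level (default 0.05).
#' @return The tally with `verdict` (`"DNA-mediated"`, `"RNA-mediated"` or
#'   `"ambiguous"`) and `verdict_p` filled, plus `p_DNA`/`p_RNA` columns.
#' @export
classify_mechanism <- function(tally, background_CtoT_rate,
                               edited_fraction = 0.9, alpha = 0.05) {
  n <- tally$n_sites_assessed
  nT <- tally$n_T
  # DNA model rejected by an excess of T; RNA model by an excess of C
  p_dna <- 1 - pbinom(nT - 1, n, background_CtoT_rate)  # P(X >= nT | DNA)
  p_rna <- pbinom(nT, n, edited_fraction)               # P(X <= nT | RNA)
  rej_dna <- p_dna < alpha
  rej_rna <- p_rna < alpha
  tally$p_DNA <- p_dna
  tally$p_RNA <- p_rna
  if (rej_rna && !rej_dna) {
    tally$verdict <- "DNA-mediated"; tally$verdict_p <- p_rna
  } else if (rej_dna && !rej_rna) {
    tally$verdict <- "RNA-mediated"; tally$verdict_p <- p_dna
  } else {
    tally$verdict <- "ambiguous"; tally$verdict_p <- min(p_dna, p_rna)
  }
  tally
}
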