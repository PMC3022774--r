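#' Standard genetic code utilities
#'
#' Codon translation for the standard nuclear/plant-mitochondrial code
#' (plant mitochondria use the standard code). Stop codons translate to
#' `"*"`; codons containing gaps or `N` translate to `NA`.
#'
#' @param codons Character vector of 3-letter codons.
#' @return Character vector of single-letter amino acids.
#' @export
translate_codons <- function(codons) {
  unname(genetic_code()[codons])
}

genetic_code <- function() {
  if (is.null(.xt_cache$code)) {
    b <- c("T", "C", "A", "G")
    codons <- as.vector(t(outer(
      as.vector(t(outer(b, b, paste0))), b, paste0)))
    aa <- strsplit(paste0(
      "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
      "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
    .xt_cache$code <- setNames(aa, codons)
  }
  .xt_cache$code
}

stop_codons <- function() c("TAA", "TAG", "TGA")

is_functional_frame <- function(res) {
  res <- res[res %in% c("A", "C", "G", "T")]
  if (length(res) %% 3 != 0) return(FALSE)
  cod <- apply(matrix(res, nrow = 3), 2, paste, collapse = "")
  n <- length(cod)
  if (n == 0) return(FALSE)
  !any(cod[-n] %in% stop_codons())
}

#' Restore a pseudogene to its ancestral reading frame
#'
#' Uses an aligned, functional (frame-intact, stop-free) homolog as the frame
#' reference. Indel runs of the pseudogene relative to the reference are
#' classified; frameshifting insertions (length not a multiple of 3) are
#' masked to `N` rather than deleted, preserving alignment coordinates, and
#' deletions are logged as compensating gap insertions. The reference frame
#' itself — the reference's non-gap columns grouped into consecutive triplets
#' — gives the codon coordinate system used by all downstream codon-level
#' analyses. No residues are invented.
#'
#' @param aln A `gene_alignment`.
#' @param pseudo Id of the (putative) pseudogene record.
#' @param reference Id of the functional homolog defining the frame.
#' @return An object of class `frame_restoration`: a list with `pseudo_id`,
#'   `reference_id`, `original` and `restored` residue vectors, `edits`
#'   (tibble: `position`, `kind` in `inserted-gap`/`deleted-base`, `length`,
#'   `frameshifting`), and `codon_map` (tibble: `codon`, `col1`, `col2`,
#'   `col3` alignment columns of each reference-frame codon).
#' @export
restore_reading_frame <- function(aln, pseudo, reference) {
  p <- aln_seq(aln, pseudo)
  r <- aln_seq(aln, reference)
  if (!is_functional_frame(r))
    stop("reference '", reference,
         "' is not frame-intact/stop-free; cannot define the ancestral frame",
         call. = FALSE)
  L <- length(p)
  p_res <- p != "-"
  r_res <- r != "-"
  # classify columns: both residues / deletion (ref base, pseudo gap) /
  # insertion (pseudo base, ref gap) / both-gap (neutral)
  state <- rep("match", L)
  state[r_res & !p_res] <- "del"
  state[!r_res & p_res] <- "ins"
  state[!r_res & !p_res] <- "none"
  restored <- p
  edits <- list()
  # indel runs, merging across both-gap columns
  runs <- rle(state[state != "none"])
  cols <- which(state != "none")
  pos <- 1L
  for (k in seq_along(runs$lengths)) {
    len <- runs$lengths[k]
    type <- runs$values[k]
    run_cols <- cols[pos:(pos + len - 1L)]
    pos <- pos + len
    if (type == "del") {
      edits[[length(edits) + 1L]] <- tibble::tibble(
        position = run_cols[1], kind = "inserted-gap", length = len,
        frameshifting = (len %% 3L != 0L))
    } else if (type == "ins") {
      fs <- (len %% 3L != 0L)
      if (fs) restored[run_cols] <- "N"
      edits[[length(edits) + 1L]] <- tibble::tibble(
        position = run_cols[1], kind = "deleted-base", length = len,
        frameshifting = fs)
    }
  }
  edits <- if (length(edits)) dplyr::bind_rows(edits) else
    tibble::tibble(position = integer(), kind = character(),
                   length = integer(), frameshifting = logical())
  ref_cols <- which(r_res)
  n_codon <- length(ref_cols) %/% 3L
  cm <- matrix(ref_cols[seq_len(3L * n_codon)], nrow = 3)
  codon_map <- tibble::tibble(codon = seq_len(n_codon),
                              col1 = cm[1, ], col2 = cm[2, ], col3 = cm[3, ])
  structure(list(pseudo_id = pseudo, reference_id = reference,
                 original = p, restored = restored, edits = edits,
                 codon_map = codon_map),
            class = "frame_restoration")
}

#' @export
print.frame_restoration <- function(x, ...) {
  cat("<frame_restoration> '", x$pseudo_id, "' restored against '",
      x$reference_id, "': ", nrow(x$edits), " edits (",
      sum(x$edits$frameshifting), " frameshifting), ",
      nrow(x$codon_map), " codons\n", sep = "")
  invisible(x)
}

#' Read a record's codons in a reference frame
#'
#' @param residues Character vector of residues (alignment-length).
#' @param codon_map Codon map from [restore_reading_frame()].
#' @return Character vector of codons; codons containing gap/`N` are `NA`.
#' @export
codons_in_frame <- function(residues, codon_map) {
  c1 <- residues[codon_map$col1]
  c2 <- residues[codon_map$col2]
  c3 <- residues[codon_map$col3]
  cod <- paste0(c1, c2, c3)
  ok <- c1 %in% c("A","C","G","T") & c2 %in% c("A","C","G","T") &
    c3 %in% c("A","C","G","T")
  cod[!ok] <- NA_character_
  cod
}

#' Report pseudogene features (frameshifting indels, premature stops)
#'
#' Scans a frame-restored record for the two hallmarks of pseudogenization:
#' indels whose length is not a multiple of three, and in-frame premature
#' stop codons (any stop before the final codon of the restored frame).
#' A record with neither feature is flagged intact.
#'
#' @param frame A `frame_restoration` from [restore_reading_frame()].
#' @return A tibble with columns `feature` (`frameshift-indel` /
#'   `premature-stop`), `codon` (1-based codon coordinate), `position`
#'   (1-based alignment column), `detail`; zero rows means intact. The
#'   `intact` flag is carried as an attribute.
#' @export
scan_pseudogene_features <- function(frame) {
  cm <- frame$codon_map
  col2codon <- function(p) {
    hit <- which(cm$col1 <= p & cm$col3 >= p)
    if (length(hit)) hit[1] else NA_integer_
  }
  feats <- list()
  fs <- frame$edits[frame$edits$frameshifting, , drop = FALSE]
  if (nrow(fs)) {
    feats[[1]] <- tibble::tibble(
      feature = "frameshift-indel",
      codon = vapply(fs$position, col2codon, integer(1)),
      position = fs$position,
      detail = paste0(fs$kind, " len=", fs$length))
  }
  cods <- codons_in_frame(frame$restored, cm)
  n <- length(cods)
  if (n > 1) {
    stops <- which(!is.na(cods[-n]) & cods[-n] %in% stop_codons())
    if (length(stops)) {
      feats[[length(feats) + 1L]] <- tibble::tibble(
        feature = "premature-stop", codon = stops,
        position = cm$col1[stops], detail = cods[stops])
    }
  }
  out <- if (length(feats)) dplyr::bind_rows(feats) else
    tibble::tibble(feature = character(), codon = integer(),
                   position = integer(), detail = character())
  attr(out, "intact") <- nrow(out) == 0L
  attr(out, "id") <- frame$pseudo_id
  out
}
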