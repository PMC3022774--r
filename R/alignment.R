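#' Alignment container
#'
#' A `gene_alignment` holds an aligned set of nucleotide sequences as a
#' character matrix (rows = sequences, columns = 1-based alignment positions)
#' together with per-sequence metadata. All coordinates in this package are
#' 1-based and ranges are inclusive, matching the convention in which a
#' conversion tract at "positions 150-189" spans 40 alignment columns.
#'
#' Residues are single characters over `A, C, G, T, -, N`. IUPAC ambiguity
#' codes other than `N` are mapped to `N` on construction with a warning.
#'
#' @param seqs Character matrix (sequences x columns) or named character
#'   vector of equal-length strings.
#' @param meta Data frame with columns `id`, `taxon`, `line`, `gene`,
#'   `copy_class` (missing columns are filled with defaults). `copy_class`
#'   must be one of `"native"`, `"foreign"`, `"reference"`, `"unknown"`.
#' @return An object of class `gene_alignment`.
#' @export
gene_alignment <- function(seqs, meta = NULL) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- ids[which(lens != lens[1])[1]]
      stop("alignment is ragged: record '", bad, "' has length ",
           lens[ids == bad][1], ", expected ", lens[1], call. = FALSE)
    }
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(seqs) <- ids
  }
  if (!is.matrix(seqs) || nrow(seqs) < 1L || ncol(seqs) < 1L)
    stop("empty alignment", call. = FALSE)
  seqs[] <- toupper(seqs)
  bad <- !(seqs %in% c("A", "C", "G", "T", "-", "N"))
  if (any(bad)) {
    warning(sum(bad), " ambiguous/unknown residues mapped to N", call. = FALSE)
    seqs[bad] <- "N"
  }
  ids <- rownames(seqs)
  if (is.null(ids)) {
    ids <- paste0("seq", seq_len(nrow(seqs)))
    rownames(seqs) <- ids
  }
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  meta <- complete_meta(meta, ids)
  structure(list(seqs = seqs, meta = meta), class = "gene_alignment")
}

complete_meta <- function(meta, ids) {
  if (is.null(meta)) meta <- tibble::tibble(id = ids)
  meta <- tibble::as_tibble(meta)
  if (!"id" %in% names(meta)) stop("metadata needs an 'id' column", call. = FALSE)
  defaults <- list(taxon = NA_character_, line = "", gene = NA_character_,
                   copy_class = "unknown")
  for (nm in names(defaults)) {
    if (!nm %in% names(meta)) meta[[nm]] <- defaults[[nm]]
  }
  meta <- meta[match(ids, meta$id), c("id", "taxon", "line", "gene", "copy_class")]
  meta$id <- ids
  meta$copy_class[is.na(meta$copy_class)] <- "unknown"
  ok <- meta$copy_class %in% c("native", "foreign", "reference", "unknown")
  if (!all(ok)) stop("invalid copy_class: ", paste(unique(meta$copy_class[!ok]),
                                                   collapse = ", "), call. = FALSE)
  meta
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat("<gene_alignment> ", nrow(x$seqs), " sequences x ", ncol(x$seqs),
      " columns\n", sep = "")
  cls <- table(x$meta$copy_class)
  cat("  copy classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.gene_alignment <- function(x) dim(x$seqs)

#' Number of alignment columns
#' @param aln A `gene_alignment`.
#' @return Integer number of columns.
#' @export
aln_length <- function(aln) ncol(aln$seqs)

#' Sequence ids of an alignment
#' @param aln A `gene_alignment`.
#' @return Character vector of record ids.
#' @export
aln_ids <- function(aln) rownames(aln$seqs)

#' Extract one sequence as a character vector
#' @param aln A `gene_alignment`.
#' @param id Record id.
#' @return Character vector of residues.
#' @export
aln_seq <- function(aln, id) {
  if (!id %in% aln_ids(aln)) stop("no record '", id, "'", call. = FALSE)
  aln$seqs[id, ]
}

#' Subset an alignment by records and/or columns
#' @param aln A `gene_alignment`.
#' @param ids Record ids to keep (default all).
#' @param columns Column indices to keep (default all).
#' @return A `gene_alignment`.
#' @export
aln_subset <- function(aln, ids = NULL, columns = NULL) {
  if (is.null(ids)) ids <- aln_ids(aln)
  if (is.null(columns)) columns <- seq_len(aln_length(aln))
  gene_alignment(aln$seqs[ids, columns, drop = FALSE],
                 aln$meta[match(ids, aln$meta$id), ])
}

#' Concatenate gene alignments sharing the same records
#'
#' Column-binds alignments (e.g. for combined multi-gene divergence
#' estimates). All alignments must contain the same record ids; metadata is
#' taken from the first, with `gene` set to the joined gene names.
#'
#' @param alignments List of `gene_alignment` objects.
#' @return A `gene_alignment`.
#' @export
aln_concat <- function(alignments) {
  ids <- aln_ids(alignments[[1]])
  for (a in alignments) {
    if (!setequal(aln_ids(a), ids))
      stop("alignments do not share record ids", call. = FALSE)
  }
  seqs <- do.call(cbind, lapply(alignments, function(a) a$seqs[ids, , drop = FALSE]))
  meta <- alignments[[1]]$meta
  meta$gene <- paste(vapply(alignments, function(a) a$meta$gene[1], character(1)),
                     collapse = "+")
  gene_alignment(seqs, meta)
}

#' Read an aligned FASTA file into a gene_alignment
#'
#' Metadata can come from a sidecar table (columns `id`, `taxon`, `line`,
#' `gene`, `copy_class`) or from a naming convention in which FASTA headers
#' are pipe-separated fields `id|taxon|line|copy_class` (trailing fields
#' optional). Fields absent from both default to unknown/empty.
#'
#' @param path FASTA file path.
#' @param metadata Data frame, path to a TSV file, or `NULL` to use the
#'   naming convention.
#' @param gene Gene name recorded for all sequences (overrides metadata).
#' @return A `gene_alignment`.
#' @export
read_fasta_alignment <- function(path, metadata = NULL, gene = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("not a FASTA alignment (no records): ", path,
                              call. = FALSE)
  lens <- lengths(dna)
  if (length(unique(lens)) > 1L) {
    bad <- names(dna)[which(lens != lens[1])[1]]
    stop("alignment is ragged: record '", bad, "' has length ",
         lens[names(dna) == bad][1], ", expected ", lens[1], call. = FALSE)
  }
  seqs <- toupper(as.character(as.matrix(dna)))
  headers <- rownames(seqs)
  if (is.character(metadata) && length(metadata) == 1L) {
    metadata <- utils::read.delim(metadata, sep = "\t", stringsAsFactors = FALSE)
  }
  if (is.null(metadata)) {
    parts <- strsplit(headers, "|", fixed = TRUE)
    getf <- function(i) vapply(parts, function(p) {
      if (length(p) >= i) p[i] else NA_character_
    }, character(1))
    ids <- getf(1)
    rownames(seqs) <- ids
    metadata <- tibble::tibble(
      id = ids, taxon = getf(2), line = dplyr::coalesce(getf(3), ""),
      copy_class = dplyr::coalesce(getf(4), "unknown"))
  }
  aln <- gene_alignment(seqs, metadata)
  if (!is.null(gene)) aln$meta$gene <- gene
  aln
}

#' Write a gene_alignment to FASTA (and optional metadata TSV)
#' @param aln A `gene_alignment`.
#' @param path Output FASTA path.
#' @param metadata_path Optional path for the metadata sidecar TSV.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path, metadata_path = NULL) {
  lines <- character(0)
  for (id in aln_ids(aln)) {
    lines <- c(lines, paste0(">", id), paste(aln$seqs[id, ], collapse = ""))
  }
  writeLines(lines, path)
  if (!is.null(metadata_path)) {
    utils::write.table(aln$meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Pairwise sequence identity with pairwise deletion
#'
#' Proportion of matching residues over columns where both sequences carry an
#' unambiguous base (`A`, `C`, `G`, `T`); gaps and `N` are excluded pairwise.
#'
#' @param aln A `gene_alignment`.
#' @param a,b Record ids.
#' @return Proportion in `[0, 1]`.
#' @export
pairwise_identity <- function(aln, a, b) {
  x <- aln_seq(aln, a); y <- aln_seq(aln, b)
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites between '", a, "' and '", b, "'",
                     call. = FALSE)
  mean(x[ok] == y[ok])
}
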