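#' Extract phylogenetically informative sites for a xenolog triplet
#'
#' For a putative recombinant (`query`, e.g. a foreign pseudogene), a
#' donor-lineage reference (`parent_a`) and the co-resident native homolog
#' (`parent_b`), the informative sites are the alignment columns where both
#' parents carry unambiguous, differing bases and the query matches exactly
#' one of them. The site string is binary: 1 where the query matches
#' `parent_b` (the candidate converting partner), 0 where it matches
#' `parent_a`. Columns where the query matches neither parent (query
#' autapomorphies at parent-divergent columns) are excluded and counted,
#' so an autapomorphy inside a tract does not break it.
#'
#' @param aln A `gene_alignment`.
#' @param query,parent_a,parent_b Record ids.
#' @return An object of class `triplet_config`: list with `sites` (tibble
#'   `column`, `state`), ids, `n_excluded`, and `testable` (FALSE when fewer
#'   than 2 informative sites).
#' @export
extract_informative_sites <- function(aln, query, parent_a, parent_b) {
  q <- aln_seq(aln, query); pa <- aln_seq(aln, parent_a); pb <- aln_seq(aln, parent_b)
  bases <- c("A", "C", "G", "T")
  cand <- which(pa %in% bases & pb %in% bases & pa != pb & q %in% bases)
  st <- integer(0); col <- integer(0); n_excl <- 0L
  if (length(cand)) {
    mA <- q[cand] == pa[cand]
    mB <- q[cand] == pb[cand]
    keep <- mA | mB
    n_excl <- sum(!keep)
    col <- cand[keep]
    st <- as.integer(mB[keep])
  }
  structure(list(query = query, parent_a = parent_a, parent_b = parent_b,
                 sites = tibble::tibble(column = col, state = st),
                 n_excluded = n_excl,
                 testable = length(col) >= 2L),
            class = "triplet_config")
}

#' @export
print.triplet_config <- function(x, ...) {
  cat("<triplet_config> query=", x$query, " A=", x$parent_a, " B=", x$parent_b,
      ": ", nrow(x$sites), " informative sites (", sum(x$sites$state),
      " match B), ", x$n_excluded, " excluded\n", sep = "")
  invisible(x)
}

#' Detect gene-conversion tracts by a permutation test on site runs
#'
#' The run statistic is the length (in informative sites) of a maximal run
#' of consecutive parent-B-supporting sites with no interior parent-A site
#' (strict runs). The permutation null shuffles the 0/1 site labels holding
#' positions fixed; the p-value of a run is the fraction of permutations
#' whose maximal run is at least as long (with the +1 continuity
#' adjustment), which is exact for the longest run and conservative for
#' secondary runs. Tracts reaching `perm_p < alpha` are reported with
#' coordinates spanning the first to last supporting site in original
#' alignment columns.
#'
#' @param cfg A `triplet_config` from [extract_informative_sites()].
#' @param n_permutations Number of label permutations (default 10000).
#' @param alpha Significance level on the permutation p (default 0.001).
#' @param seed RNG seed.
#' @return A tibble of class `conversion_tracts` with columns `query_id`,
#'   `converting_partner`, `start`, `end`, `length_nt`,
#'   `n_supporting_sites`, `run_score`, `perm_p`, `au_p` (NA until
#'   [confirm_long_tract()]), `needs_au` (`length_nt > 100`). Zero rows when
#'   nothing is significant; all candidate runs are kept in attribute
#'   `"candidates"`.
#' @export
detect_tracts <- function(cfg, n_permutations = 10000, alpha = 0.001,
                          seed = 1) {
  if (!inherits(cfg, "triplet_config")) stop("cfg must be a triplet_config",
                                             call. = FALSE)
  if (!cfg$testable) stop("untestable triplet: fewer than 2 informative sites",
                          call. = FALSE)
  if (n_permutations < 1 / alpha)
    warning("n_permutations < 1/alpha: permutation p resolution is too ",
            "coarse for the requested significance level", call. = FALSE)
  st <- cfg$sites$state
  cols <- cfg$sites$column
  n <- length(st); k <- sum(st)
  runs <- rle(st)
  ends_i <- cumsum(runs$lengths)
  starts_i <- ends_i - runs$lengths + 1L
  is_one <- runs$values == 1L
  cand <- tibble::tibble(
    first_site = starts_i[is_one], last_site = ends_i[is_one],
    run_score = runs$lengths[is_one])
  if (nrow(cand) == 0 || k == 0 || k == n) {
    out <- empty_tracts(cfg)
    attr(out, "candidates") <- cand
    return(out)
  }
  set.seed(seed)
  null_max <- .perm_max_run_null(n, k, as.integer(n_permutations))
  cand$perm_p <- vapply(cand$run_score, function(s) {
    (1 + sum(null_max >= s)) / (n_permutations + 1)
  }, numeric(1))
  cand$start <- cols[cand$first_site]
  cand$end <- cols[cand$last_site]
  sig <- cand[cand$perm_p < alpha, , drop = FALSE]
  out <- tibble::tibble(
    query_id = rep(cfg$query, nrow(sig)),
    converting_partner = rep(cfg$parent_b, nrow(sig)),
    start = sig$start, end = sig$end,
    length_nt = sig$end - sig$start + 1L,
    n_supporting_sites = sig$run_score,
    run_score = as.numeric(sig$run_score),
    perm_p = sig$perm_p,
    au_p = rep(NA_real_, nrow(sig)))
  out$needs_au <- out$length_nt > 100L
  class(out) <- c("conversion_tracts", class(out))
  attr(out, "candidates") <- cand
  attr(out, "triplet") <- c(query = cfg$query, parent_a = cfg$parent_a,
                            parent_b = cfg$parent_b)
  out
}

empty_tracts <- function(cfg = NULL) {
  out <- tibble::tibble(query_id = character(), converting_partner = character(),
                        start = integer(), end = integer(),
                        length_nt = integer(), n_supporting_sites = integer(),
                        run_score = numeric(), perm_p = numeric(),
                        au_p = numeric(), needs_au = logical())
  class(out) <- c("conversion_tracts", class(out))
  out
}

#' Phylogenetic confirmation of a long conversion tract (AU test)
#'
#' Tracts longer than 100 nt require phylogenetic confirmation: the
#' alignment is split into the tract region and the remainder, an ML tree is
#' estimated for each region, and the tract region's data are tested against
#' the remainder's topology with the approximately unbiased test. The tract
#' is confirmed when that topology is rejected (`au_p < 0.05`).
#'
#' @param aln A `gene_alignment`.
#' @param tract A one-row `conversion_tracts` tibble (or a row subset).
#' @param n_restarts ML search restarts per region (default 2).
#' @param n_rell RELL draws for the AU test (default 1000).
#' @param seed RNG seed.
#' @return The tract row with `au_p` filled and a logical `confirmed`
#'   column; `confirmed` is `NA` (flag unconfirmable) when either region has
#'   fewer than 4 variable sites.
#' @export
confirm_long_tract <- function(aln, tract, n_restarts = 2, n_rell = 1000,
                               seed = 1) {
  if (nrow(tract) != 1) stop("confirm one tract at a time", call. = FALSE)
  if (tract$length_nt <= 100)
    stop("AU confirmation applies only to tracts longer than 100 nt",
         call. = FALSE)
  cols_tract <- seq(tract$start, tract$end)
  cols_rest <- setdiff(seq_len(aln_length(aln)), cols_tract)
  reg_tract <- aln_subset(aln, columns = cols_tract)
  reg_rest <- aln_subset(aln, columns = cols_rest)
  n_var <- function(a) {
    sum(apply(a$seqs, 2, function(cl) {
      b <- unique(cl[cl %in% c("A", "C", "G", "T")]); length(b) > 1
    }))
  }
  tract$confirmed <- NA
  if (n_var(reg_tract) < 4 || n_var(reg_rest) < 4) {
    return(tract)
  }
  fit_tract <- ml_search(reg_tract, n_restarts = n_restarts, seed = seed)
  fit_rest <- ml_search(reg_rest, n_restarts = n_restarts, seed = seed + 1)
  tt <- topology_test(reg_tract,
                      list(fit_tract$tree, fit_rest$tree),
                      fit_tract$model, method = "AU", n_rell = n_rell,
                      seed = seed)
  tract$au_p <- tt$table$p_value[2]   # remainder topology on tract data
  tract$confirmed <- tract$au_p < 0.05
  tract
}

#' Split a query sequence at a tract into two derived records
#'
#' Replaces the query record by two records: `<id>__tract` carrying only the
#' tract columns (remainder gapped) and `<id>__rest` carrying the remainder
#' (tract gapped). All other records are unchanged; merging the two derived
#' records reproduces the original query.
#'
#' @param aln A `gene_alignment`.
#' @param tract One-row tract tibble (`start`, `end`).
#' @param query Query record id.
#' @return A `gene_alignment` with the query split in two.
#' @export
split_alignment_at_tract <- function(aln, tract, query) {
  stopifnot(tract$start >= 1, tract$end <= aln_length(aln))
  q <- aln_seq(aln, query)
  inside <- seq(tract$start, tract$end)
  tr_seq <- rep("-", length(q)); tr_seq[inside] <- q[inside]
  rs_seq <- q; rs_seq[inside] <- "-"
  if (all(rs_seq == "-"))
    warning("tract spans the whole sequence; remainder record is all gaps",
            call. = FALSE)
  seqs <- aln$seqs[setdiff(aln_ids(aln), query), , drop = FALSE]
  seqs <- rbind(seqs, matrix(c(tr_seq, rs_seq), nrow = 2, byrow = TRUE,
                             dimnames = list(paste0(query, c("__tract", "__rest")),
                                             NULL)))
  meta <- aln$meta[aln$meta$id != query, ]
  qm <- aln$meta[aln$meta$id == query, ]
  add <- dplyr::bind_rows(qm, qm)
  add$id <- paste0(query, c("__tract", "__rest"))
  gene_alignment(seqs, dplyr::bind_rows(meta, add))
}

#' Remove (or mask) conversion-tract columns from an alignment
#'
#' Overlapping tracts are unioned. With `action = "remove"` the tract
#' columns are dropped for all sequences and a kept-column map is returned;
#' with `action = "mask"` they are replaced by `N` in all sequences.
#'
#' @param aln A `gene_alignment`.
#' @param tracts Tract tibble with `start`/`end` columns (zero rows allowed).
#' @param action `"remove"` or `"mask"`.
#' @return A list with `alignment` and `column_map` (tibble `new`,
#'   `original`; identity map under `"mask"`).
#' @export
mask_tracts <- function(aln, tracts, action = c("remove", "mask")) {
  action <- match.arg(action)
  L <- aln_length(aln)
  drop <- rep(FALSE, L)
  if (!is.null(tracts) && nrow(tracts)) {
    stopifnot(all(tracts$start >= 1), all(tracts$end <= L))
    for (i in seq_len(nrow(tracts))) drop[seq(tracts$start[i], tracts$end[i])] <- TRUE
  }
  if (action == "mask") {
    out <- aln
    out$seqs[, drop] <- "N"
    return(list(alignment = out,
                column_map = tibble::tibble(new = seq_len(L), original = seq_len(L))))
  }
  kept <- which(!drop)
  list(alignment = aln_subset(aln, columns = kept),
       column_map = tibble::tibble(new = seq_along(kept), original = kept))
}
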