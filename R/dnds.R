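#' Jukes-Cantor correction for multiple hits
#'
#' `d = -(3/4) log(1 - 4p/3)` for an observed proportion of differences `p`.
#'
#' @param p Proportion(s) of observed differences, `0 <= p < 3/4`.
#' @return Corrected distance(s) in substitutions per site.
#' @export
jc_correct <- function(p) {
  if (any(is.na(p))) stop("p contains NA", call. = FALSE)
  if (any(p < 0) || any(p >= 0.75))
    stop("Jukes-Cantor correction undefined: p must be in [0, 0.75)",
         call. = FALSE)
  -0.75 * log(1 - 4 * p / 3)
}

# --- Nei-Gojobori codon tables (memoized) -----------------------------------

ng_tables <- function() {
  if (!is.null(.xt_cache$ng)) return(.xt_cache$ng)
  code <- genetic_code()
  codons <- names(code)
  sense <- codons[code != "*"]
  bases <- c("A", "C", "G", "T")
  # synonymous site count per sense codon (classic NG86: mutations to stop
  # codons count as non-synonymous, so S + N = 3 for every codon)
  S <- N <- setNames(numeric(length(sense)), sense)
  for (cd in sense) {
    sp <- strsplit(cd, "")[[1]]
    for (i in 1:3) for (b in setdiff(bases, sp[i])) {
      mut <- sp; mut[i] <- b
      mc <- paste(mut, collapse = "")
      if (code[mc] == code[cd]) S[cd] <- S[cd] + 1 / 3 else N[cd] <- N[cd] + 1 / 3
    }
  }
  # pathway-averaged differences for every ordered sense-codon pair
  nd <- sd <- matrix(0, length(sense), length(sense),
                     dimnames = list(sense, sense))
  path_counts <- function(a, b) {
    da <- strsplit(a, "")[[1]]; db <- strsplit(b, "")[[1]]
    pos <- which(da != db)
    d <- length(pos)
    if (d == 0) return(c(0, 0))
    perms <- all_perms(pos)
    tot_s <- tot_n <- 0; n_valid <- 0
    all_s <- all_n <- 0
    for (ord in perms) {
      cur <- da; s <- n <- 0; valid <- TRUE
      for (i in ord) {
        nxt <- cur; nxt[i] <- db[i]
        c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
        if (code[c2] == "*") valid <- FALSE
        if (code[c1] == code[c2]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      all_s <- all_s + s; all_n <- all_n + n
      if (valid) { tot_s <- tot_s + s; tot_n <- tot_n + n; n_valid <- n_valid + 1 }
    }
    if (n_valid > 0) c(tot_s, tot_n) / n_valid
    else c(all_s, all_n) / length(perms)  # all paths cross stops: keep them
  }
  for (a in sense) for (b in sense) {
    if (a < b) {
      v <- path_counts(a, b)
      sd[a, b] <- sd[b, a] <- v[1]
      nd[a, b] <- nd[b, a] <- v[2]
    }
  }
  .xt_cache$ng <- list(S = S, N = N, sd = sd, nd = nd, sense = sense)
  .xt_cache$ng
}

all_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in all_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  }
  out
}

#' Nei-Gojobori site and difference counts for two codon sequences
#'
#' Synonymous/non-synonymous site counts are per-codon fractions from the
#' standard genetic code (mutations to stop codons count as non-synonymous,
#' so `S + N = 3` per codon), averaged over the two sequences;
#' multi-difference codons are averaged over all orderings of single-step
#' pathways with pathways through stop codons excluded. Codons with a gap or
#' `N` in either member, and codons that are themselves stop codons in
#' either member, are dropped pairwise.
#'
#' @param codons_a,codons_b Equal-length character vectors of codons (`NA`
#'   allowed for unassessable codons).
#' @return List with `S`, `N` (site counts), `sd`, `nd` (difference counts),
#'   `n_codons_used`, `n_dropped`.
#' @export
count_ng_sites_and_diffs <- function(codons_a, codons_b) {
  if (length(codons_a) != length(codons_b))
    stop("codon sequences differ in length", call. = FALSE)
  tab <- ng_tables()
  ok <- !is.na(codons_a) & !is.na(codons_b) &
    codons_a %in% tab$sense & codons_b %in% tab$sense
  a <- codons_a[ok]; b <- codons_b[ok]
  list(S = sum((tab$S[a] + tab$S[b]) / 2),
       N = sum((tab$N[a] + tab$N[b]) / 2),
       sd = sum(tab$sd[cbind(a, b)]),
       nd = sum(tab$nd[cbind(a, b)]),
       n_codons_used = length(a),
       n_dropped = sum(!ok))
}

#' Pairwise dN/dS by the Nei-Gojobori method with Jukes-Cantor correction
#'
#' Implements the counting conventions used for pseudogene/native divergence
#' comparisons: predicted C-to-U edit-site columns are recoded to `T` in both
#' sequences before counting (so historical editing cannot masquerade as
#' divergence), codons overlapping detected gene-conversion tracts are
#' removed, gaps/`N` are deleted pairwise at the codon level, and standard
#' errors come from a codon-resampling bootstrap.
#'
#' @param aln A `gene_alignment` (frame-restored sequences).
#' @param a,b Record ids.
#' @param codon_map Codon map (tibble `codon`, `col1..col3`) from
#'   [restore_reading_frame()]; defaults to consecutive triplets when the
#'   alignment length is a multiple of 3.
#' @param edit_sites Integer vector of 1-based edit-site columns, or a tibble
#'   with a `column` column (e.g. edit evidence); `NULL` for none.
#' @param exclude_tracts Tibble of tracts with `start`/`end` columns (e.g.
#'   from [detect_tracts()]); overlapping codons are removed.
#' @param n_bootstrap Codon-bootstrap replicates for standard errors
#'   (default 500).
#' @param seed RNG seed for the bootstrap.
#' @return A one-row tibble of class `divergence_estimate`: `id_a`, `id_b`,
#'   `dN`, `dS`, `omega`, `se_dN`, `se_dS`, `n_codons`, `recoded_edit_sites`,
#'   `excluded_conversion_codons`, `n_bootstrap`. `omega` is `NA` when
#'   `dS = 0`.
#' @export
pairwise_dnds <- function(aln, a, b, codon_map = NULL, edit_sites = NULL,
                          exclude_tracts = NULL, n_bootstrap = 500, seed = 1) {
  x <- aln_seq(aln, a); y <- aln_seq(aln, b)
  if (is.null(codon_map)) {
    L <- length(x)
    if (L %% 3 != 0)
      stop("alignment length not a multiple of 3; supply codon_map",
           call. = FALSE)
    codon_map <- tibble::tibble(codon = seq_len(L / 3),
                                col1 = seq(1, L, 3), col2 = seq(2, L, 3),
                                col3 = seq(3, L, 3))
  }
  if (!is.null(edit_sites) && is.data.frame(edit_sites))
    edit_sites <- unique(edit_sites$column)
  n_recoded <- 0L
  if (length(edit_sites)) {
    for (j in edit_sites) {
      if (x[j] %in% c("A", "C", "G", "T")) x[j] <- "T"
      if (y[j] %in% c("A", "C", "G", "T")) y[j] <- "T"
    }
    n_recoded <- length(edit_sites)
  }
  n_excluded <- 0L
  if (!is.null(exclude_tracts) && nrow(exclude_tracts)) {
    bad <- rep(FALSE, nrow(codon_map))
    for (k in seq_len(nrow(exclude_tracts))) {
      s <- exclude_tracts$start[k]; e <- exclude_tracts$end[k]
      bad <- bad | (codon_map$col3 >= s & codon_map$col1 <= e)
    }
    n_excluded <- sum(bad)
    codon_map <- codon_map[!bad, , drop = FALSE]
  }
  ca <- codons_in_frame(x, codon_map)
  cb <- codons_in_frame(y, codon_map)
  est <- function(ia) {
    cnt <- count_ng_sites_and_diffs(ca[ia], cb[ia])
    if (cnt$S <= 0 || cnt$N <= 0) return(c(NA_real_, NA_real_))
    pS <- cnt$sd / cnt$S; pN <- cnt$nd / cnt$N
    if (pS >= 0.75 || pN >= 0.75) return(c(NA_real_, NA_real_))
    c(jc_correct(pN), jc_correct(pS))
  }
  idx <- seq_along(ca)
  point <- est(idx)
  if (any(is.na(point))) {
    cnt <- count_ng_sites_and_diffs(ca, cb)
    if (cnt$S <= 0 || cnt$N <= 0)
      stop("undefined estimate: no synonymous or non-synonymous sites remain ",
           "after exclusions", call. = FALSE)
    stop("saturated divergence (p >= 3/4); Jukes-Cantor estimate undefined",
         call. = FALSE)
  }
  ses <- c(NA_real_, NA_real_)
  if (n_bootstrap > 0) {
    set.seed(seed)
    reps <- vapply(seq_len(n_bootstrap), function(i) {
      est(sample(idx, replace = TRUE))
    }, numeric(2))
    ses <- apply(reps, 1, stats::sd, na.rm = TRUE)
  }
  cnt <- count_ng_sites_and_diffs(ca, cb)
  out <- tibble::tibble(
    id_a = a, id_b = b,
    dN = point[1], dS = point[2],
    omega = if (point[2] > 0) point[1] / point[2] else NA_real_,
    se_dN = ses[1], se_dS = ses[2],
    n_codons = cnt$n_codons_used,
    recoded_edit_sites = n_recoded,
    excluded_conversion_codons = n_excluded,
    n_bootstrap = n_bootstrap)
  class(out) <- c("divergence_estimate", class(out))
  out
}

#' Ratio of synonymous divergence between foreign and native homolog pairs
#'
#' @param native,foreign One-row `divergence_estimate` tibbles.
#' @return The ratio `foreign$dS / native$dS`; `Inf` (with a warning) when
#'   the native dS is zero.
#' @export
divergence_ratio <- function(native, foreign) {
  if (is.na(native$dS) || is.na(foreign$dS))
    stop("dS undefined in one of the estimates", call. = FALSE)
  if (native$dS == 0) {
    warning("native dS is zero; ratio is infinite", call. = FALSE)
    return(Inf)
  }
  foreign$dS / native$dS
}
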