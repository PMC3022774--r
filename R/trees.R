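aln_phyDat <- function(aln) {
  phangorn::phyDat(aln$seqs, type = "DNA")
}

#' Neighbor-joining starting tree
#'
#' Builds a neighbor-joining tree from pairwise distances. Saturated
#' distances (undefined under the correction) are replaced by 1.5x the
#' largest finite distance, with a warning. Negative branch-length estimates
#' are clamped to zero.
#'
#' @param aln A `gene_alignment` (at least 3 sequences).
#' @param distance One of `"JC"`, `"K2P"`, `"GTR"` (maximum-likelihood
#'   pairwise distances under F81-type frequencies via `phangorn::dist.ml`).
#' @return An unrooted `ape::phylo` tree.
#' @export
build_nj_tree <- function(aln, distance = c("JC", "K2P", "GTR")) {
  distance <- match.arg(distance)
  if (nrow(aln$seqs) < 3) stop("need at least 3 sequences", call. = FALSE)
  if (distance == "GTR") {
    d <- phangorn::dist.ml(aln_phyDat(aln), model = "F81",
                           bf = phangorn::baseFreq(aln_phyDat(aln)))
  } else {
    dna <- ape::as.DNAbin(aln$seqs)
    mdl <- if (distance == "JC") "JC69" else "K80"
    d <- ape::dist.dna(dna, model = mdl, pairwise.deletion = TRUE)
  }
  dm <- as.matrix(d)
  bad <- !is.finite(dm)
  diag(bad) <- FALSE
  if (any(bad)) {
    warning(sum(bad) / 2, " saturated distances set to 1.5x max finite",
            call. = FALSE)
    dm[bad] <- 1.5 * max(dm[is.finite(dm)])
  }
  tr <- ape::nj(stats::as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::unroot(tr)
}

#' Maximum-likelihood tree search under GTR+Gamma+I
#'
#' Nearest-neighbor-interchange hill climbing with interleaved optimization
#' of branch lengths, GTR exchangeabilities, Gamma shape and the invariant
#' proportion, run from a neighbor-joining start plus randomized-NNI
#' restarts; the best of `n_restarts` searches is returned. Base frequencies
#' default to empirical counts (set `optimize_freqs = TRUE` for ML
#' frequencies). Deterministic under a fixed seed.
#'
#' @param aln A `gene_alignment` (at least 4 sequences).
#' @param start Optional starting `phylo` tree; default neighbor joining.
#' @param n_restarts Number of searches (default 5); restarts beyond the
#'   first perturb the start tree by random NNI moves.
#' @param k Gamma categories (default 4).
#' @param optimize_freqs Optimize base frequencies by ML (default empirical).
#' @param seed RNG seed.
#' @return A list of class `ml_fit`: `tree` (unrooted, optimized branch
#'   lengths), `model` (a `gtr_model` with fitted parameters), `log_lik`,
#'   `converged`, and `fit` (the underlying `phangorn::pml` object).
#' @export
ml_search <- function(aln, start = NULL, n_restarts = 5, k = 4,
                      optimize_freqs = FALSE, seed = 1) {
  if (nrow(aln$seqs) < 4) stop("need at least 4 sequences", call. = FALSE)
  pd <- aln_phyDat(aln)
  set.seed(seed)
  if (is.null(start)) start <- build_nj_tree(aln)
  starts <- vector("list", max(1, n_restarts))
  starts[[1]] <- start
  if (n_restarts > 1) {
    for (i in 2:n_restarts) starts[[i]] <- phangorn::rNNI(start, moves = 2)
  }
  fits <- lapply(starts, function(tr) {
    tr$edge.length[tr$edge.length < 1e-8] <- 1e-8
    fit <- phangorn::pml(tr, pd, model = "GTR", k = k, shape = 1, inv = 0.05)
    tryCatch(
      phangorn::optim.pml(fit, model = "GTR", optNni = TRUE, optEdge = TRUE,
                          optBf = optimize_freqs, optQ = TRUE,
                          optGamma = TRUE, optInv = TRUE,
                          rearrangement = "NNI",
                          control = phangorn::pml.control(trace = 0)),
      error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all ML searches failed", call. = FALSE)
  lls <- vapply(fits, function(f) if (is.null(f)) -Inf else as.numeric(stats::logLik(f)),
                numeric(1))
  best <- fits[[which.max(lls)]]
  model <- gtr_model(rates = best$Q, base_freqs = best$bf,
                     shape = if (best$shape > 0) best$shape else Inf,
                     k = k, p_inv = best$inv)
  structure(list(tree = ape::unroot(best$tree), model = model,
                 log_lik = as.numeric(stats::logLik(best)),
                 converged = all(ok), fit = best),
            class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  cat("<ml_fit> ", length(x$tree$tip.label), " tips, log-likelihood ",
      round(x$log_lik, 2), "\n", sep = "")
  invisible(x)
}

#' Nonparametric bootstrap support for the ML topology
#'
#' Resamples alignment columns with replacement; each replicate is
#' re-analyzed by NNI search starting from the ML topology with model
#' parameters fixed at their full-data ML estimates (a reduced-restart
#' re-analysis). Support for each internal edge of the ML tree is the
#' percentage of replicate trees containing that bipartition.
#'
#' @param aln A `gene_alignment`.
#' @param fit An `ml_fit` from [ml_search()] (fitted on `aln`).
#' @param n_replicates Bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @return The ML tree with node labels set to integer percent support
#'   (root label `NA`); replicate trees in attribute `"boot_trees"`.
#' @export
bootstrap_support <- function(aln, fit, n_replicates = 100, seed = 1) {
  stopifnot(n_replicates >= 1)
  set.seed(seed)
  L <- aln_length(aln)
  boot_trees <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, replace = TRUE)
    baln <- aln
    baln$seqs <- aln$seqs[, cols, drop = FALSE]
    pd <- phangorn::phyDat(baln$seqs, type = "DNA")
    f <- phangorn::pml(fit$tree, pd, model = "GTR", k = fit$model$k,
                       shape = if (is.finite(fit$model$shape)) fit$model$shape else 100,
                       inv = fit$model$p_inv, bf = fit$model$base_freqs,
                       Q = unname(fit$fit$Q))
    f <- tryCatch(
      phangorn::optim.pml(f, optNni = TRUE, optEdge = TRUE,
                          rearrangement = "NNI",
                          control = phangorn::pml.control(trace = 0)),
      error = function(e) f)
    boot_trees[[b]] <- ape::unroot(f$tree)
  }
  class(boot_trees) <- "multiPhylo"
  tr <- fit$tree
  counts <- ape::prop.clades(tr, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tr$node.label <- round(100 * counts / n_replicates)
  # the "root" pseudo-node of an unrooted tree is not a bipartition
  tr$node.label[1] <- NA
  attr(tr, "boot_trees") <- boot_trees
  tr
}

#' Bootstrap support for one clade
#' @param tree Tree with percent node labels (from [bootstrap_support()]).
#' @param tips Tip labels of the clade.
#' @return Percent support of the smallest clade containing exactly `tips`,
#'   or `NA` if those tips are not monophyletic in `tree`.
#' @export
clade_support <- function(tree, tips) {
  if (!all(tips %in% tree$tip.label)) return(NA_real_)
  if (!ape::is.monophyletic(tree, tips)) return(NA_real_)
  node <- ape::getMRCA(tree, tips)
  if (is.null(node)) return(NA_real_)
  lab <- tree$node.label[node - length(tree$tip.label)]
  suppressWarnings(as.numeric(lab))
}
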