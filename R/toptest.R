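#' Likelihood-based tests of alternative tree topologies (SH and AU)
#'
#' Compares candidate topologies on one alignment using resampling of
#' estimated per-site log-likelihoods (RELL). The Shimodaira-Hasegawa test
#' centers each tree's resampled totals at its own mean and compares the
#' max-step statistic to the observed log-likelihood deficit; the
#' approximately unbiased test fits the signed-distance/curvature normal
#' model to multiscale RELL bootstrap probabilities (scales 0.5-1.4x the
#' site count) by weighted least squares. Branch lengths of every candidate
#' are re-optimized under the shared model before per-site likelihoods are
#' computed.
#'
#' @param aln A `gene_alignment`.
#' @param trees List of candidate `phylo` trees (identical leaf sets).
#' @param model A `gtr_model` shared across candidates.
#' @param method `"SH"` or `"AU"`.
#' @param n_rell RELL resampling draws per scale (default 1000).
#' @param seed RNG seed.
#' @param optimize_edges Re-optimize branch lengths per candidate
#'   (default TRUE).
#' @return An object of class `topology_test` whose `table` is a tibble with
#'   `tree`, `log_lik`, `delta` (log-likelihood deficit relative to the best
#'   candidate) and `p_value`.
#' @export
topology_test <- function(aln, trees, model, method = c("SH", "AU"),
                          n_rell = 1000, seed = 1, optimize_edges = TRUE) {
  method <- match.arg(method)
  if (length(trees) < 2) stop("need at least 2 candidate trees", call. = FALSE)
  leafsets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(leafsets, identical, logical(1), leafsets[[1]])))
    stop("candidate trees have unequal leaf sets", call. = FALSE)
  pd <- aln_phyDat(aln)
  site_ll <- lapply(trees, function(tr) {
    if (optimize_edges) {
      f <- phangorn::pml(ape::unroot(tr), pd, model = "GTR", k = model$k,
                         shape = if (is.finite(model$shape)) model$shape else 100,
                         inv = model$p_inv, bf = model$base_freqs,
                         Q = unname(model$rates))
      f <- tryCatch(
        phangorn::optim.pml(f, optEdge = TRUE,
                            control = phangorn::pml.control(trace = 0)),
        error = function(e) f)
      tr <- f$tree
    }
    log_likelihood(aln, tr, model)$per_site
  })
  M <- do.call(cbind, site_ll)            # sites x trees
  tot <- colSums(M)
  delta <- max(tot) - tot
  S <- nrow(M)
  K <- ncol(M)
  set.seed(seed)
  p <- if (method == "SH") {
    Tm <- matrix(0, n_rell, K)
    for (b in seq_len(n_rell)) {
      idx <- sample.int(S, replace = TRUE)
      Tm[b, ] <- colSums(M[idx, , drop = FALSE])
    }
    Tc <- sweep(Tm, 2, colMeans(Tm))
    Smax <- apply(Tc, 1, max)
    vapply(seq_len(K), function(i) mean(Smax - Tc[, i] >= delta[i]), numeric(1))
  } else {
    au_test_p(M, n_rell)
  }
  structure(list(
    table = tibble::tibble(tree = seq_len(K), log_lik = tot,
                           delta = delta, p_value = p),
    method = method, n_rell = n_rell, trees = trees), class = "topology_test")
}

# AU test: multiscale RELL + WLS fit of qnorm(1 - bp) = d*sqrt(r) + c/sqrt(r)
au_test_p <- function(M, n_rell, scales = seq(0.5, 1.4, by = 0.1)) {
  S <- nrow(M); K <- ncol(M)
  bp <- matrix(0, length(scales), K)
  for (si in seq_along(scales)) {
    m <- max(2L, round(scales[si] * S))
    wins <- numeric(K)
    for (b in seq_len(n_rell)) {
      idx <- sample.int(S, m, replace = TRUE)
      tot <- colSums(M[idx, , drop = FALSE])
      wmax <- which(tot == max(tot))
      wins[wmax] <- wins[wmax] + 1 / length(wmax)
    }
    bp[si, ] <- wins / n_rell
  }
  r <- scales
  vapply(seq_len(K), function(i) {
    bpi <- bp[, i]
    use <- bpi > 0 & bpi < 1
    if (sum(use) < 2) {
      # degenerate: tree (almost) always or never wins at every scale
      return(if (mean(bpi) > 0.5) 1 else 0)
    }
    bpi_u <- pmin(pmax(bpi[use], 1 / (2 * n_rell)), 1 - 1 / (2 * n_rell))
    z <- qnorm(1 - bpi_u)
    X <- cbind(sqrt(r[use]), 1 / sqrt(r[use]))
    w <- n_rell * stats::dnorm(z)^2 / (bpi_u * (1 - bpi_u))
    fit <- stats::lm.wfit(X, z, w)
    d <- fit$coefficients[1]; cc <- fit$coefficients[2]
    min(1, max(0, 1 - pnorm(d - cc)))
  }, numeric(1))
}

#' @export
print.topology_test <- function(x, ...) {
  cat("<topology_test> ", x$method, " test, ", nrow(x$table),
      " candidate trees, ", x$n_rell, " RELL draws\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy topology_test
#' @export
tidy.topology_test <- function(x, ...) x$table

#' @method glance topology_test
#' @export
glance.topology_test <- function(x, ...) {
  tibble::tibble(method = x$method, n_trees = nrow(x$table),
                 best_tree = x$table$tree[which.max(x$table$log_lik)],
                 n_rejected_05 = sum(x$table$p_value < 0.05),
                 n_rell = x$n_rell)
}
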