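#' Felsenstein-pruning log-likelihood under GTR+Gamma+I
#'
#' Computes the total and per-site log-likelihood of an alignment on a tree
#' by the pruning algorithm, with the discrete-Gamma / invariant-sites
#' mixture of [gtr_model()]. Gaps and `N` are treated as missing data
#' (partial likelihood 1 for every state). Site patterns are compressed, and
#' partials are rescaled per node to avoid underflow. The result is
#' invariant under re-rooting because the model is time-reversible.
#'
#' @param aln A `gene_alignment`.
#' @param tree An `ape::phylo` tree whose tip labels are record ids of
#'   `aln` (branch lengths in expected substitutions/site).
#' @param model A `gtr_model`.
#' @return A list with `total` (log-likelihood) and `per_site` (numeric
#'   vector over alignment columns summing to `total`).
#' @export
log_likelihood <- function(aln, tree, model) {
  if (!all(tree$tip.label %in% aln_ids(aln)))
    stop("tree tips missing from alignment: ",
         paste(setdiff(tree$tip.label, aln_ids(aln)), collapse = ", "),
         call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  seqs <- aln$seqs[tree$tip.label, , drop = FALSE]
  L <- ncol(seqs)
  # pattern compression
  pat_key <- apply(seqs, 2, paste, collapse = "")
  upat <- match(pat_key, unique(pat_key))
  first <- !duplicated(pat_key)
  cols <- which(first)
  P <- length(cols)
  bases <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  pi <- model$base_freqs
  w_var <- (1 - model$p_inv) / model$k
  # invariant-site likelihood per pattern: sum of pi over states compatible
  # with every (non-missing) tip
  inv_lik <- numeric(P)
  if (model$p_inv > 0) {
    for (p in seq_len(P)) {
      colv <- seqs[, cols[p]]
      obs <- unique(colv[colv %in% bases])
      inv_lik[p] <- if (length(obs) == 0) 1
      else if (length(obs) == 1) pi[obs] else 0
    }
  }
  # tip partials (4 x P), shared across categories
  tip_part <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    m <- matrix(1, 4, P, dimnames = list(bases, NULL))
    v <- seqs[i, cols]
    known <- v %in% bases
    if (any(known)) {
      m[, known] <- 0
      m[cbind(match(v[known], bases), which(known))] <- 1
    }
    tip_part[[i]] <- m
  }
  root <- ntip + 1L
  cat_loglik <- matrix(-Inf, model$k, P)
  for (cc in seq_len(model$k)) {
    r <- model$cat_rates[cc]
    partial <- vector("list", ntip + nnode)
    scaler <- matrix(0, 1, P)  # log-scale accumulated per pattern
    for (i in seq_len(ntip)) partial[[i]] <- tip_part[[i]]
    node_scaler <- rep(list(NULL), ntip + nnode)
    for (i in seq_len(ntip)) node_scaler[[i]] <- numeric(P)
    for (e in seq_along(tr$edge.length)) {
      child <- tr$edge[e, 2]
      parent <- tr$edge[e, 1]
      Pm <- gtr_prob(model, r * tr$edge.length[e])
      contrib <- Pm %*% partial[[child]]
      if (is.null(partial[[parent]])) {
        partial[[parent]] <- contrib
        node_scaler[[parent]] <- node_scaler[[child]]
      } else {
        partial[[parent]] <- partial[[parent]] * contrib
        node_scaler[[parent]] <- node_scaler[[parent]] + node_scaler[[child]]
        mx <- apply(partial[[parent]], 2, max)
        mx[mx <= 0] <- 1
        partial[[parent]] <- sweep(partial[[parent]], 2, mx, "/")
        node_scaler[[parent]] <- node_scaler[[parent]] + log(mx)
      }
    }
    lik <- colSums(pi * partial[[root]])
    cat_loglik[cc, ] <- log(lik) + node_scaler[[root]]
  }
  # mixture: p_inv * inv_lik + w_var * sum_c exp(cat_loglik)
  per_pat <- vapply(seq_len(P), function(p) {
    mx <- max(cat_loglik[, p])
    var_part <- w_var * exp(cat_loglik[, p] - mx)
    log(sum(var_part) + model$p_inv * inv_lik[p] * exp(-mx)) + mx
  }, numeric(1))
  per_site <- per_pat[upat]
  list(total = sum(per_site), per_site = per_site)
}
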