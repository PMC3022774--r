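# fixtures are built in code; nothing is read from disk

rand_aln <- function(n, L, seed = 1, ids = paste0("t", seq_len(n))) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L,
              dimnames = list(ids, NULL))
  gene_alignment(m)
}

# alignment from explicit strings
aln_from <- function(...) {
  gene_alignment(c(...))
}

# standard genetic code re-derived independently for oracle checks
oracle_code <- local({
  b <- c("T", "C", "A", "G")
  codons <- character(64); i <- 0
  for (x in b) for (y in b) for (z in b) { i <- i + 1; codons[i] <- paste0(x, y, z) }
  aa <- strsplit(paste0("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
                        "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

# brute-force NG counts for a single codon pair: enumerate pathways directly
oracle_ng_pair <- function(a, b) {
  bases <- c("A", "C", "G", "T")
  site_counts <- function(cd) {
    sp <- strsplit(cd, "")[[1]]
    s <- 0
    for (i in 1:3) for (nb in setdiff(bases, sp[i])) {
      m <- sp; m[i] <- nb
      if (oracle_code[paste(m, collapse = "")] == oracle_code[cd]) s <- s + 1 / 3
    }
    c(S = s, N = 3 - s)
  }
  da <- strsplit(a, "")[[1]]; db <- strsplit(b, "")[[1]]
  pos <- which(da != db)
  perms <- if (length(pos) == 0) list() else if (length(pos) == 1) list(pos)
  else {
    out <- list()
    rec <- function(prefix, rest) {
      if (!length(rest)) { out[[length(out) + 1]] <<- prefix; return() }
      for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
    }
    rec(integer(0), pos); out
  }
  sd <- nd <- 0
  if (length(perms)) {
    tot_s <- tot_n <- 0; nv <- 0; all_s <- all_n <- 0
    for (ord in perms) {
      cur <- da; s <- n <- 0; valid <- TRUE
      for (i in ord) {
        nxt <- cur; nxt[i] <- db[i]
        if (oracle_code[paste(nxt, collapse = "")] == "*") valid <- FALSE
        if (oracle_code[paste(cur, collapse = "")] ==
            oracle_code[paste(nxt, collapse = "")]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      all_s <- all_s + s; all_n <- all_n + n
      if (valid) { tot_s <- tot_s + s; tot_n <- tot_n + n; nv <- nv + 1 }
    }
    if (nv > 0) { sd <- tot_s / nv; nd <- tot_n / nv }
    else { sd <- all_s / length(perms); nd <- all_n / length(perms) }
  }
  sa <- site_counts(a); sb <- site_counts(b)
  list(S = (sa["S"] + sb["S"]) / 2, N = (sa["N"] + sb["N"]) / 2,
       sd = sd, nd = nd)
}

# matrix exponential by scaling-and-squaring Taylor series (oracle-side)
oracle_expm <- function(A) {
  n <- nrow(A)
  s <- max(0, ceiling(log2(max(1e-12, norm(A, "1")))) + 4)
  As <- A / 2^s
  P <- diag(n); term <- diag(n)
  for (k in 1:30) {
    term <- term %*% As / k
    P <- P + term
  }
  for (k in seq_len(s)) P <- P %*% P
  P
}

# exhaustive-likelihood oracle for a 4-taxon tree ((t1,t2),(t3,t4)) with
# tip branch lengths bl[1:4] and internal branch bl[5]
oracle_loglik_4tax <- function(seqs, bl, model) {
  bases <- c("A", "C", "G", "T")
  pi <- model$base_freqs
  k <- model$k
  rates <- if (!is.finite(model$shape)) rep(1, k) else {
    q <- qgamma(seq_len(k - 1) / k, model$shape, model$shape)
    p <- c(0, pgamma(q, model$shape + 1, model$shape), 1)
    diff(p) * k
  }
  if (model$p_inv > 0) rates <- rates / (1 - model$p_inv)
  L <- ncol(seqs)
  out <- numeric(L)
  tipP <- function(rate) lapply(bl, function(t) oracle_expm(model$Q * t * rate))
  for (s in seq_len(L)) {
    obs <- seqs[, s]
    lik_var <- 0
    for (c in seq_len(k)) {
      Ps <- tipP(rates[c])
      tot <- 0
      for (x in 1:4) for (y in 1:4) {
        term <- pi[x] * Ps[[5]][x, y]
        for (tip in 1:2) {
          b <- match(obs[tip], bases)
          term <- term * if (is.na(b)) 1 else Ps[[tip]][x, b]
        }
        for (tip in 3:4) {
          b <- match(obs[tip], bases)
          term <- term * if (is.na(b)) 1 else Ps[[tip]][y, b]
        }
        tot <- tot + term
      }
      lik_var <- lik_var + (1 - model$p_inv) / k * tot
    }
    inv <- 0
    if (model$p_inv > 0) {
      ob <- unique(obs[obs %in% bases])
      inv <- if (length(ob) == 0) 1 else if (length(ob) == 1) pi[ob] else 0
    }
    out[s] <- log(lik_var + model$p_inv * inv)
  }
  out
}

# simulate a nucleotide alignment on an arbitrary tree under a gtr_model
# (neutral, site-independent) — used to create phylogenetic test signal
sim_on_tree <- function(tree, L, model, seed = 1) {
  set.seed(seed)
  tr <- ape::reorder.phylo(tree, "cladewise")
  n <- length(tr$tip.label)
  bases <- c("A", "C", "G", "T")
  node_seq <- vector("list", n + tr$Nnode)
  node_seq[[n + 1]] <- sample(1:4, L, TRUE, prob = model$base_freqs)
  for (e in seq_len(nrow(tr$edge))) {
    P <- gtr_prob(model, tr$edge.length[e])
    par <- node_seq[[tr$edge[e, 1]]]
    child <- integer(L)
    for (b in 1:4) {
      idx <- which(par == b)
      if (length(idx))
        child[idx] <- sample(1:4, length(idx), TRUE, prob = P[b, ])
    }
    node_seq[[tr$edge[e, 2]]] <- child
  }
  m <- do.call(rbind, lapply(seq_len(n), function(i) bases[node_seq[[i]]]))
  rownames(m) <- tr$tip.label
  gene_alignment(m)
}
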