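#' General time-reversible substitution model with Gamma rates and
#' invariant sites
#'
#' Constructs a GTR+Gamma+I model. Exchangeabilities are given in the order
#' AC, AG, AT, CG, CT, GT; base frequencies in the order A, C, G, T. The
#' rate matrix is scaled so that the mean substitution rate over the full
#' site-rate mixture equals 1, i.e. branch lengths are expected
#' substitutions per site. Discrete-Gamma uses equal-probability categories
#' with category means (Yang 1994); with a proportion `p_inv` of invariant
#' sites the Gamma rates are rescaled by `1/(1 - p_inv)` so the mixture mean
#' stays 1 (the convention shared by PhyML and phangorn).
#'
#' @param rates Six non-negative exchangeabilities (AC, AG, AT, CG, CT, GT);
#'   only relative values matter.
#' @param base_freqs Four base frequencies summing to 1 (A, C, G, T).
#' @param shape Gamma shape `alpha`; `Inf` means rate homogeneity.
#' @param k Number of discrete Gamma categories (default 4).
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @return An object of class `gtr_model`.
#' @export
gtr_model <- function(rates = rep(1, 6), base_freqs = rep(0.25, 4),
                      shape = Inf, k = 4L, p_inv = 0) {
  stopifnot(length(rates) == 6, all(rates >= 0), any(rates > 0),
            length(base_freqs) == 4, all(base_freqs > 0),
            shape > 0, k >= 1, p_inv >= 0, p_inv < 1)
  base_freqs <- base_freqs / sum(base_freqs)
  names(base_freqs) <- c("A", "C", "G", "T")
  names(rates) <- c("AC", "AG", "AT", "CG", "CT", "GT")
  Q <- matrix(0, 4, 4, dimnames = list(names(base_freqs), names(base_freqs)))
  Q["A", "C"] <- rates["AC"]; Q["A", "G"] <- rates["AG"]; Q["A", "T"] <- rates["AT"]
  Q["C", "G"] <- rates["CG"]; Q["C", "T"] <- rates["CT"]; Q["G", "T"] <- rates["GT"]
  Q <- Q + t(Q)
  Q <- Q * rep(base_freqs, each = 4)   # q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freqs * diag(Q))
  Q <- Q / mu
  m <- structure(list(rates = rates / sum(rates), base_freqs = base_freqs,
                      shape = shape, k = as.integer(k), p_inv = p_inv, Q = Q),
                 class = "gtr_model")
  # eigen-decomposition via symmetrization (GTR is reversible)
  sp <- sqrt(base_freqs)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  m$eig <- list(values = e$values,
                right = diag(1 / sp) %*% e$vectors,
                left = t(e$vectors) %*% diag(sp))
  m$cat_rates <- discrete_gamma_rates(shape, k)
  if (p_inv > 0) m$cat_rates <- m$cat_rates / (1 - p_inv)
  m
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("<gtr_model> GTR+G(", x$k, ")+I\n", sep = "")
  cat("  exchangeabilities:", paste(names(x$rates),
                                    signif(x$rates, 3), sep = "=", collapse = " "), "\n")
  cat("  base freqs:", paste(names(x$base_freqs),
                             signif(x$base_freqs, 3), sep = "=", collapse = " "), "\n")
  cat("  shape:", signif(x$shape, 4), " p_inv:", signif(x$p_inv, 4), "\n")
  invisible(x)
}

#' Discrete-Gamma category rates (equal-probability bins, category means)
#' @param shape Gamma shape; `Inf` gives all-1 rates.
#' @param k Number of categories.
#' @return Numeric vector of `k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, k) {
  if (!is.finite(shape) || k == 1) return(rep(1, k))
  q <- qgamma(seq_len(k - 1) / k, shape, shape)
  p <- c(0, pgamma(q, shape + 1, shape), 1)
  diff(p) * k
}

#' GTR transition probability matrix
#' @param model A `gtr_model`.
#' @param t Branch length (expected substitutions/site at rate 1).
#' @return 4x4 matrix `P(t)` with rows = ancestral, columns = derived state.
#' @export
gtr_prob <- function(model, t) {
  P <- model$eig$right %*% (exp(model$eig$values * t) * model$eig$left)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(model$Q)
  P
}
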