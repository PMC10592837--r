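# General time reversible (GTR) substitution model: rate matrix
# construction, normalization, and transition probabilities via
# eigendecomposition under pi^(1/2) symmetrization.

#' Construct a GTR substitution model
#'
#' Builds a normalized GTR rate matrix from base frequencies and the six
#' symmetric exchangeability rates (order AC, AG, AT, CG, CT, GT; the last
#' is conventionally fixed at 1 for identifiability). The rate matrix is
#' scaled so the mean substitution rate under `pi` is 1, i.e. branch lengths
#' are expected substitutions per site.
#'
#' @param pi Base frequencies (A, C, G, T); normalized internally.
#' @param rates Six exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @return A `gtr_model` object with elements `pi`, `rates`, `Q`, and the
#'   eigendecomposition used for transition probabilities.
#' @export
gtr_model <- function(pi = rep(0.25, 4), rates = rep(1, 6)) {
  stopifnot(length(pi) == 4, length(rates) == 6, all(pi > 0), all(rates > 0))
  pi <- pi / sum(pi)
  R <- matrix(0, 4, 4)
  R[1, 2] <- R[2, 1] <- rates[1]  # A-C
  R[1, 3] <- R[3, 1] <- rates[2]  # A-G
  R[1, 4] <- R[4, 1] <- rates[3]  # A-T
  R[2, 3] <- R[3, 2] <- rates[4]  # C-G
  R[2, 4] <- R[4, 2] <- rates[5]  # C-T
  R[3, 4] <- R[4, 3] <- rates[6]  # G-T
  Q <- R %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  # Symmetrize B = D Q D^-1 with D = diag(sqrt(pi)); B is symmetric for
  # reversible Q, giving a stable eigendecomposition.
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  left <- diag(1 / sp) %*% eig$vectors     # P(t) = left diag(e^{lambda t}) right
  right <- t(eig$vectors) %*% diag(sp)
  # Spectral expansion P(t) = sum_k e^{lambda_k t} left[,k] right[k,],
  # stored as a 16 x 4 matrix so P(t) for many branch lengths is a single
  # matrix product: vec(P(t_e)) = spectral %*% exp(values * t_e).
  spectral <- vapply(1:4, function(k) as.vector(outer(left[, k], right[k, ])),
                     numeric(16))
  structure(list(
    pi = pi,
    rates = rates,
    Q = Q,
    values = eig$values,
    left = left,
    right = right,
    spectral = spectral
  ), class = "gtr_model")
}

#' Transition probability matrix P(t)
#'
#' @param model A [gtr_model()].
#' @param t Branch length in expected substitutions per site (non-negative).
#' @return The 4x4 transition probability matrix, with negative round-off
#'   clipped at 0.
#' @export
transition_matrix <- function(model, t) {
  P <- model$spectral %*% exp(model$values * t)
  P[P < 0] <- 0
  dim(P) <- c(4L, 4L)
  P
}

# All transition matrices for a vector of branch lengths at once, as a
# 16 x length(t) matrix of column-vectorized P(t); column e reshapes to the
# 4 x 4 matrix for branch e. Negative round-off clipped at 0.
#' @noRd
transition_matrices <- function(model, t) {
  P <- model$spectral %*% exp(outer(model$values, t))
  P[P < 0] <- 0
  P
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("GTR model\n  pi:", signif(x$pi, 4),
      "\n  rates (AC AG AT CG CT GT):", signif(x$rates, 4), "\n")
  invisible(x)
}

# Empirical base frequencies from encoded states (integers 1..4, NA for
# ambiguous), with a small pseudocount so no frequency is exactly zero.
#' @noRd
empirical_frequencies <- function(states, weights = NULL) {
  counts <- rep(0.25, 4)  # pseudocount
  if (is.null(weights)) weights <- rep(1, ncol(states))
  for (s in 1:4) {
    hit <- states == s
    hit[is.na(hit)] <- FALSE
    counts[s] <- counts[s] + sum(colSums(hit) * weights)
  }
  counts / sum(counts)
}
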