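# Shared numeric helpers and the integer bit-encoding of binary network
# states.  Convention used throughout: a network of n neurons has states
# sigma in {-1,+1}^n, encoded as the integer whose bit i-1 (0-based) is set
# iff neuron i is spiking; R indices are the integer code + 1.

#' Enumerate all states of a binary network
#'
#' @param n Number of binary units.
#' @return A `2^n` by `n` matrix of -1/+1 values; row `s` is the state with
#'   integer code `s - 1` (neuron `i` maps to bit `i - 1`).
#' @export
all_states <- function(n) {
  stopifnot(n >= 1, n <= 20)
  codes <- 0:(2^n - 1)
  m <- vapply(seq_len(n), function(i) bitwAnd(codes, bitwShiftL(1L, i - 1L)) > 0L,
              logical(length(codes)))
  matrix(ifelse(m, 1, -1), nrow = length(codes), ncol = n)
}

# index (1-based) of the state with bit of neuron i flipped, for all states;
# columns are neurons
flip_index <- function(n) {
  codes <- 0:(2^n - 1)
  vapply(seq_len(n), function(i) bitwXor(codes, bitwShiftL(1L, i - 1L)) + 1L,
         integer(length(codes)))
}

# logical matrix: is neuron i spiking in state s?
bit_matrix <- function(n) {
  codes <- 0:(2^n - 1)
  vapply(seq_len(n), function(i) bitwAnd(codes, bitwShiftL(1L, i - 1L)) > 0L,
         logical(length(codes)))
}

#' Total spike count of every encoded network state
#'
#' @param n Number of neurons.
#' @return Integer vector of length `2^n`: number of active (+1) neurons in
#'   each state, in encoding order.
#' @export
state_spike_counts <- function(n) {
  as.integer(rowSums(bit_matrix(n)))
}

# x*log(x/y) with the 0*log0 = 0 convention; preserves dim
xlogx_ratio <- function(x, y) {
  y <- rep(y, length.out = length(x))
  out <- x
  out[] <- 0
  pos <- which(x > 0)
  out[pos] <- x[pos] * (log(x[pos]) - log(y[pos]))
  out
}

# KL divergence between Bernoulli(p) and Bernoulli(q), elementwise
kl_bernoulli <- function(p, q) {
  xlogx_ratio(p, q) + xlogx_ratio(1 - p, 1 - q)
}

# KL divergence between two discrete distributions (nats)
kl_discrete <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(p > 0 & q <= 0)) return(Inf)
  sum(xlogx_ratio(p, q))
}

# row-wise softmax of a matrix of log-weights
softmax_rows <- function(logw) {
  m <- apply(logw, 1, max)
  w <- exp(logw - m)
  w / rowSums(w)
}

# numerically stable log(a*exp(x) + b*exp(y))
log_mix_exp <- function(a, x, b, y) {
  m <- pmax(x, y)
  m + log(a * exp(x - m) + b * exp(y - m))
}

# clip probabilities away from 0/1
clip_prob <- function(p, eps = 1e-12) {
  pmin(pmax(p, eps), 1 - eps)
}

# stationary distribution of a dense row-stochastic matrix via an anchored
# linear solve; errors on non-ergodic chains
stationary_chain <- function(P, tol = 1e-9) {
  S <- nrow(P)
  if (S == 1L) return(1)
  B <- diag(S) - t(P)
  B[1, ] <- 1
  rhs <- c(1, rep(0, S - 1))
  p <- tryCatch(solve(B, rhs), error = function(e) NULL)
  ok <- !is.null(p) && all(is.finite(p)) && all(p > -tol) &&
    max(abs(drop(p %*% P) - p)) < tol
  if (!ok) {
    stop("non-ergodic chain: the policy-induced Markov chain has no unique ",
         "strictly positive stationary distribution")
  }
  p <- pmax(p, 0)
  p / sum(p)
}

# crude irreducibility check by boolean reachability
chain_irreducible <- function(P, eps = 1e-14) {
  A <- (P > eps) | diag(nrow(P)) > 0
  k <- ceiling(log2(nrow(P))) + 1L
  R <- A
  for (i in seq_len(k)) R <- (R %*% R) > 0
  all(R)
}
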