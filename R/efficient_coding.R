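# Efficient coding as entropy-regularised RL: a network maximises the
# information its state carries about a relevant stimulus feature y(x),
# under the per-neuron coding-cost constraint, by alternating
#   (i)  reward <- log posterior p(y(x) | sigma) under the current
#        stationary law, and
#   (ii) network optimisation for that reward,
# which ascends I(y; sigma) - lambda * sum_i I(sigma_i; sigma, x).

#' Mutual information between a stimulus feature and the network state
#'
#' `I(y; sigma)` in bits, computed from the exact joint stationary law of
#' the network--input chain, aggregating input states by feature label.
#'
#' @param model An `rn_binary_network`.
#' @param inputs The driving `rn_input_chain`.
#' @param feature An `rn_feature_map` labelling every input state.
#' @param stationary Optional precomputed stationary law.
#' @return Scalar information in bits, within `[0, H(y)]`.
#' @export
feature_information <- function(model, inputs, feature, stationary = NULL) {
  D <- if (is.null(stationary)) network_stationary(model, inputs) else
    stationary
  joint <- joint_feature_law(D, feature)
  p_sigma <- rowSums(joint)
  p_y <- colSums(joint)
  mi <- 0
  for (j in seq_along(p_y)) {
    mi <- mi + sum(xlogx_ratio(joint[, j], p_sigma * p_y[j]))
  }
  mi / log(2)
}

# aggregate a joint (sigma, x) law into a (sigma, y) law
joint_feature_law <- function(D, feature) {
  labs <- feature$labels
  levels <- sort(unique(labs))
  out <- vapply(levels, function(l)
    rowSums(D[, labs == l, drop = FALSE]), numeric(nrow(D)))
  colnames(out) <- as.character(levels)
  out
}

#' Optimise a network for efficient coding of a stimulus feature
#'
#' Alternates posterior/reward updates with network optimisation until the
#' encoded information stops changing.  The outer loop is not guaranteed
#' monotone, so the information trajectory is recorded and the
#' best-information iterate returned.
#'
#' @param inputs The stimulus `rn_input_chain`.
#' @param feature An `rn_feature_map` over input states.
#' @param n_neurons Number of neurons.
#' @param lambda_cost Positive coding-cost weight.
#' @param n_outer Maximum outer (reward-update) iterations.
#' @param info_tol Stop when `I(y; sigma)` changes by less than this many
#'   bits between outer iterations.
#' @param posterior_floor Floor applied to posterior probabilities before
#'   taking logs (also the uniform-prior fallback for unvisited states).
#' @param init_bias Size of the feature-aligned tilt seeding the initial
#'   response tables, `pi_i(spike | x) = 1/2 + init_bias * y(x) / 2`.  The
#'   exactly uniform start is a degenerate fixed point of the alternation
#'   (a flat posterior makes the reward constant); the tilt selects one of
#'   the two flip-symmetric nontrivial solutions.  Set to 0 to disable.
#' @param coding_cost_mode,inner_tol,max_sweeps Passed to
#'   [optimize_network()].
#' @param verbose Print the information per outer iteration.
#' @return List of class `rn_efficient_coding`: `model`, `readout` (matrix
#'   of posteriors `p(y | sigma)`), `reward` (the final log-posterior
#'   reward table), `info_bits`, `info_trace`.
#' @export
efficient_coding_optimize <- function(inputs, feature, n_neurons, lambda_cost,
                                      n_outer = 40, info_tol = 1e-4,
                                      posterior_floor = 1e-10,
                                      init_bias = 0.01,
                                      coding_cost_mode = "population",
                                      inner_tol = 1e-8, max_sweeps = 400,
                                      verbose = FALSE) {
  ns <- 2^n_neurons
  nx <- inputs$n_states
  stopifnot(length(feature$labels) == nx)
  q0 <- 0.5 + init_bias * matrix(feature$labels, ns, nx, byrow = TRUE) / 2
  model <- binary_network_model(array(rep(q0, n_neurons),
                                      dim = c(ns, nx, n_neurons)),
                                coding_cost_mode = coding_cost_mode,
                                lambda_cost = lambda_cost)
  D <- network_stationary(model, inputs)
  best <- NULL
  trace <- numeric(0)
  reward <- NULL
  for (it in seq_len(n_outer)) {
    post <- feature_posterior(D, feature, posterior_floor)
    reward <- reward_table(log(post$by_input))
    model <- optimize_network(reward, inputs, n_neurons, lambda_cost,
                              tol = inner_tol, max_sweeps = max_sweeps,
                              coding_cost_mode = coding_cost_mode,
                              init = if (it > 1) model else NULL)
    D <- attr(model, "stationary")
    info <- feature_information(model, inputs, feature, stationary = D)
    trace <- c(trace, info)
    if (verbose) message(sprintf("outer %d: I(y; sigma) = %.6f bits", it, info))
    if (is.null(best) || info >= best$info_bits) {
      best <- list(model = model, readout = post$posterior, reward = reward,
                   info_bits = info)
    }
    # the seed tilt grows geometrically at first, so only trust the
    # small-change stopping rule once the loop has had room to amplify it
    if (it >= 8 && abs(trace[it] - trace[it - 1]) < info_tol) break
  }
  post <- feature_posterior(attr(best$model, "stationary"), feature,
                            posterior_floor)
  best$readout <- post$posterior
  best$info_trace <- trace
  class(best) <- "rn_efficient_coding"
  best
}

# posterior p(y | sigma) from a joint stationary law, with flooring and a
# uniform fallback for unvisited network states; also expanded per input
# state as p(y(x) | sigma)
feature_posterior <- function(D, feature, floor = 1e-10) {
  joint <- joint_feature_law(D, feature)
  p_sigma <- rowSums(joint)
  post <- joint / pmax(p_sigma, .Machine$double.xmin)
  unvisited <- p_sigma <= 0
  if (any(unvisited)) {
    post[unvisited, ] <- 1 / ncol(joint)
  }
  post <- pmax(post, floor)
  post <- post / rowSums(post)
  labs <- feature$labels
  levels <- sort(unique(labs))
  by_input <- post[, match(labs, levels), drop = FALSE]
  list(posterior = post, by_input = by_input, levels = levels)
}

#' Independent-neuron control with matched stimulus-dependent rates
#'
#' Builds a network whose neurons spike independently given the current
#' input, with spiking probabilities matched to the model's stationary
#' conditionals `p(sigma_i = 1 | x)`; the standard baseline for asking how
#' much recurrent coordination adds to the encoded information.
#'
#' @inheritParams feature_information
#' @return An `rn_binary_network` with state-independent response tables.
#' @export
independent_control <- function(model, inputs, stationary = NULL) {
  D <- if (is.null(stationary)) network_stationary(model, inputs) else
    stationary
  n <- model$n_neurons
  geom <- net_geometry(n)
  nx <- inputs$n_states
  p_x <- colSums(D)
  cond <- matrix(0, n, nx)
  for (i in seq_len(n)) {
    cond[i, ] <- colSums(D[geom$bits[, i], , drop = FALSE]) /
      pmax(p_x, .Machine$double.xmin)
  }
  cond <- clip_prob(cond)
  Q <- array(0, dim = c(2^n, nx, n))
  for (i in seq_len(n)) {
    Q[, , i] <- matrix(cond[i, ], 2^n, nx, byrow = TRUE)
  }
  binary_network_model(Q, coding_cost_mode = model$coding_cost_mode,
                       lambda_cost = model$lambda_cost)
}
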