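# Asynchronous binary recurrent network: at each time step one neuron,
# chosen uniformly at random, resamples its state from its response table
# pi_i(sigma_i | sigma, x) while the input makes one Markov step.  The
# network is optimised by treating each neuron's response table as the
# policy of an entropy-regularised MDP over the joint (network, input)
# state and cycling soft-greedy updates over neurons.
#
# All exact computations work on matrices indexed [network state (2^n),
# input state]; the network part of the transition operator is applied
# through precomputed single-bit flip indices, never as an explicit
# 4^n matrix.

#' Construct a binary network model
#'
#' @param spike_prob Array of dimension `c(2^n, n_input_states, n)`;
#'   `spike_prob[s, x, i]` is the probability that neuron `i` proposes a
#'   spike (`sigma_i = +1`) given joint state `(s, x)`.  A valid response
#'   table does not depend on neuron `i`'s own current bit.
#' @param spike_marginals Optional length-`n` vector of stationary proposal
#'   marginals `p(sigma_i = +1)`; computed on demand when `NULL`.
#' @param coding_cost_mode `"per_neuron"` (each neuron penalised against its
#'   own marginal) or `"population"` (penalised against the population-mean
#'   spiking probability).
#' @param lambda_cost The coding-cost weight the model was optimised at
#'   (`NA` for hand-built models).
#' @return An object of class `rn_binary_network`.
#' @export
binary_network_model <- function(spike_prob, spike_marginals = NULL,
                                 coding_cost_mode = c("per_neuron", "population"),
                                 lambda_cost = NA_real_) {
  coding_cost_mode <- match.arg(coding_cost_mode)
  stopifnot(is.array(spike_prob), length(dim(spike_prob)) == 3)
  n <- dim(spike_prob)[3]
  stopifnot(dim(spike_prob)[1] == 2^n, all(spike_prob >= 0),
            all(spike_prob <= 1))
  structure(list(n_neurons = n, n_input_states = dim(spike_prob)[2],
                 spike_prob = spike_prob, spike_marginals = spike_marginals,
                 coding_cost_mode = coding_cost_mode,
                 lambda_cost = lambda_cost, converged = NA),
            class = "rn_binary_network")
}

# ---- internal engine -------------------------------------------------------

net_geometry <- function(n) {
  list(n = n, idx = seq_len(2^n), flip = flip_index(n), bits = bit_matrix(n))
}

# one application of the joint transition operator to a distribution
# D[s, x]; network update (random neuron resampled) then input step
net_dist_step <- function(D, Q, Px, geom) {
  n <- geom$n
  Dn <- matrix(0, nrow(D), ncol(D))
  for (i in seq_len(n)) {
    Qi <- Q[, , i]
    Aup <- D * Qi
    Adn <- D - Aup
    up_mass <- Aup + Aup[geom$flip[, i], , drop = FALSE]
    dn_mass <- Adn + Adn[geom$flip[, i], , drop = FALSE]
    Ti <- up_mass
    Ti[!geom$bits[, i], ] <- dn_mass[!geom$bits[, i], ]
    Dn <- Dn + Ti
  }
  (Dn / n) %*% Px
}

# dense joint transition over states k = (x - 1) * 2^n + s (internal)
net_dense_joint <- function(Q, Px, geom) {
  ns <- nrow(Q); nx <- ncol(Q); n <- geom$n
  M <- matrix(0, ns * nx, ns * nx)
  for (x in seq_len(nx)) {
    Pnet <- matrix(0, ns, ns)
    for (i in seq_len(n)) {
      qi <- Q[, x, i]
      up <- ifelse(geom$bits[, i], geom$idx, geom$flip[, i])
      dn <- ifelse(geom$bits[, i], geom$flip[, i], geom$idx)
      Pnet[cbind(geom$idx, up)] <- Pnet[cbind(geom$idx, up)] + qi / n
      Pnet[cbind(geom$idx, dn)] <- Pnet[cbind(geom$idx, dn)] + (1 - qi) / n
    }
    for (x2 in seq_len(nx)) {
      M[(x - 1) * ns + geom$idx, (x2 - 1) * ns + geom$idx] <-
        Pnet * Px[x, x2]
    }
  }
  M
}

# joint spaces up to this size use dense direct solves; power / value
# iteration cannot be trusted on slow-mixing (metastable) chains
.rn_direct_limit <- 300L

# exact stationary law of the joint chain: dense solve for small systems,
# (warm-started) power iteration otherwise
net_stationary <- function(Q, Px, geom, init = NULL, tol = 1e-13,
                           max_iter = 200000L) {
  N <- nrow(Q) * ncol(Q)
  if (N <= .rn_direct_limit) {
    p <- stationary_chain(net_dense_joint(Q, Px, geom))
    return(matrix(p, nrow(Q), ncol(Q)))
  }
  D <- if (is.null(init)) matrix(1 / N, nrow(Q), ncol(Q)) else init
  for (it in seq_len(max_iter)) {
    Dn <- net_dist_step(D, Q, Px, geom)
    if (sum(abs(Dn - D)) < tol) return(Dn)
    D <- Dn
  }
  warning("stationary power iteration hit the iteration cap")
  D
}

# expected next-step value <v(sigma', x')> for every current (sigma, x);
# W must be V %*% t(Px)
net_expected_value <- function(W, Q, geom) {
  n <- geom$n
  PV <- matrix(0, nrow(W), ncol(W))
  for (i in seq_len(n)) {
    up <- ifelse(geom$bits[, i], geom$idx, geom$flip[, i])
    dn <- ifelse(geom$bits[, i], geom$flip[, i], geom$idx)
    Qi <- Q[, , i]
    PV <- PV + Qi * W[up, , drop = FALSE] + (1 - Qi) * W[dn, , drop = FALSE]
  }
  PV / n
}

# relative value iteration for the anchored bias function; Ret is the
# return matrix r - lambda*c, L its stationary average under D
net_value <- function(Q, Px, Ret, L, D, geom, init = NULL, tol = 1e-10,
                      max_iter = 100000L) {
  N <- nrow(Ret) * ncol(Ret)
  if (N <= .rn_direct_limit) {
    P <- net_dense_joint(Q, Px, geom)
    p <- as.numeric(D)
    M <- diag(N) - P + matrix(1, N, 1) %*% matrix(p, 1, N)
    v <- solve(M, as.numeric(Ret) - L)
    return(matrix(v - sum(p * v), nrow(Ret), ncol(Ret)))
  }
  V <- if (is.null(init)) matrix(0, nrow(Ret), ncol(Ret)) else init
  tPx <- t(Px)
  for (it in seq_len(max_iter)) {
    W <- V %*% tPx
    Vn <- Ret - L + net_expected_value(W, Q, geom)
    Vn <- Vn - sum(D * Vn)
    if (max(abs(Vn - V)) < tol) return(Vn)
    V <- Vn
  }
  warning("value iteration hit the iteration cap")
  V
}

# per-state coding cost matrix and reference marginals
net_coding_cost <- function(Q, pm, mode, geom) {
  ref <- if (mode == "population") rep(mean(pm), geom$n) else pm
  C <- matrix(0, dim(Q)[1], dim(Q)[2])
  for (i in seq_len(geom$n)) {
    C <- C + kl_bernoulli(Q[, , i], clip_prob(ref[i]))
  }
  list(C = C, ref = clip_prob(ref))
}

# stationary proposal marginals p(sigma_tilde_i = 1)
net_marginals <- function(Q, D, geom) {
  vapply(seq_len(geom$n), function(i) sum(D * Q[, , i]), numeric(1))
}

# ---- exported operations ---------------------------------------------------

#' Joint transition matrix of the network--input chain
#'
#' Explicit dense kernel over joint states `k = (x - 1) * 2^n + s`, mostly
#' for small-system tests and oracles; all solvers use the implicit
#' flip-indexed operator instead.
#'
#' @param model An `rn_binary_network`.
#' @param inputs An `rn_input_chain`.
#' @return Row-stochastic matrix of dimension `2^n * n_input_states`.
#' @export
joint_transition <- function(model, inputs) {
  n <- model$n_neurons; ns <- 2^n; nx <- inputs$n_states
  stopifnot(model$n_input_states == nx, ns * nx <= 2^14)
  geom <- net_geometry(n)
  Q <- model$spike_prob
  M <- matrix(0, ns * nx, ns * nx)
  for (x in seq_len(nx)) {
    Pnet <- matrix(0, ns, ns)
    for (i in seq_len(n)) {
      qi <- Q[, x, i]
      up <- ifelse(geom$bits[, i], geom$idx, geom$flip[, i])
      dn <- ifelse(geom$bits[, i], geom$flip[, i], geom$idx)
      for (s in geom$idx) {
        Pnet[s, up[s]] <- Pnet[s, up[s]] + qi[s] / n
        Pnet[s, dn[s]] <- Pnet[s, dn[s]] + (1 - qi[s]) / n
      }
    }
    for (x2 in seq_len(nx)) {
      rows <- (x - 1) * ns + geom$idx
      cols <- (x2 - 1) * ns + geom$idx
      M[rows, cols] <- Pnet * inputs$transition[x, x2]
    }
  }
  M
}

#' Exact stationary law of a network model
#'
#' @inheritParams joint_transition
#' @param tol Power-iteration tolerance (L1 change per step).
#' @return Matrix `[2^n, n_input_states]` of joint stationary probabilities.
#' @export
network_stationary <- function(model, inputs, tol = 1e-13) {
  geom <- net_geometry(model$n_neurons)
  net_stationary(model$spike_prob, inputs$transition, geom, tol = tol)
}

#' Exact network objective L = <r - lambda c>
#'
#' Average reward minus `lambda` times the stationary-average coding cost,
#' both computed under the exact joint stationary law.
#'
#' @inheritParams joint_transition
#' @param reward An `rn_reward_table`.
#' @param lambda_cost Coding-cost weight.
#' @param stationary Optional precomputed stationary law.
#' @return Scalar objective value, with attributes `avg_reward` and
#'   `avg_coding_cost`.
#' @export
network_objective <- function(model, inputs, reward, lambda_cost,
                              stationary = NULL) {
  geom <- net_geometry(model$n_neurons)
  Q <- model$spike_prob
  D <- if (is.null(stationary)) {
    net_stationary(Q, inputs$transition, geom)
  } else stationary
  pm <- net_marginals(Q, D, geom)
  cc <- net_coding_cost(Q, pm, model$coding_cost_mode, geom)
  L <- sum(D * (reward$values - lambda_cost * cc$C))
  structure(L, avg_reward = sum(D * reward$values),
            avg_coding_cost = sum(D * cc$C))
}

#' Optimise the dynamics of a binary network
#'
#' Alternates value updates with per-neuron soft-greedy response updates,
#' `pi_i(spike | sigma, x) = logistic(Delta_i / (n lambda) + logit(p_i))`,
#' where `Delta_i` is the expected next-input value advantage of spiking
#' and `p_i` the reference spiking marginal, cycling neurons in fixed order
#' until the objective and the tables stop moving.  The objective is
#' non-decreasing across sweeps (each neuron's update is an exact MDP
#' policy improvement).
#'
#' @param reward An `rn_reward_table` (`2^n` rows, one column per input
#'   state).
#' @param inputs An `rn_input_chain` (use a 1-state chain for autonomous
#'   networks).
#' @param n_neurons Number of neurons `n`.
#' @param lambda_cost Positive coding-cost weight.
#' @param tol Convergence tolerance on the objective increase and on the
#'   maximum response-table change per sweep.
#' @param max_sweeps Sweep cap; exceeding it returns the model flagged
#'   `converged = FALSE`.
#' @param coding_cost_mode See [binary_network_model()].
#' @param init Optional `rn_binary_network` to warm-start from.
#' @param value_tol,stationary_tol Inner tolerances of the value iteration
#'   and the stationary power iteration.
#' @param verbose Print the objective per sweep.
#' @return An optimised `rn_binary_network`; attributes `value` and
#'   `stationary` carry the final bias function and stationary law, fields
#'   `objective`, `avg_reward`, `avg_coding_cost`, `trace` the final and
#'   per-sweep objectives.
#' @export
optimize_network <- function(reward, inputs, n_neurons, lambda_cost,
                             tol = 1e-8, max_sweeps = 400,
                             coding_cost_mode = c("per_neuron", "population"),
                             init = NULL, value_tol = 1e-10,
                             stationary_tol = 1e-13, verbose = FALSE) {
  coding_cost_mode <- match.arg(coding_cost_mode)
  stopifnot(lambda_cost > 0)
  n <- n_neurons; ns <- 2^n; nx <- inputs$n_states
  stopifnot(nrow(reward$values) == ns, ncol(reward$values) == nx,
            n + log2(nx) <= 16)
  geom <- net_geometry(n)
  Px <- inputs$transition; tPx <- t(Px)
  Q <- if (!is.null(init)) init$spike_prob else array(0.5, dim = c(ns, nx, n))
  D <- attr(init, "stationary")
  V <- attr(init, "value")
  refresh <- function(Q, D, V) {
    D <- net_stationary(Q, Px, geom, init = D, tol = stationary_tol)
    pm <- net_marginals(Q, D, geom)
    cc <- net_coding_cost(Q, pm, coding_cost_mode, geom)
    Ret <- reward$values - lambda_cost * cc$C
    L <- sum(D * Ret)
    V <- net_value(Q, Px, Ret, L, D, geom, init = V, tol = value_tol)
    list(D = D, pm = pm, ref = cc$ref, C = cc$C, L = L, V = V)
  }
  st <- refresh(Q, D, V)
  trace <- numeric(0)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    Q_old <- Q
    L_old <- st$L
    for (i in seq_len(n)) {
      W <- st$V %*% tPx
      up <- ifelse(geom$bits[, i], geom$idx, geom$flip[, i])
      dn <- ifelse(geom$bits[, i], geom$flip[, i], geom$idx)
      delta <- W[up, , drop = FALSE] - W[dn, , drop = FALSE]
      Q[, , i] <- clip_prob(stats::plogis(
        delta / (n * lambda_cost) + stats::qlogis(st$ref[i])))
      st <- refresh(Q, st$D, st$V)
    }
    trace <- c(trace, st$L)
    if (verbose) message(sprintf("sweep %d: L = %.10f", sweep, st$L))
    d_Q <- max(abs(Q - Q_old))
    if (abs(st$L - L_old) < tol && d_Q < tol) {
      converged <- TRUE
      break
    }
  }
  model <- binary_network_model(Q, spike_marginals = st$pm,
                                coding_cost_mode = coding_cost_mode,
                                lambda_cost = lambda_cost)
  model$converged <- converged
  model$objective <- st$L
  model$avg_reward <- sum(st$D * reward$values)
  model$avg_coding_cost <- sum(st$D * st$C)
  model$trace <- trace
  attr(model, "value") <- st$V
  attr(model, "stationary") <- st$D
  model
}

#' Simulate a binary network
#'
#' Samples the asynchronous dynamics (one random neuron resampled per step,
#' input advancing one Markov step) after a burn-in, using R's RNG so runs
#' are reproducible under `set.seed`-style seeds.
#'
#' @inheritParams joint_transition
#' @param n_steps Number of recorded steps.
#' @param seed Integer seed.
#' @param burn_in Discarded initial steps (default `100 * n * 2^n`, capped
#'   at 10^6).
#' @param return_raster Also return the time-by-neuron -1/+1 raster.
#' @return List with `states` (1-based network state codes), `input_states`
#'   and, if requested, `raster` and `input_labels`.
#' @export
simulate_network <- function(model, inputs, n_steps, seed = 1,
                             burn_in = NULL, return_raster = TRUE) {
  n <- model$n_neurons; ns <- 2^n; nx <- inputs$n_states
  if (is.null(burn_in)) burn_in <- min(100 * n * ns, 1e6)
  set.seed(seed)
  px_cum <- t(apply(inputs$transition, 1, cumsum))
  if (nx == 1) px_cum <- matrix(1, 1, 1)
  s0 <- sample.int(ns, 1) - 1L
  x0 <- sample.int(nx, 1) - 1L
  out <- cpp_simulate_network(as.numeric(model$spike_prob), n, ns, nx,
                              px_cum, as.integer(n_steps),
                              as.integer(burn_in), s0, x0)
  states <- out$states + 1L
  xs <- out$inputs + 1L
  res <- list(states = states, input_states = xs)
  if (return_raster) {
    res$raster <- matrix(ifelse(bit_matrix(n)[states, , drop = FALSE], 1L, -1L),
                         ncol = n)
    if (!is.null(inputs$labels) && is.atomic(inputs$labels) &&
        is.null(dim(inputs$labels))) {
      res$input_labels <- inputs$labels[xs]
    }
  }
  res
}

#' Calibrate lambda to hit a target coding cost
#'
#' Bisects `lambda` (on a log scale), re-optimising the network at each
#' step, until the stationary-average coding cost matches `target_cost`
#' within a relative tolerance.  The average coding cost is monotonically
#' non-increasing in `lambda`; the bracket must straddle the target.
#'
#' @inheritParams optimize_network
#' @param target_cost Desired stationary-average coding cost (nats).
#' @param lambda_bracket Length-2 positive bracket for `lambda`.
#' @param cost_tol Relative tolerance on the achieved cost (default 2%).
#' @param max_bisect Bisection cap.
#' @param ... Further arguments to [optimize_network()].
#' @return List with the calibrated `model` and the `lambda` found.
#' @export
match_coding_cost <- function(reward, inputs, n_neurons, target_cost,
                              lambda_bracket, cost_tol = 0.02,
                              max_bisect = 40, ...) {
  stopifnot(length(lambda_bracket) == 2, all(lambda_bracket > 0),
            target_cost > 0)
  lo <- min(lambda_bracket); hi <- max(lambda_bracket)
  cost_at <- function(lambda, init = NULL) {
    m <- optimize_network(reward, inputs, n_neurons, lambda, init = init, ...)
    list(model = m, cost = m$avg_coding_cost)
  }
  at_lo <- cost_at(lo); at_hi <- cost_at(hi)
  if (!(at_lo$cost >= target_cost && at_hi$cost <= target_cost)) {
    stop(sprintf(paste0("bracket does not straddle the target cost: ",
                        "cost(%.4g) = %.6g, cost(%.4g) = %.6g, target %.6g"),
                 lo, at_lo$cost, hi, at_hi$cost, target_cost))
  }
  best <- NULL
  for (it in seq_len(max_bisect)) {
    mid <- sqrt(lo * hi)
    at_mid <- cost_at(mid, init = at_lo$model)
    best <- list(model = at_mid$model, lambda = mid)
    if (abs(at_mid$cost - target_cost) <= cost_tol * target_cost) break
    if (at_mid$cost > target_cost) {
      lo <- mid; at_lo <- at_mid
    } else {
      hi <- mid; at_hi <- at_mid
    }
  }
  best
}
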