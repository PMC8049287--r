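# Scalable track for larger (input-free) networks: the value function is
# approximated by a quadratic (pairwise-Ising) form
#   v(sigma) = sum_{i, j != i} J_ij sigma_i sigma_j + sum_i h_i sigma_i,
# trained by sampled stochastic gradient descent against a bootstrap
# target, fitted from rasters by transition maximum likelihood, and
# inverted to a reward under sparse / pairwise / global parametric
# assumptions.

#' Quadratic (Ising) value-function parameters
#'
#' @param couplings Symmetric coupling matrix `J` with zero diagonal.
#' @param biases Bias vector `h`.
#' @param rate Reference spiking probability (population-averaged marginal,
#'   scalar, or one value per neuron).
#' @param lambda_cost The coding-cost weight the parameters refer to.
#' @return An object of class `rn_ising_params`.
#' @export
ising_value_params <- function(couplings, biases, rate = 0.5,
                               lambda_cost = NA_real_) {
  J <- as.matrix(couplings)
  n <- nrow(J)
  stopifnot(ncol(J) == n, length(biases) == n,
            max(abs(J - t(J))) < 1e-10, all(abs(diag(J)) < 1e-12),
            length(rate) %in% c(1L, n))
  structure(list(couplings = (J + t(J)) / 2, biases = as.numeric(biases),
                 rate = rate, lambda_cost = lambda_cost, n_neurons = n),
            class = "rn_ising_params")
}

# v(sigma) for rows of a -1/+1 state matrix
quad_value <- function(S, J, h) {
  rowSums((S %*% J) * S) + drop(S %*% h)
}

# soft coding-cost terms: for every row sigma and neuron i,
# log( p_i exp(v(sigma^{i<-1}) / (n lambda)) +
#      (1 - p_i) exp(v(sigma^{i<- -1}) / (n lambda)) );
# returns the row sums over the requested neurons
ising_soft_term <- function(S, J, h, rate, lambda, neurons = NULL) {
  n <- ncol(S)
  if (is.null(neurons)) neurons <- seq_len(n)
  rate <- rep(clip_prob(rate), length.out = n)
  v <- quad_value(S, J, h)
  G <- 2 * (S %*% J) + matrix(h, nrow(S), n, byrow = TRUE)
  total <- numeric(nrow(S))
  for (i in neurons) {
    v_up <- (v + (1 - S[, i]) * G[, i]) / (n * lambda)
    v_dn <- (v + (-1 - S[, i]) * G[, i]) / (n * lambda)
    total <- total + log_mix_exp(rate[i], v_up, 1 - rate[i], v_dn)
  }
  total
}

#' Train Ising value parameters by sampled temporal-difference descent
#'
#' Samples batches from the evolving asynchronous dynamics and performs
#' stochastic gradient updates of `(J, h)` towards the bootstrap target
#' `v_hat(sigma) = r(sigma) - L_hat + lambda * sum_{s} log sum_s p(s) exp(v_target(sigma^{i<-s}) / (n lambda))`,
#' with the target parameters refreshed every `n_epoch` batches.  `L_hat`
#' is a running estimate of the average return, tracked alongside the
#' parameters as in standard differential (average-reward) TD learning;
#' without it the bootstrap target drifts by the average return per
#' refresh and training diverges for all but tiny learning rates.
#'
#' @param reward An input-free `rn_reward_table` (single column) or a
#'   numeric vector over the `2^n` encoded states.
#' @param n_neurons Number of neurons.
#' @param lambda_cost Positive coding-cost weight.
#' @param learning_rate Base learning rate `eta`; decayed as
#'   `eta / sqrt(round)`.
#' @param n_batch Samples per gradient update.
#' @param n_epoch Batches between target refreshes.
#' @param n_rounds Number of target refreshes.
#' @param seed RNG seed.
#' @param coupling_mask Optional logical matrix; couplings at `FALSE`
#'   entries are clamped to zero (structural perturbations).
#' @param pinned Optional indices of neurons clamped permanently active;
#'   they are never resampled and excluded from the coding-cost sum.
#' @param rate_damping Per-batch damping of the running population rate.
#' @param explore Probability that a training-time chain update resamples
#'   the selected neuron from a fair coin rather than the current policy;
#'   keeps the on-policy part of each batch covering the neighbourhood of
#'   the attractor once the dynamics sharpen.
#' @param uniform_mix Fraction of each batch drawn i.i.d. uniform over
#'   states instead of from the trajectory.  The uniform part keeps the
#'   feature second-moment matrix well conditioned everywhere, so value
#'   errors at unvisited states are corrected rather than free to run
#'   away; the on-policy part keeps the fit weighted towards the states
#'   the trained network actually occupies.
#' @param reward_resets When `TRUE` the sampling chain is restarted before
#'   every batch from a (randomly chosen) maximal-reward state.  The
#'   reward is sparse, so an unguided chain can sharpen around an
#'   unrewarded attractor before ever seeing it; restarting at rewarded
#'   states keeps the on-policy emphasis anchored where the return is,
#'   and cycling the restarts over all maximal-reward states spreads the
#'   fit evenly over them (for a symmetric reward the fitted couplings
#'   then respect the symmetry instead of locking onto one attractor).
#' @param weight_decay L2 decay applied to `(J, h)` per update, damping
#'   growth along directions the sampled states do not constrain.
#' @param init Optional `rn_ising_params` to continue from.
#' @return An `rn_ising_params`; attribute `trace` holds per-round
#'   diagnostics (mean sampled reward, max |J|).
#' @export
td_train <- function(reward, n_neurons, lambda_cost, learning_rate = 0.05,
                     n_batch = 40, n_epoch = 100, n_rounds = 250, seed = 1,
                     coupling_mask = NULL, pinned = integer(0),
                     rate_damping = 0.02, explore = 0.05,
                     uniform_mix = 0, weight_decay = 0.005,
                     reward_resets = TRUE, init = NULL) {
  n <- n_neurons
  stopifnot(lambda_cost > 0, learning_rate > 0, n <= 20)
  r_all <- if (inherits(reward, "rn_reward_table")) {
    stopifnot(ncol(reward$values) == 1, nrow(reward$values) == 2^n)
    drop(reward$values)
  } else {
    stopifnot(length(reward) == 2^n)
    as.numeric(reward)
  }
  free <- setdiff(seq_len(n), pinned)
  is_pinned <- seq_len(n) %in% pinned
  if (is.null(coupling_mask)) coupling_mask <- matrix(TRUE, n, n)
  diag(coupling_mask) <- FALSE
  if (!is.null(init)) {
    J <- init$couplings; h <- init$biases; rate <- mean(rep(init$rate, n))
  } else {
    J <- matrix(0, n, n); h <- numeric(n); rate <- 0.5
  }
  Jbar <- J; hbar <- h
  Lhat <- 0
  n_unif <- round(uniform_mix * n_batch)
  n_traj <- n_batch - n_unif
  set.seed(seed)
  state <- {
    s0 <- sample.int(2^n, 1) - 1L
    for (i in pinned) s0 <- bitwOr(s0, bitwShiftL(1L, i - 1L))
    s0
  }
  bits_pow <- 2^(seq_len(n) - 1)
  trace <- data.frame(round = integer(0), mean_reward = numeric(0),
                      max_J = numeric(0), rate = numeric(0))
  # initial burn-in under the starting policy
  state <- tail(step_ising_chain(J, h, rate, lambda_cost, 100 * n, state,
                                 is_pinned, explore), 1L)
  pin_bits <- sum(bits_pow[pinned])
  top_states <- which(r_all == max(r_all)) - 1L
  do_resets <- reward_resets && max(r_all) > min(r_all)
  for (round in seq_len(n_rounds)) {
    eta <- learning_rate / sqrt(round)
    round_r <- 0
    for (epoch in seq_len(n_epoch)) {
      if (do_resets) {
        state <- top_states[sample.int(length(top_states), 1)]
        if (pin_bits > 0) state <- bitwOr(state, pin_bits)
      }
      codes <- step_ising_chain(J, h, rate, lambda_cost, n_traj, state,
                                is_pinned, explore)
      state <- tail(codes, 1L)
      if (n_unif > 0) {
        u <- sample.int(2^n, n_unif) - 1L
        if (pin_bits > 0) u <- bitwOr(u, pin_bits)
        codes <- c(codes, u)
      }
      S <- matrix(ifelse(outer(codes, bits_pow, bitwAnd) > 0, 1, -1),
                  n_batch, n)
      v <- quad_value(S, J, h)
      vhat <- r_all[codes + 1L] - Lhat +
        lambda_cost * ising_soft_term(S, Jbar, hbar, rate, lambda_cost,
                                      neurons = free)
      delta <- v - vhat
      Lhat <- Lhat - eta * mean(delta)
      round_r <- round_r + mean(r_all[codes + 1L])
      Gm <- t(S) %*% (S * delta)
      diag(Gm) <- 0
      J <- (1 - eta * weight_decay) * J - (eta / n_batch) * Gm
      J[!coupling_mask] <- 0
      J <- (J + t(J)) / 2
      h <- (1 - eta * weight_decay) * h - (eta / n_batch) * drop(t(S) %*% delta)
      if (length(free) && n_traj > 0) {
        # the reference rate tracks the on-policy marginal only
        batch_rate <- mean((S[seq_len(n_traj), free, drop = FALSE] + 1) / 2)
        rate <- (1 - rate_damping) * rate + rate_damping * batch_rate
        rate <- min(max(rate, 1e-3), 1 - 1e-3)
      }
      if (max(abs(J)) > 1e3) {
        stop("td_train diverged (|J| > 1000); trace:\n",
             paste(utils::capture.output(print(trace)), collapse = "\n"))
      }
    }
    Jbar <- J; hbar <- h
    trace <- rbind(trace, data.frame(round = round,
                                     mean_reward = round_r / n_epoch,
                                     max_J = max(abs(J)), rate = rate,
                                     L_hat = Lhat))
  }
  out <- ising_value_params(J, h, rate = rate, lambda_cost = lambda_cost)
  attr(out, "trace") <- trace
  attr(out, "pinned") <- pinned
  out
}

# advance the asynchronous chain n_steps under the soft-optimal policy
# implied by (J, h, rate, lambda); returns the visited 0-based codes
step_ising_chain <- function(J, h, rate, lambda, n_steps, s0, is_pinned,
                             explore = 0) {
  n <- length(h)
  J4 <- 4 * J / (n * lambda)
  b <- 2 * h / (n * lambda) + stats::qlogis(clip_prob(rep(rate, length.out = n)))
  cpp_simulate_ising(J4, b, as.integer(n_steps), 0L, as.integer(s0),
                     as.logical(is_pinned), explore)
}

#' Simulate the asynchronous dynamics implied by Ising value parameters
#'
#' @param params An `rn_ising_params`.
#' @param n_steps Recorded steps.
#' @param seed RNG seed.
#' @param burn_in Discarded initial steps.
#' @param pinned Indices of neurons clamped active.
#' @param init `"stationary"` draws the initial state from the exact Gibbs
#'   stationary law (the chain satisfies detailed balance with respect to
#'   it, so the trajectory is stationary from the first step and cannot be
#'   trapped by an unlucky start); `"random"` starts uniformly.
#' @param explore Probability per step that the selected neuron is
#'   resampled from a fair coin instead of the policy; 0 gives the exact
#'   model dynamics, small positive values add local excursions around the
#'   attractor (useful when the visitation law is needed over a
#'   neighbourhood rather than a handful of locked states).
#' @return Integer vector of 1-based network state codes.
#' @export
simulate_ising <- function(params, n_steps, seed = 1, burn_in = NULL,
                           pinned = attr(params, "pinned"),
                           init = c("stationary", "random"), explore = 0) {
  init <- match.arg(init)
  n <- params$n_neurons
  if (is.null(burn_in)) burn_in <- min(100 * n * 2^n, 1e6)
  if (is.null(pinned)) pinned <- integer(0)
  set.seed(seed)
  s0 <- if (init == "stationary") {
    sample.int(2^n, 1, prob = ising_stationary(params, pinned)) - 1L
  } else {
    sample.int(2^n, 1) - 1L
  }
  for (i in pinned) s0 <- bitwOr(s0, bitwShiftL(1L, i - 1L))
  J4 <- 4 * params$couplings / (n * params$lambda_cost)
  b <- 2 * params$biases / (n * params$lambda_cost) +
    stats::qlogis(clip_prob(rep(params$rate, length.out = n)))
  cpp_simulate_ising(J4, b, as.integer(n_steps), as.integer(burn_in), s0,
                     seq_len(n) %in% pinned, explore) + 1L
}

#' Exact Gibbs stationary law of an Ising-parameterised network
#'
#' The soft-optimal asynchronous dynamics satisfy detailed balance with
#' respect to `p(sigma) propto prod_i p_i(sigma_i) exp(v(sigma)/(n lambda))`;
#' this evaluates that law exactly over all `2^n` states.
#'
#' @inheritParams simulate_ising
#' @return Probability vector over encoded states.
#' @export
ising_stationary <- function(params, pinned = attr(params, "pinned")) {
  n <- params$n_neurons
  S <- all_states(n)
  rate <- clip_prob(rep(params$rate, length.out = n))
  logp <- quad_value(S, params$couplings, params$biases) /
    (n * params$lambda_cost)
  for (i in seq_len(n)) {
    logp <- logp + ifelse(S[, i] > 0, log(rate[i]), log(1 - rate[i]))
  }
  if (!is.null(pinned) && length(pinned)) {
    ok <- rowSums(S[, pinned, drop = FALSE] > 0) == length(pinned)
    logp[!ok] <- -Inf
  }
  p <- exp(logp - max(logp))
  p / sum(p)
}

#' Implied reward of Ising value parameters
#'
#' Evaluates
#' `r_hat(sigma) = v(sigma) - lambda * sum_i log sum_s p(s) exp(v(sigma^{i<-s})/(n lambda))`,
#' the reward for which the quadratic value function would be exactly
#' optimal.
#'
#' @param params An `rn_ising_params`.
#' @param lambda_cost Coding-cost weight (defaults to the one stored in
#'   `params`).
#' @param states States to evaluate: 1-based codes, a -1/+1 matrix, or
#'   `NULL` for all `2^n` states.
#' @return Numeric vector of implied rewards.
#' @export
reward_hat <- function(params, lambda_cost = params$lambda_cost,
                       states = NULL) {
  n <- params$n_neurons
  S <- if (is.null(states)) all_states(n) else if (is.matrix(states)) states
       else all_states(n)[states, , drop = FALSE]
  quad_value(S, params$couplings, params$biases) -
    lambda_cost * ising_soft_term(S, params$couplings, params$biases,
                                  params$rate, lambda_cost)
}

#' Fit Ising value parameters from a raster by transition likelihood
#'
#' Maximises the log-likelihood of the observed asynchronous single-flip
#' chain under the soft-optimal-policy form
#' `pi_i(spike | sigma) = logistic((4 sum_j J_ij sigma_j + 2 h_i)/(n lambda) + logit(p_i))`,
#' aggregating the raster into per-state flip/stay counts.  Rows whose
#' successor differs in more than one neuron are rejected and counted.
#'
#' @param raster Time-by-neuron -1/+1 matrix, or an integer vector of
#'   1-based state codes, or a list with a `states` element.
#' @param lambda_cost Coding-cost weight of the fitted parameterisation
#'   (convention: 1 when unknown).
#' @param rate Reference spiking probabilities; `NULL` uses the empirical
#'   marginals.
#' @param max_iter Optimiser iteration cap.
#' @return An `rn_ising_params`; attributes `n_rejected`, `loglik`,
#'   `converged`.
#' @export
fit_ising_from_raster <- function(raster, lambda_cost = 1, rate = NULL,
                                  max_iter = 500) {
  codes <- raster_codes(raster)
  n <- attr(codes, "n_neurons")
  ns <- 2^n
  from <- codes[-length(codes)]
  to <- codes[-1]
  d <- bitwXor(from - 1L, to - 1L)
  multi <- d != 0L & bitwAnd(d, d - 1L) != 0L
  n_rejected <- sum(multi)
  keep <- !multi
  from <- from[keep]; to <- to[keep]; d <- d[keep]
  uniq <- sort(unique(from))
  U <- length(uniq)
  S <- all_states(n)[uniq, , drop = FALSE]
  row_of <- integer(ns); row_of[uniq] <- seq_len(U)
  stay <- tabulate(row_of[from[d == 0L]], U)
  bitsS <- S > 0
  flip_i <- as.integer(round(log2(pmax(d, 1)))) + 1L
  Cup <- matrix(0, U, n)  # flips ending with neuron i active
  Cdn <- matrix(0, U, n)
  fl <- d != 0L
  if (any(fl)) {
    ended_up <- bitwAnd(to[fl] - 1L, d[fl]) > 0L
    ri <- row_of[from[fl]]; ci <- flip_i[fl]
    up_tab <- table(factor(ri[ended_up], levels = seq_len(U)),
                    factor(ci[ended_up], levels = seq_len(n)))
    dn_tab <- table(factor(ri[!ended_up], levels = seq_len(U)),
                    factor(ci[!ended_up], levels = seq_len(n)))
    Cup[] <- as.numeric(up_tab)
    Cdn[] <- as.numeric(dn_tab)
  }
  if (is.null(rate)) {
    w_state <- tabulate(row_of[from], U)
    rate <- colSums(bitsS * w_state) / sum(w_state)
  }
  rate <- clip_prob(rep(rate, length.out = n))
  # parameters: upper-triangular a_ij (eta coupling scale), then b_i
  ut <- which(upper.tri(matrix(0, n, n)))
  unpack <- function(par) {
    a <- matrix(0, n, n)
    a[ut] <- par[seq_along(ut)]
    a <- a + t(a)
    list(a = a, b = par[length(ut) + seq_len(n)])
  }
  eta_of <- function(ab) S %*% ab$a + matrix(ab$b, U, n, byrow = TRUE)
  negll <- function(par) {
    ab <- unpack(par)
    eta <- eta_of(ab)
    q_up <- stats::plogis(eta)
    q_cur <- ifelse(bitsS, q_up, 1 - q_up)
    ll <- sum(Cup * stats::plogis(eta, log.p = TRUE)) +
      sum(Cdn * stats::plogis(-eta, log.p = TRUE)) +
      sum(stay * log(pmax(rowSums(q_cur), 1e-300)))
    -ll
  }
  gradient <- function(par) {
    ab <- unpack(par)
    eta <- eta_of(ab)
    q_up <- stats::plogis(eta)
    q_cur <- ifelse(bitsS, q_up, 1 - q_up)
    stay_tot <- pmax(rowSums(q_cur), 1e-300)
    # d ll / d eta
    G <- Cup * (1 - q_up) - Cdn * q_up +
      (stay / stay_tot) * ifelse(bitsS, 1, -1) * q_up * (1 - q_up)
    ga <- t(G) %*% S
    ga <- ga + t(ga)
    -c(ga[ut], colSums(G))
  }
  fit <- stats::optim(rep(0, length(ut) + n), negll, gradient,
                      method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 1e4))
  ab <- unpack(fit$par)
  n_lambda <- n * lambda_cost
  J <- ab$a * n_lambda / 4
  diag(J) <- 0
  h <- (ab$b - stats::qlogis(rate)) * n_lambda / 2
  out <- ising_value_params(J, h, rate = rate, lambda_cost = lambda_cost)
  attr(out, "n_rejected") <- n_rejected
  attr(out, "loglik") <- -fit$value
  attr(out, "converged") <- fit$convergence == 0
  out
}

raster_codes <- function(raster) {
  if (is.list(raster) && !is.null(raster$states)) {
    codes <- as.integer(raster$states)
    n <- if (!is.null(raster$raster)) ncol(raster$raster) else
      ceiling(log2(max(codes)))
  } else if (is.matrix(raster)) {
    n <- ncol(raster)
    codes <- as.integer(((raster + 1) / 2) %*% 2^(seq_len(n) - 1)) + 1L
  } else {
    codes <- as.integer(raster)
    n <- ceiling(log2(max(codes)))
  }
  structure(codes, n_neurons = as.integer(n))
}
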