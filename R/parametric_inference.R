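# Inverting the parametric (quadratic-value) model: the optimality
# condition projects the unknown reward onto the value-function basis,
#   <f(sigma) g(sigma)^T>_D theta = <f(sigma) r_hat(sigma)>_D,
# which pins down as many reward parameters as the value function has.
# Richer reward models need extra assumptions: the sparse model minimises
# the total reward mass subject to non-negativity and the (band-relaxed)
# moment equalities, via linear programming.

# value-function feature basis: pair products (i < j) then linears
ising_features <- function(S) {
  n <- ncol(S)
  pairs <- utils::combn(n, 2)
  F <- matrix(0, nrow(S), ncol(pairs) + n)
  for (k in seq_len(ncol(pairs))) {
    F[, k] <- S[, pairs[1, k]] * S[, pairs[2, k]]
  }
  F[, ncol(pairs) + seq_len(n)] <- S
  F
}

#' Infer a parametric reward from trained Ising value parameters
#'
#' Simulates the fitted dynamics to obtain the visitation law `D`,
#' evaluates the implied reward `r_hat` on the visited states, and fits a
#' reward model through the moment conditions of the optimality criterion:
#'
#' * `"sparse"`: non-negative reward per visited state minimising total
#'   reward mass subject to the moment equalities within a band
#'   `+-epsilon` (linear program; infeasibility is absorbed by penalised
#'   slack variables whose total is reported).
#' * `"pairwise"`: `r(sigma) = sigma' W sigma`, least squares on the
#'   moment equations.
#' * `"global"`: reward depending only on the total spike count, least
#'   squares on the moment equations.
#'
#' @param params An `rn_ising_params` from [td_train()] or
#'   [fit_ising_from_raster()].
#' @param spec_type `"sparse"`, `"pairwise"` or `"global"`.
#' @param lambda_cost Coding-cost weight used to evaluate `r_hat`
#'   (defaults to the trained one).
#' @param sim Optional precomputed simulation (1-based state codes); when
#'   `NULL`, a fresh trajectory of `n_sim` steps is drawn with `seed`.
#' @param n_sim,seed Simulation length and seed when `sim` is `NULL`.
#' @param epsilon Half-width of the moment band for the sparse LP
#'   (default `1e-6 * max |r_hat|` over visited states).
#' @param max_states Cap on the number of LP variables; only the most
#'   visited states receive free reward values (the rest are fixed at 0).
#' @return A list of class `rn_reward_spec` with `type`, visited `states`
#'   (codes), `weights`, `values` (fitted reward on visited states),
#'   `r_hat` and type-specific parameters (`table`, `W` or `W_global`),
#'   plus `slack` for the sparse model.
#' @export
infer_parametric_reward <- function(params,
                                    spec_type = c("sparse", "pairwise",
                                                  "global"),
                                    lambda_cost = params$lambda_cost,
                                    sim = NULL, n_sim = 1e5, seed = 1,
                                    epsilon = NULL, max_states = 3000) {
  spec_type <- match.arg(spec_type)
  n <- params$n_neurons
  if (is.null(sim)) sim <- simulate_ising(params, n_sim, seed = seed)
  counts <- table(sim)
  codes <- as.integer(names(counts))
  w <- as.numeric(counts) / sum(counts)
  if (length(codes) > max_states) {
    keep <- order(w, decreasing = TRUE)[seq_len(max_states)]
    keep <- sort(keep)
    codes <- codes[keep]; w <- w[keep]; w <- w / sum(w)
  }
  S <- all_states(n)[codes, , drop = FALSE]
  r_hat_v <- reward_hat(params, lambda_cost, states = S)
  F <- ising_features(S)
  Fw <- F * w
  m <- drop(crossprod(Fw, r_hat_v))   # <f r_hat>_D
  out <- list(type = spec_type, n_neurons = n, states = codes, weights = w,
              r_hat = r_hat_v, lambda_cost = lambda_cost)
  if (spec_type == "sparse") {
    fit <- sparse_reward_lp(Fw, m, epsilon, r_hat_v)
    out$values <- fit$values
    out$table <- stats::setNames(fit$values, codes)
    out$slack <- fit$slack
  } else {
    G <- if (spec_type == "pairwise") {
      ising_features(S)[, seq_len(n * (n - 1) / 2), drop = FALSE]
    } else {
      spikes <- rowSums(S > 0)
      stats::model.matrix(~ 0 + factor(spikes, levels = 0:n))
    }
    M1 <- crossprod(Fw, G)
    theta <- drop(pseudo_solve(M1, m))
    out$values <- drop(G %*% theta)
    if (spec_type == "pairwise") {
      W <- matrix(0, n, n)
      W[upper.tri(W)] <- theta / 2
      out$W <- W + t(W)
    } else {
      out$W_global <- stats::setNames(theta, 0:n)
    }
    out$gradient_norm <- sqrt(sum((crossprod(M1, drop(M1 %*% theta) - m))^2))
  }
  class(out) <- "rn_reward_spec"
  out
}

# sparse model: min sum(r) + M * sum(slack)  s.t.  |Fw' r - m| <= eps + slack
sparse_reward_lp <- function(Fw, m, epsilon, r_hat_v) {
  V <- nrow(Fw); p <- ncol(Fw)
  scale <- max(abs(r_hat_v), 1e-12)
  if (is.null(epsilon)) epsilon <- 1e-6 * scale
  A <- t(Fw)                       # p x V
  big <- 1e3 * max(1, V) * max(1, scale)
  obj <- c(rep(1, V), rep(big, p))
  A1 <- cbind(A, -diag(p))
  A2 <- cbind(A, diag(p))
  fit <- boot::simplex(a = obj, A1 = A1, b1 = m + epsilon,
                       A2 = A2, b2 = m - epsilon,
                       maxi = FALSE, n.iter = 50 * (V + 2 * p), eps = 1e-10)
  if (fit$solved != 1) {
    stop("sparse reward linear program did not solve (status ", fit$solved,
         ")")
  }
  list(values = as.numeric(fit$soln[seq_len(V)]),
       slack = sum(fit$soln[V + seq_len(p)]))
}

#' Evaluate a fitted parametric reward on arbitrary states
#'
#' @param spec An `rn_reward_spec`.
#' @param states 1-based state codes (`NULL` for all `2^n`); sparse
#'   rewards evaluate to 0 outside the visited states.
#' @return Numeric reward vector.
#' @export
eval_reward_spec <- function(spec, states = NULL) {
  n <- spec$n_neurons
  if (is.null(states)) states <- seq_len(2^n)
  if (spec$type == "sparse") {
    r <- numeric(length(states))
    idx <- match(states, spec$states)
    hit <- !is.na(idx)
    r[hit] <- spec$values[idx[hit]]
    return(r)
  }
  S <- all_states(n)[states, , drop = FALSE]
  if (spec$type == "pairwise") {
    return(quad_value(S, spec$W, numeric(n)))
  }
  spikes <- rowSums(S > 0)
  as.numeric(spec$W_global[as.character(spikes)])
}

#' Predict adapted network dynamics under a perturbation
#'
#' Re-runs the appropriate optimiser under an inferred (or given) reward
#' with a perturbed constraint, the core use of an inferred objective:
#' predicting how dynamics reorganise when the conditions change while the
#' function stays fixed.
#'
#' @param reward_spec An `rn_reward_spec` (or `rn_ising_params` rewards are
#'   not accepted; convert via [infer_parametric_reward()]).
#' @param perturbation One of `"coding_cost"`, `"remove_connections"`,
#'   `"pin_neurons"`, `"remove_cell"`, `"input_stats"`.
#' @param settings Named list:
#'   * `coding_cost`: `lambda` (new coding-cost weight).  An inferred
#'     reward is only identified jointly with `lambda` (up to a common
#'     scale), and value-fit shrinkage leaves its absolute scale biased;
#'     when `reference` (the original condition's `rn_ising_params`) and
#'     `lambda_orig` are supplied, the effective lambda of the inferred
#'     reward is first calibrated so that re-optimising under it
#'     reproduces the original stationary law, and the perturbed
#'     condition is predicted at `lambda_eff * lambda / lambda_orig`.
#'   * `remove_connections`: `lambda`, `max_distance` (ring couplings
#'     beyond it are clamped to 0).
#'   * `pin_neurons`: `lambda`, `neurons` (indices clamped active).
#'   * `remove_cell` / `input_stats`: `reward` (an `rn_reward_table` for
#'     the perturbed system), `inputs`, `n_neurons`, `target_cost`,
#'     `lambda_bracket` — re-optimised with the exact tabular solver at
#'     matched coding cost.
#' @param seed RNG seed for training-based predictions.
#' @param ... Further arguments to the underlying optimiser.
#' @return An `rn_ising_params` (training-based perturbations) or an
#'   `rn_binary_network` (tabular re-optimisations).
#' @export
perturb_and_predict <- function(reward_spec,
                                perturbation = c("coding_cost",
                                                 "remove_connections",
                                                 "pin_neurons", "remove_cell",
                                                 "input_stats"),
                                settings = list(), seed = 1, ...) {
  perturbation <- match.arg(perturbation)
  if (perturbation %in% c("coding_cost", "remove_connections",
                          "pin_neurons")) {
    stopifnot(inherits(reward_spec, "rn_reward_spec"))
    n <- reward_spec$n_neurons
    r_all <- eval_reward_spec(reward_spec)
    lambda <- settings$lambda %||% reward_spec$lambda_cost
    if (!is.null(settings$reference) && !is.null(settings$lambda_orig)) {
      lambda_eff <- calibrate_effective_lambda(
        r_all, n, settings$reference, settings$lambda_orig, seed = seed, ...)
      lambda <- lambda_eff * lambda / settings$lambda_orig
    }
    mask <- NULL
    pinned <- integer(0)
    if (perturbation == "remove_connections") {
      maxd <- settings$max_distance %||% 2
      dist <- ring_distance(n)
      mask <- dist <= maxd
      diag(mask) <- FALSE
    }
    if (perturbation == "pin_neurons") {
      pinned <- settings$neurons
      stopifnot(length(pinned) >= 1)
    }
    return(td_train(r_all, n, lambda, seed = seed, coupling_mask = mask,
                    pinned = pinned, ...))
  }
  stopifnot(!is.null(settings$reward), !is.null(settings$inputs),
            !is.null(settings$n_neurons), !is.null(settings$target_cost),
            !is.null(settings$lambda_bracket))
  match_coding_cost(settings$reward, settings$inputs, settings$n_neurons,
                    settings$target_cost, settings$lambda_bracket, ...)$model
}

# effective lambda of an inferred reward: the value over a log-spaced grid
# at which re-optimising under the inferred reward best reproduces the
# reference stationary law (KL); absorbs the unidentified reward scale
calibrate_effective_lambda <- function(r_all, n, reference, lambda_orig,
                                       factors = 2^seq(-3, 1, by = 0.5),
                                       seed = 1, ...) {
  q_ref <- ising_stationary(reference)
  best <- NULL
  for (f in factors) {
    lam <- lambda_orig * f
    p <- tryCatch(td_train(r_all, n, lam, seed = seed, ...),
                  error = function(e) NULL)
    if (is.null(p)) next   # diverged at this lambda; skip the grid point
    k <- kl_discrete(q_ref, ising_stationary(p))
    if (is.null(best) || k < best$kl) best <- list(lambda = lam, kl = k)
  }
  if (is.null(best)) stop("calibration failed at every lambda in the grid")
  best$lambda
}

# minimum-norm least-squares solution via SVD (tolerant of rank deficiency)
pseudo_solve <- function(A, b, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d)
  sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
}

# circular distance between neuron indices on a ring
ring_distance <- function(n) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  pmin(d, n - d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
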