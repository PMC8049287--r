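# Inverse entropy-regularised RL for tabular MDPs: the Bellman system is
# linear in the reward, v = A (r - r0 1) + lambda b + v0 1, so the optimal
# policy can be written directly as a function of r and the reward recovered
# by maximum likelihood.  Only (r / lambda + const) is identifiable; results
# are reported mean-centred under the lambda = 1 convention unless the
# caller fixes lambda.

#' Build the linear value--reward map for an observed policy
#'
#' Computes the matrix `A` and offset `b` such that, holding the observed
#' policy (and hence its coding cost) fixed, the anchored value function of
#' any reward `r` is `v = A r + lambda b` (note `A 1 = 0`, so constant shifts
#' of the reward do not move `v`).  Verified internally against the forward
#' solver on a probe reward.
#'
#' @param policy Observed `rn_policy` (ergodic).
#' @param mdp An `rn_mdp` supplying the transition kernel and `lambda_cost`.
#' @return A list of class `rn_inverse_problem` with `A`, `b`, `Pa` (list of
#'   per-action transition matrices), `action_marginal`, `stationary`,
#'   `lambda_cost`, `policy`, `mdp`.
#' @export
build_value_map <- function(policy, mdp) {
  S <- mdp$n_states
  P <- policy_chain(policy, mdp)
  p <- stationary_chain(P)
  marg <- drop(p %*% policy$table)
  cc <- coding_cost(policy, marg)
  c0 <- sum(p * cc)
  M <- diag(S) - P + matrix(1, S, 1) %*% matrix(p, 1, S)
  Minv <- solve(M)
  A <- Minv - matrix(1, S, 1) %*% matrix(p, 1, S)  # Minv %*% (I - 1 p')
  b <- -drop(Minv %*% (cc - c0))
  Pa <- lapply(seq_len(mdp$n_actions), function(a) mdp$transition[, a, ])
  prob <- structure(list(A = A, b = b, Pa = Pa, action_marginal = marg,
                         stationary = p, lambda_cost = mdp$lambda_cost,
                         policy = policy, mdp = mdp),
                    class = "rn_inverse_problem")
  # probe: the map must reproduce the forward solver for an arbitrary reward
  probe <- seq_len(S) %% 3 - 1
  mdp_probe <- tabular_mdp(mdp$transition, probe, mdp$lambda_cost)
  v_fwd <- evaluate_policy(policy, mdp_probe)$value
  v_map <- drop(A %*% probe) + mdp$lambda_cost * b
  if (max(abs(v_fwd - v_map)) > 1e-8) {
    stop("internal check failed: value-reward map disagrees with the forward ",
         "solver (residual ", format(max(abs(v_fwd - v_map))), ")")
  }
  prob
}

# log pi*(a|s; r) under the linear map, plus pieces needed for the gradient
inverse_policy_scores <- function(problem, r) {
  lambda <- problem$lambda_cost
  v <- drop(problem$A %*% r) + lambda * problem$b
  S <- length(v); A <- length(problem$Pa)
  EV <- vapply(problem$Pa, function(P) drop(P %*% v), numeric(S))
  scores <- EV / lambda + rep(log(problem$action_marginal), each = S)
  m <- apply(scores, 1, max)
  logZ <- m + log(rowSums(exp(scores - m)))
  list(logpi = scores - logZ, pi = exp(scores - logZ), v = v)
}

#' Infer the reward of a tabular MDP by maximum likelihood
#'
#' Finds the reward vector maximising the log-likelihood of the soft-optimal
#' policy, `<log pi*(a|s; r)>_D`, over the observations.  The problem is
#' well-posed for `lambda_cost > 0` up to an additive constant (and the
#' global scale `1/lambda`); the result is reported mean-centred.
#'
#' @param problem An `rn_inverse_problem` from [build_value_map()].
#' @param observations One of: a `n_states x n_actions` count matrix; a
#'   data.frame/matrix with columns `state`, `action` (one row per observed
#'   step); or `NULL`, meaning the exact observed policy weighted by its
#'   stationary law (the infinite-data limit).
#' @param max_iter BFGS iteration cap.
#' @return List of class `rn_inferred_mdp_reward`: `reward` (centred),
#'   `loglik`, `grad_norm`, `converged`.
#' @export
infer_reward_mle <- function(problem, observations = NULL, max_iter = 500) {
  if (problem$lambda_cost <= 0) stop("reward inference requires lambda_cost > 0")
  S <- nrow(problem$A); A <- length(problem$Pa)
  W <- observation_weights(observations, problem, S, A)
  w_state <- rowSums(W)
  keep <- w_state > 0
  lambda <- problem$lambda_cost
  # pre-contract the per-action kernels with A for the gradient
  PaA <- lapply(problem$Pa, function(P) P %*% problem$A)
  negll <- function(r) {
    sc <- inverse_policy_scores(problem, r)
    -sum(W[keep, , drop = FALSE] * sc$logpi[keep, , drop = FALSE]) +
      1e-10 * sum(r^2)
  }
  grad <- function(r) {
    sc <- inverse_policy_scores(problem, r)
    g <- numeric(S)
    for (a in seq_len(A)) {
      coef <- (W[, a] - w_state * sc$pi[, a]) / lambda
      coef[!keep] <- 0
      g <- g + drop(coef %*% PaA[[a]])
    }
    -g + 2e-10 * r
  }
  fit <- stats::optim(rep(0, S), negll, grad, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  gn <- sqrt(sum(grad(fit$par)^2))
  r_hat <- fit$par - mean(fit$par)
  structure(list(reward = r_hat, loglik = -fit$value, grad_norm = gn,
                 converged = fit$convergence == 0),
            class = "rn_inferred_mdp_reward")
}

# normalise the observation formats to a state x action weight matrix
observation_weights <- function(observations, problem, S, A) {
  if (is.null(observations)) {
    return(problem$stationary * problem$policy$table)
  }
  if (is.matrix(observations) && nrow(observations) == S &&
      ncol(observations) == A) {
    return(observations)
  }
  obs <- as.data.frame(observations)
  if (!all(c("state", "action") %in% names(obs))) {
    names(obs)[1:2] <- c("state", "action")
  }
  W <- matrix(0, S, A)
  tab <- table(factor(obs$state, levels = seq_len(S)),
               factor(obs$action, levels = seq_len(A)))
  W[] <- as.numeric(tab)
  W
}
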