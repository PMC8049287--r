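# Exact tabular solver for average-reward, mutual-information-constrained
# (entropy-regularised) MDPs.
#
# The agent maximises L = <r(s) - lambda * c(s)> under the stationary law of
# the policy-induced chain, where c(s) = KL[pi(.|s) || p_pi(.)] is the coding
# cost: how far the state-conditional action distribution departs from the
# marginal action distribution.  The optimal policy is the soft-greedy
# fixed point pi*(a|s) propto p_pi(a) exp(<v(s')>_{p(s'|s,a)} / lambda).

#' Construct a tabular MDP
#'
#' @param transition A `n_states x n_actions x n_states` array;
#'   `transition[s, a, s2]` is the probability of moving to state `s2` when
#'   action `a` is taken in state `s`.  Every `(s, a)` slice must be a
#'   probability vector.
#' @param reward Numeric vector of state rewards `r(s)`.
#' @param lambda_cost Non-negative weight of the coding-cost constraint.
#' @return An object of class `rn_mdp`.
#' @export
tabular_mdp <- function(transition, reward, lambda_cost = 1) {
  stopifnot(is.array(transition), length(dim(transition)) == 3)
  S <- dim(transition)[1]
  A <- dim(transition)[2]
  stopifnot(dim(transition)[3] == S, length(reward) == S,
            all(is.finite(reward)), is.numeric(lambda_cost),
            length(lambda_cost) == 1, lambda_cost >= 0)
  if (any(transition < 0)) stop("negative transition probability")
  rs <- apply(transition, c(1, 2), sum)
  if (max(abs(rs - 1)) > 1e-12) {
    stop("transition rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  }
  structure(list(n_states = S, n_actions = A, transition = transition,
                 reward = as.numeric(reward), lambda_cost = lambda_cost),
            class = "rn_mdp")
}

#' Construct a stochastic policy table
#'
#' @param table `n_states x n_actions` matrix of action probabilities
#'   `pi(a|s)`; rows must sum to 1.
#' @param action_marginal Optional marginal action distribution `p_pi(a)`.
#'   When omitted it is computed on demand (stationary-weighted average of
#'   the rows) by the operations that need it.
#' @return An object of class `rn_policy`.
#' @export
rn_policy <- function(table, action_marginal = NULL) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0), all(table <= 1))
  if (max(abs(rowSums(table) - 1)) > 1e-12) stop("policy rows must sum to 1")
  if (!is.null(action_marginal)) {
    stopifnot(length(action_marginal) == ncol(table),
              abs(sum(action_marginal) - 1) < 1e-9)
  }
  structure(list(table = table, action_marginal = action_marginal),
            class = "rn_policy")
}

# chain induced by a policy: P[s, s'] = sum_a pi(a|s) p(s'|s, a)
policy_chain <- function(policy, mdp) {
  S <- mdp$n_states
  P <- matrix(0, S, S)
  for (a in seq_len(mdp$n_actions)) {
    P <- P + policy$table[, a] * mdp$transition[, a, ]
  }
  P
}

#' Stationary distribution of the policy-induced chain
#'
#' @param policy An `rn_policy`.
#' @param mdp An `rn_mdp`.
#' @return Probability vector over states.
#' @export
stationary_distribution <- function(policy, mdp) {
  stationary_chain(policy_chain(policy, mdp))
}

# marginal action distribution consistent with the stationary law
consistent_marginal <- function(policy, mdp, stationary = NULL) {
  if (is.null(stationary)) stationary <- stationary_distribution(policy, mdp)
  drop(stationary %*% policy$table)
}

#' Coding cost of each state
#'
#' `c(s) = KL[pi(.|s) || p_pi(.)]`, the excess description length of the
#' state-conditional action distribution relative to the marginal.
#'
#' @param policy An `rn_policy` carrying its `action_marginal` (or pass
#'   `marginal` explicitly).
#' @param marginal Optional marginal action distribution to use.
#' @return Numeric vector `c(s) >= 0`.
#' @export
coding_cost <- function(policy, marginal = policy$action_marginal) {
  if (is.null(marginal)) stop("no action marginal available; supply `marginal`")
  tab <- policy$table
  bad <- which(tab > 0 & rep(marginal, each = nrow(tab)) == 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("infinite coding cost: pi(a=%d|s=%d) > 0 but p(a=%d) = 0",
                 bad[1, 2], bad[1, 1], bad[1, 2]))
  }
  rowSums(xlogx_ratio(tab, rep(marginal, each = nrow(tab))))
}

#' Evaluate a policy: value function, average return and coding cost
#'
#' Solves the average-reward Bellman system
#' `(I - P_pi) v = (r - r0 1) - lambda (c - c0 1)` with the anchoring
#' convention that the stationary-weighted mean of `v` is zero, so the
#' arbitrary constant `v0` is fixed.
#'
#' @inheritParams stationary_distribution
#' @return A list of class `rn_value_solution` with elements `value`,
#'   `avg_return` (`L_pi = r0 - lambda c0`), `coding_cost`, `stationary`
#'   and `action_marginal`.
#' @export
evaluate_policy <- function(policy, mdp) {
  P <- policy_chain(policy, mdp)
  p <- stationary_chain(P)
  marg <- drop(p %*% policy$table)
  cc <- coding_cost(policy, marg)
  r0 <- sum(p * mdp$reward)
  c0 <- sum(p * cc)
  rhs <- (mdp$reward - r0) - mdp$lambda_cost * (cc - c0)
  S <- mdp$n_states
  M <- diag(S) - P + matrix(1, S, 1) %*% matrix(p, 1, S)
  v <- tryCatch(solve(M, rhs), error = function(e)
    stop("numerical failure solving the Bellman system: ", conditionMessage(e)))
  resid <- max(abs(v - (rhs + drop(P %*% v) - 0)))  # (I - P)v = rhs, p'v = 0
  if (resid > 1e-7) stop("Bellman solve residual too large: ", format(resid))
  structure(list(value = v, avg_return = r0 - mdp$lambda_cost * c0,
                 coding_cost = cc, stationary = p, action_marginal = marg),
            class = "rn_value_solution")
}

#' Soft greedy policy improvement
#'
#' Returns `pi*(a|s) propto p_pi(a) exp(<v(s')>_{p(s'|s,a)} / lambda)`.  The
#' marginal `p_pi(a)` itself depends on the improved policy; by default the
#' update is iterated to a joint fixed point (rows and marginal mutually
#' consistent under the new policy's own stationary law), with damping.
#'
#' @param value An `rn_value_solution` (only `value` is used).
#' @param policy The current `rn_policy` (supplies the starting marginal).
#' @param mdp An `rn_mdp` with `lambda_cost > 0`.
#' @param marginal_mode `"self-consistent"` (default) or `"fixed"`: with
#'   `"fixed"` the previous policy's marginal is held while updating the rows.
#' @param damping Damping of the marginal fixed-point iteration.
#' @param marginal_tol Convergence tolerance on the marginal.
#' @param floor Probability floor applied to rows (keeps the chain ergodic).
#' @return The improved `rn_policy`, with `action_marginal` consistent with
#'   its own stationary distribution.
#' @export
soft_greedy_update <- function(value, policy, mdp,
                               marginal_mode = c("self-consistent", "fixed"),
                               damping = 0.5, marginal_tol = 1e-10,
                               floor = 1e-12) {
  marginal_mode <- match.arg(marginal_mode)
  lambda <- mdp$lambda_cost
  if (lambda <= 0) {
    stop("soft greedy update requires lambda_cost > 0 (lambda = 0 degenerates ",
         "to a hard argmax with ties)")
  }
  v <- if (inherits(value, "rn_value_solution")) value$value else as.numeric(value)
  S <- mdp$n_states; A <- mdp$n_actions
  # EV[s, a] = <v(s')>_{p(s'|s,a)}
  EV <- vapply(seq_len(A), function(a) drop(mdp$transition[, a, ] %*% v),
               numeric(S))
  marg <- policy$action_marginal
  if (is.null(marg)) marg <- consistent_marginal(policy, mdp)
  marg <- clip_prob(marg, floor); marg <- marg / sum(marg)
  update_rows <- function(m) {
    tab <- softmax_rows(EV / lambda + rep(log(m), each = S))
    tab <- pmax(tab, floor)
    tab / rowSums(tab)
  }
  if (marginal_mode == "fixed") {
    tab <- update_rows(marg)
    pol <- rn_policy(tab)
    pol$action_marginal <- consistent_marginal(pol, mdp)
    return(pol)
  }
  for (it in seq_len(2000)) {
    tab <- update_rows(marg)
    pol <- rn_policy(tab)
    new_marg <- consistent_marginal(pol, mdp)
    new_marg <- clip_prob(new_marg, floor); new_marg <- new_marg / sum(new_marg)
    delta <- max(abs(new_marg - marg))
    marg <- damping * marg + (1 - damping) * new_marg
    marg <- marg / sum(marg)
    if (delta < marginal_tol) break
  }
  tab <- update_rows(marg)
  pol <- rn_policy(tab)
  pol$action_marginal <- consistent_marginal(pol, mdp)
  pol
}

#' Solve an entropy-regularised average-reward MDP
#'
#' Alternates exact policy evaluation with soft greedy improvement until the
#' average return and the policy have both stopped moving.  The greedy update
#' is guaranteed not to decrease `L_pi`, so the trace of returns is
#' non-decreasing up to the tolerance.
#'
#' @param mdp An `rn_mdp` with `lambda_cost > 0`.
#' @param tol Convergence tolerance on both the increase of `L` and the
#'   maximum L1 change of any policy row.
#' @param max_iter Iteration cap; exceeding it returns the best iterate
#'   flagged `converged = FALSE`.
#' @param init Optional initial `rn_policy` (default uniform).
#' @param marginal_mode Passed to [soft_greedy_update()].
#' @return A list of class `rn_rl_solution`: `policy`, `value`
#'   (an `rn_value_solution`), `trace` (average return per iteration),
#'   `converged`, `n_iter`.
#' @export
solve_entropy_rl <- function(mdp, tol = 1e-8, max_iter = 1000, init = NULL,
                             marginal_mode = "self-consistent") {
  if (mdp$lambda_cost <= 0) stop("solve_entropy_rl requires lambda_cost > 0")
  S <- mdp$n_states; A <- mdp$n_actions
  pol <- if (is.null(init)) rn_policy(matrix(1 / A, S, A)) else init
  trace <- numeric(0)
  best <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    val <- evaluate_policy(pol, mdp)
    trace <- c(trace, val$avg_return)
    if (is.null(best) || val$avg_return >= best$value$avg_return) {
      best <- list(policy = pol, value = val)
    }
    new_pol <- soft_greedy_update(val, pol, mdp, marginal_mode = marginal_mode)
    d_pol <- max(rowSums(abs(new_pol$table - pol$table)))
    d_L <- if (it > 1) trace[it] - trace[it - 1] else Inf
    pol <- new_pol
    if (d_pol < tol && abs(d_L) < tol) {
      converged <- TRUE
      break
    }
  }
  val <- evaluate_policy(pol, mdp)
  trace <- c(trace, val$avg_return)
  if (val$avg_return >= best$value$avg_return) {
    best <- list(policy = pol, value = val)
  }
  structure(list(policy = best$policy, value = best$value, trace = trace,
                 converged = converged, n_iter = length(trace)),
            class = "rn_rl_solution")
}

#' Mutual information between actions and states under a policy
#'
#' The stationary average of the coding cost, `I(a; s)` in nats.
#'
#' @inheritParams stationary_distribution
#' @return Non-negative scalar.
#' @export
policy_mutual_information <- function(policy, mdp) {
  p <- stationary_distribution(policy, mdp)
  marg <- drop(p %*% policy$table)
  sum(p * coding_cost(policy, marg))
}
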