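# End-to-end drivers for the four benchmark experiments.  Each driver
# returns a result bundle (models, laws, summary metrics) and is what the
# command-line interface and the reproduction script call.

#' Weighted coefficient of determination (squared Pearson correlation)
#'
#' @param x,y Numeric vectors.
#' @param weights Optional non-negative weights.
#' @return `r^2` in `[0, 1]`.
#' @export
r_squared <- function(x, y, weights = NULL) {
  if (is.null(weights)) return(stats::cor(x, y)^2)
  w <- weights / sum(weights)
  mx <- sum(w * x); my <- sum(w * y)
  cov <- sum(w * (x - mx) * (y - my))
  (cov^2) / (sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

#' Conditional total-spike-count distribution of a stationary law
#'
#' @param stationary Matrix `[2^n, n_input_states]` joint stationary law.
#' @return Matrix `[n + 1, n_input_states]`; column `x` is the
#'   distribution of the total spike count conditional on input state `x`
#'   (rows named by count `0..n`).
#' @export
spike_count_distribution <- function(stationary) {
  n <- round(log2(nrow(stationary)))
  spikes <- state_spike_counts(n)
  out <- apply(stationary, 2, function(col)
    vapply(0:n, function(k) sum(col[spikes == k]), numeric(1)))
  out <- as.matrix(out)
  out <- sweep(out, 2, pmax(colSums(out), .Machine$double.xmin), "/")
  rownames(out) <- 0:n
  out
}

#' Two-level spike-count coding experiment
#'
#' An 8-neuron network driven by a slow binary input is optimised (exact
#' tabular solver, population-averaged coding cost) for the reward that
#' pays 1 for exactly `counts[1]` spikes while `x = -1` and `counts[2]`
#' spikes while `x = +1`.
#'
#' @param n_neurons Network size.
#' @param lambda_cost Coding-cost weight.
#' @param p_up,p_down Input switch rates.
#' @param counts Rewarded spike counts for `x = -1` and `x = +1`.
#' @param tol,max_sweeps Solver settings.
#' @return List with the optimised `model`, `inputs`, `reward`,
#'   `stationary`, the conditional `count_distribution`, and `modes`
#'   (most probable spike count given each input state).
#' @export
experiment_two_level <- function(n_neurons = 8, lambda_cost = 0.114,
                                 p_up = 0.02, p_down = 0.02,
                                 counts = c(2, 6), tol = 1e-9,
                                 max_sweeps = 400) {
  inputs <- binary_input_chain(p_up, p_down)
  reward <- make_reward("two_level_count", n_neurons = n_neurons,
                        counts = counts)
  model <- optimize_network(reward, inputs, n_neurons, lambda_cost,
                            tol = tol, max_sweeps = max_sweeps,
                            coding_cost_mode = "population")
  D <- attr(model, "stationary")
  cd <- spike_count_distribution(D)
  list(model = model, inputs = inputs, reward = reward, stationary = D,
       count_distribution = cd,
       modes = apply(cd, 2, which.max) - 1L,
       objective = model$objective)
}

#' Ring-attractor experiment: pairwise-Ising training and reward recovery
#'
#' Trains the quadratic value function of a ring network (reward 1 iff
#' exactly `block` adjacent neurons are active) by sampled TD descent,
#' simulates the trained dynamics, and (optionally) inverts them with the
#' sparse, pairwise and global parametric reward models.
#'
#' @param n_neurons Ring size.
#' @param lambda_cost Coding-cost weight.
#' @param block Rewarded contiguous block length.
#' @param seed RNG seed for training and simulation.
#' @param n_sim Simulation length used for the visitation law and the mode
#'   state.
#' @param infer Also run the parametric reward inference.
#' @param ... Further arguments to [td_train()].
#' @return List with `params`, the true `reward` vector, the simulated
#'   `sim` codes, `mode_state` (most visited code), `mode_run` (its
#'   maximal circular run of active neurons) and, when `infer = TRUE`,
#'   per-model `specs` and `r2` against the true reward over visited
#'   states.
#' @export
experiment_ring <- function(n_neurons = 12, lambda_cost = 0.05, block = 4,
                            seed = 1, n_sim = 1e6, infer = TRUE, ...) {
  reward <- make_reward("ring_adjacent", n_neurons = n_neurons,
                        block = block)
  params <- td_train(reward, n_neurons, lambda_cost, seed = seed, ...)
  sim <- simulate_ising(params, n_sim, seed = seed + 1)
  counts <- table(sim)
  mode_state <- as.integer(names(counts)[which.max(counts)])
  run <- max_circular_run(n_neurons)
  out <- list(params = params, reward = drop(reward$values), sim = sim,
              mode_state = mode_state, mode_run = run[mode_state],
              mode_spikes = state_spike_counts(n_neurons)[mode_state])
  if (infer) {
    r_true <- drop(reward$values)
    specs <- list()
    r2 <- c()
    for (type in c("sparse", "pairwise", "global")) {
      sp <- infer_parametric_reward(params, type, sim = sim)
      specs[[type]] <- sp
      r2[type] <- r_squared(sp$values, r_true[sp$states])
    }
    out$specs <- specs
    out$r2 <- r2
  }
  out
}

#' Efficient-coding experiment: threshold feature on coupled pixels
#'
#' Optimises `n_neurons` neurons to encode the threshold feature of an
#' `m`-pixel coupled binary stimulus, then runs inverse RL on the exact
#' optimised response probabilities, groups inputs by their inferred
#' reward profile, and reports where the recovered partition splits the
#' stimulus space.
#'
#' @param m Number of pixels.
#' @param n_neurons Number of neurons.
#' @param J,J0 Stimulus coupling and bias.
#' @param threshold Feature threshold (active-pixel count mapped to +1).
#' @param lambda_cost Coding-cost weight.
#' @param infer Also run the inverse-RL feature recovery.
#' @param ... Further arguments to [efficient_coding_optimize()].
#' @return List with the `ec` fit (model, readout, information trace), the
#'   `inputs` chain, `feature`, `info_bits`, `control_info_bits`
#'   (matched independent-neuron baseline) and, when `infer = TRUE`,
#'   `inferred` reward, `partition` and `split_count` (minimal active-pixel
#'   count in the high-reward input group).
#' @export
experiment_efficient_coding <- function(m = 7, n_neurons = 7, J = 1.5,
                                        J0 = 0, threshold = 4,
                                        lambda_cost = 0.167, infer = TRUE,
                                        ...) {
  inputs <- pixel_stimulus_chain(m, J, J0)
  feature <- make_reward("threshold_feature", m = m, threshold = threshold)
  ec <- efficient_coding_optimize(inputs, feature, n_neurons, lambda_cost,
                                  ...)
  D <- network_stationary(ec$model, inputs)
  ctrl <- independent_control(ec$model, inputs, stationary = D)
  out <- list(ec = ec, inputs = inputs, feature = feature,
              info_bits = ec$info_bits,
              control_info_bits = feature_information(ctrl, inputs, feature))
  if (infer) {
    inferred <- infer_network_reward(ec$model, inputs)
    part <- recover_feature_partition(inferred, k = 2)
    active <- state_spike_counts(m)
    high_group <- part$groups[which.max(active)]  # group of the all-on input
    out$inferred <- inferred
    out$partition <- part
    out$split_count <- min(active[part$groups == high_group])
    out$high_group_counts <- sort(unique(active[part$groups == high_group]))
  }
  out
}

#' Maze navigation experiment
#'
#' Solves the maze MDP at a low and a high coding cost and inverts the
#' low-cost optimal policy back to a reward by maximum likelihood.
#'
#' @param spec An `rn_maze_spec` (default: the 15x15 maze with a pinned
#'   random barrier layout).
#' @param lambda_low,lambda_high The two coding-cost weights.
#' @param tol Solver tolerance.
#' @param infer Also run the tabular inverse RL on the low-cost policy.
#' @return List with both solutions, their average rewards and mutual
#'   informations and, when `infer = TRUE`, the inferred reward and the
#'   index of its maximum.
#' @export
experiment_maze <- function(spec = maze_spec(), lambda_low = 0.013,
                            lambda_high = 0.13, tol = 1e-8, infer = TRUE) {
  mdp_low <- build_maze(spec, lambda_low)
  mdp_high <- build_maze(spec, lambda_high)
  sol_low <- solve_entropy_rl(mdp_low, tol = tol)
  sol_high <- solve_entropy_rl(mdp_high, tol = tol)
  avg_reward <- function(sol, mdp) sum(sol$value$stationary * mdp$reward)
  out <- list(spec = spec, low = sol_low, high = sol_high,
              avg_reward_low = avg_reward(sol_low, mdp_low),
              avg_reward_high = avg_reward(sol_high, mdp_high),
              info_low = sum(sol_low$value$stationary * sol_low$value$coding_cost),
              info_high = sum(sol_high$value$stationary * sol_high$value$coding_cost))
  if (infer) {
    prob <- build_value_map(sol_low$policy, mdp_low)
    inf <- infer_reward_mle(prob)
    out$inferred_reward <- inf$reward
    out$inferred_argmax <- which.max(inf$reward)
  }
  out
}
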