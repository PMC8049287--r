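# Shared fixtures: small random MDPs, tiny networks, and a cache so that
# expensive optimisations (the two-level network, the efficient-coding
# fit, the trained ring) are computed once per test run.

.rn_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .rn_cache)) {
    assign(name, force(expr), envir = .rn_cache)
  }
  get(name, envir = .rn_cache)
}

# random ergodic tabular MDP with dense transitions
random_mdp <- function(n_states, n_actions, lambda, seed) {
  set.seed(seed)
  T <- array(0, dim = c(n_states, n_actions, n_states))
  for (s in seq_len(n_states)) {
    for (a in seq_len(n_actions)) {
      p <- stats::runif(n_states) + 0.05
      T[s, a, ] <- p / sum(p)
    }
  }
  tabular_mdp(T, stats::rnorm(n_states), lambda)
}

# brute-force grid search over all policies of a 2-state, 2-action MDP
# (rows are Bernoulli), using closed-form 2-state stationary laws
grid_search_L <- function(mdp, k = 1000) {
  g <- seq(1e-4, 1 - 1e-4, length.out = k)
  pg <- expand.grid(p1 = g, p2 = g)
  T <- mdp$transition
  # induced chain entries as functions of the two row parameters
  P11 <- pg$p1 * T[1, 1, 1] + (1 - pg$p1) * T[1, 2, 1]
  P21 <- pg$p2 * T[2, 1, 1] + (1 - pg$p2) * T[2, 2, 1]
  ps1 <- P21 / (1 - P11 + P21)
  ps2 <- 1 - ps1
  m1 <- ps1 * pg$p1 + ps2 * pg$p2   # marginal of action 1
  kl <- function(p, m) {
    t1 <- ifelse(p > 0, p * (log(p) - log(m)), 0)
    t2 <- ifelse(p < 1, (1 - p) * (log(1 - p) - log(1 - m)), 0)
    t1 + t2
  }
  c1 <- kl(pg$p1, m1); c2 <- kl(pg$p2, m1)
  L <- ps1 * (mdp$reward[1] - mdp$lambda_cost * c1) +
    ps2 * (mdp$reward[2] - mdp$lambda_cost * c2)
  max(L)
}

# random MDP whose entropy-regularised optimum keeps every action in play
# (rewards only reach the likelihood through observed actions, so reward
# recovery presupposes an interior, state-dependent optimal policy);
# sharper transition rows and a wider reward spread than random_mdp
identifiable_mdp <- function(n_states, n_actions, lambda, seed) {
  set.seed(seed)
  T <- array(0, dim = c(n_states, n_actions, n_states))
  for (s in seq_len(n_states)) {
    for (a in seq_len(n_actions)) {
      p <- stats::runif(n_states)^3 + 0.02
      T[s, a, ] <- p / sum(p)
    }
  }
  tabular_mdp(T, 2 * stats::rnorm(n_states), lambda)
}

# first `n` seeds (from seed_start) whose optimum has interior marginals
identifiable_mdp_batch <- function(n, n_states = 5, n_actions = 3,
                                   lambda = 0.1, seed_start = 500) {
  out <- list()
  seed <- seed_start
  while (length(out) < n && seed < seed_start + 20 * n) {
    seed <- seed + 1
    mdp <- identifiable_mdp(n_states, n_actions, lambda, seed)
    sol <- solve_entropy_rl(mdp, tol = 1e-10)
    if (min(sol$policy$action_marginal) > 1e-3) {
      out[[length(out) + 1]] <- list(mdp = mdp, sol = sol)
    }
  }
  out
}

no_input <- function() input_chain(matrix(1, 1, 1))

# small autonomous count-reward network, optimised with the
# population-averaged cost (the per-neuron mode admits frozen optima)
small_count_network <- function(n = 4, lambda = 0.15, target = 2,
                                tol = 1e-12) {
  reward <- reward_table(
    matrix(as.numeric(state_spike_counts(n) == target), ncol = 1))
  list(reward = reward,
       model = optimize_network(reward, no_input(), n, lambda, tol = tol,
                                coding_cost_mode = "population"))
}

two_level_fit <- function() cached("two_level", experiment_two_level())

ring_fit <- function() cached("ring", {
  reward <- make_reward("ring_adjacent", n_neurons = 12)
  params <- td_train(reward, 12, 0.05, seed = 1)
  sim <- simulate_ising(params, 1e5, seed = 2)
  list(reward = reward, params = params, sim = sim)
})

efficient_coding_fit <- function() cached("ec", experiment_efficient_coding())
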