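# Exact tabular solver for entropy-regularised average-reward MDPs.

test_that("stationary_distribution matches symmetry, doubly-stochastic and power-iteration oracles", {
  T2 <- array(0, dim = c(2, 2, 2))
  T2[, 1, ] <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, byrow = TRUE)
  T2[, 2, ] <- T2[, 1, ]
  mdp <- tabular_mdp(T2, c(0, 0), 1)
  pol <- rn_policy(matrix(0.5, 2, 2))
  expect_equal(stationary_distribution(pol, mdp), c(0.5, 0.5), tolerance = 1e-12)

  # doubly stochastic 4-state chain -> uniform
  set.seed(1)
  M <- matrix(runif(16), 4)
  for (i in 1:50) { M <- M / rowSums(M); M <- t(t(M) / colSums(M)) }
  M <- M / rowSums(M)
  T4 <- array(0, dim = c(4, 1, 4)); T4[, 1, ] <- M
  mdp4 <- tabular_mdp(T4, numeric(4), 1)
  expect_equal(stationary_distribution(rn_policy(matrix(1, 4, 1)), mdp4),
               rep(0.25, 4), tolerance = 1e-8)

  # 3-state chain against an independent power-iteration oracle
  P <- matrix(c(0.9, 0.1, 0, 0, 0.9, 0.1, 0.1, 0, 0.9), 3, byrow = TRUE)
  T3 <- array(0, dim = c(3, 1, 3)); T3[, 1, ] <- P
  mdp3 <- tabular_mdp(T3, numeric(3), 1)
  p_oracle <- rep(1 / 3, 3)
  for (i in 1:10000) {
    p_new <- drop(p_oracle %*% P)
    if (max(abs(p_new - p_oracle)) < 1e-14) break
    p_oracle <- p_new
  }
  expect_equal(stationary_distribution(rn_policy(matrix(1, 3, 1)), mdp3),
               p_oracle, tolerance = 1e-9)
})

test_that("stationary_distribution refuses non-ergodic chains", {
  T <- array(0, dim = c(2, 1, 2))
  T[1, 1, 1] <- 1; T[2, 1, 2] <- 1   # two absorbing states
  mdp <- tabular_mdp(T, c(0, 0), 1)
  expect_error(stationary_distribution(rn_policy(matrix(1, 2, 1)), mdp),
               "non-ergodic")
})

test_that("coding cost is the KL to the action marginal", {
  # rows equal to the marginal -> zero
  pol <- rn_policy(matrix(c(0.3, 0.7, 0.3, 0.7), 2, byrow = TRUE),
                   c(0.3, 0.7))
  expect_equal(coding_cost(pol), c(0, 0))
  # deterministic distinct actions vs uniform marginal -> log 2
  pol2 <- rn_policy(matrix(c(1, 0, 0, 1), 2, byrow = TRUE), c(0.5, 0.5))
  expect_equal(coding_cost(pol2), c(log(2), log(2)))
  # direct KL arithmetic
  pol3 <- rn_policy(matrix(c(0.8, 0.2), 1), c(0.5, 0.5))
  expect_equal(coding_cost(pol3), 0.8 * log(1.6) + 0.2 * log(0.4),
               tolerance = 1e-14)
  # support outside the marginal is an error
  pol4 <- rn_policy(matrix(c(0.8, 0.2), 1), NULL)
  expect_error(coding_cost(pol4, marginal = c(1, 0)), "infinite coding cost")
})

test_that("evaluate_policy solves the Bellman system and matches the truncated series", {
  # constant reward, rows equal to the marginal: v = 0, L = rho
  T <- array(0, dim = c(3, 2, 3))
  set.seed(2)
  for (s in 1:3) {
    p <- runif(3) + 0.1
    T[s, 1, ] <- p / sum(p)
    T[s, 2, ] <- T[s, 1, ]
  }
  mdp <- tabular_mdp(T, rep(1.7, 3), 0.5)
  pol <- rn_policy(matrix(c(0.4, 0.6), 3, 2, byrow = TRUE), c(0.4, 0.6))
  val <- evaluate_policy(pol, mdp)
  expect_equal(val$avg_return, 1.7, tolerance = 1e-12)
  expect_equal(val$value, rep(0, 3), tolerance = 1e-10)

  # random MDP: Bellman residual and the finite-horizon series oracle
  mdp <- random_mdp(4, 2, 0.3, seed = 11)
  set.seed(12)
  tab <- matrix(runif(8) + 0.2, 4, 2); tab <- tab / rowSums(tab)
  pol <- rn_policy(tab)
  val <- evaluate_policy(pol, mdp)
  P <- rewardnet:::policy_chain(pol, mdp)
  ret <- mdp$reward - mdp$lambda_cost * val$coding_cost
  resid <- val$value - (ret - val$avg_return + drop(P %*% val$value))
  expect_lt(max(abs(resid)), 1e-9)
  expect_equal(sum(val$stationary * val$value), 0, tolerance = 1e-9)
  # series of Eq-type v(s) = sum_t (P^t (ret - L)) truncated at 1e4
  v_series <- numeric(4)
  term <- diag(4)
  for (t in 0:10000) {
    v_series <- v_series + drop(term %*% (ret - val$avg_return))
    term <- term %*% P
  }
  v_series <- v_series - sum(val$stationary * v_series)
  expect_equal(val$value, v_series, tolerance = 1e-6)
})

test_that("soft greedy update matches its closed form and limits", {
  # deterministic 2-action transitions, hand-set value, uniform marginal
  T <- array(0, dim = c(2, 2, 2)); T[, 1, 1] <- 1; T[, 2, 2] <- 1
  mdp <- tabular_mdp(T, c(0, 0), 1)
  pol <- rn_policy(matrix(0.5, 2, 2), c(0.5, 0.5))
  val <- structure(list(value = c(1, 0)), class = "rn_value_solution")
  up <- soft_greedy_update(val, pol, mdp, marginal_mode = "fixed")
  expect_equal(unname(up$table[, 1]), rep(exp(1) / (exp(1) + 1), 2),
               tolerance = 1e-9)

  # constant value -> policy equals the marginal
  mdp2 <- random_mdp(3, 2, 1, seed = 5)
  pol2 <- rn_policy(matrix(c(0.7, 0.3), 3, 2, byrow = TRUE), c(0.7, 0.3))
  val2 <- structure(list(value = rep(2, 3)), class = "rn_value_solution")
  up2 <- soft_greedy_update(val2, pol2, mdp2, marginal_mode = "fixed")
  expect_lt(max(abs(up2$table - rep(c(0.7, 0.3), each = 3))), 1e-9)

  # enormous lambda -> rows collapse onto the marginal (the exact optimum
  # is approached along a slow marginal drift, so cap the iterations; the
  # collapse itself happens immediately)
  mdp3 <- random_mdp(3, 2, 1e6, seed = 6)
  sol3 <- solve_entropy_rl(mdp3, tol = 1e-8, max_iter = 50)
  marg <- sol3$policy$action_marginal
  expect_lt(max(abs(sol3$policy$table - rep(marg, each = 3))), 1e-3)

  expect_error(soft_greedy_update(val, pol, tabular_mdp(T, c(0, 0), 0)),
               "lambda")
})

test_that("solve_entropy_rl matches the exhaustive policy-grid oracle", {
  mdp <- random_mdp(2, 2, 0.5, seed = 101)
  sol <- solve_entropy_rl(mdp, tol = 1e-10)
  expect_true(sol$converged)
  expect_gte(sol$value$avg_return, grid_search_L(mdp) - 1e-3)
})

test_that("constant rewards yield the marginal policy and constant shifts only move L", {
  mdp <- random_mdp(3, 2, 0.4, seed = 21)
  mdp_const <- tabular_mdp(mdp$transition, rep(0.9, 3), 0.4)
  sol <- solve_entropy_rl(mdp_const, tol = 1e-11)
  marg <- sol$policy$action_marginal
  expect_lt(max(abs(sol$policy$table - rep(marg, each = 3))), 1e-6)
  expect_equal(sol$value$avg_return, 0.9, tolerance = 1e-8)

  sol_a <- solve_entropy_rl(mdp, tol = 1e-11)
  mdp_b <- tabular_mdp(mdp$transition, mdp$reward + 3.2, 0.4)
  sol_b <- solve_entropy_rl(mdp_b, tol = 1e-11)
  expect_lt(max(abs(sol_a$policy$table - sol_b$policy$table)), 1e-8)
  expect_equal(sol_b$value$avg_return - sol_a$value$avg_return, 3.2,
               tolerance = 1e-7)
})

test_that("policy improvement is monotone and the fixed point satisfies the soft-greedy identity", {
  for (seed in 1:8) {
    mdp <- random_mdp(4, 3, 0.3, seed = 300 + seed)
    sol <- solve_entropy_rl(mdp, tol = 1e-10)
    expect_true(all(diff(sol$trace) > -1e-8))
    # fixed-point identity: the greedy update leaves the policy unchanged
    up <- soft_greedy_update(sol$value, sol$policy, mdp)
    expect_lt(max(abs(up$table - sol$policy$table)), 1e-6)
  }
})

test_that("mutual information between actions and states is non-increasing in lambda", {
  mdp0 <- random_mdp(4, 2, 1, seed = 77)
  lambdas <- c(0.05, 0.1, 0.3, 0.8, 2)
  mis <- vapply(lambdas, function(l) {
    sol <- solve_entropy_rl(tabular_mdp(mdp0$transition, mdp0$reward, l),
                            tol = 1e-10)
    policy_mutual_information(sol$policy, mdp0)
  }, numeric(1))
  expect_true(all(diff(mis) <= 1e-8))
})
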