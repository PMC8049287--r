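# Asynchronous binary-network engine: transitions, optimisation,
# simulation, objective, coding-cost calibration.

test_that("joint transition matches the frozen, single-neuron and enumeration cases", {
  # frozen network: sigma never changes, the input chain acts alone
  nx <- 2
  ch <- binary_input_chain(0.1, 0.3)
  bits <- rewardnet:::bit_matrix(2)
  Qf <- array(0, dim = c(4, nx, 2))
  for (i in 1:2) Qf[, , i] <- matrix(as.numeric(bits[, i]), 4, nx)
  frozen <- binary_network_model(Qf)
  M <- joint_transition(frozen, ch)
  for (x in 1:nx) for (s in 1:4) {
    k <- (x - 1) * 4 + s
    for (x2 in 1:nx) {
      expect_equal(M[k, (x2 - 1) * 4 + s], ch$transition[x, x2])
    }
  }
  expect_lt(max(abs(rowSums(M) - 1)), 1e-12)

  # single neuron, no input: flip probabilities (q, 1 - q)
  q <- 0.3
  one <- binary_network_model(array(q, dim = c(2, 1, 1)))
  M1 <- joint_transition(one, input_chain(matrix(1, 1, 1)))
  expect_equal(M1, matrix(c(1 - q, q, 1 - q, q), 2, byrow = TRUE),
               tolerance = 1e-12)

  # 2 neurons, hand-set tables vs brute-force enumeration of the
  # asynchronous update rule
  set.seed(13)
  Q <- array(runif(4 * 1 * 2), dim = c(4, 1, 2))
  # make tables valid (independent of the neuron's own bit)
  flip <- rewardnet:::flip_index(2)
  for (i in 1:2) {
    qi <- Q[, 1, i]
    qi[bits[, i]] <- qi[flip[bits[, i], i]]
    Q[, 1, i] <- qi
  }
  model <- binary_network_model(Q)
  M2 <- joint_transition(model, input_chain(matrix(1, 1, 1)))
  oracle <- matrix(0, 4, 4)
  for (s in 1:4) {
    for (i in 1:2) {
      up <- bitwOr(s - 1, 2^(i - 1)) + 1
      dn <- bitwAnd(s - 1, bitwNot(2^(i - 1))) + 1
      oracle[s, up] <- oracle[s, up] + Q[s, 1, i] / 2
      oracle[s, dn] <- oracle[s, dn] + (1 - Q[s, 1, i]) / 2
    }
  }
  expect_equal(M2, oracle, tolerance = 1e-12)
  # single-flip support
  d <- outer(0:3, 0:3, bitwXor)
  expect_true(all(M2[d != 0 & (bitwAnd(d, d - 1) != 0)] == 0))
})

test_that("a zero reward drives response tables to the (state-independent) marginal", {
  m <- optimize_network(reward_table(matrix(0, 8, 1)),
                        input_chain(matrix(1, 1, 1)), 3, 0.2, tol = 1e-11)
  for (i in 1:3) {
    expect_lt(diff(range(m$spike_prob[, , i])), 1e-8)
  }
  expect_equal(m$objective, 0, tolerance = 1e-9)
})

test_that("count rewards concentrate the stationary law; lower lambda means less variance", {
  fit <- small_count_network(n = 4, lambda = 0.15, target = 2)
  D <- attr(fit$model, "stationary")
  cd <- spike_count_distribution(D)
  expect_equal(unname(which.max(cd[, 1])) - 1L, 2L)
  fit_lo <- small_count_network(n = 4, lambda = 0.05, target = 2)
  vr <- function(f) {
    cd <- spike_count_distribution(attr(f$model, "stationary"))
    k <- 0:4
    sum(cd[, 1] * k^2) - sum(cd[, 1] * k)^2
  }
  expect_lt(vr(fit_lo), vr(fit))
})

test_that("network_objective is exact: constants, enumeration oracle, optimiser consistency", {
  ch <- input_chain(matrix(1, 1, 1))
  # state-independent tables, constant reward -> L = rho
  Qc <- array(0.4, dim = c(4, 1, 2))
  mc <- binary_network_model(Qc, spike_marginals = c(0.4, 0.4))
  Lc <- network_objective(mc, ch, reward_table(matrix(1.3, 4, 1)), 0.2)
  expect_equal(as.numeric(Lc), 1.3, tolerance = 1e-9)

  # hand-built 2-neuron model vs direct enumeration of <r - lambda c>
  set.seed(21)
  Q <- array(rep(runif(2), each = 4), dim = c(4, 1, 2))
  model <- binary_network_model(Q)
  rw <- reward_table(matrix(rnorm(4), ncol = 1))
  lam <- 0.3
  P <- joint_transition(model, ch)
  p <- rewardnet:::stationary_chain(P)
  pm <- vapply(1:2, function(i) sum(p * Q[, 1, i]), numeric(1))
  cc <- numeric(4)
  for (i in 1:2) {
    cc <- cc + Q[, 1, i] * log(Q[, 1, i] / pm[i]) +
      (1 - Q[, 1, i]) * log((1 - Q[, 1, i]) / (1 - pm[i]))
  }
  L_oracle <- sum(p * (drop(rw$values) - lam * cc))
  L <- network_objective(model, ch, rw, lam)
  expect_equal(as.numeric(L), L_oracle, tolerance = 1e-10)

  # optimiser's reported objective equals the exact recomputation
  fit <- small_count_network(n = 4, lambda = 0.15)
  L2 <- network_objective(fit$model, ch, fit$reward, 0.15,
                          stationary = attr(fit$model, "stationary"))
  expect_equal(as.numeric(L2), fit$model$objective, tolerance = 1e-8)
})

test_that("the objective is non-decreasing across sweeps", {
  fit <- small_count_network(n = 4, lambda = 0.15)
  expect_true(all(diff(fit$model$trace) > -1e-8))
  res <- two_level_fit()
  expect_true(all(diff(res$model$trace) > -1e-8))
})

test_that("permuting neuron labels in the reward permutes the optimised tables", {
  n <- 3
  ch <- input_chain(matrix(1, 1, 1))
  set.seed(33)
  r <- rnorm(2^n)
  perm <- c(2, 3, 1)
  # state map: bit i of the permuted state is bit perm[i] of the original
  bits <- rewardnet:::bit_matrix(n)
  code_of <- function(b) as.integer(b %*% 2^(seq_len(n) - 1)) + 1L
  s_map <- apply(bits[, perm, drop = FALSE], 1, function(b) code_of(b))
  r_perm <- r
  r_perm[s_map] <- r
  m1 <- optimize_network(reward_table(matrix(r, ncol = 1)), ch, n, 0.3,
                         tol = 1e-11, coding_cost_mode = "population")
  m2 <- optimize_network(reward_table(matrix(r_perm, ncol = 1)), ch, n, 0.3,
                         tol = 1e-11, coding_cost_mode = "population")
  for (i in seq_len(n)) {
    expect_equal(m2$spike_prob[s_map, 1, i], m1$spike_prob[, 1, perm[i]],
                 tolerance = 1e-6)
  }
})

test_that("simulation reproduces the exact stationary law and is seed-stable", {
  # frozen network: constant raster
  bits <- rewardnet:::bit_matrix(2)
  Qf <- array(0, dim = c(4, 1, 2))
  for (i in 1:2) Qf[, , i] <- matrix(as.numeric(bits[, i]), 4, 1)
  frozen <- binary_network_model(Qf)
  sim_f <- simulate_network(frozen, input_chain(matrix(1, 1, 1)), 200,
                            seed = 4, burn_in = 0)
  expect_equal(length(unique(sim_f$states)), 1L)

  # single neuron fair coin: mean within 3 SE of 0
  one <- binary_network_model(array(0.5, dim = c(2, 1, 1)))
  sim1 <- simulate_network(one, input_chain(matrix(1, 1, 1)), 4e4, seed = 5)
  expect_lt(abs(mean(sim1$raster)), 3 / sqrt(4e4))

  # empirical frequencies match the exact stationary law within 3 MC SEs
  fit <- small_count_network(n = 3, lambda = 0.2)
  ch <- input_chain(matrix(1, 1, 1))
  D <- drop(rewardnet:::net_stationary(fit$model$spike_prob, ch$transition,
                                       rewardnet:::net_geometry(3)))
  n_steps <- 2e5
  sim <- simulate_network(fit$model, ch, n_steps, seed = 6,
                          return_raster = FALSE)
  freq <- tabulate(sim$states, 8) / n_steps
  # autocorrelated chain: inflate the binomial SE by an effective factor
  se <- 3 * sqrt(D * (1 - D) / n_steps) * sqrt(2 * 3) + 1e-4
  expect_true(all(abs(freq - D) < 3 * se))
  # reproducible under the same seed
  sim2 <- simulate_network(fit$model, ch, 1000, seed = 6,
                           return_raster = FALSE)
  sim3 <- simulate_network(fit$model, ch, 1000, seed = 6,
                           return_raster = FALSE)
  expect_identical(sim2$states, sim3$states)
})

test_that("match_coding_cost hits the target and lambda is monotone in cost", {
  fit <- small_count_network(n = 4, lambda = 0.15)
  target <- fit$model$avg_coding_cost
  ch <- input_chain(matrix(1, 1, 1))
  out <- match_coding_cost(fit$reward, ch, 4, target, c(0.05, 0.5),
                           coding_cost_mode = "population", tol = 1e-10)
  expect_lt(abs(out$model$avg_coding_cost - target), 0.02 * target)
  expect_lt(abs(log(out$lambda / 0.15)), 0.35)
  # larger lambda -> lower average coding cost
  hi <- optimize_network(fit$reward, ch, 4, 0.5, tol = 1e-10,
                         coding_cost_mode = "population")
  expect_lt(hi$avg_coding_cost, fit$model$avg_coding_cost)
  # a bracket that does not straddle the target fails loudly
  expect_error(match_coding_cost(fit$reward, ch, 4, target * 50,
                                 c(0.3, 0.5),
                                 coding_cost_mode = "population"),
               "straddle")
})

test_that("removing a cell at matched coding cost preserves the rewarded spike counts", {
  res <- two_level_fit()
  target <- res$model$avg_coding_cost
  rem <- match_coding_cost(make_reward("two_level_count", n_neurons = 7),
                           res$inputs, 7, target, c(0.02, 0.6),
                           coding_cost_mode = "population", tol = 1e-9)
  expect_lt(abs(rem$model$avg_coding_cost - target), 0.02 * target)
  cd <- spike_count_distribution(attr(rem$model, "stationary"))
  expect_equal(unname(apply(cd, 2, which.max)) - 1L, c(2L, 6L))
})
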