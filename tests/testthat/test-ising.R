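# Pairwise-Ising value approximation: TD training, implied reward,
# raster fitting, parametric reward inference, perturbation predictions.

test_that("reward_hat is constant at zero parameters and matches a symbolic 2-neuron oracle", {
  p0 <- ising_value_params(matrix(0, 3, 3), rep(0, 3), rate = 0.5,
                           lambda_cost = 0.2)
  r0 <- reward_hat(p0)
  expect_lt(diff(range(r0)), 1e-12)

  J <- matrix(c(0, 0.3, 0.3, 0), 2)
  h <- c(0.2, -0.1)
  lam <- 0.4; n <- 2; rate <- 0.6
  pp <- ising_value_params(J, h, rate = rate, lambda_cost = lam)
  S <- all_states(2)
  v <- function(s) 2 * J[1, 2] * s[1] * s[2] + h[1] * s[1] + h[2] * s[2]
  oracle <- apply(S, 1, function(s) {
    soft <- 0
    for (i in 1:2) {
      up <- s; up[i] <- 1
      dn <- s; dn[i] <- -1
      soft <- soft + log(rate * exp(v(up) / (n * lam)) +
                           (1 - rate) * exp(v(dn) / (n * lam)))
    }
    v(s) - lam * soft
  })
  expect_equal(reward_hat(pp), oracle, tolerance = 1e-12)
})

test_that("a zero reward trains to (almost) no couplings", {
  p <- td_train(numeric(2^8), 8, 0.1, n_rounds = 60, seed = 3)
  expect_lt(max(abs(p$couplings)), 0.05)
})

test_that("ring training finds local excitation, distal inhibition and the activity bump", {
  fit <- ring_fit()
  J <- fit$params$couplings
  dist <- rewardnet:::ring_distance(12)
  expect_gt(mean(J[dist == 1]), 0)
  expect_lt(mean(J[dist >= 3]), 0)
  counts <- table(fit$sim)
  mode_state <- as.integer(names(counts)[which.max(counts)])
  expect_equal(max_circular_run(12)[mode_state], 4L)
  expect_equal(state_spike_counts(12)[mode_state], 4L)
  # implied reward peaks on contiguous-4 states over the whole state space
  rh <- reward_hat(fit$params)
  top <- order(rh, decreasing = TRUE)[1:5]
  expect_true(all(max_circular_run(12)[top] == 4 &
                    state_spike_counts(12)[top] == 4))
  # training beats the matched independent-neuron (zero-coupling) control
  ctrl <- ising_value_params(matrix(0, 12, 12), rep(0, 12),
                             rate = fit$params$rate, lambda_cost = 0.05)
  r_true <- fit$reward$values
  avg_r <- function(p) sum(ising_stationary(p) * drop(r_true))
  expect_gt(avg_r(fit$params), avg_r(ctrl))
})

test_that("couplings averaged over seeds are approximately circulant", {
  fit <- ring_fit()
  reward <- fit$reward
  dist <- rewardnet:::ring_distance(12)
  Jbar <- fit$params$couplings
  for (seed in 2:5) {
    Jbar <- Jbar + td_train(reward, 12, 0.05, seed = seed)$couplings
  }
  Jbar <- Jbar / 5
  dev <- max(sapply(1:6, function(d) diff(range(Jbar[dist == d]))))
  expect_lt(dev, 0.2)
})

test_that("transition-likelihood fitting recovers known Ising parameters", {
  set.seed(9)
  n <- 12
  dist <- rewardnet:::ring_distance(n)
  Jt <- matrix(0, n, n)
  Jt[dist == 1] <- 0.4; Jt[dist >= 3] <- -0.1; diag(Jt) <- 0
  Jt <- (Jt + t(Jt)) / 2
  ht <- stats::rnorm(n, 0, 0.1)
  pt <- ising_value_params(Jt, ht, rate = 1 / 3, lambda_cost = 1)
  sim <- simulate_ising(pt, 1e6, seed = 11)
  fit <- fit_ising_from_raster(sim, lambda_cost = 1, rate = 1 / 3)
  expect_true(attr(fit, "converged"))
  expect_lt(max(abs(fit$couplings - Jt)), 0.1)
  expect_lt(max(abs(fit$biases - ht)), 0.15)

  # the fitted model's stationary pairwise correlations match the raster's
  bits <- rewardnet:::bit_matrix(n)
  S <- ifelse(bits, 1, -1)
  q <- ising_stationary(fit)
  corr_model <- t(S) %*% (q * S)
  raster <- S[sim, ]
  corr_emp <- crossprod(raster) / nrow(raster)
  se <- 3 * sqrt(2 * n / length(sim))  # autocorrelation-inflated MC error
  expect_lt(max(abs(corr_model - corr_emp)), 3 * se)

  # an independent raster fits to (almost) no couplings
  ind <- ising_value_params(matrix(0, 6, 6), stats::rnorm(6, 0, 0.2),
                            rate = 0.5, lambda_cost = 1)
  sim_ind <- simulate_ising(ind, 2e5, seed = 12)
  fit_ind <- fit_ising_from_raster(sim_ind, lambda_cost = 1, rate = 0.5)
  expect_lt(max(abs(fit_ind$couplings)), 0.05)
})

test_that("sparse, pairwise and global reward models all explain the ring reward; sparse best", {
  fit <- ring_fit()
  r_true <- drop(fit$reward$values)
  r2 <- c()
  for (type in c("sparse", "pairwise", "global")) {
    sp <- infer_parametric_reward(fit$params, type, sim = fit$sim)
    r2[type] <- r_squared(sp$values, r_true[sp$states])
    expect_gt(r2[type], 0)
    if (type != "sparse") expect_lt(sp$gradient_norm, 1e-8)
  }
  expect_gt(r2[["sparse"]], 0.9)
  expect_gte(r2[["sparse"]], max(r2[["pairwise"]], r2[["global"]]))
  # the sparse solution respects non-negativity and its moment band
  sp <- infer_parametric_reward(fit$params, "sparse", sim = fit$sim)
  expect_true(all(sp$values >= -1e-10))
})

test_that("the sparse model predicts adaptation to a higher coding cost better than the global model", {
  fit <- ring_fit()
  q_true_hi <- ising_stationary(td_train(drop(fit$reward$values), 12, 0.1,
                                         seed = 5))
  kl <- function(p) rewardnet:::kl_discrete(q_true_hi, ising_stationary(p))
  pred <- list()
  for (type in c("sparse", "global")) {
    sp <- infer_parametric_reward(fit$params, type, sim = fit$sim)
    pred[[type]] <- perturb_and_predict(sp, "coding_cost",
                                        list(lambda = 0.1), seed = 5)
  }
  expect_lt(kl(pred$sparse), kl(pred$global))
})

test_that("structural perturbations act in the paper's direction", {
  fit <- ring_fit()
  sp <- infer_parametric_reward(fit$params, "sparse", sim = fit$sim)
  cal <- list(reference = fit$params, lambda_orig = 0.05)
  bits <- rewardnet:::bit_matrix(12)
  n_peaks <- apply(bits, 1, function(b) {
    if (all(b) || !any(b)) return(as.integer(any(b)))
    x <- rle(b); k <- sum(x$values)
    if (b[1] && b[12] && k > 1) k <- k - 1L
    as.integer(k)
  })
  two_peak_prob <- function(q) sum(q[n_peaks >= 2 & rowSums(bits) >= 4])
  rm_long <- perturb_and_predict(sp, "remove_connections",
                                 c(list(lambda = 0.01, max_distance = 2), cal),
                                 seed = 3)
  same_cost <- perturb_and_predict(sp, "coding_cost",
                                   c(list(lambda = 0.01), cal), seed = 3)
  # removed long-range couplings really are zero
  dist <- rewardnet:::ring_distance(12)
  expect_true(all(rm_long$couplings[dist > 2] == 0))
  # uncoordinated second peaks become relatively more likely
  expect_gt(two_peak_prob(ising_stationary(rm_long)),
            two_peak_prob(ising_stationary(same_cost)))

  pin <- perturb_and_predict(sp, "pin_neurons",
                             c(list(lambda = 0.1, neurons = c(1, 2)), cal),
                             seed = 3)
  q <- ising_stationary(pin)
  rates <- colSums(bits * q)
  expect_equal(unname(rates[1:2]), c(1, 1))
  # activity is dragged towards the pinned site
  expect_gt(mean(rates[c(3, 12)]), mean(rates[6:8]))
})
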