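# Reward inference from network dynamics: closed form, flip-statistics
# reconstruction, clustering.

test_that("closed-form reward is constant for independent neurons and matches direct arithmetic", {
  # product law -> conditionals equal marginals -> centred reward is zero
  p1 <- c(0.3, 0.7); p2 <- c(0.6, 0.4)
  p <- as.numeric(outer(p1, p2))  # order: (-,-), (+,-), (-,+), (+,+)
  r <- closed_form_reward(p)
  expect_lt(max(abs(r)), 1e-12)

  # 2-neuron law evaluated against the formula by direct arithmetic
  p <- c(0.4, 0.1, 0.1, 0.4)
  r <- closed_form_reward(p)
  m1 <- p[2] + p[4]  # P(neuron 1 active)
  m2 <- p[3] + p[4]
  oracle <- numeric(4)
  cond <- function(i, s) {
    flip <- c(2, 1, 4, 3)[s]
    if (i == 2) flip <- c(3, 4, 1, 2)[s]
    p[s] / (p[s] + p[flip])
  }
  bit <- cbind(c(F, T, F, T), c(F, F, T, T))
  for (s in 1:4) {
    oracle[s] <- log(cond(1, s)) - log(ifelse(bit[s, 1], m1, 1 - m1)) +
      log(cond(2, s)) - log(ifelse(bit[s, 2], m2, 1 - m2))
  }
  oracle <- oracle - mean(oracle)
  expect_equal(r, oracle, tolerance = 1e-10)

  # invariant to rescaling of the stationary weights
  expect_equal(closed_form_reward(7.3 * p), r, tolerance = 1e-12)
  expect_error(closed_form_reward(c(0.5, 0.5, 0, 0)), "zero-probability")
})

test_that("closed-form inversion recovers the reward an autonomous network was optimised for", {
  fit <- small_count_network(n = 4, lambda = 0.15, target = 2)
  D <- drop(attr(fit$model, "stationary"))
  r_hat <- closed_form_reward(D, lambda_cost = 0.15)
  r_true <- drop(fit$reward$values)
  expect_gt(r_squared(r_hat, r_true), 0.999)
  # with the lambda = 1 convention the recovery holds up to a positive scale
  r1 <- closed_form_reward(D)
  ct <- r_true - mean(r_true)
  slope <- stats::coef(stats::lm(r1 ~ ct))[2]
  expect_gt(slope, 0)
  expect_equal(unname(slope), 1 / 0.15, tolerance = 0.01)
})

test_that("the two inference routes agree on autonomous networks", {
  fit <- small_count_network(n = 4, lambda = 0.15, target = 2)
  D <- drop(attr(fit$model, "stationary"))
  r_closed <- closed_form_reward(D)
  inf <- infer_network_reward(fit$model)
  expect_lt(max(abs(r_closed - drop(inf$values))), 1e-6)
})

test_that("exact-table inference on the two-level network recovers the rewarded set", {
  res <- two_level_fit()
  inf <- infer_network_reward(res$model, res$inputs)
  expect_gt(r_squared(as.numeric(inf$values), as.numeric(res$reward$values)),
            0.99)
  cl <- cluster_inferred_reward(inf)
  expect_length(cl$centers, 2)
  expect_identical(which(cl$labels == 2), which(res$reward$values == 1))
})

test_that("raster-based inference recovers the reward and the rewarded clusters", {
  res <- two_level_fit()
  sim <- simulate_network(res$model, res$inputs, 1e6, seed = 1,
                          return_raster = FALSE)
  inf <- infer_network_reward(sim, res$inputs)
  ok <- !is.na(inf$values)
  expect_gt(r_squared(inf$values[ok], as.numeric(res$reward$values)[ok]), 0.9)
  cl <- cluster_inferred_reward(inf)
  high <- which(cl$labels == 2)
  true_high <- which(res$reward$values == 1 & inf$mask)
  expect_setequal(high, true_high)
})

test_that("recovery quality improves with sample size (mean over seeds)", {
  res <- two_level_fit()
  true_r <- as.numeric(res$reward$values)
  sizes <- c(1e3, 1e4, 1e5, 1e6)
  r2m <- matrix(NA_real_, 8, length(sizes))
  for (s in 1:8) {
    sim <- simulate_network(res$model, res$inputs, max(sizes), seed = s,
                            return_raster = FALSE)
    for (j in seq_along(sizes)) {
      sub <- list(states = sim$states[seq_len(sizes[j])],
                  input_states = sim$input_states[seq_len(sizes[j])])
      inf <- infer_network_reward(sub, res$inputs)
      ok <- !is.na(inf$values)
      # at 1e3 samples the unmasked set can be all-unrewarded; score 0
      r2m[s, j] <- if (stats::sd(true_r[ok]) > 0 &&
                       stats::sd(inf$values[ok]) > 0) {
        r_squared(inf$values[ok], true_r[ok])
      } else 0
    }
  }
  expect_true(all(diff(colMeans(r2m)) > 0))
})

test_that("clustering handles binary, three-level and degenerate rewards", {
  # binary values -> exact two-cluster partition
  v <- c(rep(0, 20), rep(1, 10))
  cl <- cluster_inferred_reward(v)
  expect_identical(which(cl$labels == 2), 21:30)
  # three well-separated levels
  set.seed(2)
  v3 <- c(rnorm(30, 0, 0.01), rnorm(30, 1, 0.01), rnorm(30, 10, 0.01))
  cl3 <- cluster_inferred_reward(v3, k = 3)
  expect_identical(cl3$labels, rep(1:3, each = 30))
  # all equal -> single-cluster warning
  expect_warning(cluster_inferred_reward(rep(1, 5)), "single cluster")
})
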