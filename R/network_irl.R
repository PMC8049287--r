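# Inferring the reward function a binary network optimises from its
# dynamics.  Without external input the reward has a closed form in the
# stationary law; with input, the value function is reconstructed from the
# observed single-flip statistics (it is identifiable from transitions only
# up to an additive function of the input state) and converted to a reward
# through the Bellman identity.  The coding-cost weight is not identifiable
# and is fixed to lambda = 1; rewards are reported mean-centred.

#' Closed-form reward of an input-free network
#'
#' For an optimised autonomous network the stationary law is a Gibbs
#' distribution, and the reward is
#' `r(sigma) = lambda * sum_i log( p(sigma_i | sigma_/i) / p(sigma_i) ) + const`,
#' computed here from the stationary law alone and mean-centred.  The
#' result is invariant to rescaling of `stationary`.
#'
#' @param stationary Strictly positive (un)normalised stationary weights
#'   over the `2^n` encoded network states.
#' @param lambda_cost Coding-cost weight; by convention 1 when inferring.
#' @return Mean-centred reward vector over network states.
#' @export
closed_form_reward <- function(stationary, lambda_cost = 1) {
  p <- as.numeric(stationary)
  n <- round(log2(length(p)))
  stopifnot(2^n == length(p))
  if (any(p <= 0)) {
    stop("zero-probability state encountered in a conditional: state ",
         which(p <= 0)[1] - 1)
  }
  p <- p / sum(p)
  flip <- flip_index(n)
  bits <- bit_matrix(n)
  r <- numeric(length(p))
  for (i in seq_len(n)) {
    cond <- p / (p + p[flip[, i]])
    marg <- sum(p[bits[, i]])
    r <- r + log(cond) - log(ifelse(bits[, i], marg, 1 - marg))
  }
  r <- lambda_cost * r
  r - mean(r)
}

#' Infer the reward function of a network from its dynamics
#'
#' Reconstructs the value function from the response log-odds implied by
#' the observed (or exact) single-flip transition statistics, then converts
#' it to a reward via the Bellman identity, under the `lambda = 1`
#' convention.  Given a raster, flip log-odds are estimated from flip-rate
#' ratios with Haldane--Anscombe smoothing and combined by
#' inverse-variance-weighted least squares on the flip graph; given a
#' model, the exact response tables are used and the reconstruction is
#' exact.
#'
#' Transitions determine the value only up to an additive function of the
#' input state; downstream analyses that must be invariant to this (e.g.
#' feature recovery) work with reward profiles centred across network
#' states, see [recover_feature_partition()].
#'
#' @param x An `rn_binary_network` (exact, infinite-data route) or a
#'   simulation as returned by [simulate_network()] (a list with `states`
#'   and `input_states`), or a time-by-neuron -1/+1 raster matrix.
#' @param inputs The `rn_input_chain` driving the network.  Use a 1-state
#'   chain (or `NULL`) for autonomous networks.
#' @param input_states Aligned input-state sequence when `x` is a raster
#'   matrix.
#' @param min_visits States of the joint chain visited fewer times are
#'   masked (`NA`) in the output.
#' @return List of class `rn_inferred_reward`: `values` (matrix, network
#'   state by input state, mean-centred over unmasked entries), `mask`
#'   (TRUE where reliable), `visits`, `value` (the reconstructed value
#'   function), `spike_marginals`.
#' @export
infer_network_reward <- function(x, inputs = NULL, input_states = NULL,
                                 min_visits = 10) {
  if (is.null(inputs)) inputs <- input_chain(matrix(1, 1, 1))
  nx <- inputs$n_states
  if (inherits(x, "rn_binary_network")) {
    n <- x$n_neurons
    geom <- net_geometry(n)
    pm <- x$spike_marginals
    if (is.null(pm)) {
      D <- network_stationary(x, inputs)
      pm <- net_marginals(x$spike_prob, D, geom)
    }
    est <- exact_edge_targets(x, pm, geom)
    visits <- matrix(Inf, 2^n, nx)
  } else {
    sim <- normalize_raster(x, input_states)
    n <- sim$n
    geom <- net_geometry(n)
    est <- empirical_edge_targets(sim, nx, geom)
    pm <- est$pm
    visits <- est$visits
  }
  U <- reconstruct_value(est, geom, nx)
  V <- if (nx == 1) U else U %*% solve(t(inputs$transition))
  r <- bellman_reward(U, V, pm, geom)
  mask <- visits >= min_visits
  r[!mask] <- NA_real_
  r <- r - mean(r[mask])
  structure(list(values = r, mask = mask, visits = visits, value = V,
                 spike_marginals = pm, lambda_cost = 1, n_neurons = n),
            class = "rn_inferred_reward")
}

# edge targets from exact response tables: for every neuron i, input x and
# sigma_{/i} (indexed by the bit-i = 0 state), the flip log-odds minus the
# marginal log-odds; weight 1
exact_edge_targets <- function(model, pm, geom) {
  n <- geom$n; nx <- model$n_input_states
  tgt <- list()
  for (i in seq_len(n)) {
    dn <- which(!geom$bits[, i])
    up <- geom$flip[dn, i]
    q <- clip_prob(model$spike_prob[dn, , i, drop = FALSE])
    y <- n * (stats::qlogis(q) - stats::qlogis(clip_prob(pm[i])))
    tgt[[i]] <- list(dn = dn, up = up,
                     y = matrix(y, length(dn), nx),
                     w = matrix(1, length(dn), nx))
  }
  tgt
}

normalize_raster <- function(x, input_states) {
  if (is.list(x) && !is.null(x$states)) {
    n <- round(log2(max(2, max(x$states))))
    # recover n from the raster if available
    if (!is.null(x$raster)) n <- ncol(x$raster)
    return(list(states = x$states, xs = if (is.null(x$input_states))
      rep(1L, length(x$states)) else x$input_states, n = n))
  }
  raster <- as.matrix(x)
  n <- ncol(raster)
  bits <- (raster + 1L) / 2L   # -1/+1 -> 0/1
  codes <- as.integer(bits %*% 2^(seq_len(n) - 1)) + 1L
  xs <- if (is.null(input_states)) rep(1L, nrow(raster)) else
    as.integer(input_states)
  list(states = codes, xs = xs, n = n)
}

# count-based edge targets from a trajectory of (state, input) pairs
empirical_edge_targets <- function(sim, nx, geom) {
  n <- geom$n; ns <- 2^n
  states <- sim$states; xs <- sim$xs
  T_len <- length(states) - 1L
  from <- states[seq_len(T_len)]
  from_x <- xs[seq_len(T_len)]
  to <- states[seq_len(T_len) + 1L]
  d <- bitwXor(from - 1L, to - 1L)
  multi <- d != 0 & bitwAnd(d, d - 1L) != 0
  n_rejected <- sum(multi)
  if (n_rejected > 0) {
    warning(n_rejected, " transitions changed more than one neuron and were ",
            "dropped")
  }
  keep <- !multi
  from <- from[keep]; from_x <- from_x[keep]; to <- to[keep]; d <- d[keep]
  visits <- matrix(0, ns, nx)
  vt <- table(factor(from, levels = seq_len(ns)),
              factor(from_x, levels = seq_len(nx)))
  visits[] <- as.numeric(vt)
  pm <- vapply(seq_len(n), function(i)
    sum(visits[geom$bits[, i], ]) / sum(visits), numeric(1))
  tgt <- vector("list", n)
  flipped_i <- as.integer(round(log2(pmax(d, 1)))) + 1L
  is_flip <- d != 0
  for (i in seq_len(n)) {
    dn <- which(!geom$bits[, i])
    up <- geom$flip[dn, i]
    edge_of <- integer(ns)
    edge_of[dn] <- seq_along(dn); edge_of[up] <- seq_along(dn)
    sel <- is_flip & flipped_i == i
    f_from <- from[sel]; f_x <- from_x[sel]
    went_up <- geom$bits[to[sel], i]
    count_events <- function(which_sel) {
      m <- matrix(0, length(dn), nx)
      if (any(which_sel)) {
        tb <- table(factor(edge_of[f_from[which_sel]],
                           levels = seq_along(dn)),
                    factor(f_x[which_sel], levels = seq_len(nx)))
        m[] <- as.numeric(tb)
      }
      m
    }
    F_up <- count_events(went_up)    # flips dn -> up (spike turned on)
    F_dn <- count_events(!went_up)   # flips up -> dn (spike turned off)
    N_dn <- visits[dn, , drop = FALSE]
    N_up <- visits[up, , drop = FALSE]
    y <- n * (log((F_up + 0.5) / (N_dn + 1)) - log((F_dn + 0.5) / (N_up + 1)) -
                stats::qlogis(clip_prob(pm[i])))
    w <- 1 / (1 / (F_up + 0.5) + 1 / (F_dn + 0.5))
    w[N_dn == 0 | N_up == 0] <- 0
    tgt[[i]] <- list(dn = dn, up = up, y = y, w = w)
  }
  list(targets = tgt, pm = pm, visits = visits)
}

# weighted least-squares reconstruction of u(., x) on the flip graph,
# anchored to mean zero per input state
reconstruct_value <- function(est, geom, nx) {
  tgt <- if (!is.null(est$targets)) est$targets else est
  ns <- 2^geom$n
  U <- matrix(0, ns, nx)
  for (x in seq_len(nx)) {
    L <- matrix(0, ns, ns)
    rhs <- numeric(ns)
    for (i in seq_along(tgt)) {
      e <- tgt[[i]]
      w <- e$w[, x]; y <- e$y[, x]
      for (k in seq_along(e$dn)) {
        if (w[k] <= 0) next
        a <- e$dn[k]; b <- e$up[k]
        L[a, a] <- L[a, a] + w[k]; L[b, b] <- L[b, b] + w[k]
        L[a, b] <- L[a, b] - w[k]; L[b, a] <- L[b, a] - w[k]
        rhs[b] <- rhs[b] + w[k] * y[k]
        rhs[a] <- rhs[a] - w[k] * y[k]
      }
    }
    mu <- max(mean(diag(L)), 1) * 1e-8
    L <- L + mu + diag(1e-10 * max(diag(L), 1), ns)
    U[, x] <- solve(L, rhs)
    U[, x] <- U[, x] - mean(U[, x])
  }
  U
}

# reward via the Bellman identity (lambda = 1):
# r = v - sum_i log( p_i e^{u(up_i)/n} + (1 - p_i) e^{u(dn_i)/n} )
bellman_reward <- function(U, V, pm, geom) {
  n <- geom$n
  r <- V
  for (i in seq_len(n)) {
    up <- ifelse(geom$bits[, i], geom$idx, geom$flip[, i])
    dn <- ifelse(geom$bits[, i], geom$flip[, i], geom$idx)
    p <- clip_prob(pm[i])
    r <- r - log_mix_exp(p, U[up, , drop = FALSE] / n,
                         1 - p, U[dn, , drop = FALSE] / n)
  }
  r
}

#' Cluster inferred reward values
#'
#' One-dimensional k-means over the (unmasked) inferred reward values, with
#' multiple restarts and a fixed seed; clusters are relabelled in order of
#' ascending mean.
#'
#' @param reward An `rn_inferred_reward`, or a numeric vector/matrix of
#'   reward values (`NA` allowed).
#' @param k Number of clusters.
#' @param nstart k-means restarts.
#' @param seed RNG seed for the restarts.
#' @return List with `labels` (same shape as the input values, `NA` where
#'   masked), `centers` (ascending) and `sizes`.
#' @export
cluster_inferred_reward <- function(reward, k = 2, nstart = 20, seed = 1) {
  values <- if (inherits(reward, "rn_inferred_reward")) reward$values else
    reward
  v <- as.numeric(values)
  ok <- !is.na(v)
  if (k < 2) stop("k must be at least 2")
  if (stats::sd(v[ok]) == 0) {
    warning("all reward values equal; returning a single cluster")
    labels <- ifelse(ok, 1L, NA_integer_)
    dim(labels) <- dim(values)
    return(list(labels = labels, centers = mean(v[ok]), sizes = sum(ok)))
  }
  set.seed(seed)
  km <- stats::kmeans(v[ok], centers = k, nstart = nstart)
  ord <- order(km$centers)
  relabel <- match(seq_len(k), ord)
  labels <- rep(NA_integer_, length(v))
  labels[ok] <- relabel[km$cluster]
  dim(labels) <- dim(values)
  list(labels = labels, centers = sort(as.numeric(km$centers)),
       sizes = as.integer(table(factor(labels[ok], levels = seq_len(k)))))
}

#' Group inputs by their inferred reward profile
#'
#' Clusters input states by the reward profile they induce across network
#' states, after centring each profile (which removes the per-input
#' additive component that transitions cannot identify).  Inputs mapped to
#' the same encoded feature value end up in the same group.
#'
#' @param reward An `rn_inferred_reward` with more than one input state.
#' @param k Number of input groups.
#' @param nstart,seed k-means restarts and seed.
#' @return List with `groups` (integer per input state), `profile_means`
#'   (mean centred profile value per group) and the centred `profiles`
#'   matrix (inputs by network states).
#' @export
recover_feature_partition <- function(reward, k = 2, nstart = 20, seed = 1) {
  stopifnot(inherits(reward, "rn_inferred_reward"))
  vals <- reward$values
  if (ncol(vals) < 2) stop("feature recovery needs more than one input state")
  common <- which(rowSums(!reward$mask) == 0)
  if (length(common) < 2) stop("too few network states observed under every input")
  prof <- t(vals[common, , drop = FALSE])
  prof <- prof - rowMeans(prof)
  set.seed(seed)
  km <- stats::kmeans(prof, centers = k, nstart = nstart)
  list(groups = km$cluster,
       profile_means = as.numeric(rowMeans(km$centers)),
       profiles = prof)
}
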