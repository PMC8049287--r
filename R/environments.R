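# Benchmark environments: grid-maze navigation, binary and multi-pixel
# Markov input chains, and the standard reward tables (two-level spike
# count, ring-adjacent activity, threshold stimulus feature).

#' Specify a grid maze
#'
#' Cells are indexed row-major: cell `(row, col)` is state
#' `(row - 1) * width + col`.  Barriers block edges between 4-adjacent
#' cells.  When `barriers = NULL` a connected random barrier layout is
#' generated from `seed`.
#'
#' @param width,height Maze dimensions.
#' @param barriers Either `NULL` or a 2-column matrix of cell-index pairs
#'   whose shared edge is walled off.
#' @param reward_cell Cell index carrying reward 1 (default: bottom-right).
#' @param start_cells Cells the agent is teleported to after reaching the
#'   reward (default: top-left corner).
#' @param slip_probability Probability that the executed move direction is
#'   uniform-random rather than the chosen one.
#' @param barrier_density Fraction of interior edges proposed as barriers
#'   when generating a layout.
#' @param seed Seed for barrier generation.
#' @return A list of class `rn_maze_spec`.
#' @export
maze_spec <- function(width = 15, height = 15, barriers = NULL,
                      reward_cell = width * height,
                      start_cells = 1L,
                      slip_probability = 0.05,
                      barrier_density = 0.3, seed = 20210415) {
  stopifnot(width >= 2, height >= 2,
            slip_probability >= 0, slip_probability <= 1)
  edges <- maze_edges(width, height)
  if (is.null(barriers)) {
    barriers <- generate_barriers(width, height, edges, barrier_density, seed,
                                  start_cells, reward_cell)
  } else {
    barriers <- normalize_edges(as.matrix(barriers))
  }
  spec <- structure(list(width = width, height = height, barriers = barriers,
                         reward_cell = as.integer(reward_cell),
                         start_cells = as.integer(start_cells),
                         slip_probability = slip_probability),
                    class = "rn_maze_spec")
  if (!maze_connected(spec)) stop("disconnected maze")
  spec
}

# all 4-neighbour edges of the grid, as sorted cell-index pairs
maze_edges <- function(width, height) {
  cell <- function(r, c) (r - 1L) * width + c
  e <- list()
  for (r in seq_len(height)) for (c in seq_len(width)) {
    if (c < width)  e[[length(e) + 1L]] <- c(cell(r, c), cell(r, c + 1L))
    if (r < height) e[[length(e) + 1L]] <- c(cell(r, c), cell(r + 1L, c))
  }
  do.call(rbind, e)
}

normalize_edges <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(matrix(integer(0), 0, 2))
  t(apply(m, 1, sort))
}

# random connected barrier layout from a pinned seed
generate_barriers <- function(width, height, edges, density, seed,
                              start_cells, reward_cell) {
  n_cells <- width * height
  for (attempt in seq_len(200)) {
    set.seed(seed + attempt - 1L)
    pick <- stats::runif(nrow(edges)) < density
    barriers <- edges[pick, , drop = FALSE]
    spec <- list(width = width, height = height, barriers = barriers)
    if (maze_connected(spec)) return(barriers)
  }
  stop("failed to generate a connected maze layout")
}

# BFS over open edges: every cell reachable from cell 1
maze_connected <- function(spec) {
  width <- spec$width; height <- spec$height
  n_cells <- width * height
  blocked <- edge_key(spec$barriers, n_cells)
  adj <- vector("list", n_cells)
  edges <- maze_edges(width, height)
  keys <- edge_key(edges, n_cells)
  open <- !(keys %in% blocked)
  for (k in which(open)) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n_cells); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

edge_key <- function(edges, n_cells) {
  if (is.null(edges) || nrow(edges) == 0) return(integer(0))
  edges <- normalize_edges(edges)
  edges[, 1] * (n_cells + 1) + edges[, 2]
}

#' Build the maze MDP
#'
#' A `width*height`-state, 4-action MDP (up, down, left, right).  Moving
#' into a barrier or the boundary leaves the agent in place; with
#' probability `slip_probability` the executed direction is uniform-random;
#' from the rewarded cell every action teleports uniformly to a start cell.
#' The reward vector is the indicator of the rewarded cell.
#'
#' @param spec An `rn_maze_spec`.
#' @param lambda_cost Coding-cost weight of the returned MDP.
#' @return An `rn_mdp`.
#' @export
build_maze <- function(spec, lambda_cost = 0.013) {
  width <- spec$width; height <- spec$height
  n_cells <- width * height
  blocked <- edge_key(spec$barriers, n_cells)
  # destination of a deterministic move in direction d from cell s (or s)
  dest <- matrix(0L, n_cells, 4)
  for (s in seq_len(n_cells)) {
    r <- (s - 1L) %/% width + 1L
    c <- (s - 1L) %% width + 1L
    cand <- list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
    for (d in 1:4) {
      rc <- cand[[d]]
      if (rc[1] < 1 || rc[1] > height || rc[2] < 1 || rc[2] > width) {
        dest[s, d] <- s
      } else {
        s2 <- (rc[1] - 1L) * width + rc[2]
        k <- edge_key(matrix(sort(c(s, s2)), 1), n_cells)
        dest[s, d] <- if (k %in% blocked) s else s2
      }
    }
  }
  slip <- spec$slip_probability
  T <- array(0, dim = c(n_cells, 4, n_cells))
  for (s in seq_len(n_cells)) {
    if (s == spec$reward_cell) {
      for (a in 1:4) {
        T[s, a, spec$start_cells] <- 1 / length(spec$start_cells)
      }
      next
    }
    rand_row <- numeric(n_cells)
    for (d in 1:4) rand_row[dest[s, d]] <- rand_row[dest[s, d]] + 0.25
    for (a in 1:4) {
      row <- numeric(n_cells)
      row[dest[s, a]] <- 1 - slip
      T[s, a, ] <- row + slip * rand_row
    }
  }
  reward <- numeric(n_cells)
  reward[spec$reward_cell] <- 1
  tabular_mdp(T, reward, lambda_cost)
}

#' Construct a Markov input chain
#'
#' @param transition Row-stochastic transition matrix `p(x'|x)`.
#' @param labels Optional per-state labels (e.g. scalar input values or a
#'   matrix of pixel patterns, one row per state).
#' @return A list of class `rn_input_chain`.
#' @export
input_chain <- function(transition, labels = NULL) {
  transition <- as.matrix(transition)
  stopifnot(nrow(transition) == ncol(transition), all(transition >= 0))
  if (max(abs(rowSums(transition) - 1)) > 1e-12) {
    stop("input chain rows must sum to 1")
  }
  if (nrow(transition) > 1 && !chain_irreducible(transition)) {
    stop("input chain must be irreducible")
  }
  structure(list(n_states = nrow(transition), transition = transition,
                 labels = labels),
            class = "rn_input_chain")
}

#' Two-state binary input chain
#'
#' States are `x = -1` (state 1) and `x = +1` (state 2) with switch rates
#' `p(x' = 1 | x = -1) = p_up` and `p(x' = -1 | x = 1) = p_down`.
#'
#' @param p_up,p_down Switch probabilities in (0, 1).
#' @return An `rn_input_chain` with labels `c(-1, 1)`.
#' @export
binary_input_chain <- function(p_up = 0.02, p_down = 0.02) {
  stopifnot(p_up > 0, p_up < 1, p_down > 0, p_down < 1)
  input_chain(matrix(c(1 - p_up, p_up, p_down, 1 - p_down), 2, 2,
                     byrow = TRUE),
              labels = c(-1, 1))
}

#' Asynchronous coupled binary-pixel stimulus chain
#'
#' `m` pixels `x_i = -1/+1`; at each step one pixel, chosen uniformly, is
#' resampled by a Glauber rule: it is set to +1 with probability
#' `logistic(J * sum_j x_j - J0)` (the sum runs over the current pattern),
#' otherwise to -1.  Positive `J` makes pixels cohere, so patterns dwell
#' near mostly-on / mostly-off configurations; `J0 = 0` gives the unbiased
#' chain, whose stationary law is symmetric under a global sign flip, and
#' positive `J0` lowers the probability that pixels are active.
#'
#' @param m Number of pixels (`m <= 12`).
#' @param J Coupling constant.
#' @param J0 Bias term.
#' @return An `rn_input_chain` over `2^m` states whose `labels` matrix holds
#'   the pixel patterns (bit `i - 1` of the state code is pixel `i`).
#' @export
pixel_stimulus_chain <- function(m = 7, J = 1.5, J0 = 0) {
  stopifnot(m >= 1, m <= 12)
  S <- all_states(m)
  n_states <- nrow(S)
  field <- J * rowSums(S) - J0
  p_on <- stats::plogis(field)
  flip <- flip_index(m)
  bits <- bit_matrix(m)
  P <- matrix(0, n_states, n_states)
  idx <- seq_len(n_states)
  for (i in seq_len(m)) {
    up <- ifelse(bits[, i], idx, flip[, i])   # state with pixel i on
    dn <- ifelse(bits[, i], flip[, i], idx)   # state with pixel i off
    for (s in idx) {
      P[s, up[s]] <- P[s, up[s]] + p_on[s] / m
      P[s, dn[s]] <- P[s, dn[s]] + (1 - p_on[s]) / m
    }
  }
  input_chain(P, labels = S)
}

#' Standard reward tables and feature maps
#'
#' * `"two_level_count"`: reward 1 iff the network fires `counts[1]` spikes
#'   while the input is in state 1 (`x = -1`) or `counts[2]` spikes while
#'   in state 2 (`x = +1`); for use with [binary_input_chain()].
#' * `"ring_adjacent"`: reward 1 iff exactly `block` circularly adjacent
#'   neurons are active (neuron `n` is adjacent to neuron 1).
#' * `"threshold_feature"`: feature map `y(x) = +1` iff at least
#'   `threshold` pixels are active, else `-1`.
#'
#' @param kind One of `"two_level_count"`, `"ring_adjacent"`,
#'   `"threshold_feature"`.
#' @param n_neurons Network size (first two kinds).
#' @param counts Length-2 rewarded spike counts for `"two_level_count"`.
#' @param block Rewarded block length for `"ring_adjacent"`.
#' @param m Number of pixels for `"threshold_feature"`.
#' @param threshold Minimum number of active pixels mapped to `y = +1`.
#' @return An `rn_reward_table` (matrix of rewards, rows = network states,
#'   columns = input states) or an `rn_feature_map` (vector of labels over
#'   input states).
#' @export
make_reward <- function(kind = c("two_level_count", "ring_adjacent",
                                 "threshold_feature"),
                        n_neurons = 8, counts = c(2, 6), block = 4,
                        m = 7, threshold = 4) {
  kind <- match.arg(kind)
  if (kind == "two_level_count") {
    spikes <- state_spike_counts(n_neurons)
    values <- cbind(as.numeric(spikes == counts[1]),
                    as.numeric(spikes == counts[2]))
    return(reward_table(values))
  }
  if (kind == "ring_adjacent") {
    spikes <- state_spike_counts(n_neurons)
    run <- max_circular_run(n_neurons)
    values <- matrix(as.numeric(spikes == block & run == block), ncol = 1)
    return(reward_table(values))
  }
  counts_px <- state_spike_counts(m)
  structure(list(labels = ifelse(counts_px >= threshold, 1, -1),
                 n_input_states = 2^m),
            class = "rn_feature_map")
}

#' Reward table over (network state, input state)
#'
#' @param values Numeric matrix, `2^n` rows (network states in encoding
#'   order) by `n_input_states` columns.
#' @return An `rn_reward_table`.
#' @export
reward_table <- function(values) {
  values <- as.matrix(values)
  stopifnot(all(is.finite(values)))
  n <- log2(nrow(values))
  if (abs(n - round(n)) > 1e-9) stop("number of rows must be a power of 2")
  structure(list(values = values, n_neurons = as.integer(round(n)),
                 n_input_states = ncol(values)),
            class = "rn_reward_table")
}

#' Length of the maximal circular run of active neurons in every state
#'
#' @param n Number of neurons on the ring.
#' @return Integer vector over the `2^n` encoded states; the all-active
#'   state reports `n`.
#' @export
max_circular_run <- function(n) {
  bits <- bit_matrix(n)
  apply(bits, 1, function(b) {
    if (all(b)) return(n)
    if (!any(b)) return(0L)
    bb <- c(b, b)  # unroll the circle
    r <- rle(bb)
    max(r$lengths[r$values], 0L)
  })
}
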