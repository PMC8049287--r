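# Configuration, serialisation and the experiment runner shared by the
# command-line interface.  Configs are YAML; tabular artifacts are
# tab-separated text with a commented header naming the conventions
# (row = state, neuron i = bit i - 1 of the state code).

#' Read / write an experiment configuration
#'
#' A config is a named list with at least `experiment` (one of
#' `"two_level"`, `"ring"`, `"efficient_coding"`, `"maze"`), an integer
#' `seed`, and a `params` list passed to the experiment driver.
#'
#' @param config Named list.
#' @param path File path.
#' @return `read_experiment_config` returns the config list.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(!is.null(config$experiment))
  if (is.null(config$seed)) config$seed <- 1L
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  config <- yaml::read_yaml(path)
  stopifnot(!is.null(config$experiment))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$params)) config$params <- list()
  config
}

#' Write a labelled numeric matrix or vector as TSV
#'
#' @param x Matrix or vector.
#' @param path File path.
#' @param what One-line description placed in the commented header.
#' @export
write_matrix_tsv <- function(x, path, what = "matrix") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", what),
               "# row = state (integer code order); neuron i = bit i-1"),
             con)
  utils::write.table(as.matrix(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              comment.char = "#", check.names = FALSE))
}

#' Write a simulated raster with its aligned input sequence
#'
#' One row per time step: neuron columns (-1/+1) then an `input` column
#' (1-based input-state index).
#'
#' @param sim A simulation from [simulate_network()] (with raster).
#' @param path File path.
#' @export
write_raster_tsv <- function(sim, path) {
  stopifnot(!is.null(sim$raster))
  m <- cbind(sim$raster, input = sim$input_states)
  colnames(m) <- c(paste0("neuron", seq_len(ncol(sim$raster))), "input")
  write_matrix_tsv(m, path, "raster: one row per time step, -1/+1 spikes")
}

#' @rdname write_raster_tsv
#' @export
read_raster_tsv <- function(path) {
  m <- read_matrix_tsv(path)
  list(raster = m[, -ncol(m), drop = FALSE],
       input_states = as.integer(m[, ncol(m)]),
       states = as.integer(((m[, -ncol(m), drop = FALSE] + 1) / 2) %*%
                             2^(seq_len(ncol(m) - 1) - 1)) + 1L)
}

# flat deterministic key-value manifest
write_manifest <- function(metrics, path) {
  keys <- sort(names(metrics))
  lines <- vapply(keys, function(k)
    paste0(k, "\t", paste(format(metrics[[k]], digits = 15),
                          collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Run a configured experiment end to end
#'
#' Dispatches to the experiment driver named in the config, writes the
#' result artifacts (models, laws, inferred rewards) and a flat
#' key-value `manifest.tsv` of summary metrics under `out_dir`.  All
#' randomness flows from `config$seed`, so rerunning an identical config
#' reproduces every output.
#'
#' @param config A config list (see [read_experiment_config()]).
#' @param out_dir Output directory (created if missing).
#' @return The driver's result bundle, invisibly; the manifest metrics as
#'   attribute `metrics`.
#' @export
run_experiment <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exp <- config$experiment
  params <- config$params %||% list()
  seed <- config$seed %||% 1L
  metrics <- list(experiment = exp, seed = seed)
  if (exp == "two_level") {
    res <- do.call(experiment_two_level, params)
    write_matrix_tsv(res$stationary, file.path(out_dir, "stationary.tsv"),
                     "joint stationary law p(state, input)")
    write_matrix_tsv(res$count_distribution,
                     file.path(out_dir, "spike_count_distribution.tsv"),
                     "conditional spike-count distribution per input state")
    inferred <- infer_network_reward(res$model, res$inputs)
    cl <- cluster_inferred_reward(inferred)
    write_matrix_tsv(inferred$values, file.path(out_dir, "inferred_reward.tsv"),
                     "inferred reward (lambda = 1 convention, centred)")
    metrics$mode_x1 <- res$modes[1]
    metrics$mode_x2 <- res$modes[2]
    metrics$objective <- res$objective
    metrics$cluster_centers <- cl$centers
    metrics$reward_r2 <- r_squared(as.numeric(inferred$values),
                                   as.numeric(res$reward$values))
  } else if (exp == "ring") {
    res <- do.call(experiment_ring, c(params, list(seed = seed)))
    write_matrix_tsv(res$params$couplings, file.path(out_dir, "couplings.tsv"),
                     "trained coupling matrix J")
    write_matrix_tsv(res$params$biases, file.path(out_dir, "biases.tsv"),
                     "trained bias vector h")
    if (!is.null(res$specs)) {
      sp <- res$specs$sparse
      write_matrix_tsv(cbind(state = sp$states, reward = sp$values),
                       file.path(out_dir, "sparse_reward.tsv"),
                       "sparse-LP inferred reward over visited states")
      metrics$r2_sparse <- res$r2[["sparse"]]
      metrics$r2_pairwise <- res$r2[["pairwise"]]
      metrics$r2_global <- res$r2[["global"]]
    }
    metrics$mode_state <- res$mode_state
    metrics$mode_run <- res$mode_run
  } else if (exp == "efficient_coding") {
    res <- do.call(experiment_efficient_coding, params)
    write_matrix_tsv(res$ec$readout, file.path(out_dir, "readout.tsv"),
                     "posterior p(y | network state)")
    write_matrix_tsv(res$ec$info_trace, file.path(out_dir, "info_trace.tsv"),
                     "I(y; state) in bits per outer iteration")
    metrics$info_bits <- res$info_bits
    metrics$control_info_bits <- res$control_info_bits
    if (!is.null(res$split_count)) metrics$split_count <- res$split_count
  } else if (exp == "maze") {
    res <- do.call(experiment_maze, params)
    write_matrix_tsv(res$low$policy$table, file.path(out_dir, "policy_low.tsv"),
                     "optimal policy at the low coding cost")
    if (!is.null(res$inferred_reward)) {
      write_matrix_tsv(res$inferred_reward,
                       file.path(out_dir, "inferred_reward.tsv"),
                       "inferred maze reward (centred, lambda = 1)")
      metrics$inferred_argmax <- res$inferred_argmax
    }
    metrics$avg_reward_low <- res$avg_reward_low
    metrics$avg_reward_high <- res$avg_reward_high
  } else {
    stop("unknown experiment: ", exp)
  }
  write_manifest(metrics, file.path(out_dir, "manifest.tsv"))
  attr(res, "metrics") <- metrics
  invisible(res)
}
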