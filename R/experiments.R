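#' Configure a beta sweep
#'
#' @param model Model name, see [make_model_spec()].
#' @param n Group size (default: the model's own default).
#' @param k In-degree (default 5).
#' @param topology Initial topology (default `"random"`).
#' @param beta_grid Vector of selective-exposure propensities in `[0, 1]`
#'   (default: 51 evenly spaced values, `seq(0, 1, by = 0.02)`).
#' @param reps_per_beta Replicates per grid value (default 2000; 30,000 is
#'   the long-run setting).
#' @param root_seed Integer root seed; per-replicate seeds are derived with
#'   [derive_seed()].
#' @param max_rounds Per-run round cap (default 1000).
#' @param trajectory_rounds Rounds recorded by [run_trajectory()]
#'   (default 10).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(model, n = NULL, k = 5L, topology = "random",
                              beta_grid = seq(0, 1, by = 0.02),
                              reps_per_beta = 2000L, root_seed = 1L,
                              max_rounds = 1000L, trajectory_rounds = 10L) {
  if (length(beta_grid) == 0L) stop("'beta_grid' must be non-empty")
  if (any(beta_grid < 0 | beta_grid > 1)) stop("'beta_grid' values must lie in [0, 1]")
  if (reps_per_beta < 1L) stop("'reps_per_beta' must be at least 1")
  spec <- if (is.null(n)) make_model_spec(model) else make_model_spec(model, n = n)
  structure(
    list(model = model, spec = spec, k = as.integer(k), topology = topology,
         beta_grid = as.numeric(beta_grid),
         reps_per_beta = as.integer(reps_per_beta),
         root_seed = as.integer(root_seed),
         max_rounds = as.integer(max_rounds),
         trajectory_rounds = as.integer(trajectory_rounds)),
    class = "experiment_config"
  )
}

#' Derive a per-replicate seed from a root seed
#'
#' Deterministic spawning scheme for the sweep harness:
#' `(root * 48271 + cell * 69621 + rep * 16807) mod (2^31 - 19)`, kept within
#' 32-bit integer range so every replicate is reproducible and independently
#' re-runnable from `(root_seed, cell, rep)`.
#'
#' @param root Integer root seed.
#' @param cell Cell index (e.g. position of beta on the grid).
#' @param rep Replicate index within the cell.
#' @return Integer seed.
#' @export
derive_seed <- function(root, cell, rep) {
  m <- 2147483629
  as.integer(((as.numeric(root) %% m) * 48271 +
              as.numeric(cell) * 69621 + as.numeric(rep) * 16807) %% m)
}

#' Run a beta sweep
#'
#' Runs `reps_per_beta` independent simulations to steady state for every
#' value on the beta grid, with per-replicate seeds derived from the root
#' seed, and aggregates the per-run measures per beta. Fully reproducible
#' from the config; non-converged runs are recorded, never dropped.
#'
#' @param config An [experiment_config()].
#' @param verbose If TRUE, log one line per 100 replicates.
#' @return An object of class `sweep_result`: list with `replicates` (one
#'   [summarize_state()] row per run, plus `beta`, `rep`, `seed`,
#'   `rounds_to_steady`, `converged`) and `aggregates` (per-beta means, P_G,
#'   and non-convergence count), plus the `config`.
#' @export
run_sweep <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- vector("list", length(config$beta_grid) * config$reps_per_beta)
  idx <- 0L
  for (bi in seq_along(config$beta_grid)) {
    beta <- config$beta_grid[bi]
    for (rep in seq_len(config$reps_per_beta)) {
      seed <- derive_seed(config$root_seed, bi, rep)
      res <- run_simulation(config$spec, k = config$k, beta = beta,
                            topology = config$topology, seed = seed,
                            max_rounds = config$max_rounds)
      rec <- summarize_state(res$state)
      rec$beta <- beta
      rec$rep <- rep
      rec$seed <- seed
      rec$rounds_to_steady <- res$rounds_to_steady
      rec$converged <- res$converged
      idx <- idx + 1L
      rows[[idx]] <- rec
      if (verbose && rep %% 100L == 0L) {
        message(sprintf("beta=%.2f rep=%d rounds=%d converged=%s",
                        beta, rep, res$rounds_to_steady, res$converged))
      }
    }
  }
  replicates <- do.call(rbind, rows)
  structure(
    list(replicates = replicates,
         aggregates = aggregate_sweep(replicates),
         config = config),
    class = "sweep_result"
  )
}

# per-beta aggregates, recomputable from the raw replicate rows
aggregate_sweep <- function(replicates) {
  agg_rows <- lapply(split(replicates, replicates$beta), function(d) {
    data.frame(
      beta = d$beta[1],
      n_reps = nrow(d),
      mean_individual_performance = mean(d$individual_performance),
      collective_performance = collective_performance(d),
      mean_opinion_diversity = mean(d$opinion_diversity),
      mean_giant_scc_fraction = mean(d$giant_scc_fraction),
      mean_modularity_newman = mean(d$modularity_newman),
      mean_modularity_paper = mean(d$modularity_paper),
      mean_rounds_to_steady = mean(d$rounds_to_steady),
      n_nonconverged = sum(!d$converged)
    )
  })
  out <- do.call(rbind, agg_rows)
  rownames(out) <- NULL
  out[order(out$beta), , drop = FALSE]
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> model = ", x$config$model,
      ", ", length(x$config$beta_grid), " beta value(s) x ",
      x$config$reps_per_beta, " replicate(s)\n", sep = "")
  print(x$aggregates, digits = 3)
  invisible(x)
}

#' Run the first-rounds trajectory experiment
#'
#' For each beta on the grid, runs replicates to steady state while recording
#' per-round measures for rounds `0..trajectory_rounds` (rounds after
#' convergence repeat the steady values), then aggregates per (beta, round).
#' Round 0 is the freshly sampled initial state, i.e. the no-influence null.
#'
#' @param config An [experiment_config()].
#' @param verbose If TRUE, log one line per 100 replicates.
#' @return An object of class `trajectory_result`: list with `replicates`
#'   (one row per run and round) and `aggregates` (per beta and round), plus
#'   the `config`.
#' @export
run_trajectory <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- vector("list", length(config$beta_grid) * config$reps_per_beta)
  idx <- 0L
  for (bi in seq_along(config$beta_grid)) {
    beta <- config$beta_grid[bi]
    for (rep in seq_len(config$reps_per_beta)) {
      seed <- derive_seed(config$root_seed, bi, rep)
      res <- run_simulation(config$spec, k = config$k, beta = beta,
                            topology = config$topology, seed = seed,
                            max_rounds = config$max_rounds,
                            record_trajectory = TRUE,
                            trajectory_rounds = config$trajectory_rounds)
      tr <- res$trajectory
      tr$beta <- beta
      tr$rep <- rep
      tr$seed <- seed
      tr$converged <- res$converged
      idx <- idx + 1L
      rows[[idx]] <- tr
      if (verbose && rep %% 100L == 0L) {
        message(sprintf("beta=%.2f rep=%d rounds=%d converged=%s",
                        beta, rep, res$rounds_to_steady, res$converged))
      }
    }
  }
  replicates <- do.call(rbind, rows)
  agg_rows <- lapply(split(replicates, list(replicates$beta, replicates$round)),
                     function(d) {
    data.frame(
      beta = d$beta[1],
      round = d$round[1],
      n_reps = nrow(d),
      mean_individual_performance = mean(d$individual_performance),
      collective_performance = collective_performance(d),
      mean_opinion_diversity = mean(d$opinion_diversity),
      mean_giant_scc_fraction = mean(d$giant_scc_fraction),
      mean_modularity_newman = mean(d$modularity_newman),
      mean_modularity_paper = mean(d$modularity_paper)
    )
  })
  aggregates <- do.call(rbind, agg_rows)
  rownames(aggregates) <- NULL
  aggregates <- aggregates[order(aggregates$beta, aggregates$round), , drop = FALSE]
  structure(list(replicates = replicates, aggregates = aggregates,
                 config = config),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat("<trajectory_result> model = ", x$config$model,
      ", rounds 0..", x$config$trajectory_rounds,
      ", ", length(x$config$beta_grid), " beta value(s) x ",
      x$config$reps_per_beta, " replicate(s)\n", sep = "")
  print(utils::head(x$aggregates, 12), digits = 3)
  invisible(x)
}

#' Write sweep outputs to disk
#'
#' Writes `replicates.csv`, `aggregates.csv` and `config_echo.json` into
#' `dir`.
#'
#' @param result A [run_sweep()] or [run_trajectory()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sweep_result <- function(result, dir) {
  stopifnot(inherits(result, c("sweep_result", "trajectory_result")))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$replicates, file.path(dir, "replicates.csv"),
                   row.names = FALSE)
  utils::write.csv(result$aggregates, file.path(dir, "aggregates.csv"),
                   row.names = FALSE)
  cfg <- unclass(result$config)
  cfg$spec <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
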