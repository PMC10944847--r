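#' Construct a simulation state
#'
#' Bundles the model spec, the source graph, the current opinion vector, the
#' selective-exposure propensity and the round counter into the mutable object
#' the dynamics act on. Randomness is drawn from R's global RNG stream; seed
#' with [set.seed()] (or the `seed` argument of [run_simulation()]).
#'
#' @param spec An [make_model_spec()] object.
#' @param graph A [init_sources()] graph with `graph$n == spec$n`.
#' @param opinions Numeric opinion vector of length `spec$n`.
#' @param beta Selective-exposure propensity in `[0, 1]`: each acting agent
#'   draws selective exposure with probability `beta`, naive learning
#'   otherwise.
#' @param round Non-negative round counter (default 0).
#' @return An object of class `simulation_state`.
#' @export
simulation_state <- function(spec, graph, opinions, beta, round = 0L) {
  stopifnot(inherits(spec, "opinion_model_spec"), inherits(graph, "source_graph"))
  if (graph$n != spec$n) stop("graph and spec disagree on n")
  if (length(opinions) != spec$n) stop("need one opinion per agent")
  if (beta < 0 || beta > 1) stop("'beta' must lie in [0, 1]")
  structure(
    list(spec = spec, graph = graph, opinions = as.numeric(opinions),
         beta = beta, round = as.integer(round)),
    class = "simulation_state"
  )
}

#' @export
print.simulation_state <- function(x, ...) {
  cat("<simulation_state> model = ", x$spec$name,
      ", n = ", x$spec$n, ", k = ", x$graph$k,
      ", beta = ", x$beta, ", round = ", x$round, "\n", sep = "")
  invisible(x)
}

#' Discrepancy of an agent with its information sources
#'
#' The sum of absolute differences between agent `i`'s opinion and the
#' opinions of its sources, \eqn{\sum_{j \in G(i)} |x_i - x_j|}.
#'
#' @param state A [simulation_state()].
#' @param i Agent index.
#' @return Non-negative scalar.
#' @export
discrepancy <- function(state, i) {
  stopifnot(inherits(state, "simulation_state"))
  if (i < 1L || i > state$spec$n) stop("invalid agent index")
  sum(abs(state$opinions[i] - state$opinions[state$graph$sources[i, ]]))
}

#' Naive-learning action
#'
#' Agent `i` adopts the opinion minimizing its discrepancy: the median of its
#' source opinions (majority for binary opinions with odd `k`; midpoint of the
#' two central order statistics for even `k`). A no-op iff the current opinion
#' already equals that median.
#'
#' @inheritParams discrepancy
#' @return The updated `simulation_state` (opinion of `i` possibly changed).
#' @export
naive_learning_action <- function(state, i) {
  stopifnot(inherits(state, "simulation_state"))
  state$opinions[i] <- stats::median(state$opinions[state$graph$sources[i, ]])
  state
}

#' Selective-exposure action
#'
#' Agent `i` drops its most opinion-discrepant source (ties broken uniformly
#' at random) and replaces it with a uniformly chosen non-source agent whose
#' opinion is strictly closer to `i`'s own than the dropped source's. A no-op
#' when all sources agree exactly with `i`, or when no strictly closer
#' non-source exists (the edge is retained). Opinions never change.
#'
#' @inheritParams discrepancy
#' @return The updated `simulation_state` (one source of `i` possibly
#'   replaced).
#' @export
selective_exposure_action <- function(state, i) {
  stopifnot(inherits(state, "simulation_state"))
  x <- state$opinions
  src <- state$graph$sources[i, ]
  d <- abs(x[i] - x[src])
  dmax <- max(d)
  if (dmax == 0) return(state)
  worst <- which(d == dmax)
  slot <- if (length(worst) == 1L) worst else sample(worst, 1L)
  cand <- setdiff(which(abs(x[i] - x) < dmax), c(i, src))
  if (length(cand) == 0L) return(state)
  pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
  state$graph$sources[i, slot] <- pick
  state
}

#' Advance the simulation by one round
#'
#' Draws a fresh uniform permutation of the agents; agents act sequentially in
#' that order, each seeing all updates made earlier in the same round. Each
#' acting agent independently draws selective exposure with probability `beta`
#' and naive learning otherwise (the Bernoulli draw happens every round,
#' whether or not the resulting action is a no-op).
#'
#' @param state A [simulation_state()].
#' @return A list with `state` (round counter incremented) and `changed`
#'   (TRUE iff any opinion or edge changed).
#' @export
step_round <- function(state) {
  stopifnot(inherits(state, "simulation_state"))
  before_x <- state$opinions
  before_s <- state$graph$sources
  for (i in sample.int(state$spec$n)) {
    state <- if (stats::runif(1) < state$beta) {
      selective_exposure_action(state, i)
    } else {
      naive_learning_action(state, i)
    }
  }
  state$round <- state$round + 1L
  list(state = state,
       changed = !identical(before_x, state$opinions) ||
                 !identical(before_s, state$graph$sources))
}

#' Is the state steady?
#'
#' TRUE iff every action drawable with nonzero probability is a no-op for
#' every agent: for `beta < 1`, every agent's opinion equals its source
#' median; for `beta > 0`, every agent's most-discrepant source either agrees
#' exactly with the agent or has no strictly closer non-source replacement.
#' The candidate set depends only on the maximal discrepancy, so the condition
#' is independent of how ties among most-discrepant sources are broken.
#'
#' @param state A [simulation_state()].
#' @return Logical scalar.
#' @export
is_steady <- function(state) {
  stopifnot(inherits(state, "simulation_state"))
  x <- state$opinions
  n <- state$spec$n
  for (i in seq_len(n)) {
    src <- state$graph$sources[i, ]
    if (state$beta < 1 && x[i] != stats::median(x[src])) return(FALSE)
    if (state$beta > 0) {
      dmax <- max(abs(x[i] - x[src]))
      if (dmax > 0) {
        closer <- which(abs(x[i] - x) < dmax)
        if (length(setdiff(closer, c(i, src))) > 0L) return(FALSE)
      }
    }
  }
  TRUE
}

#' Run one simulation to steady state
#'
#' Initializes opinions and the source graph from the model spec, then applies
#' [step_round()] dynamics until no drawable action can change anything (see
#' [is_steady()]) or `max_rounds` is hit. Deterministic given all parameters
#' and `seed`.
#'
#' @param spec An [make_model_spec()] object.
#' @param k In-degree (default 5).
#' @param beta Selective-exposure propensity in `[0, 1]`.
#' @param topology Initial topology, see [init_sources()].
#' @param seed Optional integer seed (applied via [set.seed()]); if `NULL`,
#'   the current RNG stream is used.
#' @param max_rounds Round cap (default 1000). Hitting the cap returns
#'   `converged = FALSE` with a warning.
#' @param record_trajectory If TRUE, per-round [summarize_state()] records for
#'   rounds `0..trajectory_rounds` are returned (the run still continues to
#'   steady state; rounds after convergence repeat the steady values).
#' @param trajectory_rounds Number of early rounds to record (default 10).
#' @param engine `"cpp"` (default, compiled round loop) or `"r"` (pure-R
#'   [step_round()] loop). Both consume R's seeded RNG stream and each is
#'   deterministic, but their draw orders differ, so they are not sample-path
#'   identical to each other.
#' @return An object of class `steady_state_result`: list with `state` (the
#'   final [simulation_state()]), `initial_opinions`, `initial_sources`,
#'   `rounds_to_steady`, `converged`, and `trajectory` (data frame or `NULL`).
#' @export
run_simulation <- function(spec, k = 5L, beta, topology = "random",
                           seed = NULL, max_rounds = 1000L,
                           record_trajectory = FALSE, trajectory_rounds = 10L,
                           engine = c("cpp", "r")) {
  stopifnot(inherits(spec, "opinion_model_spec"))
  engine <- match.arg(engine)
  if (max_rounds < 1L) stop("'max_rounds' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  x0 <- sample_initial_opinions(spec)
  g0 <- init_sources(spec$n, k, topology)

  if (engine == "cpp") {
    res <- sim_engine(x0, g0$sources, beta, as.integer(max_rounds),
                      if (record_trajectory) as.integer(trajectory_rounds) else -1L)
    g <- g0
    g$sources <- res$sources
    final <- simulation_state(spec, g, res$opinions, beta, res$rounds)
    traj <- NULL
    if (record_trajectory) {
      snaps <- res$trajectory[seq_len(res$n_snapshots)]
      traj <- do.call(rbind, lapply(seq_len(trajectory_rounds + 1L), function(r) {
        # rounds past convergence repeat the steady snapshot
        s <- if (r <= length(snaps)) snaps[[r]] else snaps[[length(snaps)]]
        gr <- g0
        gr$sources <- s$sources
        summarize_state(simulation_state(spec, gr, s$opinions, beta, r - 1L))
      }))
    }
    rounds <- res$rounds
    converged <- res$converged
  } else {
    st <- simulation_state(spec, g0, x0, beta)
    traj_rows <- if (record_trajectory) list(summarize_state(st)) else NULL
    converged <- is_steady(st)
    while (!converged && st$round < max_rounds) {
      st <- step_round(st)$state
      if (record_trajectory && st$round <= trajectory_rounds) {
        traj_rows[[st$round + 1L]] <- summarize_state(st)
      }
      converged <- is_steady(st)
    }
    final <- st
    traj <- NULL
    if (record_trajectory) {
      last <- traj_rows[[length(traj_rows)]]
      while (length(traj_rows) < trajectory_rounds + 1L) {
        last$round <- length(traj_rows)
        traj_rows[[length(traj_rows) + 1L]] <- last
      }
      traj <- do.call(rbind, traj_rows)
    }
    rounds <- final$round
  }

  if (!converged) {
    warning("simulation hit the ", max_rounds, "-round cap before steady state")
  }
  structure(
    list(state = final, initial_opinions = x0, initial_sources = g0$sources,
         rounds_to_steady = rounds, converged = converged, trajectory = traj),
    class = "steady_state_result"
  )
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat("<steady_state_result> model = ", x$state$spec$name,
      ", beta = ", x$state$beta,
      ", rounds = ", x$rounds_to_steady,
      ", converged = ", x$converged, "\n", sep = "")
  invisible(x)
}
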