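#' Summarize a simulation state
#'
#' Computes the per-run steady-state (or per-round) measures:
#' \describe{
#'   \item{`individual_performance`}{fraction of agents whose current opinion
#'     is a good decision (True for the jury model; within the two-standard-
#'     error band otherwise), \eqn{p_i = |H_i| / n}.}
#'   \item{`collective_decision`}{the aggregate of current opinions under the
#'     model's rule (majority stored as 1/0, mean, or median).}
#'   \item{`collective_good`}{whether the collective decision is good
#'     (membership in \eqn{H_G}).}
#'   \item{`opinion_diversity`}{population standard deviation \eqn{\sigma_x}
#'     of current opinions (zero iff all opinions are equal).}
#'   \item{`giant_scc_fraction`}{share of agents in the largest strongly
#'     connected component, \eqn{|C_1|}.}
#'   \item{`modularity_newman`, `modularity_paper`}{both
#'     [graph_modularity()] variants over the opinion dichotomy.}
#' }
#'
#' @param state A [simulation_state()].
#' @return One-row data frame (a `MeasureRecord`).
#' @export
summarize_state <- function(state) {
  stopifnot(inherits(state, "simulation_state"))
  spec <- state$spec
  x <- state$opinions
  decision <- aggregate_opinions(x, spec$aggregation_rule)
  labels <- dichotomize_opinions(x, spec)
  data.frame(
    individual_performance = mean(is_good_decision(x, spec)),
    collective_decision = as.numeric(decision),
    collective_good = is_good_decision(decision, spec),
    opinion_diversity = population_sd(x),
    giant_scc_fraction = giant_scc_fraction(state$graph),
    modularity_newman = graph_modularity(state$graph, labels, "newman_directed"),
    modularity_paper = graph_modularity(state$graph, labels, "paper"),
    round = state$round
  )
}

# population (not sample) standard deviation
population_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

#' Collective performance over a batch of runs
#'
#' The fraction \eqn{P_G = |H_G| / N} of runs whose collective decision was
#' good, over a collection of [summarize_state()] records from a common
#' (model, beta) cell.
#'
#' @param records Data frame with a `collective_good` column (rows from
#'   [summarize_state()]).
#' @return Numeric scalar in `[0, 1]`.
#' @export
collective_performance <- function(records) {
  if (NROW(records) == 0L) stop("empty record collection")
  mean(records$collective_good)
}
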