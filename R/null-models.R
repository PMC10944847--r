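#' Jury probability of a correct majority decision
#'
#' Exact binomial tail probability that a group of `n` independent voters,
#' each correct with probability `p`, reaches the correct decision by majority
#' rule: \eqn{P(Y > n/2)} with \eqn{Y \sim Bin(n, p)}. For `p > 0.5` this is
#' strictly increasing in (odd) `n` and tends to 1 — the classical jury
#' theorem.
#'
#' @param n Odd positive group size (even sizes need a tie rule and are
#'   rejected).
#' @param p Individual competence in `(0, 1)`.
#' @return Probability scalar.
#' @examples
#' condorcet_group_probability(101, 0.55) # 0.844
#' @export
condorcet_group_probability <- function(n, p) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  if (n %% 2L == 0L) stop("'n' must be odd (no tie rule defined)")
  if (p <= 0 || p >= 1) stop("'p' must lie in (0, 1)")
  stats::pbinom(floor(n / 2), n, p, lower.tail = FALSE)
}

#' Asymptotic variance of the sample median
#'
#' For `n = 2m + 1` i.i.d. draws from a density `f`, the sample median is
#' asymptotically normal around the population median with variance
#' \eqn{1 / (8 f(\tilde\mu)^2 m)}.
#'
#' @param density_at_median Density of the parent distribution at its median,
#'   \eqn{f(\tilde\mu) > 0}.
#' @param m Half-sample size `(n - 1) / 2`, at least 1.
#' @return Variance scalar.
#' @examples
#' median_asymptotic_variance(1 / 2, 50) # 0.01
#' @export
median_asymptotic_variance <- function(density_at_median, m) {
  if (density_at_median <= 0) stop("'density_at_median' must be positive")
  if (m < 1) stop("'m' must be at least 1")
  1 / (8 * density_at_median^2 * m)
}

#' No-influence null model of the collective decision
#'
#' The distribution and good-decision probability of the collective decision
#' obtained by simply aggregating fresh independent initial opinions, with no
#' social dynamics. For the continuous models the null is
#' \eqn{N(\mu, \sigma_{\bar x}^2)} (central limit theorem for mean
#' aggregation; sample-median asymptotics for the exponential model), so the
#' good-decision probability is \eqn{2\Phi(2) - 1 \approx 0.954}. For the
#' jury model it is the exact binomial tail
#' [condorcet_group_probability()].
#'
#' @param spec An [make_model_spec()] object.
#' @return An object of class `null_summary`: list with `name`, `true_state`,
#'   `collective_se`, `good_probability`, and `distribution` (named vector
#'   `mean`/`variance`; `NA` for the jury model, whose null is the binomial
#'   count).
#' @export
aggregation_null <- function(spec) {
  stopifnot(inherits(spec, "opinion_model_spec"))
  if (spec$name == "condorcet") {
    out <- list(
      name = spec$name,
      true_state = spec$true_state,
      collective_se = NA_real_,
      good_probability = condorcet_group_probability(spec$n, spec$params$p),
      distribution = c(mean = NA_real_, variance = NA_real_)
    )
  } else {
    out <- list(
      name = spec$name,
      true_state = spec$true_state,
      collective_se = spec$collective_se,
      good_probability = 2 * stats::pnorm(2) - 1,
      distribution = c(mean = spec$true_state,
                       variance = spec$collective_se^2)
    )
  }
  structure(out, class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat("<null_summary> model = ", x$name, "\n", sep = "")
  cat("  true state:       ", format(x$true_state, digits = 4), "\n", sep = "")
  cat("  good probability: ", format(x$good_probability, digits = 4), "\n", sep = "")
  if (!is.na(x$distribution[["mean"]])) {
    cat("  null distribution: Normal(",
        format(x$distribution[["mean"]], digits = 4), ", ",
        format(x$distribution[["variance"]], digits = 4), ")\n", sep = "")
  }
  invisible(x)
}
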