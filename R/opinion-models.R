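#' Construct an opinion-model specification
#'
#' Builds the specification of one of the four generative models of initial
#' opinions, together with its true state, aggregation rule and the standard
#' error of the no-influence collective decision.
#'
#' The four models are:
#' \describe{
#'   \item{`condorcet`}{Binary jury setting: \eqn{n = 101} agents hold i.i.d.
#'     Bernoulli opinions (1 = True) with individual competence
#'     \eqn{p = 0.55}; decisions are aggregated by majority rule.}
#'   \item{`galton`}{Continuous estimation: \eqn{n = 100} agents hold i.i.d.
#'     standard normal opinions around the true state \eqn{\mu = 0};
#'     aggregation by the mean, so the null collective decision is
#'     \eqn{N(0, \sigma^2/n) = N(0, 0.01)}.}
#'   \item{`bimodal`}{Polarized opinions: a 50/50 mixture of
#'     \eqn{N(-2, 1)} and \eqn{N(2, 1)} over \eqn{n = 100} agents, total
#'     variance \eqn{\sigma^2 = 5} by the law of total variance; mean
#'     aggregation, null variance \eqn{0.05}.}
#'   \item{`exponential`}{Skewed opinions: i.i.d. Exponential(\eqn{\lambda = 1})
#'     over \eqn{n = 101} agents; aggregation by the median. The true state is
#'     the distribution median \eqn{\tilde\mu = \ln 2} and the null standard
#'     error follows the sample-median asymptotics
#'     \eqn{\sqrt{1 / (8 f(\tilde\mu)^2 m)}} with \eqn{m = (n-1)/2}, i.e.
#'     0.1 at the default \eqn{n = 101}.}
#' }
#'
#' A collective (or individual) continuous decision is "good" when it falls
#' strictly within two collective standard errors of the true state; the
#' Condorcet criterion is categorical (the decision is True).
#'
#' @param name One of `"condorcet"`, `"galton"`, `"bimodal"`, `"exponential"`.
#' @param n Optional group-size override (positive integer; must be odd for
#'   the condorcet and exponential models).
#' @param ... Optional overrides of the model's other declared parameters:
#'   `p` (condorcet); `mu`, `sigma2` (galton); `q`, `mu_local`,
#'   `sigma2_local` (bimodal); `lambda` (exponential).
#'
#' @return An object of class `opinion_model_spec`: a list with elements
#'   `name`, `n`, `opinion_kind` (`"binary"` or `"continuous"`), `params`,
#'   `true_state`, `aggregation_rule` (`"majority"`, `"mean"` or `"median"`),
#'   `population_sd` and `collective_se` (`NA` for condorcet, whose criterion
#'   is categorical).
#'
#' @examples
#' make_model_spec("condorcet")
#' make_model_spec("galton", n = 400)
#' @export
make_model_spec <- function(name = c("condorcet", "galton", "bimodal", "exponential"),
                            n = NULL, ...) {
  name <- match.arg(name)
  overrides <- list(...)
  if (!is.null(n)) overrides$n <- n
  defaults <- switch(name,
    condorcet   = list(n = 101L, p = 0.55),
    galton      = list(n = 100L, mu = 0, sigma2 = 1),
    bimodal     = list(n = 100L, q = 0.5, mu_local = c(-2, 2), sigma2_local = 1),
    exponential = list(n = 101L, lambda = 1)
  )
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter(s) for model '", name, "': ",
         paste(unknown, collapse = ", "))
  }
  params <- utils::modifyList(defaults, overrides)
  n <- as.integer(params$n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  params$n <- n

  spec <- switch(name,
    condorcet = {
      p <- params$p
      if (p <= 0 || p >= 1) stop("'p' must lie in (0, 1)")
      if (n %% 2L == 0L) stop("'n' must be odd for the condorcet model")
      list(
        opinion_kind = "binary",
        true_state = 1,
        aggregation_rule = "majority",
        population_sd = sqrt(p * (1 - p)),
        collective_se = NA_real_
      )
    },
    galton = {
      if (params$sigma2 <= 0) stop("'sigma2' must be positive")
      sd <- sqrt(params$sigma2)
      list(
        opinion_kind = "continuous",
        true_state = params$mu,
        aggregation_rule = "mean",
        population_sd = sd,
        collective_se = sd / sqrt(n)
      )
    },
    bimodal = {
      q <- params$q
      if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
      if (length(params$mu_local) != 2L) stop("'mu_local' must have length 2")
      if (params$sigma2_local <= 0) stop("'sigma2_local' must be positive")
      w <- c(q, 1 - q)
      mu <- sum(w * params$mu_local)
      # law of total variance: between-component + within-component
      sigma2 <- sum(w * (params$mu_local - mu)^2) + sum(w * params$sigma2_local)
      list(
        opinion_kind = "continuous",
        true_state = mu,
        aggregation_rule = "mean",
        population_sd = sqrt(sigma2),
        collective_se = sqrt(sigma2 / n)
      )
    },
    exponential = {
      lambda <- params$lambda
      if (lambda <= 0) stop("'lambda' must be positive")
      if (n %% 2L == 0L) stop("'n' must be odd for the exponential model (median aggregation)")
      med <- log(2) / lambda
      m <- (n - 1) / 2
      f_med <- lambda * exp(-lambda * med) # density at the median = lambda/2
      list(
        opinion_kind = "continuous",
        true_state = med,
        aggregation_rule = "median",
        population_sd = 1 / lambda,
        collective_se = sqrt(median_asymptotic_variance(f_med, m))
      )
    }
  )
  structure(
    c(list(name = name, n = n, params = params), spec),
    class = "opinion_model_spec"
  )
}

#' @export
print.opinion_model_spec <- function(x, ...) {
  cat("<opinion_model_spec> ", x$name, "\n", sep = "")
  cat("  n:               ", x$n, "\n", sep = "")
  cat("  opinion kind:    ", x$opinion_kind, "\n", sep = "")
  cat("  aggregation:     ", x$aggregation_rule, "\n", sep = "")
  cat("  true state:      ", format(x$true_state, digits = 4), "\n", sep = "")
  cat("  population sd:   ", format(x$population_sd, digits = 4), "\n", sep = "")
  cat("  collective se:   ",
      if (is.na(x$collective_se)) "categorical (majority True)"
      else format(x$collective_se, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Draw initial opinions
#'
#' Samples `spec$n` i.i.d. initial opinions from the model's distribution,
#' using R's global random number stream. Binary opinions are encoded 1 = True,
#' 0 = False, so that the median of an odd number of sources coincides with
#' their majority.
#'
#' @param spec An [make_model_spec()] object.
#' @return Numeric vector of length `spec$n`.
#' @export
sample_initial_opinions <- function(spec) {
  stopifnot(inherits(spec, "opinion_model_spec"))
  n <- spec$n
  switch(spec$name,
    condorcet   = as.numeric(stats::rbinom(n, 1L, spec$params$p)),
    galton      = stats::rnorm(n, spec$params$mu, sqrt(spec$params$sigma2)),
    bimodal     = {
      comp <- stats::rbinom(n, 1L, spec$params$q) + 1L
      stats::rnorm(n, spec$params$mu_local[comp], sqrt(spec$params$sigma2_local))
    },
    exponential = stats::rexp(n, spec$params$lambda)
  )
}

#' Aggregate individual opinions into a collective decision
#'
#' @param opinions Numeric vector of opinions (binary opinions encoded 0/1).
#' @param rule `"majority"` (binary, odd length only: TRUE iff strictly more
#'   than half are 1), `"mean"`, or `"median"` (midpoint of the two central
#'   order statistics for even length).
#' @return For `"majority"`, a logical scalar; otherwise a numeric scalar.
#' @export
aggregate_opinions <- function(opinions, rule = c("majority", "mean", "median")) {
  rule <- match.arg(rule)
  if (length(opinions) == 0L) stop("cannot aggregate an empty opinion vector")
  switch(rule,
    majority = {
      if (!all(opinions %in% c(0, 1))) {
        stop("majority rule requires binary (0/1) opinions")
      }
      if (length(opinions) %% 2L == 0L) {
        stop("majority rule requires an odd number of opinions (no tie rule)")
      }
      sum(opinions) > length(opinions) / 2
    },
    mean   = mean(opinions),
    median = stats::median(opinions)
  )
}

#' Is a decision "good"?
#'
#' For the binary jury model a decision is good iff it is True. For the
#' continuous models a decision (individual or collective) is good iff it lies
#' strictly within two collective standard errors of the true state,
#' \eqn{|x - \mu| < 2\sigma_{\bar x}}; the same standardized band is used at
#' both levels.
#'
#' @param value The decision: logical or 0/1 for condorcet, numeric otherwise.
#'   Vectorized over `value`.
#' @param spec An [make_model_spec()] object.
#' @return Logical vector.
#' @export
is_good_decision <- function(value, spec) {
  stopifnot(inherits(spec, "opinion_model_spec"))
  if (spec$opinion_kind == "binary") {
    if (is.numeric(value) && !all(value %in% c(0, 1))) {
      stop("binary model expects logical or 0/1 decisions")
    }
    as.logical(value)
  } else {
    if (!is.numeric(value)) stop("continuous model expects numeric decisions")
    abs(value - spec$true_state) < 2 * spec$collective_se
  }
}
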