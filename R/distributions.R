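#' Log-logistic cumulative survival
#'
#' Cumulative survival under the log-logistic failure-time model,
#' \deqn{S(t) = (1 + (t/a)^k)^{-1},}
#' where `scale` (\eqn{a}, minutes) equals the median failure time and
#' `shape` (\eqn{k}, dimensionless) controls the spread of failure times:
#' \eqn{var[\log t_f] = \pi^2 / (3 k^2)}, so smaller shape means a flatter,
#' more gradual survival decline.
#'
#' @param t Nonnegative time(s), minutes.
#' @param scale Positive scale parameter \eqn{a}; the median failure time.
#' @param shape Positive shape parameter \eqn{k}.
#' @return Survival probabilities in `[0, 1]`, same length as `t`.
#' @seealso [llogis_density()], [llogis_hazard()], [llogis_quantile()]
#' @examples
#' llogis_survival(100, scale = 100, shape = 2)  # 0.5 at the median
#' @export
llogis_survival <- function(t, scale, shape) {
  check_llogis(scale, shape)
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  1 / (1 + (t / scale)^shape)
}

#' Log-logistic failure density
#'
#' The failure density \eqn{f(t) = -dS/dt}, the frequency distribution of
#' failure times:
#' \deqn{f(t) = (k/a) (t/a)^{k-1} (1 + (t/a)^k)^{-2}.}
#'
#' @inheritParams llogis_survival
#' @return Densities (per minute), same length as `t`.
#' @export
llogis_density <- function(t, scale, shape) {
  check_llogis(scale, shape)
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  z <- (t / scale)^shape
  out <- (shape / scale) * (t / scale)^(shape - 1) / (1 + z)^2
  # t = 0 limits: 0 for k > 1, 1/a for k = 1, +Inf for k < 1
  if (any(t == 0)) {
    out[t == 0] <- if (shape > 1) 0 else if (shape == 1) 1 / scale else Inf
  }
  out
}

#' Log-logistic hazard rate
#'
#' Instantaneous failure rate \eqn{h(t) = f(t)/S(t)} implied by the
#' log-logistic survival function:
#' \deqn{h(t) = (k/a)(t/a)^{k-1} / (1 + (t/a)^k).}
#' For `shape > 1` the hazard rises to a single mode and then declines;
#' for `shape <= 1` it declines monotonically.
#'
#' @inheritParams llogis_survival
#' @param t Positive time(s), minutes; `t = 0` is admitted only when
#'   `shape >= 1` (the hazard diverges at the origin otherwise).
#' @return Hazard rates (per minute).
#' @export
llogis_hazard <- function(t, scale, shape) {
  check_llogis(scale, shape)
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  if (shape < 1 && any(t == 0)) {
    stop("hazard is unbounded at t = 0 when shape < 1", call. = FALSE)
  }
  llogis_density(t, scale, shape) / llogis_survival(t, scale, shape)
}

#' Log-logistic survival quantile
#'
#' Inverse of [llogis_survival()]: the time at which cumulative survival
#' equals `prob_surviving`,
#' \eqn{t = a ((1-q)/q)^{1/k}}. `prob_surviving = 0.5` returns the scale
#' (the median failure time).
#'
#' @param prob_surviving Survival probabilities strictly inside `(0, 1)`.
#' @inheritParams llogis_survival
#' @return Times, minutes.
#' @export
llogis_quantile <- function(prob_surviving, scale, shape) {
  check_llogis(scale, shape)
  if (any(prob_surviving <= 0) || any(prob_surviving >= 1)) {
    stop("`prob_surviving` must lie strictly in (0, 1)", call. = FALSE)
  }
  scale * ((1 - prob_surviving) / prob_surviving)^(1 / shape)
}

#' Variance of log failure time implied by the shape parameter
#'
#' For the log-logistic model, \eqn{var[\log t_f] = \pi^2 / (3 k^2)}
#' (natural logs): the shape parameter is inversely related to the spread of
#' log failure times, independent of the scale.
#'
#' @param shape Positive shape parameter(s) \eqn{k}.
#' @return Variance of the natural log of failure time.
#' @export
var_log_failure_time <- function(shape) {
  if (any(shape <= 0)) stop("`shape` must be positive", call. = FALSE)
  pi^2 / (3 * shape^2)
}

#' Inverse of [var_log_failure_time()]: moment-based shape estimate
#' @param v Positive variance of log failure time.
#' @return Shape parameter.
#' @keywords internal
#' @noRd
shape_from_var_log <- function(v) pi / sqrt(3 * v)

#' Sample log-logistic failure times
#'
#' Inverse-CDF draws from the log-logistic failure-time distribution.
#' Deterministic given `seed`; with `seed = NULL` the current RNG state is
#' used.
#'
#' @param n Number of draws (`>= 1`).
#' @inheritParams llogis_survival
#' @param seed Optional integer seed.
#' @return Vector of `n` failure times, minutes.
#' @export
sample_failure_times <- function(n, scale, shape, seed = NULL) {
  check_llogis(scale, shape)
  if (length(n) != 1L || is.na(n) || n < 1) {
    stop("`n` must be a single count >= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  # u is the survival probability of the draw
  llogis_quantile(u, scale, shape)
}

.tdt_families <- c("exponential", "weibull", "loglogistic", "lognormal",
                   "gompertz")

#' Log density under one of the five candidate failure-time families
#'
#' Closed-form log density for the families compared by AIC on static assay
#' data. Parameter conventions:
#' \describe{
#'   \item{exponential}{`rate` \eqn{\lambda > 0}; constant hazard, mean
#'     failure time \eqn{1/\lambda}.}
#'   \item{weibull}{`shape`, `scale` as in [stats::dweibull()].}
#'   \item{loglogistic}{`scale`, `shape` as in [llogis_density()].}
#'   \item{lognormal}{`meanlog`, `sdlog` as in [stats::dlnorm()].}
#'   \item{gompertz}{`shape` (real), `rate` (> 0) with hazard
#'     \eqn{h(t) = rate \cdot e^{shape \cdot t}} (the `flexsurv`
#'     convention, which differs across sources).}
#' }
#'
#' @param t Nonnegative time(s), minutes.
#' @param family One of `"exponential"`, `"weibull"`, `"loglogistic"`,
#'   `"lognormal"`, `"gompertz"`.
#' @param params Named list of parameters per the conventions above.
#' @return Log densities, same length as `t`.
#' @export
family_log_density <- function(t, family, params) {
  family <- match.arg(family, .tdt_families)
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  switch(family,
    exponential = {
      if (params$rate <= 0) stop("exponential `rate` must be positive",
                                 call. = FALSE)
      stats::dexp(t, rate = params$rate, log = TRUE)
    },
    weibull = stats::dweibull(t, shape = params$shape, scale = params$scale,
                              log = TRUE),
    loglogistic = {
      check_llogis(params$scale, params$shape)
      z <- (t / params$scale)^params$shape
      log(params$shape / params$scale) +
        (params$shape - 1) * log(t / params$scale) - 2 * log1p(z)
    },
    lognormal = stats::dlnorm(t, meanlog = params$meanlog,
                              sdlog = params$sdlog, log = TRUE),
    gompertz = flexsurv::dgompertz(t, shape = params$shape,
                                   rate = params$rate, log = TRUE)
  )
}

check_llogis <- function(scale, shape) {
  if (any(!is.finite(scale)) || any(scale <= 0)) {
    stop("`scale` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(shape)) || any(shape <= 0)) {
    stop("`shape` must be positive and finite", call. = FALSE)
  }
  invisible(TRUE)
}
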