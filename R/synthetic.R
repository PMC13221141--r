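# Synthetic static and dynamic knockdown datasets with the statistical
# structure the models assume, so every stage is testable without any
# external download. Defaults emulate the empirical regime of adult
# Drosophila heat-knockdown assays: median failure times from hours at
# 33 degC down to minutes at 40 degC (TDT slope about -0.9 per degC on the
# natural-log scale), shape parameters declining from about 4 to about 2
# over the same range (variance of log failure time increasing with
# temperature), and 10-30 individuals per temperature cell.

# Per-cell / per-set sub-seeds derive from the root seed by a fixed counter
# scheme keyed on the cell temperature (times 10, rounded) or the set
# index, so adding a temperature or a set never changes other draws. Kept
# below 2^31 - 1.
derive_seed <- function(seed, key) {
  as.integer((as.numeric(seed) * 1009 + 7919 * key) %% 2147483647)
}

#' Generate a synthetic constant-temperature failure dataset
#'
#' For each assay temperature, draws `n_per_cell` log-logistic failure
#' times with temperature-linked parameters `a(T) = exp(beta0 + beta1 T)`
#' and `k(T) = exp(gamma0 + gamma1 T)`. Deterministic given `seed`; each
#' temperature cell uses a sub-seed derived from the root seed and the
#' temperature, so adding cells never perturbs existing ones. The
#' generating parameters are attached as attribute `truth` for recovery
#' tests.
#'
#' @param temperatures Assay temperatures, degC (default 33-40 by 1).
#' @param n_per_cell Individuals per temperature cell (default 20).
#' @param beta0,beta1 Log-scale link coefficients (defaults 35.6 and -0.9:
#'   a(33) about 6 h, a(40) under 1 min).
#' @param gamma0,gamma1 Log-shape link coefficients (defaults 4.7 and -0.1:
#'   k from about 4 at 33 degC to about 2 at 40 degC).
#' @param species Species label.
#' @param sex Optional sex label for all records.
#' @param seed Root integer seed.
#' @return A [failure_dataset()] with attribute `truth`.
#' @export
generate_static_dataset <- function(temperatures = 33:40, n_per_cell = 20,
                                    beta0 = 35.6, beta1 = -0.9,
                                    gamma0 = 4.7, gamma1 = -0.1,
                                    species = "synthetic", sex = NA,
                                    seed = 1) {
  if (n_per_cell < 1) stop("`n_per_cell` must be >= 1", call. = FALSE)
  rows <- lapply(temperatures, function(T) {
    a <- exp(beta0 + beta1 * T)
    k <- exp(gamma0 + gamma1 * T)
    times <- sample_failure_times(n_per_cell, a, k,
                                  seed = derive_seed(seed, round(10 * T)))
    data.frame(species = species, sex = sex, temperature = T, time = times,
               trial_id = sprintf("T%.1f", T), stringsAsFactors = FALSE)
  })
  out <- failure_dataset(do.call(rbind, rows))
  attr(out, "truth") <- list(beta0 = beta0, beta1 = beta1, gamma0 = gamma0,
                             gamma1 = gamma1)
  out
}

#' Generate a fluctuating temperature profile
#'
#' Builds stepwise or continuous assay profiles within a declared stressful
#' temperature range (default 34-42 degC, the regime of fluctuating
#' heat-coma assays).
#'
#' @param kind `"constant"`, `"step"`, `"ramp"`, or `"sinusoid"`.
#' @param bounds Admissible temperature range, degC (default `c(34, 42)`).
#' @param temperature Constant kind: the single temperature.
#' @param segment_temps,segment_durations Step kind: temperatures (degC)
#'   and durations (min) of successive segments.
#' @param from,to,duration Ramp kind: start/end temperatures and span.
#' @param midpoint,amplitude,period,duration_sin,resolution Sinusoid kind:
#'   `midpoint + amplitude * sin(2 pi t / period)` sampled every
#'   `resolution` minutes over `duration_sin` minutes.
#' @return A [temperature_profile()].
#' @export
generate_temperature_profile <- function(kind = c("constant", "step",
                                                  "ramp", "sinusoid"),
                                         bounds = c(34, 42),
                                         temperature = 38,
                                         segment_temps = c(36, 39),
                                         segment_durations = c(60, 60),
                                         from = 34, to = 42,
                                         duration = 120,
                                         midpoint = 38, amplitude = 3,
                                         period = 60, duration_sin = 240,
                                         resolution = 1) {
  kind <- match.arg(kind)
  prof <- switch(kind,
    constant = temperature_profile(0, temperature),
    step = {
      if (length(segment_temps) != length(segment_durations)) {
        stop("`segment_temps` and `segment_durations` lengths differ",
             call. = FALSE)
      }
      knots <- c(0, cumsum(segment_durations)[-length(segment_durations)])
      temperature_profile(knots, segment_temps)
    },
    ramp = temperature_profile(c(0, duration), c(from, to),
                               interpolation = "linear"),
    sinusoid = {
      tt <- seq(0, duration_sin, by = resolution)
      temperature_profile(tt, midpoint + amplitude * sin(2 * pi * tt / period),
                          interpolation = "linear")
    })
  if (min(prof$temperature) < bounds[1] || max(prof$temperature) > bounds[2]) {
    stop(sprintf("profile temperatures [%.2f, %.2f] violate bounds [%g, %g]",
                 min(prof$temperature), max(prof$temperature), bounds[1],
                 bounds[2]), call. = FALSE)
  }
  prof
}

#' Sample failure times under a fluctuating profile
#'
#' Inverse-CDF sampling from the increasing-variance dynamic survival
#' curve: draws `u ~ Uniform(0, 1)` and solves `S(t) = u` on the predicted
#' curve by bisection. Deterministic given `seed`. If a draw falls below
#' the survival reached at the horizon, the horizon is extended (doubling,
#' up to 6 times) and the extension is reported via `message()`.
#'
#' @param profile A [temperature_profile()].
#' @param model A [tdt_model()].
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed.
#' @param grid_step,horizon_mult,shape_eval Passed to
#'   [predict_survival_increasing_variance()].
#' @return Failure times, minutes.
#' @export
sample_under_profile <- function(profile, model, n, seed = NULL,
                                 grid_step = 0.1, horizon_mult = 10,
                                 shape_eval = "instantaneous") {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  pred <- predict_survival_increasing_variance(
    profile, model, grid_step = grid_step, horizon_mult = horizon_mult,
    shape_eval = shape_eval)
  floor_S <- min(pred$survival)
  tries <- 0L
  while (any(u < floor_S) && tries < 6L) {
    tries <- tries + 1L
    horizon_mult <- horizon_mult * 2
    message("extending prediction horizon to horizon_mult = ", horizon_mult,
            " to cover extreme draws")
    pred <- predict_survival_increasing_variance(
      profile, model, grid_step = grid_step, horizon_mult = horizon_mult,
      shape_eval = shape_eval)
    floor_S <- min(pred$survival)
  }
  u <- pmax(u, floor_S + 1e-12)
  # S is nonincreasing on the grid up to numerical jitter at shape jumps;
  # invert the monotone envelope
  S_env <- cummin(pred$survival)
  vapply(u, function(ui) {
    i <- which(S_env <= ui)[1]
    if (is.na(i)) return(max(pred$times))
    if (i == 1L || S_env[i] == ui) return(pred$times[i])
    t0 <- pred$times[i - 1]; t1 <- pred$times[i]
    s0 <- S_env[i - 1]; s1 <- S_env[i]
    if (s0 == s1) return(t1)
    t0 + (s0 - ui) / (s0 - s1) * (t1 - t0)
  }, numeric(1))
}
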