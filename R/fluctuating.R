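# Prediction of failure-time distributions under fluctuating temperature
# profiles: damage accumulation, the deterministic additive-damage
# (Jorgensen-style) median predictor, the pooled average-survival-curve
# (Rezende-style) predictor, and the increasing-variance log-logistic
# predictor.

#' Construct a temperature profile
#'
#' A time-indexed temperature trajectory for a fluctuating assay. Times are
#' minutes starting at 0; temperatures in degrees Celsius. With
#' `interpolation = "stepwise"` (the default; experimental profiles are
#' chamber setpoints) the temperature at the i-th knot holds until the next
#' knot; with `"linear"` temperatures are interpolated between knots.
#' Beyond the last knot the final temperature is held indefinitely.
#'
#' @param time Nondecreasing times, minutes, starting at 0. Duplicated
#'   times are deduplicated keeping the last value.
#' @param temperature Temperatures, degC, same length as `time`.
#' @param interpolation `"stepwise"` or `"linear"`.
#' @return A `temperature_profile`.
#' @export
temperature_profile <- function(time, temperature,
                                interpolation = c("stepwise", "linear")) {
  interpolation <- match.arg(interpolation)
  if (length(time) != length(temperature) || length(time) < 1) {
    stop("`time` and `temperature` must have equal length >= 1",
         call. = FALSE)
  }
  if (is.unsorted(time)) stop("`time` must be nondecreasing", call. = FALSE)
  if (time[1] != 0) stop("profile must start at time 0", call. = FALSE)
  keep <- !duplicated(time, fromLast = TRUE)
  time <- time[keep]; temperature <- temperature[keep]
  if (any(!is.finite(temperature))) {
    stop("temperatures must be finite", call. = FALSE)
  }
  structure(list(time = time, temperature = temperature,
                 interpolation = interpolation),
            class = "temperature_profile")
}

#' @export
print.temperature_profile <- function(x, ...) {
  cat(sprintf(
    "<temperature_profile> %s | %d knot(s) | span %.1f min | %.1f-%.1f degC\n",
    x$interpolation, length(x$time), max(x$time),
    min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' Temperature at given times along a profile
#' @param profile A [temperature_profile()].
#' @param t Times, minutes (>= 0); beyond the last knot the final
#'   temperature is held.
#' @return Temperatures, degC.
#' @export
profile_temperature <- function(profile, t) {
  stopifnot(inherits(profile, "temperature_profile"))
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  if (profile$interpolation == "stepwise") {
    idx <- findInterval(t, profile$time)
    idx[idx < 1] <- 1L
    profile$temperature[idx]
  } else {
    stats::approx(profile$time, profile$temperature, xout = t, rule = 2,
                  ties = "ordered")$y
  }
}

#' Accumulate temperature-dependent damage along a profile
#'
#' Integrates a temperature-dependent injury rate over a profile:
#' `D(t) = integral of rate(T(u)) du` from 0 to `t`, the additive-damage
#' assumption. For stepwise profiles the integral is piecewise closed form
#' (exact); for linearly interpolated profiles it is a trapezoid rule on a
#' grid of step `grid_step` minutes.
#'
#' @param profile A [temperature_profile()].
#' @param rate_at_temperature Function mapping temperature (degC) to a
#'   positive, finite per-minute rate; vectorized.
#' @param t_end End of the trajectory, minutes.
#' @param grid_step Integration step for linear profiles (default 0.1 min).
#' @return A `damage_trajectory`: knot `times`, cumulative `damage`, and
#'   the final holding rate; evaluate anywhere with [damage_at()].
#' @export
accumulate_damage <- function(profile, rate_at_temperature, t_end,
                              grid_step = 0.1) {
  stopifnot(inherits(profile, "temperature_profile"))
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  if (profile$interpolation == "stepwise") {
    knots <- profile$time[profile$time < t_end]
    temps <- profile$temperature[profile$time < t_end]
    times <- c(knots, t_end)
    rates <- rate_at_temperature(temps)
    bad <- which(!is.finite(rates) | rates <= 0)
    if (length(bad)) {
      stop("non-finite or nonpositive rate on segment starting at t = ",
           knots[bad[1]], " min (T = ", temps[bad[1]], " degC)",
           call. = FALSE)
    }
    damage <- c(0, cumsum(rates * diff(times)))
    final_rate <- rates[length(rates)]
  } else {
    times <- sort(unique(c(seq(0, t_end, by = grid_step), profile$time[
      profile$time <= t_end], t_end)))
    temps <- profile_temperature(profile, times)
    rates <- rate_at_temperature(temps)
    bad <- which(!is.finite(rates) | rates <= 0)
    if (length(bad)) {
      stop("non-finite or nonpositive rate at t = ", times[bad[1]],
           " min (T = ", temps[bad[1]], " degC)", call. = FALSE)
    }
    damage <- c(0, cumsum(0.5 * (rates[-1] + rates[-length(rates)]) *
                            diff(times)))
    final_rate <- rates[length(rates)]
  }
  structure(list(times = times, damage = damage, final_rate = final_rate),
            class = "damage_trajectory")
}

#' Evaluate a damage trajectory
#' @param traj A [accumulate_damage()] result.
#' @param t Times, minutes; beyond the trajectory end, damage grows at the
#'   final holding rate.
#' @return Cumulative damage (dimensionless).
#' @export
damage_at <- function(traj, t) {
  stopifnot(inherits(traj, "damage_trajectory"))
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  tm <- traj$times[length(traj$times)]
  dm <- traj$damage[length(traj$damage)]
  inside <- t <= tm
  out <- numeric(length(t))
  if (any(inside)) {
    out[inside] <- stats::approx(traj$times, traj$damage, xout = t[inside],
                                 ties = "ordered")$y
  }
  out[!inside] <- dm + traj$final_rate * (t[!inside] - tm)
  out
}

# First time at which cumulative damage reaches `target` (exact inversion of
# the piecewise-linear trajectory; damage is strictly increasing).
damage_first_crossing <- function(traj, target) {
  d <- traj$damage; tt <- traj$times
  m <- length(d)
  if (target <= d[m]) {
    i <- which(d >= target)[1]
    if (i == 1L) return(tt[1])
    tt[i - 1] + (target - d[i - 1]) / (d[i] - d[i - 1]) * (tt[i] - tt[i - 1])
  } else {
    tt[m] + (target - d[m]) / traj$final_rate
  }
}

#' Deterministic additive-damage prediction of median failure time
#'
#' The deterministic model: injury accrues at rate `1/t50(T)` with
#' `t50(T) = exp(intercept + slope * T)` from the TDT regression, damage is
#' additive across temperatures, and the median failure occurs when
#' accumulated damage reaches 1. At constant temperature this returns
#' exactly `t50(T)`.
#'
#' @param profile A [temperature_profile()].
#' @param tdt A [fit_tdt_regression()] result.
#' @param horizon_mult Search horizon as a multiple of the constant-
#'   temperature median at the profile's coolest temperature (default 10).
#' @param grid_step Integration step for linear profiles.
#' @return Predicted median failure time, minutes. If damage never reaches
#'   1 within the horizon, `NA` with attribute `beyond_horizon = TRUE`.
#' @export
predict_median_jorgensen <- function(profile, tdt, horizon_mult = 10,
                                     grid_step = 0.1) {
  stopifnot(inherits(tdt, "tdt_regression"))
  horizon <- horizon_mult * tdt_median(tdt, min(profile$temperature))
  traj <- accumulate_damage(profile, function(T) 1 / tdt_median(tdt, T),
                            t_end = horizon, grid_step = grid_step)
  if (damage_at(traj, horizon) < 1) {
    return(structure(NA_real_, beyond_horizon = TRUE))
  }
  structure(damage_first_crossing(traj, 1), beyond_horizon = FALSE)
}

#' Pooled average relative survival curve
#'
#' The empirical ingredient of the average-survival-curve model: every
#' observed failure time is rescaled to relative time
#' \eqn{r = t_f / t50(T_{assay})} using the TDT regression, the rescaled times are
#' pooled across temperatures, and a single survival curve in relative time
#' is estimated from the pool. The working curve interpolates linearly
#' between the midpoints of the empirical survival jumps (and is 1 at
#' \eqn{r = 0}, 0 beyond the largest pooled value); the relative failure
#' density is a kernel estimate on `log r` (Silverman bandwidth, scaled by
#' `bw_adjust`) transformed back to the `r` scale.
#'
#' @param data A [failure_dataset()] (single species) spanning >= 2
#'   temperatures.
#' @param tdt The [fit_tdt_regression()] fitted to the same data.
#' @param bw_adjust Bandwidth multiplier for the density estimate.
#' @return An `average_relative_curve`: pooled `r`, interpolation knots,
#'   and a density grid. Evaluate with [curve_survival()],
#'   [empirical_survival()], [curve_density()].
#' @export
build_average_relative_curve <- function(data, tdt, bw_adjust = 1) {
  data <- failure_dataset(data)
  stopifnot(inherits(tdt, "tdt_regression"))
  if (length(unique(data$temperature)) < 2) {
    stop("need >= 2 temperatures to pool a relative curve", call. = FALSE)
  }
  r <- sort(data$time / tdt_median(tdt, data$temperature))
  n <- length(r)
  if (n == 0) stop("empty pool of relative times", call. = FALSE)
  degenerate <- stats::var(r) < 1e-24
  mids <- 1 - (seq_len(n) - 0.5) / n
  if (degenerate) {
    surv_x <- c(0, r[1]); surv_y <- c(1, 0.5)
    dens <- NULL
  } else {
    surv_x <- c(0, r); surv_y <- c(1, mids)
    kd <- stats::density(log(r), bw = "nrd0", adjust = bw_adjust, n = 512)
    dens <- list(x = exp(kd$x), y = kd$y / exp(kd$x))  # f_r(r) = f_log(log r)/r
  }
  structure(list(r = r, n = n, surv_x = surv_x, surv_y = surv_y,
                 dens = dens, degenerate = degenerate),
            class = "average_relative_curve")
}

#' @export
print.average_relative_curve <- function(x, ...) {
  cat(sprintf(
    "<average_relative_curve> %d pooled relative times | r in [%.3g, %.3g]%s\n",
    x$n, min(x$r), max(x$r), if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Smoothed survival of the average relative curve
#' @param curve An [build_average_relative_curve()] result.
#' @param r Relative times (>= 0).
#' @return Survival probabilities (1 at r = 0; 0 beyond the largest pooled
#'   relative time).
#' @export
curve_survival <- function(curve, r) {
  stopifnot(inherits(curve, "average_relative_curve"))
  out <- stats::approx(curve$surv_x, curve$surv_y, xout = r, rule = 2,
                       ties = "ordered")$y
  out[r > max(curve$surv_x)] <- 0
  out
}

#' Raw empirical survival of the pooled relative times
#' @inheritParams curve_survival
#' @return Right-continuous empirical survival, `mean(pool > r)`.
#' @export
empirical_survival <- function(curve, r) {
  stopifnot(inherits(curve, "average_relative_curve"))
  vapply(r, function(ri) mean(curve$r > ri), numeric(1))
}

#' Relative failure density of the average curve
#' @inheritParams curve_survival
#' @return Kernel density of the pooled relative times (per unit r); 0
#'   outside the kernel support; error for a degenerate (point-mass) pool.
#' @export
curve_density <- function(curve, r) {
  stopifnot(inherits(curve, "average_relative_curve"))
  if (curve$degenerate) {
    stop("density undefined for a degenerate (point-mass) pool",
         call. = FALSE)
  }
  out <- stats::approx(curve$dens$x, curve$dens$y, xout = r,
                       ties = "ordered")$y
  out[is.na(out)] <- 0
  pmax(out, 0)
}

# invert a nonincreasing piecewise-linear curve at survival level s
curve_inverse <- function(curve, s) {
  y <- curve$surv_y; x <- curve$surv_x
  i <- which(y <= s)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L || y[i] == s) return(x[i])
  x[i - 1] + (y[i - 1] - s) / (y[i - 1] - y[i]) * (x[i] - x[i - 1])
}

new_survival_prediction <- function(times, survival, density, median_tf,
                                    model_label, beyond_horizon,
                                    shape_eval = NULL) {
  structure(list(times = times, survival = survival, density = density,
                 median_tf = median_tf, model_label = model_label,
                 beyond_horizon = beyond_horizon, shape_eval = shape_eval),
            class = "survival_prediction")
}

#' @export
print.survival_prediction <- function(x, ...) {
  cat(sprintf(
    "<survival_prediction> model = %s%s | median t_f = %s min | grid of %d points to %.1f min\n",
    x$model_label,
    if (!is.null(x$shape_eval)) paste0(" (shape: ", x$shape_eval, ")") else "",
    if (is.na(x$median_tf)) "beyond horizon" else sprintf("%.2f", x$median_tf),
    length(x$times), max(x$times)))
  invisible(x)
}

# central finite differences of survival on the grid, negatives clipped at 0
fd_density <- function(times, survival) {
  n <- length(times)
  d <- numeric(n)
  d[1] <- (survival[1] - survival[2]) / (times[2] - times[1])
  d[n] <- (survival[n - 1] - survival[n]) / (times[n] - times[n - 1])
  d[2:(n - 1)] <- (survival[1:(n - 2)] - survival[3:n]) /
    (times[3:n] - times[1:(n - 2)])
  pmax(d, 0)
}

#' Average-survival-curve prediction under a fluctuating profile
#'
#' The probabilistic pooled-curve model: relative time accumulates as
#' `R(t) = integral dt'/t50(T(t'))` (the same additive accumulation as the
#' deterministic model) and survival is the average relative curve
#' evaluated at the accumulated relative time, `S(t) = S_avg(R(t))`. The
#' median solves `S(t) = 0.5`; the failure density comes from central
#' finite differences of `S` on the grid.
#'
#' @param profile A [temperature_profile()].
#' @param curve An [build_average_relative_curve()] result (built from the
#'   same TDT regression).
#' @param tdt The [fit_tdt_regression()] result.
#' @param grid_step Output grid step, minutes (default 0.1).
#' @param horizon_mult Horizon multiple of the coolest-temperature median.
#' @return A `survival_prediction` with `model_label = "rezende"`.
#' @export
predict_survival_rezende <- function(profile, curve, tdt, grid_step = 0.1,
                                     horizon_mult = 10) {
  stopifnot(inherits(curve, "average_relative_curve"),
            inherits(tdt, "tdt_regression"))
  horizon <- horizon_mult * tdt_median(tdt, min(profile$temperature))
  traj <- accumulate_damage(profile, function(T) 1 / tdt_median(tdt, T),
                            t_end = horizon, grid_step = grid_step)
  times <- seq(0, horizon, by = grid_step)
  R <- damage_at(traj, times)
  S <- curve_survival(curve, R)
  r_half <- curve_inverse(curve, 0.5)
  if (is.na(r_half) || r_half > damage_at(traj, horizon)) {
    med <- NA_real_; beyond <- TRUE
  } else {
    med <- damage_first_crossing(traj, r_half); beyond <- FALSE
  }
  new_survival_prediction(times, S, fd_density(times, S), med, "rezende",
                          beyond)
}

#' Coefficients of the temperature-linked log-logistic model
#'
#' The coefficient set consumed by the increasing-variance predictor:
#' `log a(T) = beta0 + beta1 * T` (scale/median link) and
#' `log k(T) = gamma0 + gamma1 * T` (shape link; `gamma1 = 0` recovers a
#' constant shape). Usually produced from a joint fit via [as_tdt_model()].
#'
#' @param beta0 Log-scale intercept, log-minutes.
#' @param beta1 Log-scale slope, per degC (negative for heat stress).
#' @param gamma0 Log-shape intercept.
#' @param gamma1 Log-shape slope, per degC.
#' @param temp_range Optional fitted temperature range, degC; predictions
#'   outside it warn about extrapolation.
#' @return A `tdt_model`.
#' @export
tdt_model <- function(beta0, beta1, gamma0, gamma1 = 0, temp_range = NULL) {
  stopifnot(is.finite(beta0), is.finite(beta1), is.finite(gamma0),
            is.finite(gamma1))
  structure(list(beta0 = beta0, beta1 = beta1, gamma0 = gamma0,
                 gamma1 = gamma1, temp_range = temp_range),
            class = "tdt_model")
}

#' @export
print.tdt_model <- function(x, ...) {
  cat(sprintf(
    "<tdt_model> log a(T) = %.3f %+.4f T | log k(T) = %.3f %+.4f T\n",
    x$beta0, x$beta1, x$gamma0, x$gamma1))
  invisible(x)
}

#' Scale (median) of the temperature-linked log-logistic at temperature T
#' @param model A [tdt_model()].
#' @param temperature Temperature(s), degC.
#' @return Scale a(T), minutes.
#' @export
model_scale <- function(model, temperature) {
  stopifnot(inherits(model, "tdt_model"))
  exp(model$beta0 + model$beta1 * temperature)
}

#' Shape of the temperature-linked log-logistic at temperature T
#' @inheritParams model_scale
#' @return Shape k(T), dimensionless.
#' @export
model_shape <- function(model, temperature) {
  stopifnot(inherits(model, "tdt_model"))
  exp(model$gamma0 + model$gamma1 * temperature)
}

check_extrapolation <- function(model, profile) {
  if (is.null(model$temp_range)) return(invisible())
  lo <- min(profile$temperature); hi <- max(profile$temperature)
  d <- max(model$temp_range[1] - lo, hi - model$temp_range[2], 0)
  if (d > 0) {
    warning(sprintf(
      "profile extends %.1f degC beyond the fitted temperature range [%.1f, %.1f]; the log-linear links are extrapolated",
      d, model$temp_range[1], model$temp_range[2]), call. = FALSE)
  }
  invisible()
}

#' Increasing-variance log-logistic prediction under a fluctuating profile
#'
#' The parametric dynamic model: scaled damage accumulates as
#' `D_a(t) = integral dt'/a(T(t'))` and cumulative survival is
#' \deqn{S(t) = (1 + D_a(t)^{k(T(t))})^{-1},}
#' with the shape evaluated at the instantaneous temperature (default), so
#' both the position and the shape of the survival curve track temperature.
#' At constant temperature this reduces exactly to the static log-logistic
#' survival with parameters `(a(T), k(T))`. Alternative shape evaluations —
#' the duration-weighted mean shape up to `t`, or the shape frozen at the
#' profile's dominant (longest-duration) temperature — are available and
#' recorded in the output.
#'
#' @param profile A [temperature_profile()].
#' @param model A [tdt_model()].
#' @param grid_step Output grid step, minutes (default 0.1).
#' @param horizon_mult Horizon multiple of the coolest-temperature median.
#' @param shape_eval `"instantaneous"`, `"duration-weighted"`, or
#'   `"frozen"`.
#' @return A `survival_prediction` with
#'   `model_label = "increasing_variance"`; the median is found by
#'   bisection to 1e-6 min.
#' @export
predict_survival_increasing_variance <- function(profile, model,
                                                 grid_step = 0.1,
                                                 horizon_mult = 10,
                                                 shape_eval = c(
                                                   "instantaneous",
                                                   "duration-weighted",
                                                   "frozen")) {
  stopifnot(inherits(profile, "temperature_profile"),
            inherits(model, "tdt_model"))
  shape_eval <- match.arg(shape_eval)
  check_extrapolation(model, profile)
  horizon <- horizon_mult * model_scale(model, min(profile$temperature))
  traj <- accumulate_damage(profile, function(T) 1 / model_scale(model, T),
                            t_end = horizon, grid_step = grid_step)
  k_fun <- switch(shape_eval,
    instantaneous = function(t) {
      model_shape(model, profile_temperature(profile, t))
    },
    "duration-weighted" = {
      ktraj <- accumulate_damage(profile,
                                 function(T) model_shape(model, T),
                                 t_end = horizon, grid_step = grid_step)
      function(t) ifelse(t > 0, damage_at(ktraj, t) / t,
                         model_shape(model, profile_temperature(profile, 0)))
    },
    frozen = {
      k0 <- model_shape(model, dominant_temperature(profile, horizon))
      function(t) rep(k0, length(t))
    })
  S_fun <- function(t) {
    D <- damage_at(traj, t)
    1 / (1 + D^k_fun(t))
  }
  times <- seq(0, horizon, by = grid_step)
  S <- S_fun(times)
  med <- bisect_median(S_fun, times, S)
  new_survival_prediction(times, S, fd_density(times, S),
                          med$median, "increasing_variance",
                          med$beyond_horizon, shape_eval = shape_eval)
}

# longest-duration temperature of a stepwise profile over [0, horizon]
dominant_temperature <- function(profile, horizon) {
  times <- c(profile$time[profile$time < horizon], horizon)
  temps <- profile$temperature[profile$time < horizon]
  dur <- tapply(diff(times), temps, sum)
  as.numeric(names(dur)[which.max(dur)])
}

# first crossing of S(t) = 0.5: bracket on the grid, then bisection
bisect_median <- function(S_fun, times, S_grid, tol = 1e-6) {
  i <- which(S_grid <= 0.5)[1]
  if (is.na(i)) return(list(median = NA_real_, beyond_horizon = TRUE))
  if (S_grid[i] == 0.5) return(list(median = times[i],
                                    beyond_horizon = FALSE))
  if (i == 1L) return(list(median = times[1], beyond_horizon = FALSE))
  lo <- times[i - 1]; hi <- times[i]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (S_fun(mid) > 0.5) lo <- mid else hi <- mid
  }
  list(median = (lo + hi) / 2, beyond_horizon = FALSE)
}

#' Log-likelihood of observed failure times under a predicted curve
#'
#' Sum over individuals of the log predicted failure density at their
#' observed failure time. Densities are interpolated linearly on the
#' prediction grid and floored at `eps` (per minute) so the sum stays
#' finite where the numerical density vanishes; the number of floored
#' observations is reported as attribute `n_floored`.
#'
#' @param prediction A `survival_prediction`.
#' @param observed_times Observed failure times, minutes, within the
#'   prediction grid's span.
#' @param eps Density floor (default 1e-12 per minute).
#' @return The log-likelihood (scalar) with attribute `n_floored`.
#' @export
profile_log_likelihood <- function(prediction, observed_times, eps = 1e-12) {
  stopifnot(inherits(prediction, "survival_prediction"))
  if (length(observed_times) == 0) {
    return(structure(0, n_floored = 0L))
  }
  if (any(observed_times < 0)) {
    stop("observed times must be nonnegative", call. = FALSE)
  }
  if (any(observed_times > max(prediction$times))) {
    stop("observed time beyond the prediction grid; rerun the prediction ",
         "with a larger `horizon_mult`", call. = FALSE)
  }
  d <- stats::approx(prediction$times, prediction$density,
                     xout = observed_times, ties = "ordered")$y
  n_floored <- sum(d < eps)
  structure(sum(log(pmax(d, eps))), n_floored = n_floored)
}
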