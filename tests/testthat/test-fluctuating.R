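# Damage accumulation and the three fluctuating-temperature predictors.

test_that("damage accumulates linearly, piecewise, and order-free", {
  # constant temperature, rate 1/100 per min
  p <- temperature_profile(0, 38)
  traj <- accumulate_damage(p, function(T) rep(1 / 100, length(T)), 300)
  expect_equal(damage_at(traj, 250), 2.5)
  expect_equal(damage_at(traj, 0), 0)
  # stepwise: 60 min at rate 1/120, then 1/60
  rate <- function(T) ifelse(T < 38, 1 / 120, 1 / 60)
  p2 <- temperature_profile(c(0, 60), c(36, 39))
  tr2 <- accumulate_damage(p2, rate, 200)
  expect_equal(damage_at(tr2, 60), 0.5)
  expect_equal(damage_at(tr2, 90), 1.0)
  # permuting segments leaves total damage unchanged
  p3 <- temperature_profile(c(0, 140), c(39, 36))
  tr3 <- accumulate_damage(p3, rate, 200)
  expect_equal(damage_at(tr2, 200), damage_at(tr3, 200))
  # damage is nondecreasing and zero at the origin
  tt <- seq(0, 200, by = 0.5)
  expect_true(all(diff(damage_at(tr2, tt)) >= 0))
  expect_error(accumulate_damage(p2, function(T) rep(-1, length(T)), 100),
               "nonpositive rate")
})

test_that("stepwise closed-form damage equals the trapezoid computation", {
  rate <- function(T) 1 / exp(20 - 0.45 * T)
  pstep <- temperature_profile(c(0, 45, 100), c(36, 40, 37))
  # same knots expressed as a (piecewise-constant-by-construction) linear
  # profile sampled densely
  tt <- sort(unique(c(seq(0, 150, by = 0.01), 45 - 1e-9, 100 - 1e-9)))
  plin <- temperature_profile(tt, profile_temperature(pstep, tt),
                              interpolation = "linear")
  tr_exact <- accumulate_damage(pstep, rate, 150)
  tr_grid <- accumulate_damage(plin, rate, 150, grid_step = 0.01)
  at <- c(10, 45, 80, 120, 150)
  expect_equal(damage_at(tr_grid, at), damage_at(tr_exact, at),
               tolerance = 1e-6)
})

test_that("additive-damage median prediction reduces to the static median", {
  tdt <- exact_tdt(intercept = 20, slope = -0.45)
  p <- temperature_profile(0, 38)
  expect_equal(as.numeric(predict_median_jorgensen(p, tdt)),
               tdt_median(tdt, 38), tolerance = 1e-6)
  # two-step profile with t50 = 120 then 60: damage 0.5 + (t-60)/60 = 1 at 90
  tdt2 <- exact_tdt(intercept = log(120), slope = -log(2))
  p2 <- temperature_profile(c(0, 60), c(0, 1))
  expect_equal(as.numeric(predict_median_jorgensen(p2, tdt2)), 90,
               tolerance = 1e-9)
  # time-reversal with the median at a segment boundary
  p_rev <- temperature_profile(c(0, 30), c(1, 0))
  # 30 min at rate 1/60 -> D = 0.5; then rate 1/120 -> +60 min = 90 total
  expect_equal(as.numeric(predict_median_jorgensen(p_rev, tdt2)), 90,
               tolerance = 1e-9)
  # damage never reaching 1 within the horizon is flagged
  slow <- exact_tdt(intercept = log(1e5), slope = 0)
  out <- predict_median_jorgensen(temperature_profile(0, 38), slow,
                                  horizon_mult = 0.5)
  expect_true(is.na(out))
  expect_true(attr(out, "beyond_horizon"))
})

test_that("average relative curve pools rescaled times correctly", {
  tdt <- exact_tdt(intercept = 20, slope = -0.45)
  # craft data whose relative times are exactly {0.5, 1, 2}
  temps <- c(36, 38, 40)
  times <- c(0.5, 1, 2) * tdt_median(tdt, temps)
  d <- failure_dataset(data.frame(species = "s", temperature = temps,
                                  time = times, trial_id = "t"))
  curve <- build_average_relative_curve(d, tdt)
  expect_equal(empirical_survival(curve, 1.0 + 1e-12), 1 / 3)
  expect_equal(empirical_survival(curve, 0.4), 1)
  expect_equal(empirical_survival(curve, 2.5), 0)
  # smoothed curve: 1 at 0, nonincreasing, 0 beyond the pool
  r <- seq(0, 3, by = 0.01)
  s <- curve_survival(curve, r)
  expect_equal(s[1], 1)
  expect_true(all(diff(s) <= 0))
  expect_equal(curve_survival(curve, 2.4), 0)
  # degenerate pool: every time equals its predicted median
  d2 <- failure_dataset(data.frame(species = "s", temperature = temps,
                                   time = tdt_median(tdt, temps),
                                   trial_id = "t"))
  c2 <- build_average_relative_curve(d2, tdt)
  expect_true(c2$degenerate)
  expect_equal(curve_survival(c2, 0.99), 1 - 0.5 * 0.99)
  expect_equal(curve_survival(c2, 1.01), 0)
  expect_error(curve_density(c2, 1), "degenerate")
})

test_that("pooled curve approaches the true relative survival law", {
  # constant-shape log-logistic: relative time r = t / a(T) has survival
  # (1 + r^k)^(-1) at every temperature, so the pooled curve estimates it
  k <- 3
  temps <- seq(34, 40, 1.5)
  n_per <- 400   # 2000 total
  rows <- lapply(seq_along(temps), function(i) {
    a <- exp(35 - 0.85 * temps[i])
    data.frame(species = "s", temperature = temps[i],
               time = sample_failure_times(n_per, a, k, seed = 500 + i),
               trial_id = "t")
  })
  d <- failure_dataset(do.call(rbind, rows))
  tdt <- fit_tdt_regression(d)
  curve <- build_average_relative_curve(d, tdt)
  r <- seq(0.05, 6, by = 0.05)
  expect_lt(max(abs(curve_survival(curve, r) - 1 / (1 + r^k))), 0.05)
})

test_that("average-curve prediction composes accumulation with the curve", {
  tdt <- exact_tdt(intercept = 20, slope = -0.45)
  temps <- c(36, 38, 40)
  times <- c(0.5, 1, 2) * tdt_median(tdt, temps)
  d <- failure_dataset(data.frame(species = "s", temperature = temps,
                                  time = times, trial_id = "t"))
  curve <- build_average_relative_curve(d, tdt)
  # constant temperature: S(t) is the curve stretched by t50(T)
  p <- temperature_profile(0, 39)
  pred <- predict_survival_rezende(p, curve, tdt, grid_step = 0.05)
  t50 <- tdt_median(tdt, 39)
  expect_equal(pred$survival,
               curve_survival(curve, pred$times / t50), tolerance = 1e-9)
  expect_equal(pred$survival[1], 1)
  expect_true(all(diff(pred$survival) <= 1e-12))
  expect_true(all(pred$density >= 0))
  # degenerate curve: median coincides with the additive-damage median
  d2 <- failure_dataset(data.frame(species = "s", temperature = temps,
                                   time = tdt_median(tdt, temps),
                                   trial_id = "t"))
  c2 <- build_average_relative_curve(d2, tdt)
  p2 <- temperature_profile(c(0, 30), c(37, 39.5))
  prz <- predict_survival_rezende(p2, c2, tdt, grid_step = 0.01)
  pj <- predict_median_jorgensen(p2, tdt)
  expect_equal(prz$median_tf, as.numeric(pj), tolerance = 0.02)
})

test_that("increasing-variance prediction reduces to the static law at constant T", {
  m <- truth_model()
  for (T in c(35, 37.5, 40)) {
    p <- temperature_profile(0, T)
    pred <- predict_survival_increasing_variance(p, m)
    expect_lt(max(abs(pred$survival -
                        llogis_survival(pred$times, model_scale(m, T),
                                        model_shape(m, T)))), 1e-9)
    expect_equal(pred$median_tf, model_scale(m, T), tolerance = 1e-5)
    expect_equal(pred$model_label, "increasing_variance")
  }
})

test_that("increasing-variance stepwise prediction matches a fine-grid oracle", {
  # constant shape (gamma1 = 0): S(t) = (1 + D_a(t)^k)^(-1) with damage
  # integrated by brute force on a 1e-3-minute grid
  m <- tdt_model(truth_pars$beta0, truth_pars$beta1, log(2.5), 0)
  p <- temperature_profile(c(0, 20, 50), c(39, 36, 40))
  pred <- predict_survival_increasing_variance(p, m, grid_step = 0.1)
  h <- 1e-3
  tt <- seq(0, max(pred$times), by = h)
  D <- cumsum(c(0, h / model_scale(m, profile_temperature(p, tt[-length(tt)]))))
  S_oracle <- 1 / (1 + D^2.5)
  idx <- match(round(pred$times, 6), round(tt, 6))
  expect_lt(max(abs(pred$survival - S_oracle[idx]), na.rm = TRUE), 1e-6)
  expect_equal(pred$survival[1], 1)
  # grid refinement below 0.1 min leaves the curve unchanged
  fine <- predict_survival_increasing_variance(p, m, grid_step = 0.02)
  idx2 <- match(round(pred$times, 6), round(fine$times, 6))
  expect_lt(max(abs(pred$survival - fine$survival[idx2])), 1e-4)
  expect_lt(abs(pred$median_tf - fine$median_tf), 1e-4)
})

test_that("nonincreasing survival within constant-shape segments", {
  m <- truth_model()
  p <- temperature_profile(c(0, 15, 40), c(40, 36, 39))
  pred <- predict_survival_increasing_variance(p, m)
  seg <- findInterval(pred$times, c(0, 15, 40))
  for (s in unique(seg)) {
    expect_true(all(diff(pred$survival[seg == s]) <= 1e-12))
  }
})

test_that("all three predictors agree at constant temperature", {
  d <- generate_static_dataset(temperatures = seq(34, 40, 1.5),
                               n_per_cell = 100, seed = 71)
  tdt <- fit_tdt_regression(d)
  curve <- build_average_relative_curve(d, tdt)
  aft <- fit_aft_model(d, "loglogistic", shape_link = "loglinear")
  m <- as_tdt_model(aft)
  p <- temperature_profile(0, 37)
  med_j <- as.numeric(predict_median_jorgensen(p, tdt))
  med_r <- predict_survival_rezende(p, curve, tdt, grid_step = 0.02)$median_tf
  med_iv <- predict_survival_increasing_variance(p, m,
                                                 grid_step = 0.02)$median_tf
  expect_equal(med_j, tdt_median(tdt, 37), tolerance = 1e-6)
  # rezende and jorgensen share the t50 rescaling; the pooled curve's
  # median relative time is near 1 up to sampling noise
  expect_lt(abs(med_r - med_j) / med_j, 0.1)
  # increasing-variance median is exp(beta0 + beta1 T) from the joint fit,
  # close to the TDT-regression median
  expect_lt(abs(med_iv - med_j) / med_j, 0.1)
})

test_that("dynamic log-likelihood matches the analytic constant-T density", {
  m <- truth_model()
  T <- 38
  a <- model_scale(m, T); k <- model_shape(m, T)
  p <- temperature_profile(0, T)
  pred <- predict_survival_increasing_variance(p, m, grid_step = 0.01)
  ll <- profile_log_likelihood(pred, a)
  expect_equal(as.numeric(ll), log(k / (4 * a)), tolerance = 1e-4)
  expect_identical(attr(ll, "n_floored"), 0L)
  # additivity over individuals
  obs <- c(a / 2, a, 2 * a)
  expect_equal(as.numeric(profile_log_likelihood(pred, c(obs, obs))),
               2 * as.numeric(profile_log_likelihood(pred, obs)),
               tolerance = 1e-12)
  expect_error(profile_log_likelihood(pred, max(pred$times) + 1),
               "horizon")
})

test_that("alternative shape evaluations are offered and recorded", {
  m <- truth_model()
  p <- temperature_profile(c(0, 30), c(36, 40))
  for (ev in c("instantaneous", "duration-weighted", "frozen")) {
    pred <- predict_survival_increasing_variance(p, m, shape_eval = ev)
    expect_equal(pred$shape_eval, ev)
    expect_equal(pred$survival[1], 1)
  }
  # at constant temperature all evaluations coincide
  pc <- temperature_profile(0, 38)
  s1 <- predict_survival_increasing_variance(pc, m,
                                             shape_eval = "instantaneous")
  s2 <- predict_survival_increasing_variance(pc, m, shape_eval = "frozen")
  expect_equal(s1$survival, s2$survival, tolerance = 1e-12)
})

test_that("extrapolation beyond the fitted temperature range warns", {
  m <- truth_model()
  m$temp_range <- c(34, 40)
  expect_warning(
    predict_survival_increasing_variance(temperature_profile(0, 42), m),
    "extrapolat")
  expect_silent(
    predict_survival_increasing_variance(temperature_profile(0, 38), m))
})
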