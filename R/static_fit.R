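# Maximum-likelihood fitting of failure-time models to constant-temperature
# assay data: per-cell log-logistic fits, the TDT regression, joint AFT fits
# with temperature-linked scale and (optionally) shape, AIC family ranking,
# and diagnostics for the TDT assumptions.

log1pexp <- function(w) ifelse(w > 0, w + log1p(exp(-w)), log1p(exp(w)))

# Stable log-logistic log density in terms of log(t), log(a), log(k).
# logf = log k - log a + (k - 1)(log t - log a) - 2 log(1 + exp(k (log t - log a)))
llogis_logdens_stable <- function(log_t, log_a, log_k) {
  k <- exp(log_k)
  u <- log_t - log_a
  log_k - log_a + (k - 1) * u - 2 * log1pexp(k * u)
}

#' Fit a log-logistic model to one assay cell
#'
#' Maximum-likelihood estimate of the log-logistic scale and shape for the
#' failure times of a single species x temperature cell. Optimization is on
#' unconstrained coordinates (log scale, log shape) by quasi-Newton search
#' with three starting points (moment-based, median-based, and a perturbed
#' start) to guard against local optima; standard errors come from the
#' observed information at the optimum.
#'
#' @param times Positive failure times, minutes; at least 2 distinct values.
#' @param species,temperature Optional labels carried into the result.
#' @return A `cell_fit` list: `scale_hat`, `shape_hat`, `log_scale_se`,
#'   `shape_se`, `loglik`, `n`, `converged`, plus the labels.
#' @export
fit_cell <- function(times, species = NA_character_, temperature = NA_real_) {
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("failure times must be positive and finite", call. = FALSE)
  }
  if (length(unique(times)) < 2) {
    stop("need >= 2 distinct failure times (identical times imply ",
         "shape -> Inf)", call. = FALSE)
  }
  lt <- log(times)
  v <- stats::var(lt)
  k0 <- shape_from_var_log(v)
  a0 <- stats::median(times)
  nll <- function(par) -sum(llogis_logdens_stable(lt, par[1], par[2]))
  starts <- list(c(log(a0), log(k0)),
                 c(log(a0), log(max(k0 / 2, 0.25))),
                 c(mean(lt), log(k0) + 0.5))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("cell fit failed from every start", call. = FALSE)
  H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  se <- c(NA_real_, NA_real_)
  ok_hess <- FALSE
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) {
      se <- sqrt(diag(V))
      ok_hess <- TRUE
    }
  }
  scale_hat <- exp(best$par[1])
  shape_hat <- exp(best$par[2])
  structure(list(
    species = species, temperature = temperature,
    n = length(times),
    scale_hat = scale_hat, shape_hat = shape_hat,
    log_scale_se = se[1],
    shape_se = se[2] * shape_hat,   # delta method from log shape
    loglik = -best$value,
    converged = best$convergence == 0 && ok_hess
  ), class = "cell_fit")
}

#' @export
print.cell_fit <- function(x, ...) {
  cat(sprintf(
    "<cell_fit> %s @ %.1f degC | n = %d | scale = %.3g (median, min) | shape = %.3g | loglik = %.2f%s\n",
    x$species, x$temperature, x$n, x$scale_hat, x$shape_hat, x$loglik,
    if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Per-cell log-logistic fits over a whole dataset
#'
#' Runs [fit_cell()] independently on every species x temperature cell.
#' Cells that fail to fit are flagged, never dropped silently.
#'
#' @param data A [failure_dataset()].
#' @return Data frame with one row per cell: `species`, `temperature`, `n`,
#'   `scale_hat`, `shape_hat`, `log_scale_se`, `shape_se`, `loglik`,
#'   `converged`.
#' @export
fit_cells <- function(data) {
  data <- failure_dataset(data)
  cells <- unique(data[, c("species", "temperature")])
  cells <- cells[order(cells$species, cells$temperature), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- data$time[data$species == cells$species[i] &
                       data$temperature == cells$temperature[i]]
    f <- tryCatch(fit_cell(sub, cells$species[i], cells$temperature[i]),
                  error = function(e) NULL)
    if (is.null(f)) {
      data.frame(species = cells$species[i],
                 temperature = cells$temperature[i], n = length(sub),
                 scale_hat = NA_real_, shape_hat = NA_real_,
                 log_scale_se = NA_real_, shape_se = NA_real_,
                 loglik = NA_real_, converged = FALSE)
    } else {
      data.frame(species = f$species, temperature = f$temperature, n = f$n,
                 scale_hat = f$scale_hat, shape_hat = f$shape_hat,
                 log_scale_se = f$log_scale_se, shape_se = f$shape_se,
                 loglik = f$loglik, converged = f$converged)
    }
  })
  do.call(rbind, rows)
}

#' Thermal death time (TDT) regression
#'
#' Ordinary least squares of log median failure time on temperature:
#' `log(t50) = intercept + slope * T`, the classical linear TDT relation
#' (natural logs; temperatures in degrees Celsius as given, no recentering).
#' Residuals are returned for the linearity diagnostic.
#'
#' @param x Either a [failure_dataset()] containing a single species, or a
#'   data frame with columns `temperature` and `median_time` (minutes), e.g.
#'   from [cell_medians()].
#' @return A `tdt_regression`: `slope` (per degC), `intercept`
#'   (log-minutes), `r_squared`, `residuals`, and the per-temperature table.
#' @export
fit_tdt_regression <- function(x) {
  if (inherits(x, "failure_dataset")) {
    sp <- unique(x$species)
    if (length(sp) > 1) {
      stop("dataset spans multiple species (", paste(sp, collapse = ", "),
           "); fit one species at a time", call. = FALSE)
    }
    x <- cell_medians(x)
  }
  x <- as.data.frame(x)
  if (!all(c("temperature", "median_time") %in% names(x))) {
    stop("need columns `temperature` and `median_time`", call. = FALSE)
  }
  if (length(unique(x$temperature)) < 2) {
    stop("need >= 2 distinct temperatures", call. = FALSE)
  }
  fit <- stats::lm(log(median_time) ~ temperature, data = x)
  res <- unname(stats::residuals(fit))
  y <- log(x$median_time)
  structure(list(
    slope = unname(stats::coef(fit)["temperature"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
    residuals = res,
    table = x
  ), class = "tdt_regression")
}

#' @export
print.tdt_regression <- function(x, ...) {
  cat(sprintf(
    "<tdt_regression> log(t50) = %.3f %+.4f * T | R^2 = %.4f | %d temperatures\n",
    x$intercept, x$slope, x$r_squared, nrow(x$table)))
  invisible(x)
}

#' Median failure time predicted by a TDT regression
#' @param tdt A [fit_tdt_regression()] result.
#' @param temperature Temperature(s), degC.
#' @return Predicted median failure time(s) t50, minutes.
#' @export
tdt_median <- function(tdt, temperature) {
  stopifnot(inherits(tdt, "tdt_regression"))
  exp(tdt$intercept + tdt$slope * temperature)
}

# ---- joint temperature-linked AFT fitting -------------------------------

# Family parameterization with a location linear predictor loc = b0 + b1*T
# (species-specific b0 when requested) and an optional shape linear
# predictor. For positive shape parameters the link is log (guarantees
# positivity); a linear (identity) link is available for sensitivity
# analysis. The Gompertz shape is real-valued, so its link is always
# identity.
aft_family_info <- function(family) {
  switch(family,
    exponential = list(n_shape = 0L),
    weibull     = list(n_shape = 1L, shape_positive = TRUE),
    loglogistic = list(n_shape = 1L, shape_positive = TRUE),
    lognormal   = list(n_shape = 1L, shape_positive = TRUE),
    gompertz    = list(n_shape = 1L, shape_positive = FALSE),
    stop("unknown family: ", family, call. = FALSE))
}

# Negative log-likelihood for the joint fit. par packs:
#   b0 (one per species level), b1, then shape coefs (g0 [per species if
#   species_shape_intercepts], optionally g1).
aft_nll_factory <- function(lt, temp, sp_idx, n_sp, family, shape_link,
                            shape_transform, species_shape_intercepts) {
  info <- aft_family_info(family)
  t_raw <- exp(lt)
  function(par) {
    b0 <- par[seq_len(n_sp)]
    b1 <- par[n_sp + 1L]
    loc <- b0[sp_idx] + b1 * temp
    if (info$n_shape == 1L) {
      off <- n_sp + 1L
      n_g0 <- if (species_shape_intercepts) n_sp else 1L
      g0 <- par[off + seq_len(n_g0)]
      g0v <- if (species_shape_intercepts) g0[sp_idx] else g0
      eta <- if (shape_link == "loglinear") {
        g0v + par[off + n_g0 + 1L] * temp
      } else g0v + 0 * temp
    }
    ll <- switch(family,
      loglogistic = {
        log_k <- shape_eta_to_log(eta, shape_transform, positive = TRUE)
        if (anyNA(log_k)) return(1e10)
        llogis_logdens_stable(lt, loc, log_k)
      },
      weibull = {
        log_k <- shape_eta_to_log(eta, shape_transform, positive = TRUE)
        if (anyNA(log_k)) return(1e10)
        k <- exp(log_k)
        u <- lt - loc
        log_k - loc + (k - 1) * u - exp(pmin(k * u, 700))
      },
      lognormal = {
        log_s <- shape_eta_to_log(eta, shape_transform, positive = TRUE)
        if (anyNA(log_s)) return(1e10)
        stats::dnorm(lt, mean = loc, sd = exp(log_s), log = TRUE) - lt
      },
      exponential = {
        # mean failure time exp(loc); rate = exp(-loc)
        -loc - t_raw * exp(-loc)
      },
      gompertz = {
        # rate = exp(-loc), shape real = eta (identity link)
        rate <- exp(-loc)
        b <- eta
        ifelse(abs(b) < 1e-12,
               log(rate) - rate * t_raw,
               log(rate) + b * t_raw - (rate / b) * (exp(pmin(b * t_raw, 700)) - 1))
      })
    val <- -sum(ll)
    if (!is.finite(val)) 1e10 else val
  }
}

shape_eta_to_log <- function(eta, shape_transform, positive) {
  if (!positive) return(eta)
  if (shape_transform == "log") eta
  else ifelse(eta > 0, log(eta), NA_real_)   # identity link: eta is the shape
}

#' Joint accelerated-failure-time fit with temperature-linked parameters
#'
#' Fits one parametric failure-time family to all records jointly, with the
#' location parameter linear in assay temperature (for scale-type families,
#' `log scale = beta0 + beta1 * T`; for the lognormal, `meanlog` itself is
#' linear; for the exponential and Gompertz the rate is `exp(-(beta0 +
#' beta1 * T))`). The shape parameter is either constant or linked to
#' temperature: by default `log shape = gamma0 + gamma1 * T`, which keeps
#' the shape positive; an identity link (`shape = gamma0 + gamma1 * T`) is
#' available via `shape_transform = "identity"` for sensitivity analysis.
#' The Gompertz shape is real-valued and always uses the identity link.
#'
#' Optimization is quasi-Newton on unconstrained coordinates with
#' multi-start (OLS/moment-based start plus perturbations, and any
#' user-supplied extra starts); standard errors from the observed
#' information.
#'
#' @param data A [failure_dataset()] spanning >= 2 temperatures.
#' @param family One of `"exponential"`, `"weibull"`, `"loglogistic"`,
#'   `"lognormal"`, `"gompertz"`.
#' @param shape_link `"constant"` or `"loglinear"` (shape linked to
#'   temperature). The exponential has no shape parameter and admits no
#'   link.
#' @param shape_transform `"log"` (default) or `"identity"`; how the shape
#'   linear predictor maps to the shape parameter (ignored for Gompertz).
#' @param intercepts `"common"` (one location intercept) or `"species"`
#'   (one location and one shape intercept per species, shared slopes).
#' @param extra_starts Optional list of full parameter vectors to add to
#'   the start set.
#' @return An `aft_fit`: `family`, `shape_link`, `coefficients` (named:
#'   `beta0[.species]`, `beta1`, `gamma0[.species]`, `gamma1` as present),
#'   `se`, `vcov`, `loglik`, `aic`, `n`, `n_params`, `converged`.
#' @export
fit_aft_model <- function(data, family = "loglogistic",
                          shape_link = c("constant", "loglinear"),
                          shape_transform = c("log", "identity"),
                          intercepts = c("common", "species"),
                          extra_starts = NULL) {
  data <- failure_dataset(data)
  family <- match.arg(family, .tdt_families)
  shape_link <- match.arg(shape_link)
  shape_transform <- match.arg(shape_transform)
  intercepts <- match.arg(intercepts)
  info <- aft_family_info(family)
  if (family == "exponential" && shape_link == "loglinear") {
    stop("the exponential family has no shape parameter to link",
         call. = FALSE)
  }
  if (length(unique(data$temperature)) < 2) {
    stop("need >= 2 distinct temperatures", call. = FALSE)
  }
  sp_levels <- sort(unique(data$species))
  if (intercepts == "common") {
    sp_idx <- rep(1L, nrow(data)); n_sp <- 1L
  } else {
    sp_idx <- match(data$species, sp_levels); n_sp <- length(sp_levels)
  }
  species_shape_int <- intercepts == "species" && info$n_shape == 1L
  lt <- log(data$time)
  # optimize with the temperature centered (intercepts and slopes are
  # nearly collinear on the raw degC scale and defeat quasi-Newton
  # search); coefficients and covariance are transformed back to the
  # as-given degC parameterization afterwards
  t_center <- mean(range(data$temperature))
  temp <- data$temperature - t_center

  # start values: per-species OLS of log time on temperature for the
  # location; pooled residual moments for the shape
  b0_start <- numeric(n_sp); b1s <- numeric(n_sp)
  for (s in seq_len(n_sp)) {
    sel <- sp_idx == s
    cf <- stats::coef(stats::lm(lt[sel] ~ temp[sel]))
    b0_start[s] <- cf[1]; b1s[s] <- cf[2]
  }
  b1_start <- mean(b1s)
  resid <- lt - (b0_start[sp_idx] + b1_start * temp)
  v <- max(stats::var(resid), 1e-6)
  g0_start <- switch(family,
    loglogistic = log(shape_from_var_log(v)),
    weibull = log(1.2 / sqrt(v)),          # var[log t] ~ (pi^2/6)/k^2
    lognormal = 0.5 * log(v),
    gompertz = 0,
    NULL)
  if (family == "gompertz") b0_start <- b0_start  # mean-time location
  if (!is.null(g0_start) && shape_transform == "identity" &&
      info$shape_positive) {
    g0_start <- exp(g0_start)
  }
  base <- c(b0_start, b1_start)
  if (info$n_shape == 1L) {
    base <- c(base, rep(g0_start, if (species_shape_int) n_sp else 1L))
    if (shape_link == "loglinear") base <- c(base, 0)
  }
  # linear map between the centered fitting parameterization and the
  # as-given degC parameterization: beta0 = beta0c - c * beta1 (and
  # likewise for the shape intercepts when the shape is linked)
  p_len <- length(base)
  n_g0 <- if (info$n_shape == 1L) (if (species_shape_int) n_sp else 1L) else 0L
  A <- diag(p_len)
  A[seq_len(n_sp), n_sp + 1L] <- -t_center
  if (info$n_shape == 1L && shape_link == "loglinear") {
    A[n_sp + 1L + seq_len(n_g0), p_len] <- -t_center
  }
  to_centered <- solve(A)
  starts <- list(base, base + 0.2, base - 0.2)
  if (info$n_shape == 1L && shape_link == "loglinear") {
    for (g1 in c(-0.1, 0.1)) {
      s <- base; s[p_len] <- g1; starts <- c(starts, list(s))
    }
  }
  if (!is.null(extra_starts)) {
    starts <- c(starts, lapply(extra_starts,
                               function(s) drop(to_centered %*% s)))
  }

  nll <- aft_nll_factory(lt, temp, sp_idx, n_sp, family, shape_link,
                         shape_transform, species_shape_int)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, nll, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || best$value >= 1e10) {
    stop("AFT fit failed to converge for family `", family, "`",
         call. = FALSE)
  }
  par_c <- best$par
  nm_b0 <- if (n_sp == 1L) "beta0" else paste0("beta0.", sp_levels)
  nms <- c(nm_b0, "beta1")
  if (info$n_shape == 1L) {
    nm_g0 <- if (species_shape_int) paste0("gamma0.", sp_levels) else "gamma0"
    nms <- c(nms, nm_g0)
    if (shape_link == "loglinear") nms <- c(nms, "gamma1")
  }
  par <- drop(A %*% par_c)
  names(par) <- nms
  H <- tryCatch(stats::optimHess(par_c, nll), error = function(e) NULL)
  V <- NULL; se <- rep(NA_real_, length(par)); names(se) <- nms
  if (!is.null(H)) {
    Vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vc) && all(diag(Vc) > 0)) {
      V <- A %*% Vc %*% t(A)
      se <- sqrt(diag(V)); names(se) <- nms
      dimnames(V) <- list(nms, nms)
    }
  }
  p <- length(par)
  structure(list(
    family = family, shape_link = shape_link,
    shape_transform = shape_transform, intercepts = intercepts,
    coefficients = par, se = se, vcov = V,
    loglik = -best$value, aic = 2 * p + 2 * best$value,
    n = nrow(data), n_params = p,
    converged = best$convergence == 0
  ), class = "aft_fit")
}

#' @export
print.aft_fit <- function(x, ...) {
  cat(sprintf("<aft_fit> family = %s | shape_link = %s | n = %d | loglik = %.2f | AIC = %.2f%s\n",
              x$family, x$shape_link, x$n, x$loglik, x$aic,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Extract a fluctuating-temperature model from an AFT fit
#'
#' Converts a log-logistic [fit_aft_model()] result into the coefficient set
#' the dynamic predictors consume (see [tdt_model()]). Requires a common
#' intercept fit.
#'
#' @param fit A log-logistic `aft_fit`.
#' @return A [tdt_model()].
#' @export
as_tdt_model <- function(fit) {
  stopifnot(inherits(fit, "aft_fit"))
  if (fit$family != "loglogistic") {
    stop("dynamic predictors require a log-logistic fit", call. = FALSE)
  }
  if (fit$intercepts != "common") {
    stop("use a common-intercept fit for prediction", call. = FALSE)
  }
  cf <- fit$coefficients
  tdt_model(beta0 = cf[["beta0"]], beta1 = cf[["beta1"]],
            gamma0 = cf[["gamma0"]],
            gamma1 = if ("gamma1" %in% names(cf)) cf[["gamma1"]] else 0)
}

#' Rank the five candidate families by AIC
#'
#' Fits all five families with the location parameter linear in temperature
#' and a constant shape (the exponential has no shape), and ranks them from
#' lowest AIC (rank 1, best) to highest. AIC ties within 1e-9 are broken by
#' fewer parameters, then by family name. Families that fail to converge
#' are flagged and excluded from the ranking, never dropped silently.
#'
#' @param data A [failure_dataset()].
#' @param shape_link Passed to [fit_aft_model()] for the 2-parameter
#'   families (default `"constant"`, mirroring the standard comparison).
#' @return Data frame: `family`, `n_params`, `loglik`, `aic`, `converged`,
#'   `rank` (NA for non-converged families), sorted by rank.
#' @export
rank_families_by_aic <- function(data, shape_link = "constant") {
  data <- failure_dataset(data)
  rows <- lapply(.tdt_families, function(fam) {
    sl <- if (fam == "exponential") "constant" else shape_link
    fit <- tryCatch(fit_aft_model(data, fam, shape_link = sl),
                    error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(family = fam, n_params = NA_integer_, loglik = NA_real_,
                 aic = NA_real_, converged = FALSE)
    } else {
      data.frame(family = fam, n_params = fit$n_params, loglik = fit$loglik,
                 aic = fit$aic, converged = fit$converged)
    }
  })
  tab <- do.call(rbind, rows)
  ok <- tab$converged & is.finite(tab$aic)
  tab$rank <- NA_integer_
  if (any(ok)) {
    sub <- tab[ok, ]
    aic_key <- round(sub$aic / 1e-9) * 1e-9   # snap ties within 1e-9
    o <- order(aic_key, sub$n_params, sub$family)
    tab$rank[ok][o] <- seq_len(sum(ok))
  }
  tab[order(is.na(tab$rank), tab$rank), ]
}

#' Likelihood-ratio test for a temperature trend in the shape parameter
#'
#' Tests whether the log-logistic shape parameter changes with temperature
#' by comparing nested joint AFT fits: the full model links the shape to
#' temperature (`log k = gamma0 + gamma1 * T`) and the reduced model holds
#' it constant (`gamma1 = 0`). The statistic is `2 * (loglik_full -
#' loglik_reduced)` on 1 degree of freedom. With `pooling = "pooled"`,
#' species enter through fixed location and shape intercepts while the
#' temperature slopes (`beta1`, `gamma1`) are shared — a fixed-effect
#' simplification of a multi-species trend test.
#'
#' @param data A [failure_dataset()]; a single species for
#'   `pooling = "per-species"`.
#' @param pooling `"per-species"` or `"pooled"` (species fixed intercepts,
#'   shared slopes).
#' @return A `shape_trend`: `gamma0` (intercept(s)), `gamma1`,
#'   `lr_statistic`, `df`, `p_value`, plus both fits.
#' @export
test_shape_trend <- function(data, pooling = c("per-species", "pooled")) {
  data <- failure_dataset(data)
  pooling <- match.arg(pooling)
  if (length(unique(data$temperature)) < 3) {
    stop("need >= 3 distinct temperatures", call. = FALSE)
  }
  if (pooling == "per-species" && length(unique(data$species)) > 1) {
    stop("per-species pooling requires a single species; got: ",
         paste(unique(data$species), collapse = ", "), call. = FALSE)
  }
  ic <- if (pooling == "pooled") "species" else "common"
  reduced <- fit_aft_model(data, "loglogistic", shape_link = "constant",
                           intercepts = ic)
  # seed the full fit with the reduced solution (gamma1 = 0) so the nested
  # likelihood ordering holds by construction
  red_par <- unname(c(reduced$coefficients, 0))
  full <- fit_aft_model(data, "loglogistic", shape_link = "loglinear",
                        intercepts = ic, extra_starts = list(red_par))
  lr <- 2 * (full$loglik - reduced$loglik)
  if (lr < -1e-6) {
    stop("optimizer failure: reduced model beat the full model (LR = ",
         format(lr), ")", call. = FALSE)
  }
  lr <- max(lr, 0)
  cf <- full$coefficients
  g0 <- cf[grep("^gamma0", names(cf))]
  structure(list(
    gamma0 = g0, gamma1 = cf[["gamma1"]],
    lr_statistic = lr, df = 1L,
    p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE),
    full = full, reduced = reduced
  ), class = "shape_trend")
}

#' @export
print.shape_trend <- function(x, ...) {
  cat(sprintf(
    "<shape_trend> gamma1 = %.4f per degC | LR = %.3f, df = %d, p = %.4g\n",
    x$gamma1, x$lr_statistic, x$df, x$p_value))
  invisible(x)
}

#' Diagnostic for non-constant hazard ratios between temperatures
#'
#' Tests the proportional-hazards assumption across assay temperatures: a
#' Cox model with temperature as the only covariate is compared by
#' likelihood ratio against the same model augmented with a temperature x
#' log(time) interaction (a time-varying coefficient, 1 degree of freedom).
#' A large statistic means the hazard ratio between temperatures changes
#' over time, so a proportional-hazards treatment of these data is invalid.
#'
#' @param data A [failure_dataset()] spanning >= 2 temperatures, with >= 2
#'   events per temperature.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
test_ph_nonconstancy <- function(data) {
  data <- failure_dataset(data)
  if (length(unique(data$temperature)) < 2) {
    stop("need >= 2 distinct temperatures", call. = FALSE)
  }
  per_t <- table(data$temperature)
  if (any(per_t < 2)) {
    stop("need >= 2 events per temperature; too few at: ",
         paste(names(per_t)[per_t < 2], collapse = ", "), call. = FALSE)
  }
  df <- data.frame(time = data$time, status = 1, temperature = data$temperature)
  reduced <- survival::coxph(survival::Surv(time, status) ~ temperature,
                             data = df)
  full <- survival::coxph(
    survival::Surv(time, status) ~ temperature + survival::tt(temperature),
    data = df, tt = function(x, t, ...) x * log(t))
  lr <- max(0, 2 * (full$loglik[2] - reduced$loglik[2]))
  list(statistic = lr, df = 1L,
       p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE))
}
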