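# Scoring of the three fluctuating-temperature models against observed
# failure times: per-set predicted vs observed medians, sums of absolute
# errors, per-set log-likelihood differences, and the paired test.

#' Construct one fluctuating-assay set observation
#'
#' One assay set: a temperature profile plus the observed failure times of
#' the individuals exposed to it. The observed median is the standard
#' mid-point sample median.
#'
#' @param set_id Label.
#' @param profile A [temperature_profile()].
#' @param observed_times Positive failure times, minutes.
#' @param sex Optional label; sets are compared separately by sex when
#'   present.
#' @return A `set_observation`.
#' @export
set_observation <- function(set_id, profile, observed_times, sex = NA) {
  stopifnot(inherits(profile, "temperature_profile"))
  observed_times <- as.numeric(observed_times)
  if (length(observed_times) < 1 || any(!is.finite(observed_times)) ||
      any(observed_times <= 0)) {
    stop("`observed_times` must be positive and finite", call. = FALSE)
  }
  structure(list(set_id = as.character(set_id), sex = sex,
                 profile = profile, observed_times = observed_times,
                 observed_median = stats::median(observed_times)),
            class = "set_observation")
}

#' Sum of absolute median-prediction errors across sets
#'
#' @param predictions Named numeric vector of predicted medians (minutes),
#'   one per set.
#' @param observations Named numeric vector of observed medians with the
#'   same names.
#' @return List: `sae` (total, minutes) and `per_set` (named absolute
#'   errors).
#' @export
sum_absolute_error <- function(predictions, observations) {
  if (is.null(names(predictions)) || is.null(names(observations))) {
    stop("both vectors must be named by set", call. = FALSE)
  }
  miss <- setdiff(names(predictions), names(observations))
  extra <- setdiff(names(observations), names(predictions))
  if (length(miss) || length(extra)) {
    stop("set mismatch; missing from observations: ",
         paste(miss, collapse = ", "), "; missing from predictions: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  per_set <- abs(predictions - observations[names(predictions)])
  list(sae = sum(per_set), per_set = per_set)
}

#' Paired test on per-set log-likelihood differences
#'
#' One-sample t test of mean(delta) = 0 on the per-set log-likelihood
#' differences between two models (two-sided, df = n - 1), plus the count
#' of sets with a strictly positive difference (ties count as
#' non-positive).
#'
#' @param deltas Per-set log-likelihood differences (>= 2 values).
#' @return List: `t_statistic`, `df`, `p_value`, `n_positive`.
#' @export
paired_delta_loglik_test <- function(deltas) {
  deltas <- as.numeric(deltas)
  if (length(deltas) < 2) stop("need >= 2 deltas", call. = FALSE)
  if (stats::sd(deltas) == 0) {
    stop("degenerate variance: all deltas identical", call. = FALSE)
  }
  tt <- stats::t.test(deltas, mu = 0)
  list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n_positive = sum(deltas > 0))
}

compare_one_group <- function(static_data, sets, config) {
  tdt <- fit_tdt_regression(static_data)
  curve <- build_average_relative_curve(static_data, tdt,
                                        bw_adjust = config$bw_adjust)
  aft <- fit_aft_model(static_data, "loglogistic",
                       shape_link = config$shape_link)
  model <- as_tdt_model(aft)
  model$temp_range <- range(static_data$temperature)
  rows <- list(); dll <- numeric(0)
  for (s in sets) {
    obs_med <- s$observed_median
    jm <- tryCatch(
      predict_median_jorgensen(s$profile, tdt,
                               horizon_mult = config$horizon_mult,
                               grid_step = config$grid_step),
      error = function(e) stop("jorgensen prediction failed for set `",
                               s$set_id, "`: ", conditionMessage(e),
                               call. = FALSE))
    rz <- tryCatch(
      predict_survival_rezende(s$profile, curve, tdt,
                               grid_step = config$grid_step,
                               horizon_mult = config$horizon_mult),
      error = function(e) stop("rezende prediction failed for set `",
                               s$set_id, "`: ", conditionMessage(e),
                               call. = FALSE))
    iv <- tryCatch(
      predict_survival_increasing_variance(
        s$profile, model, grid_step = config$grid_step,
        horizon_mult = config$horizon_mult,
        shape_eval = config$shape_eval),
      error = function(e) stop("increasing-variance prediction failed for ",
                               "set `", s$set_id, "`: ",
                               conditionMessage(e), call. = FALSE))
    ll_rz <- profile_log_likelihood(rz, s$observed_times, eps = config$eps)
    ll_iv <- profile_log_likelihood(iv, s$observed_times, eps = config$eps)
    dll <- c(dll, as.numeric(ll_iv) - as.numeric(ll_rz))
    meds <- c(jorgensen = as.numeric(jm), rezende = rz$median_tf,
              increasing_variance = iv$median_tf)
    lls <- c(jorgensen = NA_real_, rezende = as.numeric(ll_rz),
             increasing_variance = as.numeric(ll_iv))
    rows[[length(rows) + 1L]] <- data.frame(
      set_id = s$set_id, sex = if (is.na(s$sex)) NA_character_ else s$sex,
      model = names(meds), n = length(s$observed_times),
      observed_median = obs_med, predicted_median = unname(meds),
      absolute_error = abs(unname(meds) - obs_med), loglik = unname(lls),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  names(dll) <- vapply(sets, function(s) s$set_id, character(1))
  list(rows = tab, delta_ll = dll)
}

#' Full three-model comparison on fluctuating-temperature sets
#'
#' End-to-end comparison: fits the TDT regression, the pooled average
#' relative curve, and the temperature-linked log-logistic model on the
#' static data, predicts every assay set under all three models, and
#' assembles the comparison statistics — per-model sums of absolute median
#' errors, per-set log-likelihood differences (increasing variance minus
#' average-curve model; positive favors the increasing-variance model), the
#' paired t test on those differences, and the count of sets favoring the
#' increasing-variance model. Deterministic given its inputs.
#'
#' When the sets carry a `sex` label and `pool_sexes = FALSE` (default),
#' sexes are fitted and scored separately (using the matching static-data
#' subset when the static table has a `sex` column); the per-set
#' log-likelihood test is computed over all sets together.
#'
#' @param static_data A [failure_dataset()] of constant-temperature records
#'   (single species).
#' @param sets List of [set_observation()]s.
#' @param config Optional overrides: `shape_link` (default `"loglinear"`),
#'   `grid_step` (0.1 min), `horizon_mult` (10), `eps` (1e-12),
#'   `bw_adjust` (1), `shape_eval` (`"instantaneous"`), `pool_sexes`
#'   (FALSE).
#' @return A `model_comparison`: `rows` (one row per set x model), `sae`
#'   (per model, or per model x sex), `delta_ll`, `t_test`, `n_positive`,
#'   `n_sets`, and the effective `config`.
#' @export
run_full_comparison <- function(static_data, sets, config = list()) {
  static_data <- failure_dataset(static_data)
  defaults <- list(shape_link = "loglinear", grid_step = 0.1,
                   horizon_mult = 10, eps = 1e-12, bw_adjust = 1,
                   shape_eval = "instantaneous", pool_sexes = FALSE)
  config <- utils::modifyList(defaults, config)
  if (!length(sets)) stop("no assay sets supplied", call. = FALSE)
  sexes <- vapply(sets, function(s) as.character(s$sex), character(1))
  by_sex <- !config$pool_sexes && !all(is.na(sexes))
  groups <- if (by_sex) split(sets, sexes) else list(all = sets)
  static_has_sex <- !all(is.na(static_data$sex))
  parts <- lapply(names(groups), function(g) {
    sd <- static_data
    if (by_sex && static_has_sex && g %in% unique(static_data$sex)) {
      sd <- failure_dataset(static_data[static_data$sex == g, ,
                                        drop = FALSE])
    }
    compare_one_group(sd, groups[[g]], config)
  })
  rows <- do.call(rbind, lapply(parts, `[[`, "rows"))
  delta_ll <- do.call(c, lapply(parts, `[[`, "delta_ll"))
  rows$.sex_group <- if (by_sex) rows$sex else "all"
  sae <- stats::aggregate(absolute_error ~ model + .sex_group, data = rows,
                          FUN = sum)
  names(sae) <- c("model", "sex", "sae")
  rows$.sex_group <- NULL
  t_test <- if (length(delta_ll) >= 2 && stats::sd(delta_ll) > 0) {
    paired_delta_loglik_test(delta_ll)
  } else NULL
  structure(list(rows = rows, sae = sae, delta_ll = delta_ll,
                 t_test = t_test,
                 n_positive = sum(delta_ll > 0), n_sets = length(delta_ll),
                 config = config),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %d sets x 3 models\n", x$n_sets))
  cat("Sum of absolute median errors (min):\n")
  print(x$sae, row.names = FALSE)
  if (!is.null(x$t_test)) {
    cat(sprintf(
      "Delta loglik (increasing_variance - rezende): t = %.4f, df = %d, p = %.4g; positive in %d of %d sets\n",
      x$t_test$t_statistic, x$t_test$df, x$t_test$p_value, x$n_positive,
      x$n_sets))
  }
  invisible(x)
}
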