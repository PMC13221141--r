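#' Construct a failure-time dataset
#'
#' Validates and classes a table of individual failure (knockdown) records
#' from static thermal-tolerance assays. Each row is one individual: the
#' species (or population label), the constant assay temperature in degrees
#' Celsius, the failure time in minutes, and a trial identifier. An optional
#' `sex` column is carried through and used by [run_full_comparison()].
#'
#' @param x A data frame with columns `species`, `temperature`, `time`,
#'   `trial_id` and optionally `sex`.
#' @return A `failure_dataset` (a validated data frame).
#' @export
failure_dataset <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  needed <- c("species", "temperature", "time", "trial_id")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"sex" %in% names(x)) x$sex <- NA_character_
  x$temperature <- as.numeric(x$temperature)
  x$time <- as.numeric(x$time)
  bad_t <- which(!is.finite(x$time) | x$time <= 0)
  if (length(bad_t)) {
    stop("failure times must be positive and finite; offending row(s): ",
         paste(utils::head(bad_t, 10), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$temperature))) {
    stop("temperatures must be finite", call. = FALSE)
  }
  class(x) <- c("failure_dataset", "data.frame")
  x
}

#' @export
print.failure_dataset <- function(x, ...) {
  cat(sprintf(
    "<failure_dataset> %d records | %d species | %d temperatures (%.1f-%.1f degC)\n",
    nrow(x), length(unique(x$species)), length(unique(x$temperature)),
    min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' Drop assay groups below a minimum trial size
#'
#' Removes every (species, temperature, trial) group with fewer than `min_n`
#' individuals. Small trials give unstable estimates of the shape parameter
#' and can prevent the per-cell maximum-likelihood fits from converging; the
#' default threshold of 10 individuals mirrors standard practice for these
#' assays. Record order is preserved; the dropped groups are reported in the
#' `"dropped"` attribute of the result.
#'
#' @param data A [failure_dataset()].
#' @param min_n Minimum group size to retain (default 10).
#' @return The filtered `failure_dataset`, with attribute `dropped`: a data
#'   frame of removed groups and their sizes.
#' @export
filter_min_trial_size <- function(data, min_n = 10) {
  data <- failure_dataset(data)
  if (min_n < 1) stop("`min_n` must be >= 1", call. = FALSE)
  key <- interaction(data$species, data$temperature, data$trial_id,
                     drop = TRUE)
  sizes <- table(key)
  keep_groups <- names(sizes)[sizes >= min_n]
  keep <- key %in% keep_groups
  grp <- unique(as.data.frame(data)[, c("species", "temperature",
                                        "trial_id")])
  grp$n <- as.integer(sizes[as.character(
    interaction(grp$species, grp$temperature, grp$trial_id, drop = TRUE))])
  dropped <- grp[grp$n < min_n, , drop = FALSE]
  rownames(dropped) <- NULL
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("no data after filtering at min_n = ", min_n, call. = FALSE)
  }
  rownames(out) <- NULL
  out <- failure_dataset(out)
  attr(out, "dropped") <- dropped
  out
}

#' Per-cell sample medians of failure time
#'
#' Sample median failure time for each species x temperature cell; the
#' empirical counterpart of the log-logistic scale parameter and the input
#' to the thermal-death-time regression.
#'
#' @param data A [failure_dataset()].
#' @return Data frame with columns `species`, `temperature`, `n`,
#'   `median_time` (minutes).
#' @export
cell_medians <- function(data) {
  data <- failure_dataset(data)
  agg <- stats::aggregate(time ~ species + temperature, data = data,
                          FUN = stats::median)
  names(agg)[names(agg) == "time"] <- "median_time"
  cnt <- stats::aggregate(time ~ species + temperature, data = data,
                          FUN = length)
  agg$n <- cnt$time
  agg[order(agg$species, agg$temperature), c("species", "temperature", "n",
                                             "median_time")]
}
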