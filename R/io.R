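# Delimited-text input and output. Times are minutes everywhere and the
# column is named `time_min` on disk to prevent silent unit bugs; decimal
# point ".", NA for unavailable values.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

read_delim_checked <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (nrow(df) == 0) stop("no data rows in ", path, call. = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cc in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & df[[cc]] != "NA")
    if (length(bad)) {
      stop("unparsable number in column `", cc, "` of ", path, ", line ",
           bad[1] + 1L, ": \"", df[[cc]][bad[1]], "\"", call. = FALSE)
    }
    df[[cc]] <- v
  }
  df
}

#' Read a constant-temperature failure table
#'
#' Reads a delimited text file (comma or tab separated, UTF-8, "." decimal
#' point) with header columns `species`, `temperature_C`, `time_min`,
#' `trial_id` and optionally `sex`, in any column order. Rows with
#' nonpositive or unparsable failure times are rejected with their line
#' numbers.
#'
#' @param path File path.
#' @return A [failure_dataset()].
#' @export
read_failure_table <- function(path) {
  df <- read_delim_checked(path,
                           required = c("species", "temperature_C",
                                        "time_min", "trial_id"),
                           numeric_cols = c("temperature_C", "time_min"))
  bad <- which(!is.finite(df$time_min) | df$time_min <= 0)
  if (length(bad)) {
    stop("nonpositive or missing time_min in ", path, ", line ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(species = df$species,
                    sex = if ("sex" %in% names(df)) df$sex else NA_character_,
                    temperature = df$temperature_C, time = df$time_min,
                    trial_id = df$trial_id, stringsAsFactors = FALSE)
  failure_dataset(out)
}

#' Write a failure dataset as delimited text
#' @param data A [failure_dataset()].
#' @param path Output path (`.tsv` extension writes tab-separated,
#'   otherwise comma-separated).
#' @return `path`, invisibly.
#' @export
write_failure_table <- function(data, path) {
  data <- failure_dataset(data)
  out <- data.frame(species = data$species, sex = data$sex,
                    temperature_C = data$temperature, time_min = data$time,
                    trial_id = data$trial_id)
  write_table_atomic(out, path)
}

#' Read temperature profiles from a long table
#'
#' Columns `time_min`, `temperature_C`, and optionally `set_id` (one
#' profile per set; a single profile when absent) and `interpolation`
#' (`"stepwise"`/`"linear"`, constant within a set).
#'
#' @param path File path.
#' @return Named list of [temperature_profile()]s.
#' @export
read_profile_table <- function(path) {
  df <- read_delim_checked(path, required = c("time_min", "temperature_C"),
                           numeric_cols = c("time_min", "temperature_C"))
  if (!"set_id" %in% names(df)) df$set_id <- "profile"
  out <- lapply(split(df, df$set_id), function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    interp <- if ("interpolation" %in% names(d)) d$interpolation[1] else
      "stepwise"
    temperature_profile(d$time_min, d$temperature_C, interpolation = interp)
  })
  out[unique(df$set_id)]
}

#' Write temperature profiles as a long table
#' @param profiles Named list of [temperature_profile()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  if (is.null(names(profiles))) names(profiles) <- seq_along(profiles)
  rows <- lapply(names(profiles), function(id) {
    p <- profiles[[id]]
    data.frame(set_id = id, time_min = p$time, temperature_C = p$temperature,
               interpolation = p$interpolation)
  })
  write_table_atomic(do.call(rbind, rows), path)
}

#' Read observed failure times for fluctuating assay sets
#'
#' Columns `set_id`, `time_min`, optionally `sex`.
#'
#' @param path File path.
#' @return Data frame with `set_id`, `time_min`, `sex`.
#' @export
read_observed_table <- function(path) {
  df <- read_delim_checked(path, required = c("set_id", "time_min"),
                           numeric_cols = "time_min")
  bad <- which(!is.finite(df$time_min) | df$time_min <= 0)
  if (length(bad)) {
    stop("nonpositive or missing time_min in ", path, ", line ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  df[, c("set_id", "time_min", "sex")]
}

# atomic write: temp file in the same directory, then rename
write_table_atomic <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(df, tmp, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE); unlink(tmp)
  }
  invisible(path)
}
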