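#' Uniformly sampled time series
#'
#' The universal currency of the package: a scalar series on a regular time
#' grid with explicit missing values (`NA`). Timestamps are implied by
#' `start_time + (k - 1) * step` and never stored per sample, so averaging,
#' differencing and segmentation can reason about the grid directly.
#'
#' @param values numeric vector, `NA` marking missing samples.
#' @param start_time timestamp of the first sample (`POSIXct` or a string
#'   parseable as UTC).
#' @param step sampling interval in minutes (positive scalar).
#' @param variable short label for the measured quantity, e.g. `"chlorophyll"`.
#' @param units unit label, e.g. `"mg m-3"`.
#' @param transformed logical; `TRUE` marks a rate-of-change series produced
#'   by [log_smooth_diff()].
#' @return An object of class `tw_ts`.
#' @examples
#' w <- timeseries(sin(2 * pi * (0:143) / 74.52), "2007-01-01", step = 10,
#'                 variable = "water_level", units = "m")
#' w
#' @export
timeseries <- function(values, start_time, step, variable = "value",
                       units = "", transformed = FALSE) {
  if (!is.numeric(step) || length(step) != 1L || is.na(step) || step <= 0)
    stop("`step` must be a single positive number of minutes")
  values <- as.numeric(values)
  if (length(values) < 1L) stop("`values` must contain at least one sample")
  start_time <- as_utc(start_time)
  structure(
    list(values = values, start_time = start_time, step = step,
         variable = variable, units = units, transformed = isTRUE(transformed)),
    class = "tw_ts")
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  out <- tryCatch(
    as.POSIXct(x, tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                              "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")),
    error = function(e) stop("unparseable timestamp: ", x[1L], call. = FALSE))
  if (any(is.na(out))) stop("unparseable timestamp: ", x[which(is.na(out))[1L]])
  out
}

#' @export
length.tw_ts <- function(x) length(x$values)

#' Timestamps of a series
#'
#' @param x a `tw_ts` object.
#' @return `POSIXct` vector of the implied sample times (UTC).
#' @export
ts_timestamps <- function(x) {
  stopifnot(inherits(x, "tw_ts"))
  x$start_time + (seq_along(x$values) - 1) * x$step * 60
}

# minutes elapsed since the first sample
ts_minutes <- function(x) (seq_along(x$values) - 1) * x$step

#' @export
print.tw_ts <- function(x, ...) {
  n <- length(x$values)
  nmiss <- sum(is.na(x$values))
  cat(sprintf("<tw_ts> %s%s: %d samples @ %g min from %s UTC (%d missing)%s\n",
              x$variable,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              n, x$step, format(x$start_time, "%Y-%m-%d %H:%M"),
              nmiss, if (x$transformed) ", rate-of-change" else ""))
  invisible(x)
}

#' @export
plot.tw_ts <- function(x, ...) {
  graphics::plot(ts_timestamps(x), x$values, type = "l",
                 xlab = "time", ylab = paste(x$variable, x$units), ...)
  invisible(x)
}

# check that two series share grid and length
check_coregistered <- function(x, y) {
  stopifnot(inherits(x, "tw_ts"), inherits(y, "tw_ts"))
  if (x$step != y$step || length(x$values) != length(y$values) ||
      abs(as.numeric(difftime(x$start_time, y$start_time, units = "mins"))) >
        1e-6)
    stop("series are not co-registered (start, step and length must match)")
  invisible(TRUE)
}

#' Write a series as a timestamped CSV file
#'
#' The on-disk interchange format is a two-column CSV with header
#' `timestamp,value`: ISO-8601 UTC timestamps and a numeric value column in
#' which missing samples appear as empty fields.
#'
#' @param x a `tw_ts` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  stopifnot(inherits(x, "tw_ts"))
  stamps <- format(ts_timestamps(x), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  vals <- ifelse(is.na(x$values), "",
                 formatC(x$values, digits = 10, format = "g"))
  writeLines(c("timestamp,value", paste(stamps, vals, sep = ",")), path)
  invisible(path)
}

#' Read a timestamped CSV file as a time series
#'
#' Inverse of [write_timeseries()]. The sampling cadence is inferred from the
#' timestamp column (the most common positive spacing); timestamps that are
#' slightly off-grid are snapped to the nearest grid point provided they lie
#' within half a step, and grid points with no row become missing samples.
#'
#' @param path CSV file with a header and columns `timestamp,value`.
#' @param variable,units labels attached to the result (defaults taken from
#'   the file name).
#' @return A `tw_ts` object.
#' @export
read_timeseries <- function(path, variable = NULL, units = "") {
  df <- utils::read.csv(path, colClasses = c("character", "character"))
  if (ncol(df) < 2L) stop("expected columns `timestamp,value` in ", path)
  stamps <- as_utc(df[[1L]])
  if (is.unsorted(stamps, strictly = TRUE))
    stop("non-monotone timestamps in ", path)
  vals <- suppressWarnings(as.numeric(df[[2L]]))
  vals[!nzchar(trimws(df[[2L]]))] <- NA_real_
  if (length(stamps) < 2L) {
    return(timeseries(vals, stamps[1L], step = 1,
                      variable = variable %||% csv_stem(path), units = units))
  }
  diffs <- as.numeric(difftime(stamps[-1L], stamps[-length(stamps)],
                               units = "mins"))
  # cadence inference: the most frequent (then smallest) spacing under
  # which every observed spacing is close to an integer multiple of it —
  # multiples > 1 are grid holes, jitter up to 10% of a step is tolerated
  tab <- sort(table(diffs), decreasing = TRUE)
  cands <- as.numeric(names(tab))
  cands <- cands[order(-as.numeric(tab), cands)]
  step <- NA_real_
  for (d in cands) {
    if (d <= 0) next
    err <- abs(diffs - round(diffs / d) * d)
    if (all(err <= 0.1 * d)) {
      step <- d
      break
    }
  }
  if (is.na(step)) stop("ambiguous sampling cadence in ", path)
  rel <- as.numeric(difftime(stamps, stamps[1L], units = "mins"))
  k <- round(rel / step)
  if (any(abs(rel - k * step) > step / 2))
    stop("timestamp off the inferred ", step, "-min grid by more than half a ",
         "step in ", path)
  if (anyDuplicated(k)) stop("duplicate grid timestamps in ", path)
  out <- rep(NA_real_, max(k) + 1L)
  out[k + 1L] <- vals
  timeseries(out, stamps[1L], step = step,
             variable = variable %||% csv_stem(path), units = units)
}

csv_stem <- function(path) sub("\\.[^.]*$", "", basename(path))

`%||%` <- function(a, b) if (is.null(a)) b else a
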