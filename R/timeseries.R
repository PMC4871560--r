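#' Pupil-size time series
#'
#' Container for a uniformly sampled pupil-size signal. Sample `i`
#' (1-based) is located at time `start_time + (i - 1) / rate` seconds.
#' Invalid samples (lost pupil during blinks, tracking dropouts) are
#' represented by a logical mask rather than sentinel values, so that
#' downstream filters never see placeholder numbers.
#'
#' @param samples numeric vector of pupil sizes (recorder arbitrary units,
#'   or z-units after normalization).
#' @param rate sampling rate in Hz, > 0.
#' @param start_time time of the first sample in seconds (default 0).
#' @param valid logical mask, same length as `samples`; `FALSE` marks
#'   samples that must not be trusted (default all `TRUE`).
#' @param units one of `"raw"` or `"zscored"`.
#'
#' @return An object of class `pupil_ts`.
#' @export
pupil_ts <- function(samples, rate, start_time = 0,
                     valid = rep(TRUE, length(samples)),
                     units = c("raw", "zscored")) {
  units <- match.arg(units)
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop("pupil_ts: 'samples' must be non-empty")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("pupil_ts: 'rate' must be a single positive number")
  valid <- as.logical(valid)
  if (length(valid) != length(samples))
    stop("pupil_ts: 'valid' must have the same length as 'samples'")
  structure(
    list(samples = samples, rate = rate, start_time = start_time,
         valid = valid, units = units),
    class = "pupil_ts"
  )
}

#' @export
print.pupil_ts <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf(
    "<pupil_ts> %d samples @ %g Hz (%.2f s), start %.3f s, units '%s', %d invalid\n",
    n, x$rate, n / x$rate, x$start_time, x$units, sum(!x$valid)))
  invisible(x)
}

#' @export
length.pupil_ts <- function(x) length(x$samples)

#' Sample times of a pupil time series
#'
#' @param ts a [pupil_ts()] object.
#' @return numeric vector of sample times in seconds.
#' @export
ts_times <- function(ts) {
  ts$start_time + (seq_along(ts$samples) - 1) / ts$rate
}

#' Duration of a pupil time series in seconds
#' @param ts a [pupil_ts()] object.
#' @return length of the recording in seconds.
#' @export
ts_duration <- function(ts) length(ts$samples) / ts$rate

#' Event table
#'
#' Timestamped, typed events: sound onsets, blinks, saccades, or custom
#' labels. Rows are kept sorted by time (stable within ties), which keeps
#' times non-decreasing within every type.
#'
#' @param time event times in seconds.
#' @param type character labels, e.g. `"sound_high"`, `"sound_low"`,
#'   `"blink"`, `"saccade"`.
#' @param duration optional durations in seconds (`NA` where not
#'   applicable); must be >= 0 when present.
#' @param amplitude optional amplitudes in degrees of visual angle;
#'   must be >= 0 when present.
#' @param run_id run label (recycled).
#'
#' @return A `data.frame` with class `event_table`.
#' @export
event_table <- function(time = numeric(), type = character(),
                        duration = NA_real_, amplitude = NA_real_,
                        run_id = "run1") {
  n <- length(time)
  if (length(type) != n)
    stop("event_table: 'time' and 'type' must have equal length")
  df <- data.frame(
    time = as.numeric(time),
    type = as.character(type),
    duration = rep_len(as.numeric(duration), n),
    amplitude = rep_len(as.numeric(amplitude), n),
    run_id = rep_len(as.character(run_id), n),
    stringsAsFactors = FALSE
  )
  if (n > 0) {
    bad_d <- !is.na(df$duration) & df$duration < 0
    bad_a <- !is.na(df$amplitude) & df$amplitude < 0
    if (any(bad_d)) stop("event_table: negative durations")
    if (any(bad_a)) stop("event_table: negative amplitudes")
    df <- df[order(df$time), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("event_table", "data.frame")
  df
}

#' Subset an event table by type
#' @param events an [event_table()].
#' @param types character vector of type labels to keep.
#' @return an `event_table` containing only the requested types.
#' @export
events_of_type <- function(events, types) {
  out <- events[events$type %in% types, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}

# Anchor time used when an event enters a regression design. Blink
# responses are locked to the end of the blink (eye reopening); saccade
# rows are recorded at saccade offset already. Everything else anchors
# at the event time.
event_anchor_times <- function(events) {
  t <- events$time
  blink <- events$type == "blink" & !is.na(events$duration)
  t[blink] <- t[blink] + events$duration[blink]
  t
}

## ---------------------------------------------------------------------
## Delimited-text readers and writers. Native exchange format is TSV with
## a one-line header; numeric columns carry >= 9 significant digits.

fmt_num <- function(x) {
  out <- sprintf("%.10g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv_impl <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA"),
    error = function(e) stop("I/O failure writing '", path, "': ",
                             conditionMessage(e))
  )
}

read_tsv_impl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a pupil sample stream from delimited text
#'
#' Expects a tab-delimited file with a header. The default dialect uses
#' columns `time_s` and `pupil`, plus optional `gaze_x`, `gaze_y` and
#' `valid` (0/1). The sampling rate is inferred as the reciprocal of the
#' median inter-sample interval; spacing must be uniform to within 1%.
#' Samples with a missing or zero pupil value, or `valid == 0`, are
#' flagged invalid in the mask (no row is ever dropped).
#'
#' @param path file path.
#' @param dialect named list mapping roles to column names; entries
#'   `time`, `pupil`, and optionally `valid`.
#' @return a [pupil_ts()].
#' @export
read_samples <- function(path,
                         dialect = list(time = "time_s", pupil = "pupil",
                                        valid = "valid")) {
  df <- read_tsv_impl(path)
  for (role in c("time", "pupil")) {
    col <- dialect[[role]]
    if (is.null(col) || !col %in% names(df))
      stop("read_samples: required column '", role, "' (", col,
           ") missing in ", path)
  }
  tm <- as.numeric(df[[dialect$time]])
  if (anyNA(tm)) stop("read_samples: unparseable time values in ", path)
  if (is.unsorted(tm, strictly = TRUE))
    stop("read_samples: time column must be strictly increasing")
  if (length(tm) < 2) stop("read_samples: need at least 2 samples")
  dt <- diff(tm)
  med <- stats::median(dt)
  if (any(abs(dt - med) > 0.01 * med))
    stop("read_samples: non-uniform sample spacing (beyond 1% of median)")
  pupil <- as.numeric(df[[dialect$pupil]])
  valid <- !is.na(pupil) & pupil != 0
  vc <- dialect$valid
  if (!is.null(vc) && vc %in% names(df))
    valid <- valid & (as.numeric(df[[vc]]) != 0)
  pupil[is.na(pupil)] <- 0
  pupil_ts(pupil, rate = 1 / med, start_time = tm[1], valid = valid)
}

#' Write a pupil sample stream to delimited text
#'
#' Inverse of [read_samples()]; round-trips are lossless to 1e-9
#' relative tolerance.
#'
#' @param ts a [pupil_ts()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(ts, path) {
  stopifnot(inherits(ts, "pupil_ts"))
  df <- data.frame(time_s = ts_times(ts), pupil = ts$samples,
                   valid = as.integer(ts$valid))
  # a zero pupil value is the invalid sentinel on disk; keep mask authoritative
  df$pupil[!ts$valid & df$pupil == 0] <- 0
  write_tsv_impl(df, path)
  invisible(path)
}

#' Read an event table from delimited text
#'
#' Requires columns `time_s` and `type`; optional `duration_s`,
#' `amplitude_deg` and `run_id`. Unknown type labels are preserved
#' verbatim. Rows are sorted by time.
#'
#' @param path file path.
#' @return an [event_table()].
#' @export
read_events <- function(path) {
  df <- read_tsv_impl(path)
  if (!all(c("time_s", "type") %in% names(df)))
    stop("read_events: columns 'time_s' and 'type' are required in ", path)
  if (nrow(df) == 0)
    return(event_table())
  tm <- suppressWarnings(as.numeric(df$time_s))
  if (anyNA(tm)) stop("read_events: unparseable time values in ", path)
  event_table(
    time = tm,
    type = as.character(df$type),
    duration = if ("duration_s" %in% names(df)) as.numeric(df$duration_s) else NA_real_,
    amplitude = if ("amplitude_deg" %in% names(df)) as.numeric(df$amplitude_deg) else NA_real_,
    run_id = if ("run_id" %in% names(df)) as.character(df$run_id) else "run1"
  )
}

#' Write an event table to delimited text
#'
#' @param events an [event_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- data.frame(time_s = events$time, type = events$type,
                   duration_s = events$duration,
                   amplitude_deg = events$amplitude,
                   run_id = events$run_id)
  write_tsv_impl(df, path)
  invisible(path)
}

#' Write estimated kernels to delimited text
#'
#' One row per lag; first column `lag_s`, then one column per event
#' type.
#'
#' @param kernels numeric matrix, lags x event types, with column names,
#'   or a `fir_fit` object (its kernel matrix is used).
#' @param lags lag axis in seconds (ignored when `kernels` is a
#'   `fir_fit`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kernels <- function(kernels, path, lags = NULL) {
  if (inherits(kernels, "fir_fit")) {
    lags <- kernels$lags
    kernels <- kernels$kernels
  }
  if (is.null(kernels) || length(kernels) == 0 || NROW(kernels) == 0)
    stop("write_kernels: empty kernel estimates")
  kernels <- as.matrix(kernels)
  if (is.null(colnames(kernels)))
    stop("write_kernels: kernel matrix must carry event-type column names")
  if (is.null(lags) || length(lags) != nrow(kernels))
    stop("write_kernels: 'lags' must match the number of kernel rows")
  df <- data.frame(lag_s = lags, kernels, check.names = FALSE)
  write_tsv_impl(df, path)
  invisible(path)
}

#' Read kernels written by [write_kernels()]
#'
#' @param path file path.
#' @return list with `lags` (numeric) and `kernels` (matrix, one column
#'   per event type).
#' @export
read_kernels <- function(path) {
  df <- read_tsv_impl(path)
  if (!"lag_s" %in% names(df)) stop("read_kernels: missing 'lag_s' column")
  list(lags = as.numeric(df$lag_s),
       kernels = as.matrix(df[setdiff(names(df), "lag_s")]))
}
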