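#' Preprocessing configuration
#'
#' Defaults reproduce a standard pupillometry pipeline: linear blink
#' interpolation padded by 150 ms on each side, a 0.02--4 Hz third-order
#' Butterworth band-pass for the phasic signal, a 0.02 Hz low-pass for
#' the tonic signal, z-scoring with a per-session divisor, and
#' resampling to 10 Hz.
#'
#' @param interp_pad_before seconds of signal replaced before each blink
#'   onset (default 0.150).
#' @param interp_pad_after seconds replaced after each blink offset
#'   (default 0.150).
#' @param band_low phasic high-pass cutoff in Hz (default 0.02).
#' @param band_high phasic low-pass cutoff in Hz (default 4).
#' @param filter_order Butterworth order per pass (default 3).
#' @param tonic_cutoff tonic low-pass cutoff in Hz (default 0.02).
#' @param target_rate analysis sampling rate in Hz (default 10).
#' @param baseline_window window relative to event onset, in seconds,
#'   over which tonic values are averaged (default `c(-0.5, 0)`).
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(interp_pad_before = 0.150,
                              interp_pad_after = 0.150,
                              band_low = 0.02, band_high = 4,
                              filter_order = 3, tonic_cutoff = 0.02,
                              target_rate = 10,
                              baseline_window = c(-0.5, 0)) {
  stopifnot(interp_pad_before >= 0, interp_pad_after >= 0,
            band_low > 0, band_low < band_high, filter_order >= 1,
            tonic_cutoff > 0, target_rate > 0,
            length(baseline_window) == 2,
            baseline_window[1] < baseline_window[2])
  if (band_high >= target_rate / 2)
    stop("preprocess_config: band_high must be below the target Nyquist (",
         target_rate / 2, " Hz)")
  structure(
    list(interp_pad_before = interp_pad_before,
         interp_pad_after = interp_pad_after,
         band_low = band_low, band_high = band_high,
         filter_order = filter_order, tonic_cutoff = tonic_cutoff,
         target_rate = target_rate, baseline_window = baseline_window),
    class = "preprocess_config")
}

#' Detect blinks from the validity mask
#'
#' Fallback detector for recordings that lack tracker-provided blink
#' events: every maximal run of invalid samples lasting at least
#' `min_gap` seconds becomes one blink with onset and duration.
#'
#' @param ts a [pupil_ts()].
#' @param min_gap minimum dropout duration counted as a blink, seconds.
#' @return an [event_table()] of `blink` rows.
#' @export
detect_blinks <- function(ts, min_gap = 0.05) {
  stopifnot(inherits(ts, "pupil_ts"))
  if (!any(ts$valid))
    stop("detect_blinks: recording contains no valid samples")
  r <- rle(!ts$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths / ts$rate >= min_gap)
  if (!any(keep))
    return(event_table())
  onset <- ts$start_time + (starts[keep] - 1) / ts$rate
  dur <- r$lengths[keep] / ts$rate
  event_table(time = onset, type = rep("blink", length(onset)),
              duration = dur)
}

# merge overlapping/touching [start, end] windows; both vectors sorted by start
merge_windows <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Linearly interpolate blink gaps
#'
#' Replaces samples from `interp_pad_before` seconds before each blink
#' onset until `interp_pad_after` seconds after its offset with the
#' straight line joining the nearest valid boundary samples.
#' Overlapping or touching windows are merged first. Windows that
#' extend past a recording edge hold the nearest valid value. Any
#' remaining invalid samples (brief tracking dropouts outside detected
#' blinks) are repaired with the same linear rule and zero padding.
#' All repaired samples are marked valid.
#'
#' @param ts a [pupil_ts()].
#' @param blinks an [event_table()] with `blink` rows (onset +
#'   duration); pass `detect_blinks(ts)` when the tracker supplied none.
#' @param cfg a [preprocess_config()].
#' @return a fully valid [pupil_ts()].
#' @export
interpolate_blinks <- function(ts, blinks, cfg = preprocess_config()) {
  stopifnot(inherits(ts, "pupil_ts"))
  x <- ts$samples
  n <- length(x)
  valid <- ts$valid
  blinks <- events_of_type(blinks, "blink")

  win <- NULL
  if (nrow(blinks) > 0) {
    dur <- ifelse(is.na(blinks$duration), 0, blinks$duration)
    if (any(blinks$time + dur < ts$start_time) ||
        any(blinks$time > ts$start_time + n / ts$rate))
      stop("interpolate_blinks: blink outside recording extent")
    s <- blinks$time - cfg$interp_pad_before - ts$start_time
    e <- blinks$time + dur + cfg$interp_pad_after - ts$start_time
    win <- merge_windows(s, e)
  }
  # remaining invalid runs outside blink windows: same rule, zero padding
  inv <- !valid
  if (!is.null(win)) {
    for (i in seq_len(nrow(win))) {
      a <- max(1L, as.integer(floor(win[i, 1] * ts$rate)) + 1L)
      b <- min(n, as.integer(ceiling(win[i, 2] * ts$rate)) + 1L)
      inv[a:b] <- FALSE          # handled by the padded window
    }
  }
  if (any(inv)) {
    r <- rle(inv)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    extra <- cbind(start = (starts[r$values] - 1) / ts$rate,
                   end = (ends[r$values] - 1) / ts$rate)
    win <- if (is.null(win)) extra else rbind(win, extra)
  }
  if (is.null(win) || nrow(win) == 0)
    return(pupil_ts(x, ts$rate, ts$start_time, rep(TRUE, n), ts$units))
  win <- merge_windows(win[, 1], win[, 2])

  for (i in seq_len(nrow(win))) {
    a <- as.integer(floor(win[i, 1] * ts$rate)) + 1L
    b <- as.integer(ceiling(win[i, 2] * ts$rate)) + 1L
    if (a <= 1L && b >= n)
      stop("interpolate_blinks: gap covers the entire recording")
    a <- max(1L, a); b <- min(n, b)
    left <- if (a > 1L) x[a - 1L] else NA_real_
    right <- if (b < n) x[b + 1L] else NA_real_
    if (is.na(left) && is.na(right))
      stop("interpolate_blinks: no valid boundary sample")
    idx <- a:b
    x[idx] <- if (is.na(left)) right
      else if (is.na(right)) left
      else left + (right - left) * (idx - (a - 1L)) / (b + 1L - (a - 1L))
    valid[idx] <- TRUE
  }
  pupil_ts(x, ts$rate, ts$start_time, valid, ts$units)
}

#' Band-pass the pupil signal into its phasic component
#'
#' Zero-phase (forward-backward) third-order Butterworth band-pass,
#' applied as a low-pass at `band_high` composed with a high-pass at
#' `band_low`. The signal must be fully valid (interpolate first).
#'
#' @param ts a fully valid [pupil_ts()].
#' @param cfg a [preprocess_config()].
#' @return band-passed [pupil_ts()] at the input rate.
#' @export
bandpass_phasic <- function(ts, cfg = preprocess_config()) {
  stopifnot(inherits(ts, "pupil_ts"))
  if (!all(ts$valid))
    stop("bandpass_phasic: signal contains invalid samples; interpolate first")
  if (ts_duration(ts) < 3 / cfg$band_low)
    warning("bandpass_phasic: record shorter than ~3 high-pass time constants; ",
            "edge effects may dominate")
  y <- zerophase_highpass(ts$samples, ts$rate, cfg$band_low, cfg$filter_order)
  y <- zerophase_lowpass(y, ts$rate, cfg$band_high, cfg$filter_order)
  pupil_ts(y, ts$rate, ts$start_time, units = ts$units)
}

#' Extract the tonic (slow baseline) pupil signal
#'
#' Zero-phase third-order Butterworth low-pass at `tonic_cutoff`
#' (default 0.02 Hz), retaining the slow drift component removed from
#' the phasic signal.
#'
#' @param ts a fully valid [pupil_ts()].
#' @param cfg a [preprocess_config()].
#' @return low-passed [pupil_ts()], same length and rate as the input.
#' @export
extract_tonic <- function(ts, cfg = preprocess_config()) {
  stopifnot(inherits(ts, "pupil_ts"))
  if (!all(ts$valid))
    stop("extract_tonic: signal contains invalid samples; interpolate first")
  if (ts_duration(ts) < 3 / cfg$tonic_cutoff)
    warning("extract_tonic: record shorter than ~3 filter time constants")
  y <- zerophase_lowpass(ts$samples, ts$rate, cfg$tonic_cutoff,
                         cfg$filter_order)
  pupil_ts(y, ts$rate, ts$start_time, units = ts$units)
}

#' Normalize band-passed segments to z-units
#'
#' Each condition segment is demeaned on its own, but all segments
#' belonging to one session are divided by a single standard deviation,
#' computed from the session's concatenated band-passed signal, so
#' amplitude comparisons across conditions are not distorted.
#'
#' @param segments list of band-passed [pupil_ts()] objects (one per
#'   condition segment).
#' @param session grouping vector, one label per segment (default: all
#'   one session).
#' @return list of [pupil_ts()] in z-units, same structure as the input.
#' @export
normalize_segments <- function(segments, session = rep(1L, length(segments))) {
  stopifnot(length(segments) > 0, length(session) == length(segments))
  if (any(vapply(segments, function(s) length(s$samples) < 2, logical(1))))
    stop("normalize_segments: every segment needs at least 2 samples")
  sds <- tapply(seq_along(segments), session, function(ix) {
    stats::sd(unlist(lapply(segments[ix], `[[`, "samples")))
  })
  if (any(sds == 0 | !is.finite(sds)))
    stop("normalize_segments: degenerate (zero-variance) session signal")
  lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    pupil_ts((s$samples - mean(s$samples)) / sds[[as.character(session[i])]],
             s$rate, s$start_time, units = "zscored")
  })
}

#' Resample a low-passed signal to the analysis rate
#'
#' When the input rate is an integer multiple of `target_rate`,
#' resampling averages non-overlapping blocks centred on the output
#' sample times, so no timing bias is introduced. Otherwise the signal
#' is linearly interpolated onto the target grid.
#'
#' @param ts a [pupil_ts()], already low-passed at or below the target
#'   Nyquist frequency.
#' @param target_rate output rate in Hz.
#' @return a [pupil_ts()] at `target_rate`.
#' @export
resample_to <- function(ts, target_rate) {
  stopifnot(inherits(ts, "pupil_ts"), target_rate > 0)
  if (target_rate >= ts$rate)
    stop("resample_to: target rate must be below the input rate")
  ratio <- ts$rate / target_rate
  n <- length(ts$samples)
  if (abs(ratio - round(ratio)) < 1e-9) {
    dec <- as.integer(round(ratio))
    # block j (0-based) averages input samples whose nearest output
    # sample is j: input index i (0-based) maps to round(i / dec)
    j <- as.integer(round((seq_len(n) - 1) / dec))
    y <- as.numeric(tapply(ts$samples, j, mean))
    y <- y[seq_len(n %/% dec)]          # drop trailing partial block
    return(pupil_ts(y, target_rate, ts$start_time, units = ts$units))
  }
  t_in <- ts_times(ts)
  t_out <- seq(ts$start_time, t_in[n], by = 1 / target_rate)
  pupil_ts(stats::approx(t_in, ts$samples, xout = t_out, rule = 2)$y,
           target_rate, ts$start_time, units = ts$units)
}

#' Tonic pupil size at event onsets
#'
#' Averages the tonic signal over a window relative to each event onset
#' (default -0.5 to 0 s) and z-scores the values within each run.
#' Windows extending past a recording edge are clamped to the available
#' samples; an event is excluded (z-score `NA`, `included = FALSE`) only
#' when its window has no overlap with the recording at all.
#'
#' @param tonic a [pupil_ts()] from [extract_tonic()].
#' @param events an [event_table()].
#' @param window numeric length-2, window in seconds relative to onset.
#' @return a `data.frame` with columns `time`, `type`, `run_id`,
#'   `tonic_raw` (window mean), `tonic_z` (z within run) and `included`.
#' @export
tonic_at_events <- function(tonic, events, window = c(-0.5, 0)) {
  stopifnot(inherits(tonic, "pupil_ts"), nrow(events) > 0,
            length(window) == 2, window[1] < window[2])
  n <- length(tonic$samples)
  t0 <- tonic$start_time
  raw <- rep(NA_real_, nrow(events))
  for (i in seq_len(nrow(events))) {
    a <- as.integer(floor((events$time[i] + window[1] - t0) * tonic$rate)) + 1L
    b <- as.integer(ceiling((events$time[i] + window[2] - t0) * tonic$rate))
    if (b < 1L || a > n) next                    # no overlap: excluded
    raw[i] <- mean(tonic$samples[max(1L, a):min(n, b)])
  }
  included <- !is.na(raw)
  if (any(!included))
    warning("tonic_at_events: ", sum(!included),
            " event(s) outside the recording excluded")
  z <- rep(NA_real_, length(raw))
  for (r in unique(events$run_id)) {
    ix <- which(events$run_id == r & included)
    if (length(ix) == 0) next
    s <- stats::sd(raw[ix])
    if (length(ix) < 2 || is.na(s) || s == 0) {
      z[ix] <- 0
      warning("tonic_at_events: degenerate tonic variance in run '", r,
              "'; z-scores set to 0")
    } else {
      z[ix] <- (raw[ix] - mean(raw[ix])) / s
    }
  }
  data.frame(time = events$time, type = events$type, run_id = events$run_id,
             tonic_raw = raw, tonic_z = z, included = included,
             stringsAsFactors = FALSE)
}

#' Full preprocessing pipeline
#'
#' Fixed stage order: blink interpolation, then the band-pass (phasic
#' branch) and the tonic low-pass (tonic branch), then per-condition
#' normalization of the phasic signal, then resampling to the analysis
#' rate.
#'
#' @param ts raw [pupil_ts()].
#' @param blinks blink [event_table()] (or `NULL` to run
#'   [detect_blinks()]).
#' @param cfg a [preprocess_config()].
#' @param normalize divide by the session standard deviation and demean
#'   (default `TRUE`). Disable when the input is already in z-units,
#'   e.g. simulator output generated on the canonical z scale.
#' @return list with `phasic` (z-units, `target_rate`) and `tonic`
#'   (input rate) [pupil_ts()] objects.
#' @export
preprocess_pupil <- function(ts, blinks = NULL, cfg = preprocess_config(),
                             normalize = TRUE) {
  if (is.null(blinks)) {
    blinks <- if (all(ts$valid)) event_table() else detect_blinks(ts)
  }
  clean <- if (nrow(blinks) > 0 || !all(ts$valid))
    interpolate_blinks(ts, blinks, cfg) else ts
  phasic <- bandpass_phasic(clean, cfg)
  tonic <- extract_tonic(clean, cfg)
  if (normalize)
    phasic <- normalize_segments(list(phasic))[[1]]
  phasic <- resample_to(phasic, cfg$target_rate)
  list(phasic = phasic, tonic = tonic)
}
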