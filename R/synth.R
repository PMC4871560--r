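#' Synthetic experiment specification
#'
#' Describes one simulated recording run of the auditory-event paradigm:
#' two sound types whose timing is either narrowly Gaussian ("fixed",
#' mean 3 or 5 s) or shifted-exponential ("random", 1.5 s plus an
#' exponential chosen for equal mean), whose identity either alternates
#' or follows a Markov chain with 40% transition probability; blinks and
#' saccades as independent Poisson processes at the observed average
#' rates (0.11 and 0.8 Hz); event-locked responses generated from the
#' canonical kernels; a slowly decaying tonic baseline; optional
#' tonic-phasic gain coupling; white Gaussian measurement noise at the
#' raw rate; and optional blink-induced sample dropout.
#'
#' @param condition_timing `"fixed"` (Gaussian intervals) or `"random"`
#'   (shifted exponential, flat hazard).
#' @param condition_identity `"known"` (strict high/low alternation) or
#'   `"unknown"` (Markov chain, 40% transition probability).
#' @param experiment_version 1 (mean interval 3 s, sd 0.4) or 2 (mean
#'   5 s, sd 0.5).
#' @param run_duration run length in seconds (default 150).
#' @param saccade_rate Poisson rate, Hz (default 0.8).
#' @param blink_rate Poisson rate, Hz (default 0.11).
#' @param blink_duration_range uniform blink-duration bounds in seconds
#'   (default `c(0.1, 0.3)`).
#' @param saccade_lnorm `c(meanlog, sdlog)` of the log-normal saccade
#'   amplitude model; the analytic mode `exp(meanlog - sdlog^2)` must be
#'   below 1 degree (microsaccades dominate). Default gives mode 0.5
#'   degrees.
#' @param kernel_set `"table1"`, `"table2"`, or a named kernel list with
#'   entries `auditory`, `blink`, `saccade`.
#' @param tonic an [exp_decay()] describing the tonic drift (default
#'   amplitude 1 z, tau 60 s, offset 0).
#' @param beta tonic-phasic coupling: each event's kernel is scaled by
#'   `1 - beta * tonic_z(t_event)` where `tonic_z` is the z-scored
#'   tonic value across the run's events (default 0: no coupling).
#' @param noise_sd white measurement-noise sd at the raw rate, z-units
#'   (default 0.1).
#' @param dropout corrupt samples during blinks (+/- 20 ms) to zero and
#'   mark them invalid (default `TRUE`).
#' @param raw_rate recorder sampling rate in Hz (default 1000).
#' @param seed integer seed for all randomness in the session.
#' @return a list of class `experiment_spec`.
#' @export
experiment_spec <- function(condition_timing = c("fixed", "random"),
                            condition_identity = c("known", "unknown"),
                            experiment_version = 1,
                            run_duration = 150,
                            saccade_rate = 0.8, blink_rate = 0.11,
                            blink_duration_range = c(0.1, 0.3),
                            saccade_lnorm = c(meanlog = log(0.5) + 0.49,
                                              sdlog = 0.7),
                            kernel_set = "table1",
                            tonic = exp_decay(1, 60, 0),
                            beta = 0, noise_sd = 0.1, dropout = TRUE,
                            raw_rate = 1000, seed = 1L) {
  condition_timing <- match.arg(condition_timing)
  condition_identity <- match.arg(condition_identity)
  stopifnot(experiment_version %in% c(1, 2), run_duration > 0,
            saccade_rate > 0, blink_rate > 0, noise_sd >= 0, raw_rate > 0,
            length(blink_duration_range) == 2,
            blink_duration_range[1] <= blink_duration_range[2])
  imean <- if (experiment_version == 1) 3 else 5
  isd <- if (experiment_version == 1) 0.4 else 0.5
  if (run_duration <= imean)
    stop("experiment_spec: run_duration must exceed the mean interval")
  if (exp(saccade_lnorm[1] - saccade_lnorm[2]^2) >= 1)
    stop("experiment_spec: saccade amplitude mode must be < 1 degree")
  kernels <- if (is.character(kernel_set))
    canonical_kernels(kernel_set) else kernel_set
  stopifnot(all(c("auditory", "blink", "saccade") %in% names(kernels)))
  structure(
    list(condition_timing = condition_timing,
         condition_identity = condition_identity,
         experiment_version = experiment_version,
         interval_mean = imean, interval_sd = isd,
         run_duration = run_duration,
         saccade_rate = saccade_rate, blink_rate = blink_rate,
         blink_duration_range = blink_duration_range,
         saccade_lnorm = saccade_lnorm,
         kernels = kernels, tonic = tonic, beta = beta,
         noise_sd = noise_sd, dropout = dropout, raw_rate = raw_rate,
         seed = as.integer(seed)),
    class = "experiment_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate sound events for a synthetic run
#'
#' Inter-event intervals are drawn from the spec's timing model
#' (Gaussian for fixed timing; 1.5 s plus an exponential with mean
#' `interval_mean - 1.5` for random timing, preserving the mean) and
#' accumulated until the run ends. Identities alternate strictly in the
#' known-identity condition, or follow a Markov chain with transition
#' probability 0.4 in the unknown-identity condition.
#'
#' @param spec an [experiment_spec()].
#' @param seed integer seed (default derived from the spec).
#' @return an [event_table()] of `sound_high` / `sound_low` rows.
#' @export
generate_sound_events <- function(spec, seed = spec$seed) {
  with_seed(seed, {
    n_max <- ceiling(spec$run_duration / max(spec$interval_mean - 3 *
                                               spec$interval_sd, 0.5)) + 10
    iv <- if (spec$condition_timing == "fixed") {
      pmax(stats::rnorm(n_max, spec$interval_mean, spec$interval_sd), 0.1)
    } else {
      1.5 + stats::rexp(n_max, rate = 1 / (spec$interval_mean - 1.5))
    }
    times <- cumsum(iv)
    times <- times[times < spec$run_duration]
    n <- length(times)
    if (n == 0) return(event_table())
    type <- character(n)
    if (spec$condition_identity == "known") {
      type <- rep(c("sound_high", "sound_low"), length.out = n)
    } else {
      lab <- c("sound_high", "sound_low")
      cur <- sample(1:2, 1)
      for (i in seq_len(n)) {
        type[i] <- lab[cur]
        if (stats::runif(1) < 0.4) cur <- 3L - cur
      }
    }
    event_table(time = times, type = type)
  })
}

# renewal process with a refractory dead time: intervals are
# dead + Exp(lambda') with 1/lambda' = 1/rate - dead, so the achieved
# event rate equals `rate` exactly while no two events fall closer than
# `dead` seconds (intersaccadic intervals below ~0.15 s are
# physiologically impossible; overlapping blinks likewise).
renewal_times <- function(rate, dead, duration) {
  stopifnot(1 / rate > dead)
  n_max <- ceiling(duration * rate * 2) + 20
  iv <- dead + stats::rexp(n_max, rate = 1 / (1 / rate - dead))
  t <- cumsum(iv)
  t[t < duration]
}

#' Generate ocular (blink and saccade) events
#'
#' Blinks and saccades are independent point processes at the spec
#' rates: exponential inter-event intervals plus a refractory dead time
#' (0.15 s for saccades, 0.5 s for blinks), with intensity corrected so
#' the long-run rates equal the spec rates exactly. Blinks carry
#' uniform durations; saccades carry log-normal amplitudes (mode below
#' 1 degree). Events closer than 0.5 s to the run end are dropped.
#'
#' @param spec an [experiment_spec()].
#' @param seed integer seed (default `spec$seed + 1`).
#' @return an [event_table()] of `blink` / `saccade` rows.
#' @export
generate_ocular_events <- function(spec, seed = spec$seed + 1L) {
  with_seed(seed, {
    dur <- spec$run_duration
    bt <- renewal_times(spec$blink_rate, 0.5, dur)
    st <- renewal_times(spec$saccade_rate, 0.15, dur)
    bd <- stats::runif(length(bt), spec$blink_duration_range[1],
                       spec$blink_duration_range[2])
    sa <- stats::rlnorm(length(st), spec$saccade_lnorm[1],
                        spec$saccade_lnorm[2])
    keep_b <- bt < dur - 0.5
    keep_s <- st < dur - 0.5
    event_table(
      time = c(bt[keep_b], st[keep_s]),
      type = c(rep("blink", sum(keep_b)), rep("saccade", sum(keep_s))),
      duration = c(bd[keep_b], rep(NA_real_, sum(keep_s))),
      amplitude = c(rep(NA_real_, sum(keep_b)), sa[keep_s]))
  })
}

#' Synthesize a raw pupil recording from events
#'
#' Assembles the clean signal as the sum of event-locked kernel
#' responses (auditory kernel at sound times, blink kernel at blink
#' offsets, saccade kernel at saccade times) plus the tonic drift. With
#' coupling `beta != 0`, each event's kernel is scaled by
#' `1 - beta * tonic_z(t_event)` with the tonic value z-scored across
#' the run's events. White Gaussian noise at the raw rate is added, and
#' with `dropout = TRUE` samples during each blink (padded by 20 ms) are
#' corrupted to zero and marked invalid -- the artifact the
#' interpolation stage must repair. Ground truth is stored before
#' corruption.
#'
#' @param spec an [experiment_spec()].
#' @param sound_events,ocular_events [event_table()]s within the run.
#' @param seed integer seed for the noise (default `spec$seed + 2`).
#' @return list of class `pupil_session` with elements `raw` (a
#'   [pupil_ts()]) and `truth` (events, clean signal, tonic curve, true
#'   kernels on the analysis lag grid, per-event amplitudes).
#' @export
synthesize <- function(spec, sound_events, ocular_events,
                       seed = spec$seed + 2L) {
  all_ev <- rbind(sound_events, ocular_events)
  if (nrow(all_ev) > 0 && (any(all_ev$time < 0) ||
                           any(all_ev$time > spec$run_duration)))
    stop("synthesize: events outside the run duration")
  n <- as.integer(round(spec$run_duration * spec$raw_rate))
  t <- (seq_len(n) - 1) / spec$raw_rate
  tonic_curve <- decay_value(spec$tonic, t)

  ev <- event_table(
    time = c(sound_events$time, ocular_events$time),
    type = c(sound_events$type, ocular_events$type),
    duration = c(sound_events$duration, ocular_events$duration),
    amplitude = c(sound_events$amplitude, ocular_events$amplitude))
  anchors <- event_anchor_times(ev)

  amp <- rep(1, nrow(ev))
  if (spec$beta != 0 && nrow(ev) >= 2) {
    tz <- decay_value(spec$tonic, anchors)
    tz <- (tz - mean(tz)) / stats::sd(tz)
    amp <- 1 - spec$beta * tz
  }

  kernel_for <- function(type) switch(type,
    sound_high = , sound_low = spec$kernels$auditory,
    blink = spec$kernels$blink,
    saccade = spec$kernels$saccade,
    NULL)

  support <- 10                                   # s; canonical curves <1e-9 beyond
  ks <- as.integer(round(support * spec$raw_rate))
  clean <- tonic_curve
  for (i in seq_len(nrow(ev))) {
    kern <- kernel_for(ev$type[i])
    if (is.null(kern)) next
    i0 <- as.integer(floor(anchors[i] * spec$raw_rate)) + 1L
    if (i0 > n) next
    j <- max(1L, i0):min(n, i0 + ks - 1L)
    clean[j] <- clean[j] + amp[i] * kernel_value(kern, t[j] - anchors[i])
  }

  raw <- clean
  if (spec$noise_sd > 0)
    raw <- raw + with_seed(seed, stats::rnorm(n, 0, spec$noise_sd))
  valid <- rep(TRUE, n)
  if (spec$dropout) {
    blinks <- events_of_type(ocular_events, "blink")
    for (i in seq_len(nrow(blinks))) {
      a <- max(1L, as.integer(floor((blinks$time[i] - 0.02) *
                                      spec$raw_rate)) + 1L)
      b <- min(n, as.integer(ceiling((blinks$time[i] + blinks$duration[i] +
                                        0.02) * spec$raw_rate)) + 1L)
      raw[a:b] <- 0
      valid[a:b] <- FALSE
    }
  }

  lag_grid <- seq(-0.5, 5 - 0.1, by = 0.1)
  true_kernels <- cbind(
    sound_high = kernel_value(spec$kernels$auditory, lag_grid),
    sound_low = kernel_value(spec$kernels$auditory, lag_grid),
    blink = kernel_value(spec$kernels$blink, lag_grid),
    saccade = kernel_value(spec$kernels$saccade, lag_grid))

  structure(
    list(raw = pupil_ts(raw, spec$raw_rate, 0, valid, units = "zscored"),
         truth = list(events = ev, anchors = anchors, amplitudes = amp,
                      clean = clean, tonic = tonic_curve,
                      lags = lag_grid, kernels = true_kernels,
                      spec = spec)),
    class = "pupil_session")
}

#' @export
print.pupil_session <- function(x, ...) {
  cat("<pupil_session>\n  ")
  print(x$raw)
  tt <- table(x$truth$events$type)
  cat("  events:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper: generates sound and ocular events from the spec
#' and synthesizes the raw recording. All randomness derives from
#' `spec$seed`, so identical specs give identical sessions.
#'
#' @param spec an [experiment_spec()].
#' @return a `pupil_session` (see [synthesize()]).
#' @export
simulate_session <- function(spec) {
  sounds <- generate_sound_events(spec)
  ocular <- generate_ocular_events(spec)
  synthesize(spec, sounds, ocular)
}
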