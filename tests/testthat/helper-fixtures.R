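# shared fixtures built in code

# analysis-grid-aligned noise-free session used by exact-recovery tests:
# events snapped to the 10 Hz grid so the staggered 0/1 design is exactly
# specified, tonic flat so no unmodeled drift enters the window
make_exact_session <- function(seed = 1L, run_duration = 300) {
  spec <- experiment_spec(run_duration = run_duration, noise_sd = 0,
                          dropout = FALSE, beta = 0,
                          tonic = exp_decay(1e-9, 60, 0), seed = seed)
  snap <- function(ev) {
    ev$time <- round(ev$time * 10) / 10
    ev$duration <- ifelse(is.na(ev$duration), NA_real_,
                          round(ev$duration * 10) / 10)
    ev
  }
  sounds <- snap(generate_sound_events(spec))
  ocular <- snap(generate_ocular_events(spec))
  synthesize(spec, sounds, ocular)
}

# deconvolve a session at defaults, returning the post-processed fit
recover_fit <- function(session, phasic = NULL) {
  if (is.null(phasic)) phasic <- resample_to(session$raw, 10)
  d <- build_design_matrix(session$truth$events,
                           n_samples = length(phasic$samples),
                           rate = 10, window = c(-0.5, 5),
                           event_types = c("sound_high", "sound_low",
                                           "blink", "saccade"))
  postprocess_kernels(fir_deconv(d, phasic))
}

# brute-force staggered design construction (independent oracle)
naive_design <- function(events, n_samples, rate, window, event_types) {
  L <- round((window[2] - window[1]) * rate)
  X <- matrix(0, n_samples, length(event_types) * L)
  anchors <- events$time
  bl <- events$type == "blink" & !is.na(events$duration)
  anchors[bl] <- anchors[bl] + events$duration[bl]
  for (e in seq_along(event_types)) {
    for (i in which(events$type == event_types[e])) {
      for (j in seq_len(L)) {
        lag <- window[1] + (j - 1) / rate
        r <- round((anchors[i] + lag) * rate) + 1
        if (r >= 1 && r <= n_samples) X[r, (e - 1) * L + j] <- 1
      }
    }
  }
  X
}
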