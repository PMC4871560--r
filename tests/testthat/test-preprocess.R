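test_that("blink detection finds maximal invalid runs above min_gap", {
  valid <- rep(TRUE, 2000)
  valid[501:620] <- FALSE                 # 120 ms at 1 kHz
  valid[1001:1020] <- FALSE               # 20 ms: below min_gap
  ts <- pupil_ts(rnorm(2000), 1000, valid = valid)
  bl <- detect_blinks(ts, min_gap = 0.05)
  expect_identical(nrow(bl), 1L)
  expect_equal(bl$duration, 0.120, tolerance = 1e-9)
  expect_equal(bl$time, 0.500, tolerance = 1e-3)

  expect_identical(nrow(detect_blinks(pupil_ts(rnorm(100), 100))), 0L)
  expect_error(detect_blinks(pupil_ts(1:10, 100, valid = rep(FALSE, 10))),
               "no valid samples")
})

test_that("linear signals are their own blink interpolant", {
  t <- (0:4999) / 1000
  x <- 2 * t
  valid <- rep(TRUE, 5000)
  valid[2001:2200] <- FALSE
  ts <- pupil_ts(x + ifelse(valid, 0, 99), 1000, valid = valid)
  bl <- detect_blinks(ts)
  out <- interpolate_blinks(ts, bl)
  expect_true(all(out$valid))
  expect_equal(out$samples, x, tolerance = 1e-9)
})

test_that("overlapping interpolation windows merge into one span", {
  x <- sin((0:2999) / 300)
  ts <- pupil_ts(x, 1000)
  # two blinks whose 150 ms pads overlap
  bl <- event_table(time = c(1.0, 1.25), type = c("blink", "blink"),
                    duration = c(0.1, 0.1))
  out <- interpolate_blinks(ts, bl)
  # the whole span 0.85..1.5 must be one straight line
  i <- 851:1500
  seg <- out$samples[i]
  expect_lt(max(abs(diff(diff(seg)))), 1e-12)
})

test_that("a gap covering the whole recording is an error", {
  ts <- pupil_ts(1:100, 100, valid = rep(FALSE, 100))
  bl <- event_table(0.0, "blink", duration = 1.0)
  expect_error(interpolate_blinks(ts, bl), "entire recording")
})

test_that("band-pass preserves in-band sine amplitude and kills DC", {
  t <- (0:199999) / 1000
  s <- sin(2 * pi * 1 * t)
  out <- bandpass_phasic(pupil_ts(s, 1000))
  mid <- 50000:150000
  expect_gt(max(abs(out$samples[mid])), 0.95)
  expect_lt(max(abs(out$samples[mid])), 1.05)

  const <- bandpass_phasic(pupil_ts(rep(7, 200000), 1000))
  expect_lt(max(abs(const$samples)), 7 * 1e-6)
})

test_that("out-of-band sine is attenuated at least as the analytic response", {
  t <- (0:199999) / 1000
  s <- sin(2 * pi * 10 * t)
  out <- bandpass_phasic(pupil_ts(s, 1000))
  # order-3 Butterworth magnitude at 10 Hz with 4 Hz cutoff
  H <- 1 / sqrt(1 + (10 / 4)^6)
  expect_lt(max(abs(out$samples[50000:150000])), H)
})

test_that("tonic extraction passes DC, tracks slow decay, rejects 1 Hz", {
  const <- extract_tonic(pupil_ts(rep(3.5, 400000), 1000))
  expect_lt(max(abs(const$samples - 3.5)), 1e-6)

  t <- (0:399999) / 1000
  dec <- exp(-t / 120)
  out <- extract_tonic(pupil_ts(dec, 1000))
  mid <- 40000:360000
  expect_lt(max(abs(out$samples[mid] - dec[mid]) / dec[mid]), 0.05)

  s <- sin(2 * pi * t)
  leak <- extract_tonic(pupil_ts(s, 1000))
  core <- 100000:300000                  # away from filter edge transients
  expect_lt(max(abs(leak$samples[core])), 1e-3)
})

test_that("normalization demeans per condition with one session divisor", {
  set.seed(7)
  a <- pupil_ts(rnorm(5000, 5, 2), 100)
  b <- pupil_ts(rnorm(5000, -5, 2), 100)
  out <- normalize_segments(list(a, b))
  expect_equal(mean(out[[1]]$samples), 0, tolerance = 1e-12)
  expect_equal(mean(out[[2]]$samples), 0, tolerance = 1e-12)
  # shared divisor: ratio of the segment spreads is preserved
  expect_equal(sd(out[[1]]$samples) / sd(out[[2]]$samples),
               sd(a$samples) / sd(b$samples), tolerance = 1e-9)
  # one segment, one session: unit variance
  solo <- normalize_segments(list(a))
  expect_equal(sd(solo[[1]]$samples), 1, tolerance = 1e-12)
  # scale invariance
  out10 <- normalize_segments(list(pupil_ts(a$samples * 10, 100),
                                   pupil_ts(b$samples * 10, 100)))
  expect_equal(out10[[1]]$samples, out[[1]]$samples, tolerance = 1e-9)
  expect_error(normalize_segments(list(pupil_ts(rep(1, 10), 100))),
               "degenerate")
})

test_that("resampling averages centred blocks without timing bias", {
  const <- resample_to(pupil_ts(rep(2.5, 100000), 1000), 10)
  expect_equal(const$rate, 10)
  expect_length(const$samples, 1000L)    # 100 s at 10 Hz
  expect_equal(const$samples, rep(2.5, 1000), tolerance = 1e-12)

  t <- (0:99999) / 1000
  s <- sin(2 * pi * 1 * t)
  out <- resample_to(pupil_ts(s, 1000), 10)
  grid <- (seq_along(out$samples) - 1) / 10
  # block averaging smooths by a sinc factor; compare to the smoothed sine
  att <- sin(pi * 1 * 0.1) / (pi * 1 * 0.1)
  interior <- 2:(length(grid) - 1)       # first/last blocks are half width
  expect_lt(max(abs(out$samples[interior] - att * sin(2 * pi * grid[interior]))),
            0.02)
})

test_that("non-integer rate ratios fall back to linear interpolation", {
  t <- (0:9999) / 250
  out <- resample_to(pupil_ts(2 + t, 250), 60)
  expect_equal(out$rate, 60)
  tg <- ts_times(out)
  expect_equal(out$samples, 2 + tg, tolerance = 1e-6)
})

test_that("tonic values at events are window means, z-scored per run", {
  # linear tonic ramp: analytic window means, monotone in event time
  tonic <- pupil_ts(3 * (0:9999) / 100, 100)  # slope 3 z / s
  ev <- event_table(time = c(20, 50, 80), type = rep("sound_high", 3))
  tv <- tonic_at_events(tonic, ev)
  expected <- 3 * (ev$time - 0.25 - 0.005)    # mean over [-0.5, 0) grid
  expect_equal(tv$tonic_raw, expected, tolerance = 1e-2)
  expect_true(all(diff(tv$tonic_raw) > 0))
  expect_equal(mean(tv$tonic_z), 0, tolerance = 1e-12)
  expect_equal(sd(tv$tonic_z), 1, tolerance = 1e-12)

  # constant tonic: degenerate, all-zero scores with a warning
  flat <- pupil_ts(rep(1, 10000), 100)
  expect_warning(tvf <- tonic_at_events(flat, ev), "degenerate")
  expect_equal(tvf$tonic_z, c(0, 0, 0))

  # event before recording start is excluded and reported (the single
  # surviving event also makes the run's z-scoring degenerate, which warns)
  ev2 <- event_table(time = c(-5, 50), type = rep("sound_low", 2))
  ws <- character()
  tv2 <- withCallingHandlers(
    tonic_at_events(tonic, ev2),
    warning = function(w) {
      ws <<- c(ws, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("excluded", ws)))
  expect_identical(tv2$included, c(FALSE, TRUE))
})

test_that("zero-phase filtering introduces no lag", {
  t <- (0:99999) / 1000
  s <- sin(2 * pi * 0.5 * t)
  out <- suppressWarnings(bandpass_phasic(pupil_ts(s, 1000)))  # short record
  cc <- ccf(out$samples[20000:80000], s[20000:80000], lag.max = 5,
            plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
})

test_that("phasic and tonic branches jointly reconstruct the signal", {
  set.seed(3)
  # broadband synthetic: slow drift + in-band oscillations + noise
  t <- (0:299999) / 1000
  x <- 2 * exp(-t / 100) + 0.5 * sin(2 * pi * 0.3 * t) +
    0.2 * sin(2 * pi * 2 * t) + rnorm(length(t), 0, 0.05)
  ts <- pupil_ts(x, 1000)
  cfg <- preprocess_config()
  phasic <- bandpass_phasic(ts, cfg)
  tonic <- extract_tonic(ts, cfg)
  resid <- x - phasic$samples - tonic$samples
  mid <- 30000:270000
  expect_lt(sqrt(mean(resid[mid]^2)) / sd(x), 0.10)
})

test_that("re-filtering band-passed output is a near no-op in the passband", {
  t <- (0:199999) / 1000
  s <- sin(2 * pi * 0.5 * t) + 0.5 * sin(2 * pi * 1.5 * t)
  once <- bandpass_phasic(pupil_ts(s, 1000))
  twice <- bandpass_phasic(once)
  mid <- 50000:150000
  expect_lt(max(abs(twice$samples[mid] - once$samples[mid])), 0.02)
})
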