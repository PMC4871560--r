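test_that("gamma kernel evaluates the gain-scaled gamma density", {
  k <- gamma_kernel(shape = 1, scale = 1, gain = 1)
  expect_equal(kernel_value(k, 0), 1.0)        # exponential density at 0
  expect_equal(kernel_value(k, -0.5), 0)       # zero before the event
  # unit-gain density integrates to 1 for every canonical row
  for (kk in canonical_kernels("table1")[1:4]) {
    u <- gamma_kernel(kk$shape, kk$scale, gain = 1)
    I <- integrate(function(x) kernel_value(u, x), 0, 50 * kk$shape * kk$scale,
                   rel.tol = 1e-9)$value
    expect_equal(I, 1, tolerance = 1e-6)
  }
  expect_error(gamma_kernel(-1, 1), "shape")
  expect_error(gamma_kernel(2, 0), "scale")
})

test_that("erlang kernel peaks exactly at its timing parameter", {
  k <- erlang_kernel(scale = 3.385, shape = 4.684, t_peak = 1.448)
  expect_equal(kernel_value(k, 0), 0)
  expect_identical(time_to_peak(k), 1.448)     # analytic
  # numeric argmax agrees
  g <- seq(0, 10, by = 1e-4)
  expect_lt(abs(g[which.max(kernel_value(k, g))] - 1.448), 1e-4)
  expect_error(erlang_kernel(1, -2, 1), "shape")
})

test_that("numeric time-to-peak matches the gamma closed form", {
  bn <- canonical_kernels("table1")$blink_negative
  expect_equal(time_to_peak(bn), (bn$shape - 1) * bn$scale, tolerance = 1e-4)
  aud <- canonical_kernels("table1")$auditory
  expect_equal(time_to_peak(aud), (aud$shape - 1) * aud$scale,
               tolerance = 1e-4)
})

test_that("the two canonical parameterizations describe the same responses", {
  t1 <- canonical_kernels("table1")
  t2 <- canonical_kernels("table2")
  g <- seq(0, 6, by = 1e-3)
  for (nm in c("auditory", "blink_negative", "blink_positive", "saccade")) {
    v1 <- kernel_value(t1[[nm]], g)
    v2 <- kernel_value(t2[[nm]], g)
    p1 <- g[which.max(abs(v1))]; p2 <- g[which.max(abs(v2))]
    expect_lt(abs(p1 - p2), 0.2)                              # peak times
    a1 <- v1[which.max(abs(v1))]; a2 <- v2[which.max(abs(v2))]
    expect_lt(abs(a1 - a2) / abs(a1), 0.15)                   # peak heights
    expect_identical(sign(a1), sign(a2))
  }
  # biphasic blink: negative extremum precedes the positive one
  bl <- kernel_value(t1$blink, g)
  expect_lt(g[which.min(bl)], g[which.max(bl)])
  expect_lt(min(bl), 0)
  expect_gt(max(bl), 0)
})

test_that("kernel fitting recovers known parameters and is idempotent", {
  lags <- seq(-0.5, 4.9, by = 0.1)
  aud <- canonical_kernels("table1")$auditory
  f <- fit_kernel(lags, kernel_value(aud, lags), family = "gamma")
  expect_lt(abs(coef(f)["shape"] - aud$shape) / aud$shape, 1e-3)
  expect_lt(abs(coef(f)["scale"] - aud$scale) / aud$scale, 1e-3)
  expect_lt(abs(coef(f)["gain"] - aud$gain) / aud$gain, 1e-3)

  # re-fitting the fitted curve returns the same parameters
  f2 <- fit_kernel(f$lags, predict(f), family = "gamma")
  expect_equal(coef(f2), coef(f), tolerance = 1e-6)

  er <- canonical_kernels("table2")$saccade
  fe <- fit_kernel(lags, kernel_value(er, lags), family = "erlang")
  expect_lt(abs(coef(fe)["t_peak"] - er$t_peak) / er$t_peak, 1e-3)

  bl <- canonical_kernels("table1")$blink
  fb <- fit_kernel(lags, kernel_value(bl, lags), family = "double_gamma")
  expect_lt(abs(coef(fb)["neg_gain"] - (-0.604)) / 0.604, 1e-2)
  expect_lt(abs(coef(fb)["pos_gain"] - 0.419) / 0.419, 1e-2)

  fz <- fit_kernel(lags, rep(0, 55), family = "gamma")
  expect_true(fz$degenerate)
  expect_equal(unname(coef(fz)["gain"]), 0)
})

test_that("nuisance regression removes exactly-kernel-shaped responses", {
  ck <- canonical_kernels("table1")
  rate <- 10; n <- 2400
  bl <- event_table(time = c(30, 81, 150.5, 200), type = rep("blink", 4),
                    duration = rep(0.2, 4))
  sc <- event_table(time = c(10, 50.5, 120, 180, 231), type = rep("saccade", 5))
  t <- (0:(n - 1)) / rate
  sig <- numeric(n)
  kl <- round(6 * rate)
  kv_b <- kernel_value(ck$blink, (seq_len(kl) - 1) / rate)
  for (tt in bl$time + 0.2) {
    i0 <- round(tt * rate) + 1
    sig[i0:(i0 + kl - 1)] <- sig[i0:(i0 + kl - 1)] + kv_b
  }
  res <- nuisance_clean(pupil_ts(sig, rate), bl, sc, ck)
  expect_equal(unname(res$coefficients["blink"]), 1.0, tolerance = 1e-6)
  expect_lt(sqrt(mean(res$residual$samples^2)), 1e-6)

  # no ocular events: identity transform plus warning
  expect_warning(
    id <- nuisance_clean(pupil_ts(sig, rate), event_table(), event_table()),
    "no ocular events")
  expect_equal(id$residual$samples, sig)
})

test_that("nuisance cleaning strictly reduces variance on a full session", {
  ses <- make_exact_session(seed = 9)
  ph <- resample_to(ses$raw, 10)
  ev <- ses$truth$events
  res <- nuisance_clean(ph, events_of_type(ev, "blink"),
                        events_of_type(ev, "saccade"))
  expect_lt(var(res$residual$samples), var(ph$samples))
  # the auditory response survives in the residuals
  d <- build_design_matrix(ev, n_samples = length(ph$samples), rate = 10,
                           window = c(-0.5, 5),
                           event_types = c("sound_high", "sound_low"))
  fit <- postprocess_kernels(fir_deconv(d, res$residual))
  truth <- kernel_value(canonical_kernels("table1")$auditory, fit$lags)
  # within the bounds of leftover ocular-response misfit (one amplitude per
  # class is removed, residual shape differences remain)
  expect_lt(max(abs(rowMeans(fit$kernels) - truth)), 0.1)
})

test_that("exponential decay fitting is exact on clean decays", {
  y <- decay_value(exp_decay(1, 60, 0), seq(0, 300, by = 0.1))
  f <- fit_exponential_decay(pupil_ts(y, 10))
  expect_equal(f$amplitude, 1, tolerance = 1e-3)
  expect_equal(f$tau, 60, tolerance = 60 * 1e-3)
  expect_equal(f$offset, 0, tolerance = 1e-3)

  # constant signal: amplitude collapses to ~0 (tau unidentified)
  fc <- suppressWarnings(fit_exponential_decay(pupil_ts(rep(2, 3000), 10)))
  expect_lt(abs(fc$amplitude), 1e-6)
  # non-decaying (rising ramp): tau pinned at the search bound, warned
  expect_warning(fit_exponential_decay(pupil_ts(seq(0, 1, length.out = 3000),
                                                10)),
                 "search bound")

  # noisy decay: tau within 10%
  set.seed(8)
  yn <- decay_value(exp_decay(1, 60, 0.2), seq(0, 300, by = 0.1)) +
    rnorm(3001, 0, 0.1)
  fn <- fit_exponential_decay(pupil_ts(yn, 10))
  expect_lt(abs(fn$tau - 60) / 60, 0.10)
})
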