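test_that("paper-default design has 220 columns, 55 samples per kernel", {
  ev <- event_table(time = c(10, 20, 30, 40),
                    type = c("sound_high", "sound_low", "blink", "saccade"),
                    duration = c(NA, NA, 0.1, NA))
  d <- build_design_matrix(ev, n_samples = 600, rate = 10,
                           window = c(-0.5, 5))
  expect_identical(d$L, 55L)
  expect_identical(ncol(d$values), 220L)
  expect_true(all(d$values %in% c(0, 1)))
})

test_that("a single event yields a staggered identity block", {
  ev <- event_table(time = 1.0, type = "sound_high")
  d <- build_design_matrix(ev, n_samples = 50, rate = 10,
                           window = c(0, 0.3))
  expect_identical(ncol(d$values), 3L)
  ones <- which(d$values == 1, arr.ind = TRUE)
  expect_identical(nrow(ones), 3L)
  expect_equal(unname(ones[order(ones[, 2]), 1]), c(11, 12, 13))  # consecutive rows
})

test_that("design construction matches a naive double-loop oracle", {
  set.seed(11)
  types <- c("sound_high", "blink", "saccade")
  for (i in 1:10) {
    n <- sample(80:200, 1)
    k <- sample(1:3, 1)
    ne <- sample(3:8, 1)
    ev <- event_table(time = runif(ne, 0, n / 10),
                      type = sample(types[1:k], ne, replace = TRUE),
                      duration = ifelse(runif(ne) < 0.5, NA, runif(ne, 0, 0.3)))
    w <- c(-0.2, 0.8)
    d <- suppressWarnings(        # a drawn type may have zero events
      build_design_matrix(ev, n_samples = n, rate = 10, window = w,
                          event_types = types[1:k]))
    X0 <- naive_design(ev, n, 10, w, types[1:k])
    expect_equal(unname(d$values), X0)
  }
})

test_that("FIR solve is exact for zero input and noise-free on-grid data", {
  ev <- event_table(time = c(2, 10, 17, 25), type = rep("sound_high", 4))
  d <- build_design_matrix(ev, n_samples = 320, rate = 10, window = c(-0.5, 5))
  f0 <- fir_deconv(d, rep(0, 320))
  expect_true(all(f0$kernels == 0))

  # y built by placing a known 55-sample kernel at non-overlapping events
  truth <- kernel_value(canonical_kernels("table1")$auditory, d$lags)
  y <- numeric(320)
  for (tt in ev$time) {
    rows <- round((tt + d$lags) * 10) + 1
    y[rows] <- y[rows] + truth
  }
  f <- fir_deconv(d, y)
  expect_lt(max(abs(f$kernels[, 1] - truth)), 1e-8)
})

test_that("solver matches the explicit normal-equations oracle", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(100:200, 1)
    ne <- sample(4:10, 1)
    ev <- event_table(time = sort(runif(ne, 0, n / 10 - 1)),
                      type = sample(c("a", "b"), ne, replace = TRUE))
    d <- suppressWarnings(      # a drawn type may have zero events
      build_design_matrix(ev, n_samples = n, rate = 10,
                          window = c(-0.2, 1), event_types = c("a", "b")))
    y <- rnorm(n)
    X <- d$values
    if (kappa(crossprod(X)) >= 1e8) next   # keep the oracle well posed
    f <- fir_deconv(d, y)
    h0 <- solve(crossprod(X), crossprod(X, y))
    expect_lt(max(abs(f$coefficients - drop(h0))), 1e-8)
  }
})

test_that("solve is linear in the data and residuals are orthogonal to X", {
  set.seed(5)
  ev <- event_table(time = sort(runif(12, 0, 25)),
                    type = sample(c("a", "b"), 12, replace = TRUE))
  d <- build_design_matrix(ev, n_samples = 300, rate = 10,
                           window = c(-0.5, 2), event_types = c("a", "b"))
  y1 <- rnorm(300); y2 <- rnorm(300)
  f1 <- fir_deconv(d, y1); f2 <- fir_deconv(d, y2)
  f12 <- fir_deconv(d, 2 * y1 - 3 * y2)
  expect_lt(max(abs(f12$coefficients -
                      (2 * f1$coefficients - 3 * f2$coefficients))), 1e-9)
  g <- crossprod(d$values, residuals(f1))
  expect_lt(max(abs(g)), 1e-6 * sqrt(sum(y1^2)))
})

test_that("rank-deficient designs return the minimum-norm solution", {
  # two event types with identical event times -> duplicated column blocks
  ev <- event_table(time = c(rep(c(3, 9, 15), 2)),
                    type = rep(c("a", "b"), each = 3))
  d <- build_design_matrix(ev, n_samples = 200, rate = 10,
                           window = c(0, 1), event_types = c("a", "b"))
  y <- rnorm(200)
  expect_warning(f <- fir_deconv(d, y), "rank deficient")
  # minimum-norm: both duplicated blocks share the estimate equally
  expect_equal(f$kernels[, "a"], f$kernels[, "b"], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("kernel post-processing baselines and is nearly idempotent", {
  lags <- seq(-0.5, 4.9, by = 0.1)
  const <- matrix(3, 55, 1, dimnames = list(NULL, "a"))
  out <- postprocess_kernels(const, lags = lags)
  expect_lt(max(abs(out)), 1e-9)

  smooth <- matrix(kernel_value(canonical_kernels("table1")$auditory, lags),
                   dimnames = list(NULL, "a"))
  once <- postprocess_kernels(smooth, lags = lags)
  twice <- postprocess_kernels(once, lags = lags)
  expect_lt(max(abs(twice - once)), 0.01 * max(abs(once)))

  expect_error(postprocess_kernels(smooth, lags = lags,
                                   baseline_window = c(-2, -1)),
               "baseline window")
})

test_that("variance partition sums to one and isolates single types", {
  ses <- make_exact_session(seed = 3)
  ph <- resample_to(ses$raw, 10)
  d1 <- build_design_matrix(ses$truth$events, n_samples = length(ph$samples),
                            rate = 10, window = c(-0.5, 5),
                            event_types = "saccade")
  f1 <- fir_deconv(d1, ph)
  vp1 <- variance_partition(f1)
  expect_equal(unname(vp1$fractions), 1)

  f4 <- recover_fit(ses)
  vp <- variance_partition(fir_deconv(f4$design, ph))
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-12)
  expect_true(all(vp$fractions >= 0))
})

test_that("zero-gain event types contribute a negligible variance fraction", {
  spec <- experiment_spec(run_duration = 300, noise_sd = 0, dropout = FALSE,
                          beta = 0, tonic = exp_decay(1e-9, 60, 0), seed = 4,
                          kernel_set = list(
                            auditory = canonical_kernels()$auditory,
                            blink = canonical_kernels()$blink,
                            saccade = gamma_kernel(6.451, 0.172, 1e-9)))
  ses <- simulate_session(spec)
  ph <- resample_to(ses$raw, 10)
  d <- build_design_matrix(ses$truth$events, n_samples = length(ph$samples),
                           rate = 10, window = c(-0.5, 5),
                           event_types = c("sound_high", "sound_low",
                                           "blink", "saccade"))
  vp <- variance_partition(fir_deconv(d, ph))
  expect_lt(vp$fractions["saccade"], 0.01)
})

test_that("group averaging gives zero SEM for identical subjects", {
  ses <- make_exact_session(seed = 2, run_duration = 120)
  f <- recover_fit(ses)
  ga <- group_average(list(f, f, f))
  expect_equal(ga$mean, f$kernels, tolerance = 1e-12)
  expect_true(all(ga$sem == 0))
  ga2 <- group_average(list(f$kernels, -f$kernels))
  expect_true(all(abs(ga2$mean) < 1e-12))
  g <- f; g$lags <- g$lags + 0.05
  expect_error(group_average(list(f, g)), "lag axes")
})
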