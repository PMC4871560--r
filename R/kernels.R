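#' Gamma-density impulse-response kernel
#'
#' The pupil impulse response is modelled as a gain-scaled gamma
#' probability density:
#' \deqn{v(x) = gain \cdot \frac{x^{k-1} e^{-x/\theta}}{\theta^k \Gamma(k)},
#'   \quad x \ge 0}
#' and 0 for `x < 0`. The gain multiplies the *normalized* density, so
#' the kernel integrates to `gain`; with this convention the gamma and
#' Erlang-gamma canonical parameter sets describe the same curves.
#'
#' @param shape shape parameter k, > 0 (dimensionless).
#' @param scale scale parameter theta, > 0 (seconds).
#' @param gain signed multiplicative gain in z-units (area under the
#'   kernel).
#' @return an object of class `gamma_kernel`.
#' @export
gamma_kernel <- function(shape, scale, gain = 1) {
  if (!is.finite(shape) || shape <= 0) stop("gamma_kernel: shape must be > 0")
  if (!is.finite(scale) || scale <= 0) stop("gamma_kernel: scale must be > 0")
  structure(list(shape = shape, scale = scale, gain = gain),
            class = c("gamma_kernel", "pupil_kernel"))
}

#' Erlang-gamma impulse-response kernel
#'
#' Unnormalized parameterization
#' \deqn{v(x) = s \, x^{n} e^{-n x / x_{max}}, \quad x \ge 0}
#' whose extremum of |v| lies exactly at `x = t_peak`, making the timing
#' parameter directly interpretable.
#'
#' @param scale signed, unnormalized scale s.
#' @param shape shape n, > 0.
#' @param t_peak time to peak in seconds, > 0.
#' @return an object of class `erlang_kernel`.
#' @export
erlang_kernel <- function(scale, shape, t_peak) {
  if (!is.finite(shape) || shape <= 0) stop("erlang_kernel: shape must be > 0")
  if (!is.finite(t_peak) || t_peak <= 0)
    stop("erlang_kernel: t_peak must be > 0")
  structure(list(scale = scale, shape = shape, t_peak = t_peak),
            class = c("erlang_kernel", "pupil_kernel"))
}

#' Double-gamma (biphasic) kernel
#'
#' Sum of a fast negative and a slower positive gamma component, used
#' for the biphasic blink response. The negative component's mode must
#' precede the positive component's mode.
#'
#' @param negative a [gamma_kernel()] with `gain < 0`.
#' @param positive a [gamma_kernel()] with `gain > 0`.
#' @return an object of class `double_gamma_kernel`.
#' @export
double_gamma_kernel <- function(negative, positive) {
  stopifnot(inherits(negative, "gamma_kernel"),
            inherits(positive, "gamma_kernel"))
  if (negative$gain >= 0 || positive$gain <= 0)
    stop("double_gamma_kernel: component gains must be negative / positive")
  if (gamma_mode(negative) >= gamma_mode(positive))
    stop("double_gamma_kernel: negative component's mode must precede ",
         "the positive component's mode")
  structure(list(negative = negative, positive = positive),
            class = c("double_gamma_kernel", "composite_kernel",
                      "pupil_kernel"))
}

#' Additive combination of kernels
#'
#' @param ... `pupil_kernel` objects.
#' @return an object of class `composite_kernel` whose value is the sum
#'   of its components.
#' @export
kernel_sum <- function(...) {
  comps <- list(...)
  stopifnot(all(vapply(comps, inherits, logical(1), "pupil_kernel")))
  structure(list(components = comps),
            class = c("composite_kernel", "pupil_kernel"))
}

#' Exponential decay model for tonic pupil size
#'
#' `value(t) = amplitude * exp(-t / tau) + offset`, used to describe the
#' slow fall of tonic pupil size over the course of a recording run.
#'
#' @param amplitude initial amplitude above the asymptote, z-units.
#' @param tau decay time constant in seconds, > 0.
#' @param offset asymptotic level, z-units.
#' @return an object of class `exp_decay`.
#' @export
exp_decay <- function(amplitude, tau, offset = 0) {
  if (!is.finite(tau) || tau <= 0) stop("exp_decay: tau must be > 0")
  structure(list(amplitude = amplitude, tau = tau, offset = offset),
            class = "exp_decay")
}

#' Evaluate an exponential decay
#' @param decay an [exp_decay()].
#' @param t times in seconds.
#' @return numeric vector of values.
#' @export
decay_value <- function(decay, t) {
  decay$amplitude * exp(-t / decay$tau) + decay$offset
}

# closed-form mode of a gamma-density kernel
gamma_mode <- function(k) if (k$shape > 1) (k$shape - 1) * k$scale else 0

#' Evaluate a kernel at given times
#'
#' @param kernel a `pupil_kernel` object.
#' @param x times in seconds (kernels are 0 for `x < 0`).
#' @return numeric vector of kernel values (z-units).
#' @export
kernel_value <- function(kernel, x) UseMethod("kernel_value")

#' @export
kernel_value.gamma_kernel <- function(kernel, x) {
  out <- numeric(length(x))
  ok <- x >= 0 & is.finite(x)
  out[ok] <- kernel$gain *
    stats::dgamma(x[ok], shape = kernel$shape, scale = kernel$scale)
  out
}

#' @export
kernel_value.erlang_kernel <- function(kernel, x) {
  out <- numeric(length(x))
  ok <- x >= 0 & is.finite(x)
  out[ok] <- kernel$scale * x[ok]^kernel$shape *
    exp(-kernel$shape * x[ok] / kernel$t_peak)
  out
}

#' @export
kernel_value.composite_kernel <- function(kernel, x) {
  comps <- if (inherits(kernel, "double_gamma_kernel"))
    list(kernel$negative, kernel$positive) else kernel$components
  Reduce(`+`, lapply(comps, kernel_value, x = x))
}

#' @export
print.pupil_kernel <- function(x, ...) {
  cat("<", class(x)[1], "> ", sep = "")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Time to peak of a kernel
#'
#' Location of the global extremum of |value| on `[0, 20]` s. For
#' [erlang_kernel()] this is the analytic `t_peak`; for other kernels it
#' is found by a grid search refined by golden-section optimization to
#' 1e-4 s.
#'
#' @param kernel a `pupil_kernel`.
#' @param upper upper search bound in seconds (default 20).
#' @return peak time in seconds.
#' @export
time_to_peak <- function(kernel, upper = 20) UseMethod("time_to_peak")

#' @export
time_to_peak.erlang_kernel <- function(kernel, upper = 20) kernel$t_peak

#' @export
time_to_peak.pupil_kernel <- function(kernel, upper = 20) {
  grid <- seq(0, upper, by = 1e-3)
  av <- abs(kernel_value(kernel, grid))
  i <- which.max(av)
  lo <- grid[max(1L, i - 2L)]
  hi <- grid[min(length(grid), i + 2L)]
  stats::optimize(function(t) -abs(kernel_value(kernel, t)),
                  interval = c(lo, hi), tol = 1e-6)$minimum
}

#' Canonical pupil-response kernel sets
#'
#' Published parameter constants for the four event-locked pupil
#' response profiles (auditory event, negative and positive blink
#' components, saccade), in two equivalent parameterizations: gamma
#' probability densities with gain (`"table1"`) or unnormalized
#' Erlang-gamma curves (`"table2"`). The `blink` entry combines the two
#' blink components into one biphasic kernel.
#'
#' @param parameterization `"table1"` (gamma density + gain) or
#'   `"table2"` (Erlang-gamma).
#' @return named list of kernels: `auditory`, `blink_negative`,
#'   `blink_positive`, `saccade`, `blink`.
#' @export
canonical_kernels <- function(parameterization = c("table1", "table2")) {
  parameterization <- match.arg(parameterization)
  if (parameterization == "table1") {
    auditory <- gamma_kernel(shape = 5.078, scale = 0.314, gain = 0.3)
    blink_neg <- gamma_kernel(shape = 8.337, scale = 0.115, gain = -0.604)
    blink_pos <- gamma_kernel(shape = 15.433, scale = 0.178, gain = 0.419)
    saccade <- gamma_kernel(shape = 6.451, scale = 0.172, gain = -0.175)
    blink <- double_gamma_kernel(blink_neg, blink_pos)
  } else {
    auditory <- erlang_kernel(scale = 3.385, shape = 4.684, t_peak = 1.448)
    blink_neg <- erlang_kernel(scale = -6661.622, shape = 7.751,
                               t_peak = 0.844)
    blink_pos <- erlang_kernel(scale = 0.823, shape = 17.061, t_peak = 2.540)
    saccade <- erlang_kernel(scale = -8.969, shape = 3.737, t_peak = 0.917)
    blink <- kernel_sum(blink_neg, blink_pos)
  }
  list(auditory = auditory, blink_negative = blink_neg,
       blink_positive = blink_pos, saccade = saccade, blink = blink)
}

## ---------------------------------------------------------------------
## Nonlinear least-squares kernel fitting. Shape parameters are searched
## by Nelder-Mead on log scale from a fixed set of deterministic starts;
## the linear amplitude parameters (gain / scale) are profiled out
## analytically at every evaluation, so fits are reproducible
## bit-for-bit for identical input.

profile_gain <- function(y, g) {
  den <- sum(g * g)
  if (den == 0) 0 else sum(y * g) / den
}

fit_gamma_ls <- function(x, y, starts) {
  obj <- function(p) {
    k <- exp(p[1]); th <- exp(p[2])
    g <- stats::dgamma(x, shape = k, scale = th)
    gain <- profile_gain(y, g)
    sum((y - gain * g)^2)
  }
  best <- NULL
  for (s in starts) {
    o <- stats::optim(log(s), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  k <- exp(best$par[1]); th <- exp(best$par[2])
  g <- stats::dgamma(x, shape = k, scale = th)
  gain <- profile_gain(y, g)
  list(kernel = gamma_kernel(k, th, gain), rss = best$value,
       converged = best$convergence == 0)
}

fit_erlang_ls <- function(x, y, starts) {
  obj <- function(p) {
    n <- exp(p[1]); tp <- exp(p[2])
    g <- ifelse(x > 0, x^n * exp(-n * x / tp), 0)
    if (any(!is.finite(g))) return(1e30)
    s <- profile_gain(y, g)
    sum((y - s * g)^2)
  }
  best <- NULL
  for (st in starts) {
    o <- stats::optim(log(st), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  n <- exp(best$par[1]); tp <- exp(best$par[2])
  g <- ifelse(x > 0, x^n * exp(-n * x / tp), 0)
  s <- profile_gain(y, g)
  list(kernel = erlang_kernel(s, n, tp), rss = best$value,
       converged = best$convergence == 0)
}

fit_double_gamma_ls <- function(x, y, starts) {
  obj <- function(p) {
    k1 <- exp(p[1]); t1 <- exp(p[2]); k2 <- exp(p[3]); t2 <- exp(p[4])
    if ((k1 - 1) * t1 >= (k2 - 1) * t2) return(1e30)  # mode ordering
    g1 <- stats::dgamma(x, shape = k1, scale = t1)
    g2 <- stats::dgamma(x, shape = k2, scale = t2)
    G <- cbind(g1, g2)
    co <- tryCatch(qr.solve(crossprod(G), crossprod(G, y)),
                   error = function(e) NULL)
    if (is.null(co) || co[1] >= 0 || co[2] <= 0) return(1e30)  # sign constraint
    sum((y - G %*% co)^2)
  }
  best <- NULL
  for (st in starts) {
    o <- stats::optim(log(st), obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (best$value >= 1e30)
    stop("fit_kernel: double-gamma fit failed from every start ",
         "(constraints unsatisfiable on this input)")
  k1 <- exp(best$par[1]); t1 <- exp(best$par[2])
  k2 <- exp(best$par[3]); t2 <- exp(best$par[4])
  G <- cbind(stats::dgamma(x, shape = k1, scale = t1),
             stats::dgamma(x, shape = k2, scale = t2))
  co <- qr.solve(crossprod(G), crossprod(G, y))
  list(kernel = double_gamma_kernel(gamma_kernel(k1, t1, co[1]),
                                    gamma_kernel(k2, t2, co[2])),
       rss = best$value, converged = best$convergence == 0)
}

# deterministic multi-start initializations for the shape search
gamma_starts <- function(x, y) {
  ay <- abs(y); sw <- sum(ay)
  starts <- list(c(5.078, 0.314), c(6.451, 0.172),   # canonical auditory/saccade
                 c(2, 0.5), c(10, 0.1))
  if (sw > 0) {
    m <- sum(x * ay) / sw
    v <- sum((x - m)^2 * ay) / sw
    if (m > 0 && v > 0)
      starts <- c(list(c(max(m^2 / v, 0.5), max(v / m, 1e-3))), starts)
  }
  tp <- x[which.max(ay)]
  if (tp > 0) starts <- c(starts, list(c(4, tp / 3), c(8, tp / 7)))
  starts
}

#' Fit a parametric kernel to an observed response profile
#'
#' Least-squares fit of a gamma, Erlang-gamma or double-gamma model to a
#' lag-indexed response (e.g. a deconvolved FIR kernel), restricted to
#' lags >= 0. Shape parameters are optimized from several deterministic
#' moment-based and canonical starting points; amplitude parameters are
#' profiled out analytically, so the fit is fully reproducible.
#' Double-gamma fits enforce negative-then-positive component ordering.
#'
#' @param lags lag axis in seconds (>= 10 points spanning the response).
#' @param values observed response at each lag, z-units.
#' @param family `"gamma"`, `"erlang"` or `"double_gamma"`.
#' @return an object of class `kernel_fit`: list with `kernel` (the
#'   fitted `pupil_kernel`), `family`, `rss`, `rms`, `lags`, `observed`,
#'   `fitted`, `degenerate` and `converged`.
#' @export
fit_kernel <- function(lags, values,
                       family = c("gamma", "erlang", "double_gamma")) {
  family <- match.arg(family)
  stopifnot(length(lags) == length(values))
  keep <- lags >= 0
  x <- lags[keep]; y <- values[keep]
  if (length(x) < 10)
    stop("fit_kernel: need at least 10 non-negative lag points")
  degenerate <- FALSE
  if (all(abs(y) < 1e-12)) {
    degenerate <- TRUE
    fit <- switch(family,
      gamma = list(kernel = gamma_kernel(2, 0.5, 0), rss = 0, converged = TRUE),
      erlang = list(kernel = erlang_kernel(0, 2, 1), rss = 0, converged = TRUE),
      double_gamma = list(
        kernel = double_gamma_kernel(gamma_kernel(8.337, 0.115, -1e-12),
                                     gamma_kernel(15.433, 0.178, 1e-12)),
        rss = 0, converged = TRUE))
  } else {
    fit <- switch(family,
      gamma = fit_gamma_ls(x, y, gamma_starts(x, y)),
      erlang = {
        tp <- max(x[which.max(abs(y))], 0.2)
        fit_erlang_ls(x, y, list(c(4.684, 1.448), c(3.737, 0.917),
                                 c(3, tp), c(8, tp), c(15, tp),
                                 c(5, tp * 1.5)))
      },
      double_gamma = {
        base <- c(8.337, 0.115, 15.433, 0.178)
        fit_double_gamma_ls(x, y, list(
          base,
          base * c(1, 0.75, 1, 0.75), base * c(1, 1.25, 1, 1.25),
          base * c(0.7, 1, 0.7, 1), base * c(1.3, 1, 1.3, 1),
          c(6, 0.15, 10, 0.3), c(10, 0.1, 20, 0.15),
          base * c(1.15, 0.85, 0.85, 1.15)))
      })
  }
  fitted <- kernel_value(fit$kernel, x)
  structure(list(kernel = fit$kernel, family = family, rss = fit$rss,
                 rms = sqrt(mean((y - fitted)^2)), lags = x, observed = y,
                 fitted = fitted, degenerate = degenerate,
                 converged = fit$converged),
            class = "kernel_fit")
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf("<kernel_fit> family '%s', rms %.4g%s%s\n", x$family, x$rms,
              if (x$degenerate) " (degenerate input)" else "",
              if (!x$converged) " (not converged)" else ""))
  print(x$kernel)
  invisible(x)
}

#' @export
coef.kernel_fit <- function(object, ...) {
  k <- object$kernel
  switch(object$family,
    gamma = c(shape = k$shape, scale = k$scale, gain = k$gain),
    erlang = c(scale = k$scale, shape = k$shape, t_peak = k$t_peak),
    double_gamma = c(neg_shape = k$negative$shape, neg_scale = k$negative$scale,
                     neg_gain = k$negative$gain, pos_shape = k$positive$shape,
                     pos_scale = k$positive$scale, pos_gain = k$positive$gain))
}

#' @export
predict.kernel_fit <- function(object, newlags = object$lags, ...) {
  kernel_value(object$kernel, newlags)
}

#' @export
plot.kernel_fit <- function(x, ...) {
  graphics::plot(x$lags, x$observed, type = "p", pch = 16, cex = 0.6,
                 xlab = "lag (s)", ylab = "response (z)", ...)
  fine <- seq(min(x$lags), max(x$lags), length.out = 400)
  graphics::lines(fine, kernel_value(x$kernel, fine), col = "grey40", lwd = 2)
  invisible(x)
}

#' Fit an exponential decay to a tonic pupil trace
#'
#' Fits `amplitude * exp(-t / tau) + offset` by least squares. Given
#' `tau`, the amplitude and offset are linear and solved exactly, so
#' only `tau` is searched (golden-section on log scale), initialized
#' from head/tail means and the log-linear slope. For a non-decaying
#' input the fit is returned with `tau` at the search bound and a
#' warning.
#'
#' @param tonic a [pupil_ts()] (or numeric vector with `rate`).
#' @param rate sampling rate in Hz when `tonic` is a plain vector.
#' @return an [exp_decay()] with attributes `rss` and `rms`.
#' @export
fit_exponential_decay <- function(tonic, rate = NULL) {
  if (inherits(tonic, "pupil_ts")) {
    y <- tonic$samples
    t <- ts_times(tonic) - tonic$start_time
  } else {
    stopifnot(!is.null(rate))
    y <- as.numeric(tonic)
    t <- (seq_along(y) - 1) / rate
  }
  n <- length(y)
  stopifnot(n >= 10)
  dur <- t[n]
  sse_for <- function(ltau) {
    b <- exp(-t / exp(ltau))
    X <- cbind(1, b)
    co <- qr.solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% co)^2)
  }
  lo <- log(dur / 200); hi <- log(dur * 10)
  opt <- stats::optimize(sse_for, interval = c(lo, hi), tol = 1e-10)
  tau <- exp(opt$minimum)
  b <- exp(-t / tau)
  X <- cbind(1, b)
  co <- drop(qr.solve(crossprod(X), crossprod(X, y)))
  if (opt$minimum > hi - 1e-3 || opt$minimum < lo + 1e-3)
    warning("fit_exponential_decay: tau at search bound; ",
            "input may not be an exponential decay")
  out <- exp_decay(amplitude = unname(co[2]), tau = tau,
                   offset = unname(co[1]))
  attr(out, "rss") <- opt$objective
  attr(out, "rms") <- sqrt(opt$objective / n)
  out
}

#' Regress blink and saccade responses out of the phasic signal
#'
#' Builds one regressor per ocular event class by convolving the event
#' impulse train (blinks anchored at blink offset) with the
#' corresponding kernel shape truncated at 6 s, adds an intercept, and
#' solves ordinary least squares. The fitted coefficients are relative
#' amplitudes: a coefficient of 1 means the data carry the kernel at
#' exactly its stated gain. The residuals retain everything the ocular
#' regressors cannot explain and are the recommended input for
#' cognitive analyses.
#'
#' @param phasic band-passed [pupil_ts()].
#' @param blink_events,saccade_events [event_table()]s (may be empty).
#' @param kernels named kernel list with `blink` and `saccade` entries;
#'   default [canonical_kernels()]`("table1")`.
#' @param support kernel support for the convolution regressors,
#'   seconds (default 6).
#' @return list with `residual` ([pupil_ts()]), `coefficients` (named:
#'   intercept, blink, saccade), and `fitted` (numeric vector).
#' @export
nuisance_clean <- function(phasic, blink_events, saccade_events,
                           kernels = canonical_kernels("table1"),
                           support = 6) {
  stopifnot(inherits(phasic, "pupil_ts"))
  n <- length(phasic$samples)
  make_reg <- function(events, kernel) {
    if (is.null(events) || nrow(events) == 0) return(NULL)
    anchors <- event_anchor_times(events) - phasic$start_time
    kl <- as.integer(round(support * phasic$rate))
    kv <- kernel_value(kernel, (seq_len(kl) - 1) / phasic$rate)
    reg <- numeric(n)
    for (a in anchors) {
      i0 <- as.integer(round(a * phasic$rate)) + 1L
      if (i0 > n) next
      j <- max(1L, i0):min(n, i0 + kl - 1L)
      reg[j] <- reg[j] + kv[j - i0 + 1L]
    }
    reg
  }
  rb <- make_reg(blink_events, kernels$blink)
  rs <- make_reg(saccade_events, kernels$saccade)
  if (is.null(rb) && is.null(rs)) {
    warning("nuisance_clean: no ocular events; returning input unchanged")
    return(list(residual = phasic,
                coefficients = c(intercept = 0, blink = NA, saccade = NA),
                fitted = numeric(n)))
  }
  X <- cbind(intercept = rep(1, n), blink = rb, saccade = rs)
  fit <- stats::lm.fit(X, phasic$samples)
  co <- c(intercept = unname(fit$coefficients["intercept"]),
          blink = if (is.null(rb)) NA_real_
                  else unname(fit$coefficients["blink"]),
          saccade = if (is.null(rs)) NA_real_
                    else unname(fit$coefficients["saccade"]))
  list(residual = pupil_ts(fit$residuals, phasic$rate, phasic$start_time,
                           units = phasic$units),
       coefficients = co,
       fitted = drop(X %*% ifelse(is.na(fit$coefficients), 0,
                                  fit$coefficients)))
}
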