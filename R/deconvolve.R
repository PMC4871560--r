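#' Build a staggered FIR design matrix
#'
#' One indicator column per (event type, lag) pair. For an event at time
#' `t` and lag `lag_j = window[1] + j / rate` (j = 0, ..., L-1), the row
#' at sample index `round((t + lag_j) * rate)` (0-based) of column
#' `(type, j)` is set to 1 when it falls inside the recording; rows
#' outside are simply not set (truncation at the edges). Column order is
#' deterministic: event types in the order given, lags ascending. With
#' four event types and a window of -0.5 to 5 s at 10 Hz the design has
#' 55 samples per kernel and 220 columns.
#'
#' @param events an [event_table()]. Blink rows are anchored at blink
#'   offset (`time + duration`); saccade rows are assumed to be recorded
#'   at saccade offset already.
#' @param n_samples number of rows (signal length at `rate`).
#' @param rate analysis sampling rate in Hz (default 10).
#' @param window kernel window in seconds, half-open `[start, end)`
#'   (default `c(-0.5, 5)`).
#' @param event_types character vector fixing type order; defaults to
#'   the types present, in order of first appearance. A type with zero
#'   events yields an all-zero column block and a warning.
#' @return an object of class `fir_design`: list with `values`
#'   (n_samples x (E*L) 0/1 matrix), `event_types`, `window`, `rate`,
#'   `L`, `lags`.
#' @export
build_design_matrix <- function(events, n_samples, rate = 10,
                                window = c(-0.5, 5),
                                event_types = unique(events$type)) {
  if (n_samples <= 0) stop("build_design_matrix: n_samples must be > 0")
  stopifnot(length(window) == 2, window[1] < window[2])
  if (nrow(events) == 0) stop("build_design_matrix: no events")
  L <- as.integer(round((window[2] - window[1]) * rate))
  lags <- window[1] + (seq_len(L) - 1) / rate
  E <- length(event_types)
  X <- matrix(0, nrow = n_samples, ncol = E * L)
  anchors <- event_anchor_times(events)
  for (e in seq_len(E)) {
    tt <- anchors[events$type == event_types[e]]
    if (length(tt) == 0) {
      warning("build_design_matrix: no events of type '", event_types[e],
              "'; zero column block")
      next
    }
    for (j in seq_len(L)) {
      rows <- as.integer(round((tt + lags[j]) * rate)) + 1L
      rows <- rows[rows >= 1L & rows <= n_samples]
      if (length(rows)) X[rows, (e - 1L) * L + j] <- 1
    }
  }
  colnames(X) <- paste0(rep(event_types, each = L), "@",
                        sprintf("%.2f", rep(lags, E)))
  structure(list(values = X, event_types = event_types, window = window,
                 rate = rate, L = L, lags = lags),
            class = "fir_design")
}

#' @export
print.fir_design <- function(x, ...) {
  cat(sprintf("<fir_design> %d x %d (%d types x %d lags, window [%g, %g) s @ %g Hz)\n",
              nrow(x$values), ncol(x$values), length(x$event_types), x$L,
              x$window[1], x$window[2], x$rate))
  invisible(x)
}

#' Least-squares FIR deconvolution of event-locked pupil responses
#'
#' Estimates the response kernel of every event type simultaneously by
#' solving the least-squares problem `min ||y - X h||^2` for the
#' staggered indicator design `X`; the solution is the classical
#' `h = (X'X)^{-1} X'y`, computed through the singular value
#' decomposition of `X`. When the design is rank deficient or
#' ill-conditioned (condition number above `cond_tol`), small singular
#' values are dropped, the minimum-norm solution is returned, and a rank
#' warning is emitted. Because all event types are estimated jointly,
#' linear contamination of cognitive responses by overlapping blink and
#' saccade responses is removed.
#'
#' @param design a [build_design_matrix()] result, or an
#'   [event_table()] (the design is then built with `...` passed on).
#' @param y a [pupil_ts()] at the design rate, or a numeric vector with
#'   `length == nrow(design$values)`.
#' @param cond_tol condition-number threshold for the minimum-norm
#'   fallback (default 1e10).
#' @param ... passed to [build_design_matrix()] when `design` is an
#'   event table.
#' @return an object of class `fir_fit`: kernel matrix (`L` lags x
#'   types), lag axis, fitted values, residuals, `r_squared`, per-type
#'   explained-variance fractions, and the design.
#' @export
fir_deconv <- function(design, y, cond_tol = 1e10, ...) {
  if (inherits(y, "pupil_ts")) yv <- y$samples else yv <- as.numeric(y)
  if (inherits(design, "event_table"))
    design <- build_design_matrix(design, n_samples = length(yv), ...)
  stopifnot(inherits(design, "fir_design"))
  X <- design$values
  if (length(yv) != nrow(X))
    stop("fir_deconv: length(y) (", length(yv),
         ") does not match design rows (", nrow(X), ")")
  sv <- svd(X)
  d <- sv$d
  keep <- d > d[1] / cond_tol
  if (!all(keep))
    warning("fir_deconv: design is rank deficient or ill-conditioned; ",
            "returning the minimum-norm solution (dropped ",
            sum(!keep), " singular values)")
  h <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], yv)) / d[keep])
  h <- drop(h)
  fitted <- drop(X %*% h)
  resid <- yv - fitted
  K <- matrix(h, nrow = design$L, ncol = length(design$event_types))
  colnames(K) <- design$event_types
  vy <- stats::var(yv)
  structure(
    list(kernels = K, lags = design$lags,
         event_types = design$event_types, design = design, y = yv,
         coefficients = h, fitted = fitted, residuals = resid,
         r_squared = if (vy > 0) 1 - stats::var(resid) / vy else NA_real_,
         sigma = stats::sd(resid),
         rank_deficient = !all(keep)),
    class = "fir_fit")
}

#' @export
print.fir_fit <- function(x, ...) {
  cat(sprintf("<fir_fit> %d event types x %d lags (window [%g, %g) s @ %g Hz)\n",
              ncol(x$kernels), nrow(x$kernels),
              x$design$window[1], x$design$window[2], x$design$rate))
  cat(sprintf("  R^2 = %.4f, residual sd = %.4g%s\n", x$r_squared, x$sigma,
              if (x$rank_deficient) " [rank deficient]" else ""))
  cat("  types:", paste(x$event_types, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.fir_fit <- function(object, ...) object$kernels

#' @export
fitted.fir_fit <- function(object, ...) object$fitted

#' @export
residuals.fir_fit <- function(object, ...) object$residuals

#' @export
summary.fir_fit <- function(object, ...) {
  vp <- variance_partition(object)
  peaks <- apply(object$kernels, 2, function(k) {
    i <- which.max(abs(k)); c(peak = k[i], t_peak = object$lags[i])
  })
  out <- list(fit = object, variance_partition = vp, peaks = t(peaks))
  class(out) <- "summary.fir_fit"
  out
}

#' @export
print.summary.fir_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-type peak and timing:\n")
  print(round(x$peaks, 4))
  cat("\nExplained-variance fractions:\n")
  print(round(x$variance_partition$fractions, 4))
  cat(sprintf("Total R^2: %.4f\n", x$variance_partition$r_squared))
  invisible(x)
}

#' @export
plot.fir_fit <- function(x, types = x$event_types, ...) {
  graphics::matplot(x$lags, x$kernels[, types, drop = FALSE], type = "l",
                    lty = 1, xlab = "lag (s)", ylab = "response (z)", ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  graphics::legend("topright", legend = types, lty = 1,
                   col = seq_along(types), bty = "n")
  invisible(x)
}

#' Post-process estimated kernels
#'
#' Low-passes every kernel (zero-phase Butterworth, default 4 Hz cutoff,
#' order 3) and subtracts the mean over the baseline window (default
#' -0.5 to 0 s before the event) so every kernel starts from a zero
#' baseline.
#'
#' @param fit a `fir_fit` (returned modified), or a numeric kernel
#'   matrix with `lags` supplied.
#' @param lowpass low-pass cutoff in Hz (default 4).
#' @param baseline_window length-2 numeric, seconds (default
#'   `c(-0.5, 0)`); must lie within the kernel window.
#' @param lags lag axis when `fit` is a plain matrix.
#' @param order filter order (default 3).
#' @return same class as `fit`, with kernels filtered and baselined.
#' @export
postprocess_kernels <- function(fit, lowpass = 4, baseline_window = c(-0.5, 0),
                                lags = NULL, order = 3) {
  is_fit <- inherits(fit, "fir_fit")
  K <- if (is_fit) fit$kernels else as.matrix(fit)
  if (is_fit) lags <- fit$lags
  stopifnot(!is.null(lags), nrow(K) == length(lags))
  rate <- 1 / stats::median(diff(lags))
  if (baseline_window[1] < min(lags) - 1e-9 ||
      baseline_window[2] > max(lags) + 1 / rate + 1e-9)
    stop("postprocess_kernels: baseline window outside the kernel window")
  bl <- lags >= baseline_window[1] & lags < baseline_window[2]
  if (!any(bl)) stop("postprocess_kernels: empty baseline window")
  out <- apply(K, 2, function(k) {
    if (lowpass < rate / 2) k <- zerophase_lowpass(k, rate, lowpass, order)
    k - mean(k[bl])
  })
  out <- matrix(out, nrow = nrow(K), dimnames = dimnames(K))
  if (is_fit) {
    fit$kernels <- out
    fit
  } else out
}

#' Per-event-type explained-variance partition
#'
#' Quantifies how much of the variance explained by the FIR model each
#' event type contributes: `fraction_c = Var(X_c h_c) / sum_c' Var(X_c'
#' h_c')`, where `X_c h_c` is the fitted contribution of type `c`.
#' Covariance cross-terms between types are excluded, so the fractions
#' are non-negative and sum to 1; total R-squared is reported
#' separately.
#'
#' @param fit a `fir_fit`.
#' @return list with `fractions` (named, sums to 1), `variances` (raw
#'   per-type fitted-contribution variances), `r_squared`, and
#'   `formula` (a note on the convention used).
#' @export
variance_partition <- function(fit) {
  stopifnot(inherits(fit, "fir_fit"))
  L <- fit$design$L
  v <- vapply(seq_along(fit$event_types), function(e) {
    cols <- (e - 1L) * L + seq_len(L)
    stats::var(drop(fit$design$values[, cols, drop = FALSE] %*%
                      fit$coefficients[cols]))
  }, numeric(1))
  names(v) <- fit$event_types
  tot <- sum(v)
  if (tot <= 0) stop("variance_partition: zero total explained variance")
  list(fractions = v / tot, variances = v, r_squared = fit$r_squared,
       formula = "per-type fitted-contribution variance / sum over types; covariance cross-terms excluded")
}

#' Average kernel estimates across subjects
#'
#' @param fits list of `fir_fit` objects (or kernel matrices with
#'   identical dimensions) from >= 2 subjects with identical lag axes.
#' @return list with `mean` and `sem` matrices (lags x types) and
#'   `lags`.
#' @export
group_average <- function(fits) {
  stopifnot(length(fits) >= 2)
  get_k <- function(f) if (inherits(f, "fir_fit")) f$kernels else as.matrix(f)
  get_l <- function(f) if (inherits(f, "fir_fit")) f$lags else NULL
  lags <- get_l(fits[[1]])
  Ks <- lapply(fits, get_k)
  dims <- vapply(Ks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("group_average: mismatched kernel dimensions")
  for (f in fits) {
    l <- get_l(f)
    if (!is.null(lags) && !is.null(l) && max(abs(l - lags)) > 1e-9)
      stop("group_average: mismatched lag axes")
  }
  arr <- simplify2array(Ks)                       # lags x types x subjects
  m <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), stats::sd) / sqrt(length(fits))
  dimnames(m) <- dimnames(Ks[[1]])
  dimnames(s) <- dimnames(Ks[[1]])
  list(mean = m, sem = s, lags = lags, n = length(fits))
}
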