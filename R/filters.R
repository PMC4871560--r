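# Zero-phase Butterworth filtering.
#
# All filtering in the package is forward-backward (zero-phase), so that
# event-locked kernel timing is not biased by causal filter lag. Two
# numerical precautions on top of signal::butter:
#
#  * each pass is initialized at the steady state implied by the first
#    sample, and the signal is padded by odd reflection, so constants and
#    slow trends pass a low-pass without multi-minute edge transients;
#  * for cutoffs far below the Nyquist frequency (normalized cutoff
#    < 0.01, e.g. 0.02 Hz at 1000 Hz sampling) the transfer-function
#    coefficients become numerically degenerate, so the signal is first
#    block-averaged down to an internal rate where the normalized cutoff
#    is well conditioned, filtered there, and linearly interpolated back
#    onto the original grid. Content above the internal Nyquist is, by
#    construction, in the filter's deep stop band.

# one steady-state-initialized forward pass of a low-pass filter
lp_forward_pass <- function(flt, x) {
  k <- length(flt$a) - 1
  as.numeric(signal::filter(flt, x,
                            init.x = rep(x[1], k),
                            init.y = rep(x[1], k)))
}

#' Zero-phase low-pass Butterworth filter
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz (0 < cutoff < rate/2).
#' @param order filter order (per pass; default 3).
#' @return filtered numeric vector, same length as `x`.
#' @export
zerophase_lowpass <- function(x, rate, cutoff, order = 3) {
  stopifnot(is.numeric(x), length(x) > 1, cutoff > 0, cutoff < rate / 2,
            order >= 1)
  wn <- cutoff / (rate / 2)
  if (wn < 0.01) {
    dec <- max(1L, min(as.integer(0.01 * (rate / 2) / cutoff),
                       as.integer(rate / (8 * cutoff))))
    if (dec > 1L) {
      n <- length(x)
      nd <- n %/% dec
      if (nd < 8)
        stop("zerophase_lowpass: record too short for cutoff ", cutoff, " Hz")
      xd <- colMeans(matrix(x[seq_len(nd * dec)], nrow = dec))
      yd <- zerophase_lowpass(xd, rate / dec, cutoff, order)
      td <- (seq_len(nd) - 0.5) * dec / rate
      return(stats::approx(td, yd, xout = (seq_len(n) - 1) / rate,
                           rule = 2)$y)
    }
  }
  flt <- signal::butter(order, wn, type = "low")
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(3 * rate / cutoff)))
  xp <- if (pad > 0)
    c(2 * x[1] - rev(x[2:(pad + 1)]), x,
      2 * x[n] - rev(x[(n - pad):(n - 1)]))
  else x
  y <- rev(lp_forward_pass(flt, rev(lp_forward_pass(flt, xp))))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase high-pass filter (low-pass complement)
#'
#' Implemented as `x - zerophase_lowpass(x, ...)`, which is itself a
#' zero-phase high-pass with the same cutoff and remains numerically
#' exact for cutoffs several decades below the Nyquist frequency.
#'
#' @inheritParams zerophase_lowpass
#' @return filtered numeric vector, same length as `x`.
#' @export
zerophase_highpass <- function(x, rate, cutoff, order = 3) {
  x - zerophase_lowpass(x, rate, cutoff, order)
}
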