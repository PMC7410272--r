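# Zero-phase low-pass filtering and finite differences.
#
# 2nd-order Butterworth biquad (bilinear transform design) applied forward and
# backward (effective 4th order, zero phase lag) -- the standard smoothing used
# on motion-capture trajectories before numerical differentiation. Implemented
# on stats::filter (C-level recursion) since no DSP package is assumed.

butter2_lowpass <- function(cutoff, fs) {
  stopifnot(cutoff > 0, fs > 0, cutoff < fs / 2)
  K <- tan(pi * cutoff / fs)
  Q <- 1 / sqrt(2)
  norm <- 1 / (1 + K / Q + K^2)
  list(
    b = c(K^2, 2 * K^2, K^2) * norm,
    a = c(1, 2 * (K^2 - 1) * norm, (1 - K / Q + K^2) * norm)
  )
}

# Single forward pass of the biquad; zero transient is avoided by seeding the
# recursion at its DC steady state for the first padded sample.
biquad_pass <- function(x, coef) {
  b <- coef$b; a <- coef$a
  n <- length(x)
  # moving-average part with edge replication for the first two samples
  xp <- c(x[1], x[1], x)
  z <- b[1] * xp[3:(n + 2)] + b[2] * xp[2:(n + 1)] + b[3] * xp[1:n]
  y0 <- x[1] # DC gain is 1
  as.numeric(stats::filter(z, -a[2:3], method = "recursive", init = c(y0, y0)))
}

#' Zero-phase low-pass filter
#'
#' Forward-backward 2nd-order Butterworth low-pass (effective 4th order,
#' zero phase). Signals are padded by odd reflection at both ends before
#' filtering so that edges and linear trends are preserved.
#'
#' @param x numeric vector or matrix (columns filtered independently).
#' @param cutoff cutoff frequency, Hz. `Inf` (or `NULL`) returns `x` unchanged.
#' @param fs sampling frequency, Hz.
#' @return filtered object, same shape as `x`.
#' @export
filter_lowpass <- function(x, cutoff, fs) {
  if (is.null(cutoff) || !is.finite(cutoff)) return(x)
  if (is.matrix(x)) {
    return(apply(x, 2, filter_lowpass, cutoff = cutoff, fs = fs))
  }
  n <- length(x)
  coef <- butter2_lowpass(cutoff, fs)
  pad <- min(n - 1, max(12L, ceiling(3 * fs / cutoff)))
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  xx <- c(head_pad, x, tail_pad)
  y <- biquad_pass(xx, coef)
  y <- rev(biquad_pass(rev(y), coef))
  y[(pad + 1):(pad + n)]
}

# Central first difference, one-sided at the ends.
fdiff <- function(x, dt) {
  if (is.matrix(x)) return(apply(x, 2, fdiff, dt = dt))
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * dt)
  d[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * dt)
  d
}

# Central second difference; endpoints copy their interior neighbour.
fdiff2 <- function(x, dt) {
  if (is.matrix(x)) return(apply(x, 2, fdiff2, dt = dt))
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
  d[1] <- (2 * x[1] - 5 * x[2] + 4 * x[3] - x[4]) / dt^2
  d[n] <- (2 * x[n] - 5 * x[n - 1] + 4 * x[n - 2] - x[n - 3]) / dt^2
  d
}
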