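#' Butterworth low-pass design
#'
#' Designs digital Butterworth low-pass coefficients by bilinear transform of
#' the analog prototype. Returned as transfer-function coefficients
#' `b` (numerator) and `a` (denominator, `a[1] = 1`).
#'
#' @param cutoff cutoff frequency in Hz (-3 dB point of a single pass).
#' @param fs sampling rate in Hz; must exceed `2 * cutoff`.
#' @param order filter order (default 2).
#' @return list with elements `b` and `a`.
#' @export
butter_lowpass <- function(cutoff, fs, order = 2L) {
  stopifnot(cutoff > 0, fs > 0, order >= 1L)
  if (fs <= 2 * cutoff) {
    stop(sprintf("sampling rate %g Hz must exceed twice the cutoff %g Hz", fs, cutoff))
  }
  order <- as.integer(order)
  wc <- tan(pi * cutoff / fs)  # prewarped analog cutoff
  # analog Butterworth poles on the left half of the circle of radius wc
  k <- seq_len(order)
  p_a <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # bilinear transform z = (1 + s) / (1 - s)
  p_z <- (1 + p_a) / (1 - p_a)
  # n zeros at z = -1; a(z), b(z) as real polynomials
  a <- poly_from_roots(p_z)
  b <- poly_from_roots(rep(-1 + 0i, order))
  # unit DC gain
  gain <- Re(sum(a)) / Re(sum(b))
  list(b = Re(b) * gain, a = Re(a))
}

# expand prod (z - r_i) into monic polynomial coefficients, highest power first
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (root in r) coefs <- c(coefs, 0) - c(0, coefs) * root
  coefs
}

# steady-state initial filter state for a step of unit height (direct form II
# transposed), so transients at the series edges are suppressed
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (n == 1L) return(numeric(0))
  A <- rbind(-a[-1L], cbind(diag(1, n - 2L, n - 2L), rep(0, n - 2L)))
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n - 1L) - t(A), B)
}

apply_lfilter <- function(x, b, a, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (is.null(zi)) zi <- rep(0, n - 1L)
  lfilter_cpp(as.numeric(b), as.numeric(a), as.numeric(x), as.numeric(zi))
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies the filter forward and backward (two passes), which cancels the
#' phase response and doubles the effective order: the kinematics-community
#' standard for smoothing movement signals without shifting event timing.
#' Series edges are handled by odd-mirror padding plus steady-state filter
#' initialization.
#'
#' @param x numeric vector, or matrix with one series per column.
#' @param cutoff cutoff frequency in Hz per pass (default 6).
#' @param fs sampling rate in Hz.
#' @param order Butterworth order per pass (default 2; two passes give an
#'   effective 4th-order magnitude response).
#' @return filtered series, same shape as `x`.
#' @export
lowpass_filter <- function(x, cutoff = 6, fs, order = 2L) {
  if (is.matrix(x)) {
    return(apply(x, 2L, lowpass_filter, cutoff = cutoff, fs = fs, order = order))
  }
  stopifnot(is.numeric(x))
  if (anyNA(x)) stop("series contains missing values; interpolate gaps first")
  coefs <- butter_lowpass(cutoff, fs, order)
  # long enough to swallow the filter transient at low cutoffs
  npad <- max(3L * (max(length(coefs$a), length(coefs$b)) - 1L),
              as.integer(ceiling(fs / cutoff)))
  if (length(x) <= npad) {
    stop(sprintf("series too short to filter stably (need > %d samples)", npad))
  }
  zi <- lfilter_zi(coefs$b, coefs$a)
  # odd mirror extension about the first/last sample
  pre <- 2 * x[1L] - x[seq(npad + 1L, 2L, by = -1L)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - npad, by = -1L)]
  ext <- c(pre, x, post)
  y <- apply_lfilter(ext, coefs$b, coefs$a, zi * ext[1L])
  y <- rev(y)
  y <- apply_lfilter(y, coefs$b, coefs$a, zi * y[1L])
  y <- rev(y)
  y[(npad + 1L):(npad + length(x))]
}
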