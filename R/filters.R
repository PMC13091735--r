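# Zero-phase Butterworth filtering of epoch arrays.
#
# Filter design comes from signal::butter; application is a compiled
# forward-reverse (zero-phase) pass with odd-reflection padding. Band-pass
# responses are realized as a cascade of order-4 high-pass and low-pass
# stages, which is numerically robust for extreme relative corner
# frequencies (e.g., 0.5 Hz at fs 500); the band-stop notch is a single
# order-4 design.

# steady-state initial condition of the filter's step response (the
# scipy/MATLAB lfilter_zi construction), so the forward and reverse passes
# start settled at the padded edge value
filter_zi <- function(b, a) {
  len <- max(length(a), length(b))
  b <- c(b, rep(0, len - length(b))) / a[1]
  a <- c(a, rep(0, len - length(a))) / a[1]
  n <- len - 1
  comp <- matrix(0, n, n)
  comp[1, ] <- -a[2:len]
  if (n > 1) comp[cbind(2:n, 1:(n - 1))] <- 1
  rhs <- b[2:len] - a[2:len] * b[1]
  solve(diag(n) - t(comp), rhs)
}

.filtfilt_mat <- function(b, a, x) {
  .filtfilt_mat_zi(b, a, x, filter_zi(b, a))
}

# apply one or more zero-phase b/a filter stages along the time dimension of
# trials x channels x samples (or a plain matrix with time in rows / a
# vector); multi-stage cascades share one array flatten
zp_filter <- function(x, b, a = NULL) {
  stages <- if (is.null(a)) b else list(list(b = b, a = a))
  if (is.numeric(x) && is.null(dim(x))) {
    m <- matrix(x, ncol = 1)
    for (s in stages) m <- .filtfilt_mat(s$b, s$a, m)
    return(m[, 1])
  }
  if (is.matrix(x)) {
    for (s in stages) x <- .filtfilt_mat(s$b, s$a, x)
    return(x)
  }
  d <- dim(x)
  m <- matrix(aperm(x, c(3, 1, 2)), nrow = d[3])
  for (s in stages) m <- .filtfilt_mat(s$b, s$a, m)
  aperm(array(m, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Zero-phase band-stop (notch) filter
#'
#' Fourth-order Butterworth band-stop applied forward-reverse (zero phase)
#' along time. The default 49--51 Hz band removes 50 Hz mains while
#' attenuating a 40 Hz response by well under 0.5 dB.
#'
#' @param epochs An [epoch_set()].
#' @param band Length-2 numeric stop band in Hz, inside Nyquist.
#' @return Filtered `assr_epochs`.
#' @export
notch_filter <- function(epochs, band = c(49, 51)) {
  nyq <- epochs$sampling_rate_hz / 2
  if (band[1] >= band[2] || band[2] >= nyq || band[1] <= 0) {
    stop("notch band must satisfy 0 < low < high < Nyquist")
  }
  bt <- signal::butter(4, band / nyq, type = "stop")
  replace_data(epochs, zp_filter(epochs$data, bt$b, bt$a))
}

#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth high-pass and low-pass in cascade, each applied
#' forward-reverse (zero phase). Used for the artifact-screening
#' pseudo-datasets (110--140, 0.5--80, 5--40, 39--41 Hz) and the final
#' 5--60 Hz analysis band.
#'
#' @param epochs An [epoch_set()].
#' @param low_hz,high_hz Corner frequencies, `0 < low < high < Nyquist`.
#' @return Filtered `assr_epochs`.
#' @export
bandpass_filter <- function(epochs, low_hz, high_hz) {
  nyq <- epochs$sampling_rate_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("band corners must satisfy 0 < low < high < Nyquist")
  }
  hp <- signal::butter(4, low_hz / nyq, type = "high")
  lp <- signal::butter(4, high_hz / nyq, type = "low")
  replace_data(epochs, zp_filter(epochs$data, list(hp, lp)))
}
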