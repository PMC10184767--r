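#' Dominant frequency of an oscillating series
#'
#' Estimates the frequency of the strongest spectral peak of the detrended,
#' Hann-windowed series, refined by quadratic interpolation on the
#' log-magnitude around the peak bin (with 4x zero padding). Used to set
#' the adaptive low-pass cutoff before any event detection.
#'
#' A series is declared non-oscillatory — an error — when it is flat or
#' when the spectral peak does not stand out from the broadband floor
#' (peak power below `min_snr` times the mean power), which is the
#' behaviour wanted for, e.g., a fin that never beats.
#'
#' @param x numeric series (one value per frame).
#' @param fps frames per second.
#' @param min_snr peak-to-mean spectral power ratio below which the series
#'   is declared to have no detectable oscillation.
#' @return frequency in Hz.
#' @export
dominant_frequency <- function(x, fps, min_snr = 20) {
  stopifnot(fps > 0)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("series too short for frequency estimation", call. = FALSE)
  if (!all(is.finite(x))) stop("series contains non-finite values",
                               call. = FALSE)
  # remove mean and linear trend so drift does not masquerade as a tone
  tt <- seq_len(n)
  x <- stats::lm.fit(cbind(1, tt), x)$residuals
  if (max(abs(x)) < 1e-12 * max(1, abs(mean(x))) || sd(x) == 0)
    stop("no oscillation detectable: flat series", call. = FALSE)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))   # Hann
  nfft <- 2^ceiling(log2(4 * n))
  spec <- Mod(fft(c(x * w, rep(0, nfft - n))))[1:(nfft %/% 2)]
  pow <- spec^2
  k <- which.max(pow[-1]) + 1L                            # skip DC
  if (pow[k] < min_snr * mean(pow))
    stop("no oscillation detectable: spectral peak below noise floor",
         call. = FALSE)
  lk <- log(pmax(spec[(k - 1):(k + 1)], .Machine$double.xmin))
  off <- refine_parabolic(lk[1], lk[2], lk[3])
  (k - 1 + off) * fps / nfft
}

#' Adaptive zero-phase low-pass filter
#'
#' Removes digitization jitter from point series by low-pass filtering at a
#' multiple (default 5) of the movement frequency: body points at 5x the
#' body wave frequency, fin points at 5x the fin beat frequency. The filter
#' is a 4th-order Butterworth applied forward and backward (zero phase, so
#' peak and adduction timing is preserved), with odd-reflection padding of
#' one cutoff period to suppress edge transients on short trials.
#'
#' @param x numeric series.
#' @param fps frames per second.
#' @param base_freq movement frequency in Hz.
#' @param multiple cutoff multiple (default 5); cutoff is
#'   `multiple * base_freq` and must lie below the Nyquist frequency.
#' @return filtered series, same length as `x`.
#' @export
lowpass_adaptive <- function(x, fps, base_freq, multiple = 5) {
  stopifnot(fps > 0, base_freq > 0, multiple > 0)
  cutoff <- multiple * base_freq
  if (cutoff >= fps / 2)
    stop(sprintf("cutoff %.3g Hz is at or above Nyquist %.3g Hz",
                 cutoff, fps / 2), call. = FALSE)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("series too short to filter", call. = FALSE)
  if (sd(x) == 0) return(x)               # DC passes unchanged
  pad <- min(n - 1, max(8L, ceiling(fps / cutoff)))
  left <- 2 * x[1] - x[(pad + 1):2]       # odd reflection about the ends
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(left, x, right)
  bf <- signal::butter(4, cutoff / (fps / 2), type = "low")
  yp <- signal::filtfilt(bf, xp)
  yp[(pad + 1):(pad + n)]
}
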