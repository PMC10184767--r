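#' Local maxima with prominence and spacing constraints
#'
#' Finds strict local maxima of a numeric series, computes each peak's
#' topographic prominence (height above the higher of the two bounding
#' valleys, valleys delimited by the nearest higher terrain or the series
#' ends), and greedily enforces a minimum spacing keeping the taller peak.
#'
#' @param x numeric vector.
#' @param min_prominence minimum prominence a peak must reach.
#' @param min_spacing minimum index separation between retained peaks.
#' @return integer vector of peak indices, increasing.
#' @export
find_peaks <- function(x, min_prominence = 0, min_spacing = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  # plateau-tolerant local maxima: strictly rising before, non-rising after
  cand <- which(vapply(2:(n - 1), function(i)
    x[i] > x[i - 1] && x[i] >= x[i + 1], logical(1))) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    lmin <- x[i]; j <- i
    while (j > 1 && x[j - 1] <= x[i]) { j <- j - 1; lmin <- min(lmin, x[j]) }
    rmin <- x[i]; j <- i
    while (j < n && x[j + 1] <= x[i]) { j <- j + 1; rmin <- min(rmin, x[j]) }
    x[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (!length(keep) || min_spacing <= 1) return(sort(keep))
  ord <- keep[order(x[keep], decreasing = TRUE)]
  chosen <- integer(0)
  for (i in ord) {
    if (!length(chosen) || all(abs(chosen - i) >= min_spacing))
      chosen <- c(chosen, i)
  }
  sort(chosen)
}

# quadratic (three-point parabola) refinement of an extremum location;
# returns the fractional offset in [-0.5, 0.5] from the centre sample
refine_parabolic <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (!is.finite(den) || abs(den) < .Machine$double.eps) return(0)
  off <- 0.5 * (ym1 - yp1) / den
  max(-0.5, min(0.5, off))
}
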