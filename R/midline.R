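#' Midline and midline-sequence containers
#'
#' A `midline` is an ordered head-to-tail polyline in pixel coordinates
#' with its cumulative arc length and the normalized body fraction
#' `s_frac` in `[0, 1]`. A `midline_sequence` collects one midline per
#' frame with the frame rate and a robust body-length estimate.
#'
#' @param points n x 2 matrix of (x, y) pixel coordinates, head first.
#' @return an object of class `midline`.
#' @export
midline <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 2)
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg <= 0)) {
    keep <- c(TRUE, seg > 0)
    points <- points[keep, , drop = FALSE]
    if (nrow(points) < 2) stop("degenerate midline", call. = FALSE)
    seg <- sqrt(rowSums(diff(points)^2))
  }
  arclen <- c(0, cumsum(seg))
  structure(list(points = points, arclen = arclen,
                 s_frac = arclen / arclen[length(arclen)]),
            class = "midline")
}

new_midline_sequence <- function(midlines, fps, body_length_px = NULL) {
  stopifnot(length(midlines) >= 1, fps > 0)
  if (is.null(body_length_px))
    body_length_px <- median(vapply(midlines, function(m)
      m$arclen[length(m$arclen)], numeric(1)))
  structure(list(midlines = midlines, fps = fps,
                 body_length_px = body_length_px),
            class = "midline_sequence")
}

#' @export
print.midline_sequence <- function(x, ...) {
  cat(sprintf("<midline_sequence> %d frames @ %g fps, BL %.1f px, %d pts/frame\n",
              length(x$midlines), x$fps, x$body_length_px,
              nrow(x$midlines[[1]]$points)))
  invisible(x)
}

#' Extract the midline of a binary silhouette
#'
#' Skeletonizes the single foreground component (Zhang-Suen thinning),
#' takes the skeleton path between the pixels nearest the nose and tail
#' landmarks (Dijkstra over the 8-connected skeleton graph, which discards
#' side branches such as fin spurs), anchors the ends to the landmarks,
#' lightly smooths `x(s)`, `y(s)` (moving average, window `n_points / 20`)
#' and resamples to `n_points` equally spaced arc-length points.
#'
#' @param frame logical matrix (TRUE = foreground), raster convention.
#' @param nose,tail landmark positions `c(x, y)` in pixels; each must lie
#'   within `anchor_tol` pixels of the foreground.
#' @param n_points points in the resampled midline (>= 50, default 100).
#' @param anchor_tol landmark-to-foreground tolerance in pixels.
#' @param smooth logical; apply the pre-curvature smoothing pass.
#' @return a [midline].
#' @export
extract_midline <- function(frame, nose, tail, n_points = 100,
                            anchor_tol = 10, smooth = TRUE) {
  stopifnot(is.matrix(frame))
  if (!any(frame)) stop("empty frame: no foreground", call. = FALSE)
  lab <- cpp_label8(frame)
  sizes <- tabulate(lab[lab > 0])
  big <- which(sizes >= 0.1 * max(sizes))
  if (length(big) > 1) stop("ambiguous silhouette: multiple large components",
                            call. = FALSE)
  comp <- lab == which.max(sizes)
  idx <- which(comp, arr.ind = TRUE)   # (row, col)
  d_nose <- min(sqrt((idx[, 2] - nose[1])^2 + (idx[, 1] - nose[2])^2))
  d_tail <- min(sqrt((idx[, 2] - tail[1])^2 + (idx[, 1] - tail[2])^2))
  if (d_nose > anchor_tol || d_tail > anchor_tol)
    stop(sprintf(
      "landmark farther than %g px from foreground (nose %.1f, tail %.1f)",
      anchor_tol, d_nose, d_tail), call. = FALSE)
  # crop to the bounding box (1-px pad) for the pixel passes
  r0 <- max(1L, min(idx[, 1]) - 1L); r1 <- min(nrow(frame), max(idx[, 1]) + 1L)
  c0 <- max(1L, min(idx[, 2]) - 1L); c1 <- min(ncol(frame), max(idx[, 2]) + 1L)
  sub <- comp[r0:r1, c0:c1, drop = FALSE]
  skel <- cpp_thin(sub)
  path <- cpp_skeleton_path(skel, nose[1] - c0 + 1, nose[2] - r0 + 1,
                            tail[1] - c0 + 1, tail[2] - r0 + 1)
  if (nrow(path) < 2)
    stop("skeleton path between nose and tail not found", call. = FALSE)
  pts <- cbind(x = path[, 1] + c0 - 1, y = path[, 2] + r0 - 1)
  # anchor the path to the landmarks so the blunt head/tail caps, which
  # thinning erodes by about one half-width, are restored
  if (sqrt(sum((pts[1, ] - nose)^2)) > 1.5) pts <- rbind(nose, pts)
  n <- nrow(pts)
  if (sqrt(sum((pts[n, ] - tail)^2)) > 1.5) pts <- rbind(pts, tail)
  m <- midline(pts)
  resample_midline(m, n_points = n_points, smooth = smooth)
}

# local-polynomial (Savitzky-Golay) smoothing of x(s), y(s) followed by
# equal-arc resampling. Raw skeletons are pixel-quantized and curvature is
# a second derivative, so unsmoothed paths are unusable downstream; a
# smoothing spline is unsuitable because its natural boundary conditions
# force curvature to zero at the head and tail, exactly where the bending
# wave is measured.
resample_midline <- function(m, n_points = 100, smooth = TRUE,
                             sg_window = 33) {
  pts <- m$points
  if (smooth && nrow(pts) > 12) {
    w <- min(sg_window, floor(nrow(pts) / 3))
    if (w %% 2 == 0) w <- w - 1L
    if (w >= 5)
      pts <- apply(pts, 2, function(v) signal::sgolayfilt(v, p = 3, n = w))
  }
  m2 <- midline(pts)
  L <- m2$arclen[length(m2$arclen)]
  si <- seq(0, L, length.out = n_points)
  midline(cbind(x = approx(m2$arclen, m2$points[, 1], si)$y,
                y = approx(m2$arclen, m2$points[, 2], si)$y))
}

# centred moving average with shrinking window at the ends
smooth_ma <- function(x, w) {
  h <- (w - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1, n - i)
    mean(x[(i - k):(i + k)])
  }, numeric(1))
}

#' Extract midlines for every frame of a binary stack
#'
#' @param stack a [binary_stack].
#' @param track a [point_track] with nose and tail landmarks (used to
#'   anchor and orient each frame's midline).
#' @param n_points,anchor_tol,smooth passed to [extract_midline()].
#' @return a `midline_sequence` with `body_length_px` set by
#'   [estimate_body_length()].
#' @export
extract_midline_sequence <- function(stack, track, n_points = 100,
                                     anchor_tol = 10, smooth = TRUE) {
  stopifnot(inherits(stack, "binary_stack"), inherits(track, "point_track"))
  nf <- length(stack$frames)
  if (nrow(track$landmarks$nose) != nf)
    stop("track and stack frame counts differ", call. = FALSE)
  mids <- vector("list", nf)
  for (k in seq_len(nf)) {
    mids[[k]] <- extract_midline(
      stack$frames[[k]],
      nose = c(track$landmarks$nose$x[k], track$landmarks$nose$y[k]),
      tail = c(track$landmarks$tail$x[k], track$landmarks$tail$y[k]),
      n_points = n_points, anchor_tol = anchor_tol, smooth = smooth)
  }
  ms <- new_midline_sequence(mids, fps = stack$fps)
  ms$body_length_px <- estimate_body_length(ms)
  ms
}

#' Robust body length from a midline sequence
#'
#' Median of the per-frame midline arc lengths; the denominator for every
#' body-length-normalized variable. Intended for sequences of at least 5
#' frames.
#'
#' @param midlines a `midline_sequence`.
#' @return body length in pixels.
#' @export
estimate_body_length <- function(midlines) {
  stopifnot(inherits(midlines, "midline_sequence"))
  median(vapply(midlines$midlines,
                function(m) m$arclen[length(m$arclen)], numeric(1)))
}

#' Signed curvature along a midline
#'
#' Curvature is the arc-length derivative of the unwrapped tangent angle,
#' by central differences on the resampled midline. The sign follows the
#' stored point order and raster axes: positive where the tangent angle
#' increases head to tail, which for a swimmer heading in +x with y
#' downward is bending toward the fish's left.
#'
#' @param midline a [midline].
#' @param body_length_px optional; when given, curvature is also returned
#'   in BL^-1 as attribute `kappa_bl`.
#' @return numeric vector of signed curvature, px^-1, one value per point.
#' @export
curvature <- function(midline, body_length_px = NULL) {
  pts <- midline$points
  n <- nrow(pts)
  # tangent by central differences (one-sided at the ends)
  dx <- c(pts[2, 1] - pts[1, 1], pts[3:n, 1] - pts[1:(n - 2), 1],
          pts[n, 1] - pts[n - 1, 1])
  dy <- c(pts[2, 2] - pts[1, 2], pts[3:n, 2] - pts[1:(n - 2), 2],
          pts[n, 2] - pts[n - 1, 2])
  theta <- unwrap_angle(atan2(dy, dx))
  s <- midline$arclen
  k <- numeric(n)
  k[2:(n - 1)] <- (theta[3:n] - theta[1:(n - 2)]) / (s[3:n] - s[1:(n - 2)])
  k[1] <- k[2]; k[n] <- k[n - 1]
  if (!is.null(body_length_px)) attr(k, "kappa_bl") <- k * body_length_px
  k
}

unwrap_angle <- function(theta) {
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(theta[1], theta[1] + cumsum(d))
}

#' Curvature field of a midline sequence
#'
#' Samples signed curvature on the body-fraction x frame grid. Curvature
#' is a second spatial derivative, so on midlines extracted from
#' pixel-quantized silhouettes it carries substantial noise; since that
#' noise is independent across frames while the bending signal at a fixed
#' body position oscillates far below the frame rate, a short moving
#' average along the time axis (window `smooth_window` frames) suppresses
#' it without biasing positions along the body.
#'
#' @param midlines a `midline_sequence`.
#' @param smooth_window odd moving-average window in frames for the
#'   along-time smoothing of curvature (1 = none).
#' @return a `curvature_field`: list with `kappa` (n_points x n_frames
#'   matrix, px^-1), `s_frac`, `fps`, `body_length_px`, and the midlines
#'   themselves (needed for chord measurements).
#' @export
curvature_field <- function(midlines, smooth_window = 7) {
  stopifnot(inherits(midlines, "midline_sequence"))
  ks <- vapply(midlines$midlines, curvature,
               numeric(nrow(midlines$midlines[[1]]$points)))
  if (smooth_window > 1 && ncol(ks) > smooth_window)
    ks <- t(apply(ks, 1, smooth_ma, w = smooth_window))
  structure(list(kappa = ks, s_frac = midlines$midlines[[1]]$s_frac,
                 fps = midlines$fps,
                 body_length_px = midlines$body_length_px,
                 midlines = midlines$midlines),
            class = "curvature_field")
}
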