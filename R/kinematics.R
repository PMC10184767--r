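#' Lateral excursion of the tail relative to the heading
#'
#' Computes the signed lateral excursion of the tail tip: its deviation
#' from a drift reference, projected on the normal of the local heading.
#' The heading is the mean nose-to-tail body axis (which stays defined
#' even for a fish oscillating in place); with `cycle_s` set it is
#' averaged over a sliding window of one locomotor cycle, and the drift
#' reference is the tail's own one-cycle moving-average path, so slow
#' drift or gentle turning is removed before peak detection while the
#' projected vector stays almost purely lateral (axis-tilt error is second
#' order). Positive values lie on the fish-left side (cross-product
#' convention, raster axes).
#'
#' @param track a [point_track] with nose and tail landmarks.
#' @param cycle_s locomotor cycle duration in seconds, or `NULL` for a
#'   single global axis.
#' @return numeric series of signed lateral excursion in pixels.
#' @export
tail_lateral <- function(track, cycle_s = NULL) {
  stopifnot(inherits(track, "point_track"))
  nose <- as.matrix(track$landmarks$nose[, c("x", "y")])
  tl <- as.matrix(track$landmarks$tail[, c("x", "y")])
  n <- nrow(nose)
  axes <- nose - tl                    # per-frame body axis, tail -> nose
  u_g <- colMeans(axes)
  u_g <- u_g / sqrt(sum(u_g^2))
  n_g <- c(u_g[2], -u_g[1])            # fish-left normal
  if (is.null(cycle_s)) {
    rel <- sweep(tl, 2, colMeans(tl))
    return(as.numeric(rel %*% n_g))
  }
  w <- max(5L, round(cycle_s * track$fps))
  if (w %% 2 == 0) w <- w + 1L
  h <- w %/% 2
  # one-cycle mean tail path; where the window is truncated (first/last
  # half cycle) the reference is extended linearly along the local drift
  # rather than letting the window shrink, which would drag the reference
  # toward the instantaneous excursion and distort edge peaks
  ref <- apply(tl, 2, smooth_ma, w = w)
  uax <- apply(axes, 2, smooth_ma, w = w)  # cycle-mean local heading
  if (n > 2 * w) {
    for (col in 1:2) {
      i0 <- h + 1L; i1 <- n - h
      sl0 <- (ref[i0 + h, col] - ref[i0, col]) / h
      ref[1:(i0 - 1), col] <- ref[i0, col] + ((1:(i0 - 1)) - i0) * sl0
      sl1 <- (ref[i1, col] - ref[i1 - h, col]) / h
      ref[(i1 + 1):n, col] <- ref[i1, col] + (((i1 + 1):n) - i1) * sl1
      uax[1:(i0 - 1), col] <- uax[i0, col]
      uax[(i1 + 1):n, col] <- uax[i1, col]
    }
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    u <- uax[i, ]
    nu <- sqrt(sum(u^2))
    u <- if (nu > 0) u / nu else u_g
    nv <- c(u[2], -u[1])
    if (sum(nv * n_g) < 0) nv <- -nv
    out[i] <- sum((tl[i, ] - ref[i, ]) * nv)
  }
  out
}

#' Detect tail-beat peak events
#'
#' Finds the per-side maxima of the tail's lateral excursion: local extrema
#' with prominence at least `min_prominence_frac` of the series range and
#' spacing at least `min_spacing_cycles` of the estimated cycle. Side
#' alternation is enforced by keeping the larger of two consecutive
#' same-side peaks. A trial with fewer than 3 peaks on each side is
#' rejected (error), mirroring the steady-cycle acceptance rule.
#'
#' @param lateral signed lateral excursion series (see [tail_lateral()]),
#'   already low-pass filtered.
#' @param fps frames per second.
#' @param f_est body wave frequency estimate in Hz; `NULL` to estimate via
#'   [dominant_frequency()].
#' @param min_prominence_frac prominence threshold as a fraction of range.
#' @param min_spacing_cycles minimum peak spacing in cycles.
#' @return data.frame with columns `frame`, `time`, `side`
#'   (`"left"`/`"right"`), `excursion` (signed px); attribute `f_est`.
#' @export
detect_tail_peaks <- function(lateral, fps, f_est = NULL,
                              min_prominence_frac = 0.1,
                              min_spacing_cycles = 0.3) {
  lateral <- as.numeric(lateral)
  if (is.null(f_est))
    f_est <- tryCatch(dominant_frequency(lateral, fps), error = function(e)
      stop("trial rejected: ", conditionMessage(e), call. = FALSE))
  spacing <- max(1, round(min_spacing_cycles / f_est * fps))
  prom <- min_prominence_frac * diff(range(lateral))
  if (prom <= 0)
    stop("trial rejected: flat lateral excursion", call. = FALSE)
  iL <- find_peaks(lateral, min_prominence = prom, min_spacing = spacing)
  iR <- find_peaks(-lateral, min_prominence = prom, min_spacing = spacing)
  ev <- rbind(
    if (length(iL)) data.frame(frame = iL, side = "left",
                               excursion = lateral[iL]),
    if (length(iR)) data.frame(frame = iR, side = "right",
                               excursion = lateral[iR]))
  if (is.null(ev) || nrow(ev) == 0)
    stop("trial rejected: no tail peaks detected", call. = FALSE)
  ev <- ev[order(ev$frame), ]
  # enforce alternation: among consecutive same-side events keep the larger
  repeat {
    same <- which(ev$side[-1] == ev$side[-nrow(ev)])
    if (!length(same)) break
    i <- same[1]
    drop <- if (abs(ev$excursion[i]) >= abs(ev$excursion[i + 1])) i + 1 else i
    ev <- ev[-drop, ]
  }
  nL <- sum(ev$side == "left"); nR <- sum(ev$side == "right")
  if (max(nL, nR) < 3)
    stop(sprintf(
      "trial rejected: only %d same-side tail peaks (3 required)",
      max(nL, nR)), call. = FALSE)
  ev$time <- (ev$frame - 1) / fps
  rownames(ev) <- NULL
  structure(ev[, c("frame", "time", "side", "excursion")], f_est = f_est)
}

#' Swimming speed in body lengths per second
#'
#' Net displacement of the body-centre proxy (midpoint of nose and tail)
#' over an integer number of locomotor cycles, divided by the elapsed time
#' and the body length. When peak events are supplied the window runs from
#' the first to the last peak on the better-sampled side (whole cycles);
#' otherwise the full series is used.
#'
#' @param track a [point_track] (ideally low-pass filtered).
#' @param body_length_px body length in pixels.
#' @param peaks optional result of [detect_tail_peaks()].
#' @return speed in BL s^-1.
#' @export
swimming_speed <- function(track, body_length_px, peaks = NULL) {
  stopifnot(inherits(track, "point_track"), body_length_px > 0)
  nose <- as.matrix(track$landmarks$nose[, c("x", "y")])
  tl <- as.matrix(track$landmarks$tail[, c("x", "y")])
  ctr <- (nose + tl) / 2
  n <- nrow(ctr)
  if (!is.null(peaks)) {
    side <- names(which.max(table(peaks$side)))
    fr <- peaks$frame[peaks$side == side]
    if (length(fr) >= 2) {
      i0 <- fr[1]; i1 <- fr[length(fr)]
      dt <- (i1 - i0) / track$fps
      return(sqrt(sum((ctr[i1, ] - ctr[i0, ])^2)) / dt / body_length_px)
    }
  }
  dt <- (n - 1) / track$fps
  sqrt(sum((ctr[n, ] - ctr[1, ])^2)) / dt / body_length_px
}

#' Tail-beat amplitude in body lengths
#'
#' For each (left, right, left) triple of consecutive peak events, the
#' perpendicular distance from the tail position at the intervening
#' right-side maximum to the line through the tail positions at the two
#' left-side maxima, divided by two and normalized by body length; the
#' trial value is the mean over triples. The chord construction makes the
#' measure insensitive to straight-line drift between beats.
#'
#' @param peaks result of [detect_tail_peaks()].
#' @param tail_xy n x 2 matrix of per-frame tail positions (filtered), px.
#' @param body_length_px body length in pixels.
#' @return amplitude in BL.
#' @export
tail_amplitude <- function(peaks, tail_xy, body_length_px) {
  tail_xy <- as.matrix(tail_xy)
  ev <- peaks[order(peaks$frame), ]
  vals <- numeric(0)
  iL <- which(ev$side == "left")
  for (k in seq_along(iL)[-length(iL)]) {
    a <- iL[k]; b <- iL[k + 1]
    mid <- which(ev$side == "right" & seq_len(nrow(ev)) > a &
                   seq_len(nrow(ev)) < b)
    if (length(mid) != 1) next
    p1 <- tail_xy[ev$frame[a], ]
    p2 <- tail_xy[ev$frame[b], ]
    pr <- tail_xy[ev$frame[mid], ]
    v <- p2 - p1
    nv <- sqrt(sum(v^2))
    # coincident left peaks (zero drift): the chord degenerates to a
    # point and the construction reduces to plain point distance
    d <- if (nv < .Machine$double.eps) sqrt(sum((pr - p1)^2))
    else abs(v[1] * (pr[2] - p1[2]) - v[2] * (pr[1] - p1[1])) / nv
    vals <- c(vals, d / 2 / body_length_px)
  }
  if (!length(vals))
    stop("trial rejected: no (left, right, left) tail-peak triple",
         call. = FALSE)
  mean(vals)
}

#' Body wave frequency in Hz
#'
#' Locomotor cycles per second: the mean of `1 / dt` over consecutive
#' same-side tail-peak pairs (both sides pooled).
#'
#' @param peaks result of [detect_tail_peaks()].
#' @return frequency in Hz.
#' @export
body_wave_frequency <- function(peaks) {
  rates <- numeric(0)
  for (s in unique(peaks$side)) {
    tt <- sort(peaks$time[peaks$side == s])
    if (length(tt) >= 2) rates <- c(rates, 1 / diff(tt))
  }
  if (!length(rates))
    stop("trial rejected: no same-side peak pair", call. = FALSE)
  mean(rates)
}

#' Pectoral fin beat frequency in Hz (or absent)
#'
#' A fin beat cycle runs between two consecutive adductions of the right
#' pectoral fin; adductions are local minima of the fin tip's perpendicular
#' distance to the local body axis, detected with the same prominence and
#' spacing rules as the tail peaks after adaptive low-pass filtering at
#' `multiple` times the fin beat frequency. The axis is the nose-to-tail
#' direction averaged over `axis_window_s` seconds and anchored on the
#' equally smoothed nose path: the instantaneous nose-tail line swings
#' with every tail beat, which would imprint the body wave on the fin
#' distance of a fish that never moves its fins. When no beating is
#' detectable, or fewer than 2 adductions occur, the result is `NA`
#' (absent) — never zero.
#'
#' @param track a [point_track]; the `fin_right` landmark is required.
#' @param body_length_px body length in pixels (sets the minimum excursion
#'   regarded as real fin motion, `min_excursion_bl`).
#' @param multiple low-pass cutoff multiple (default 5).
#' @param min_excursion_bl fin-tip excursion below this fraction of BL is
#'   treated as no fin use.
#' @param min_prominence_frac,min_spacing_cycles as in
#'   [detect_tail_peaks()].
#' @param axis_window_s smoothing window (s) for the local body axis.
#' @return frequency in Hz, or `NA_real_` when the fins are not used.
#' @export
pectoral_fin_frequency <- function(track, body_length_px, multiple = 5,
                                   min_excursion_bl = 0.01,
                                   min_prominence_frac = 0.1,
                                   min_spacing_cycles = 0.3,
                                   axis_window_s = 0.5) {
  stopifnot(inherits(track, "point_track"))
  if (is.null(track$landmarks$fin_right))
    stop("fin landmark required", call. = FALSE)
  nose <- as.matrix(track$landmarks$nose[, c("x", "y")])
  tl <- as.matrix(track$landmarks$tail[, c("x", "y")])
  fin <- as.matrix(track$landmarks$fin_right[, c("x", "y")])
  w <- max(5L, round(axis_window_s * track$fps))
  if (w %% 2 == 0) w <- w + 1L
  w <- min(w, nrow(nose) - (1 - nrow(nose) %% 2))
  axes <- apply(tl - nose, 2, smooth_ma, w = w)
  nose_s <- apply(nose, 2, smooth_ma, w = w)
  nv <- sqrt(rowSums(axes^2))
  d <- abs(axes[, 1] * (fin[, 2] - nose_s[, 2]) -
             axes[, 2] * (fin[, 1] - nose_s[, 1])) / pmax(nv, 1e-9)
  f_fin <- tryCatch(dominant_frequency(d, track$fps),
                    error = function(e) NA_real_)
  if (is.na(f_fin)) return(NA_real_)
  df <- lowpass_adaptive(d, track$fps, f_fin, multiple = multiple)
  if (diff(range(df)) < min_excursion_bl * body_length_px)
    return(NA_real_)
  spacing <- max(1, round(min_spacing_cycles / f_fin * track$fps))
  prom <- min_prominence_frac * diff(range(df))
  add <- find_peaks(-df, min_prominence = prom, min_spacing = spacing)
  if (length(add) < 2) return(NA_real_)
  mean(1 / diff((add - 1) / track$fps))
}

#' Pectoral fin state
#'
#' `"On"` when a fin beat frequency is present, `"Off"` when absent.
#'
#' @param fin_freq result of [pectoral_fin_frequency()].
#' @return `"On"` or `"Off"`.
#' @export
fin_state <- function(fin_freq) {
  if (is.null(fin_freq) || is.na(fin_freq)) "Off" else "On"
}

#' Body wave speed from the curvature field, in %BL per second
#'
#' Tracks local extrema of |curvature| along the posterior body across
#' frames (matched by nearest-position continuity within each bending
#' sign) and times each extremum's transit from 75% to 95% BL. The speed
#' of each complete transit is `(0.95 - 0.75) / (t95 - t75) * 100`; the
#' trial value is the mean over all transits of both signs. A standing
#' (non-traveling) flexion produces no transit and the result is `NA`
#' with a warning.
#'
#' @param cf a [curvature_field()].
#' @param s_lo,s_hi transit interval in body fraction (defaults 0.75,
#'   0.95).
#' @param min_height_frac extremum height threshold as a fraction of the
#'   field's maximum |curvature|.
#' @param track_window body-fraction window in which extrema are tracked.
#' @param max_step_bl largest plausible extremum displacement per frame
#'   (body fractions).
#' @return speed in %BL s^-1, or `NA` if no extremum completes the
#'   transit.
#' @export
body_wave_speed <- function(cf, s_lo = 0.75, s_hi = 0.95,
                            min_height_frac = 0.2,
                            track_window = c(0.55, 1),
                            max_step_bl = 0.05) {
  stopifnot(inherits(cf, "curvature_field"))
  K <- cf$kappa
  s <- cf$s_frac
  sel <- which(s >= track_window[1] & s <= track_window[2])
  hmin <- min_height_frac * max(abs(K))
  nfr <- ncol(K)
  # per-frame extrema of |kappa| with parabolic position refinement
  extrema <- vector("list", nfr)
  for (t in seq_len(nfr)) {
    a <- abs(K[sel, t])
    pk <- find_peaks(a, min_prominence = hmin * 0.5)
    pk <- pk[a[pk] >= hmin]
    if (!length(pk)) next
    sp <- vapply(pk, function(i) {
      off <- if (i > 1 && i < length(a))
        refine_parabolic(a[i - 1], a[i], a[i + 1]) else 0
      s[sel[i]] + off * (s[sel[2]] - s[sel[1]])
    }, numeric(1))
    extrema[[t]] <- data.frame(s = sp, sgn = sign(K[sel[pk], t]))
  }
  # continuity tracking
  tracks <- list()
  active <- data.frame(id = integer(0), s = numeric(0), sgn = numeric(0),
                       frame = integer(0))
  next_id <- 1L
  for (t in seq_len(nfr)) {
    active <- active[t - active$frame <= 3, , drop = FALSE]
    ex <- extrema[[t]]
    if (!is.null(ex) && nrow(ex)) {
      used <- rep(FALSE, nrow(active))
      for (e in seq_len(nrow(ex))) {
        gap <- t - active$frame
        ds <- ex$s[e] - active$s
        ok <- which(!used & active$sgn == ex$sgn[e] &
                      ds >= -0.02 & ds <= max_step_bl * gap)
        if (length(ok)) {
          j <- ok[which.min(abs(ds[ok]))]
          used[j] <- TRUE
          id <- active$id[j]
          tracks[[id]]$s <- c(tracks[[id]]$s, ex$s[e])
          tracks[[id]]$t <- c(tracks[[id]]$t, (t - 1) / cf$fps)
          active$s[j] <- ex$s[e]; active$frame[j] <- t
        } else {
          tracks[[next_id]] <- list(s = ex$s[e], t = (t - 1) / cf$fps)
          active <- rbind(active, data.frame(
            id = next_id, s = ex$s[e], sgn = ex$sgn[e], frame = t))
          used <- c(used, TRUE)
          next_id <- next_id + 1L
        }
      }
    }
  }
  cross_time <- function(ss, tt, level) {
    i <- which(ss[-1] >= level & ss[-length(ss)] < level)
    if (!length(i)) {
      if (ss[1] >= level) return(NULL)       # started past the level
      return(NULL)
    }
    i <- i[1]
    frac <- (level - ss[i]) / (ss[i + 1] - ss[i])
    tt[i] + frac * (tt[i + 1] - tt[i])
  }
  speeds <- numeric(0)
  for (tr in tracks) {
    if (length(tr$s) < 3) next
    if (tr$s[1] > s_lo || max(tr$s) < s_hi) next
    t1 <- cross_time(tr$s, tr$t, s_lo)
    t2 <- cross_time(tr$s, tr$t, s_hi)
    if (is.null(t1) || is.null(t2) || t2 <= t1) next
    speeds <- c(speeds, (s_hi - s_lo) / (t2 - t1) * 100)
  }
  if (!length(speeds)) {
    warning("no curvature extremum completed the ", s_lo * 100, "-",
            s_hi * 100, "% BL transit; wave speed missing", call. = FALSE)
    return(NA_real_)
  }
  structure(mean(speeds), speeds = speeds)
}

#' Body wavelength from curvature extrema, in body lengths
#'
#' Per frame, the straight-line (chord) distance between consecutive
#' curvature extrema of the same sign along the midline, normalized by
#' body length; the trial value is the mean over frames and pairs. The
#' spacing between adjacent opposite-sign extrema times two is returned
#' alongside as a diagnostic (`wavelength_alt`), covering the
#' half-wavelength reading of extremum spacing.
#'
#' @param cf a [curvature_field()].
#' @param min_height_frac extremum height threshold as a fraction of the
#'   frame's maximum |curvature|. The default is deliberately low: with a
#'   tailward-growing amplitude envelope the anterior curvature extrema
#'   are weak, and discarding them would bias the spacing toward the
#'   compressed posterior pairs.
#' @param s_range body-fraction window searched for extrema; the default
#'   skips the anterior 5%, where landmark-anchored skeleton midlines can
#'   carry a junction kink.
#' @param min_sep_bl minimum separation between counted extrema, BL.
#' @param smooth_bl along-body moving-average window (BL) applied to each
#'   frame's curvature profile before extremum search; well below half of
#'   any plausible undulatory wavelength, it removes residual
#'   pixel-quantization wiggles that would register as spurious extrema.
#' @return list with `wavelength` (BL, `NA` with a warning when no frame
#'   shows two same-sign extrema) and `wavelength_alt`.
#' @export
body_wavelength <- function(cf, min_height_frac = 0.1,
                            s_range = c(0.05, 1), min_sep_bl = 0.08,
                            smooth_bl = 0.1) {
  stopifnot(inherits(cf, "curvature_field"))
  s <- cf$s_frac
  BL <- cf$body_length_px
  sel <- which(s >= s_range[1] & s <= s_range[2])
  ds <- s[2] - s[1]
  spacing <- max(3, round(min_sep_bl / ds))
  wsm <- round(smooth_bl / ds)
  if (wsm %% 2 == 0) wsm <- wsm + 1L
  vals <- numeric(0)
  alts <- numeric(0)
  for (t in seq_len(ncol(cf$kappa))) {
    k <- cf$kappa[, t]
    if (wsm >= 3) k <- smooth_ma(k, wsm)
    hmin <- min_height_frac * max(abs(k[sel]))
    if (hmin <= 0) next
    m <- cf$midlines[[t]]
    locate <- function(y) {
      pk <- find_peaks(y[sel], min_prominence = hmin,
                       min_spacing = spacing)
      pk <- pk[y[sel][pk] >= hmin]
      vapply(pk, function(i) {
        off <- if (i > 1 && i < length(sel))
          refine_parabolic(y[sel][i - 1], y[sel][i], y[sel][i + 1]) else 0
        s[sel[i]] + off * ds
      }, numeric(1))
    }
    chord <- function(s1, s2) {
      p1 <- c(approx(s, m$points[, 1], s1)$y, approx(s, m$points[, 2], s1)$y)
      p2 <- c(approx(s, m$points[, 1], s2)$y, approx(s, m$points[, 2], s2)$y)
      sqrt(sum((p2 - p1)^2))
    }
    pos <- locate(k)       # maxima (one bending sign)
    neg <- locate(-k)      # minima (the other)
    for (ss in list(pos, neg)) {
      if (length(ss) >= 2)
        for (i in seq_len(length(ss) - 1))
          vals <- c(vals, chord(ss[i], ss[i + 1]) / BL)
    }
    allx <- sort(c(pos, neg))
    sgn <- sign(approx(s, k, allx)$y)
    if (length(allx) >= 2) {
      for (i in seq_len(length(allx) - 1))
        if (sgn[i] != sgn[i + 1])
          alts <- c(alts, 2 * chord(allx[i], allx[i + 1]) / BL)
    }
  }
  if (!length(vals)) {
    warning("no frame with two same-sign curvature extrema; wavelength missing",
            call. = FALSE)
    return(list(wavelength = NA_real_,
                wavelength_alt = if (length(alts)) mean(alts) else NA_real_))
  }
  list(wavelength = mean(vals),
       wavelength_alt = if (length(alts)) mean(alts) else NA_real_)
}

# low-pass filter the x and y series of selected landmarks
filter_track <- function(track, base_freq, multiple = 5,
                         landmarks = names(track$landmarks)) {
  lms <- track$landmarks
  for (nm in intersect(landmarks, names(lms))) {
    lms[[nm]]$x <- lowpass_adaptive(lms[[nm]]$x, track$fps, base_freq,
                                    multiple)
    lms[[nm]]$y <- lowpass_adaptive(lms[[nm]]$y, track$fps, base_freq,
                                    multiple)
  }
  point_track(lms, fps = track$fps)
}

#' Assemble the full kinematic record of one trial
#'
#' Runs the whole measurement chain on one trial: body length from the
#' midlines; body wave frequency estimated from the tail's lateral
#' excursion; nose and tail series low-pass filtered at 5x that frequency;
#' tail peaks detected and the trial rejected unless it spans at least
#' `min_cycles` locomotor cycles; then swimming speed, tail amplitude,
#' wave frequency, fin frequency and state, and the curvature-wave speed
#' and wavelength. Any rejecting sub-computation marks the trial rejected
#' with its reason; a missing fin frequency is propagated as missing
#' (`NA`), never zero.
#'
#' @param track a [point_track] with nose, tail and fin landmarks.
#' @param midlines the trial's `midline_sequence` (analytic or extracted
#'   from silhouettes).
#' @param metadata optional one-row data.frame (fish id, viscosity, light,
#'   lateral line, trial index) prepended to the record.
#' @param multiple low-pass cutoff multiple (default 5).
#' @param min_cycles minimum locomotor cycles for acceptance (default 3).
#' @return one-row data.frame with the seven magnitude variables,
#'   `n_cycles`, `accepted`, `reject_reason`.
#' @export
assemble_trial <- function(track, midlines, metadata = NULL, multiple = 5,
                           min_cycles = 3) {
  stopifnot(inherits(track, "point_track"),
            inherits(midlines, "midline_sequence"))
  rec <- data.frame(swim_speed = NA_real_, fin_freq = NA_real_,
                    fin_state = NA_character_, tail_amp = NA_real_,
                    wave_freq = NA_real_, wave_speed = NA_real_,
                    wavelength = NA_real_, wavelength_alt = NA_real_,
                    n_cycles = NA_integer_, accepted = FALSE,
                    reject_reason = NA_character_,
                    stringsAsFactors = FALSE)
  res <- tryCatch({
    BL <- estimate_body_length(midlines)
    lat0 <- tail_lateral(track)
    f0 <- dominant_frequency(lat0, track$fps)
    ftr <- filter_track(track, f0, multiple, c("nose", "tail"))
    lat <- tail_lateral(ftr, cycle_s = 1 / f0)
    peaks <- detect_tail_peaks(lat, track$fps, f_est = f0)
    n_cycles <- max(table(peaks$side)) - 1L
    if (n_cycles < min_cycles)
      stop(sprintf("trial rejected: %d locomotor cycles (%d required)",
                   n_cycles, min_cycles), call. = FALSE)
    wf <- body_wave_frequency(peaks)
    amp <- tail_amplitude(
      peaks, as.matrix(ftr$landmarks$tail[, c("x", "y")]), BL)
    u <- swimming_speed(ftr, BL, peaks)
    ff <- pectoral_fin_frequency(track, BL, multiple = multiple)
    cf <- curvature_field(midlines)
    v <- suppressWarnings(body_wave_speed(cf))
    wl <- suppressWarnings(body_wavelength(cf))
    rec$swim_speed <- u
    rec$fin_freq <- ff
    rec$fin_state <- fin_state(ff)
    rec$tail_amp <- amp
    rec$wave_freq <- wf
    rec$wave_speed <- as.numeric(v)
    rec$wavelength <- wl$wavelength
    rec$wavelength_alt <- wl$wavelength_alt
    rec$n_cycles <- as.integer(n_cycles)
    rec$accepted <- TRUE
    rec
  }, error = function(e) {
    rec$reject_reason <- conditionMessage(e)
    rec
  })
  if (!is.null(metadata)) res <- cbind(as.data.frame(metadata), res)
  res
}
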