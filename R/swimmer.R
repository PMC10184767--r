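#' Parameters of a synthetic undulatory swimmer
#'
#' Ground-truth description of a traveling-wave swimmer used to emulate one
#' filmed trial. The midline is an amplitude-enveloped sinusoidal traveling
#' wave in the swimming frame plus uniform forward translation: with `s` the
#' head-to-tail body fraction, lateral displacement (in px, perpendicular to
#' the heading) is
#' `A * BL * s^p * sin(2*pi*(f*t - s/lambda))`,
#' so the bending wave travels tailward at `f * lambda` body lengths per
#' second. Image coordinates are raster: origin top left, x = column,
#' y = row (downward); "fish-left" is the side given by the cross product
#' of the heading with the lateral offset.
#'
#' @param body_length_px body length BL in pixels.
#' @param swim_speed forward speed U, body lengths per second.
#' @param wave_freq body wave frequency f, Hz (> 0).
#' @param wavelength body wavelength lambda, body lengths (> 0).
#' @param tail_amp tail-tip peak lateral excursion A, body lengths (>= 0).
#' @param amp_exponent envelope exponent p: amplitude grows toward the tail
#'   as `s^p`. The envelope of real fish is not claimed; this is a free knob.
#' @param fin_freq pectoral fin beat frequency, Hz, or `NULL` when the fins
#'   are not used (then `fin_state` must be `"Off"`).
#' @param fin_state `"On"` or `"Off"`; must be consistent with `fin_freq`.
#' @param fps frame rate, frames per second.
#' @param duration trial duration, seconds.
#' @param jitter_sd landmark digitization noise sd, pixels.
#' @param halfwidth function of body fraction `s` in `[0, 1]` returning the
#'   silhouette half-width in pixels; strictly positive except at the tail
#'   tip. Default `halfwidth_max * BL * (1 - s^2)`.
#' @param halfwidth_max maximum half-width as a fraction of BL (used only
#'   when `halfwidth` is `NULL`).
#' @param start head position `c(x, y)` in pixels at time 0.
#' @param seed integer seed controlling all randomness tied to this trial.
#' @return an object of class `swimmer_params`.
#' @export
swimmer_params <- function(body_length_px = 300, swim_speed = 0.5,
                           wave_freq = 2.5, wavelength = 0.6,
                           tail_amp = 0.08, amp_exponent = 2,
                           fin_freq = 3.5, fin_state = NULL,
                           fps = 500, duration = 2, jitter_sd = 1,
                           halfwidth = NULL, halfwidth_max = 0.04,
                           start = c(1.1 * body_length_px, 128), seed = 1L) {
  if (is.null(fin_state)) fin_state <- if (is.null(fin_freq)) "Off" else "On"
  fin_state <- match.arg(fin_state, c("On", "Off"))
  if (is.null(halfwidth)) {
    w0 <- halfwidth_max * body_length_px
    halfwidth <- function(s) w0 * (1 - s^2)
  }
  p <- structure(list(
    body_length_px = body_length_px, swim_speed = swim_speed,
    wave_freq = wave_freq, wavelength = wavelength, tail_amp = tail_amp,
    amp_exponent = amp_exponent, fin_freq = fin_freq, fin_state = fin_state,
    fps = fps, duration = duration, jitter_sd = jitter_sd,
    halfwidth = halfwidth, start = start, seed = as.integer(seed)),
    class = "swimmer_params")
  validate_swimmer_params(p)
  p
}

validate_swimmer_params <- function(p) {
  stopifnot(inherits(p, "swimmer_params"))
  if (!(is.numeric(p$wave_freq) && p$wave_freq > 0))
    stop("wave_freq must be > 0", call. = FALSE)
  if (!(p$wavelength > 0)) stop("wavelength must be > 0", call. = FALSE)
  if (!(p$tail_amp >= 0)) stop("tail_amp must be >= 0", call. = FALSE)
  if (!(p$fps > 0)) stop("fps must be > 0", call. = FALSE)
  if (!(p$body_length_px > 0)) stop("body_length_px must be > 0", call. = FALSE)
  if (!(p$duration > 0)) stop("duration must be > 0", call. = FALSE)
  if (!(p$jitter_sd >= 0)) stop("jitter_sd must be >= 0", call. = FALSE)
  if (is.null(p$fin_freq) != (p$fin_state == "Off"))
    stop("fin_freq must be absent exactly when fin_state is 'Off'",
         call. = FALSE)
  if (!is.null(p$fin_freq) && p$fin_freq <= 0)
    stop("fin_freq must be > 0 when present", call. = FALSE)
  invisible(p)
}

#' @export
print.swimmer_params <- function(x, ...) {
  cat("<swimmer_params>\n")
  cat(sprintf("  BL %.0f px | U %.3g BL/s | f %.3g Hz | lambda %.3g BL | A %.3g BL\n",
              x$body_length_px, x$swim_speed, x$wave_freq, x$wavelength,
              x$tail_amp))
  cat(sprintf("  fins %s%s | %g fps x %g s | jitter %.2g px | seed %d\n",
              x$fin_state,
              if (is.null(x$fin_freq)) "" else sprintf(" (%.3g Hz)", x$fin_freq),
              x$fps, x$duration, x$jitter_sd, x$seed))
  invisible(x)
}

#' Factorial study design of swimming trials
#'
#' Builds the trial grid of the study the simulator emulates: each fish
#' swims under all 8 conditions (2 viscosities x 2 light levels x 2 lateral
#' line states), with repeated trials per condition.
#'
#' @param n_fish number of individuals (default 5).
#' @param n_trials trials per fish per condition (default 2).
#' @return data.frame with columns `fish_id`, `viscosity` (1 or 40 cP),
#'   `light` ("light"/"dark"), `lateral_line` ("intact"/"blocked"),
#'   `trial_index`.
#' @export
study_design <- function(n_fish = 5, n_trials = 2) {
  d <- expand.grid(
    trial_index = seq_len(n_trials),
    lateral_line = c("intact", "blocked"),
    light = c("light", "dark"),
    viscosity = c(1, 40),
    fish_id = sprintf("fish%02d", seq_len(n_fish)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d[, c("fish_id", "viscosity", "light", "lateral_line", "trial_index")]
}

#' Generate the analytic midline sequence of a synthetic swimmer
#'
#' Evaluates the traveling-wave kinematic model of [swimmer_params()] on a
#' regular grid of body fractions for every frame. Trials shorter than 3
#' locomotor cycles are refused, mirroring the trial-acceptance rule for
#' filmed trials.
#'
#' @param params a `swimmer_params` object.
#' @param n_points midline points per frame (>= 50).
#' @return a `midline_sequence`: list of per-frame [midline] objects plus
#'   `fps` and `body_length_px` (median per-frame arc length).
#' @export
generate_midline_sequence <- function(params, n_points = 100) {
  validate_swimmer_params(params)
  if (n_points < 50) stop("n_points must be >= 50", call. = FALSE)
  if (params$duration < 3 / params$wave_freq)
    stop(sprintf(
      "trial spans %.2f locomotor cycles; at least 3 are required",
      params$duration * params$wave_freq), call. = FALSE)
  nf <- round(params$duration * params$fps)
  BL <- params$body_length_px
  A <- params$tail_amp; pexp <- params$amp_exponent
  lam <- params$wavelength; f <- params$wave_freq
  # dense arc-length grid: s is the body fraction measured along the body,
  # so the midline keeps constant length BL while it bends (x is recovered
  # by integrating dx = sqrt((BL ds)^2 - dy^2))
  nd <- max(1000L, 10L * n_points)
  sd_ <- seq(0, 1, length.out = nd)
  so <- seq(0, 1, length.out = n_points)
  env <- A * BL * sd_^pexp
  denv <- if (pexp == 0) rep(0, nd) else A * BL * pexp * sd_^(pexp - 1)
  if (pexp < 1 && pexp != 0) denv[1] <- 0
  mids <- vector("list", nf)
  for (k in seq_len(nf)) {
    t <- (k - 1) / params$fps
    phi <- 2 * pi * (f * t - sd_ / lam)
    y <- env * sin(phi)
    dyds <- denv * sin(phi) - env * (2 * pi / lam) * cos(phi)
    rel <- dyds / BL
    if (any(abs(rel) >= 1))
      stop("tail_amp too large for an inextensible body (|dy/ds| >= BL)",
           call. = FALSE)
    dxds <- BL * sqrt(1 - rel^2)
    # cumulative trapezoid, head (s = 0) at the leading end
    xrel <- c(0, cumsum((dxds[-1] + dxds[-nd]) / 2 * diff(sd_)))
    head_x <- params$start[1] + params$swim_speed * BL * t
    x <- head_x - xrel
    yy <- params$start[2] + y
    mids[[k]] <- midline(cbind(x = approx(sd_, x, so)$y,
                               y = approx(sd_, yy, so)$y))
  }
  new_midline_sequence(mids, fps = params$fps, body_length_px = BL)
}

#' Render a midline sequence to a binary silhouette stack
#'
#' The silhouette of each frame is the union of disks centred on a densely
#' resampled midline, with radius given by the half-width profile (strictly
#' positive except at the tail tip).
#'
#' @param midlines a `midline_sequence`.
#' @param params optional `swimmer_params` supplying the half-width profile.
#' @param width,height image size in pixels; `NULL` fits the motion with a
#'   margin.
#' @param halfwidth optional half-width function of body fraction,
#'   overriding `params`.
#' @return a `binary_stack` (see [binary_stack()]).
#' @export
render_silhouette <- function(midlines, params = NULL, width = NULL,
                              height = NULL, halfwidth = NULL) {
  stopifnot(inherits(midlines, "midline_sequence"))
  if (is.null(halfwidth)) {
    if (!is.null(params)) halfwidth <- params$halfwidth
    else halfwidth <- function(s) 0.04 * midlines$body_length_px * (1 - s^2)
  }
  sgrid <- seq(0, 0.995, by = 0.005)
  hw <- halfwidth(sgrid)
  if (any(hw <= 0))
    stop("halfwidth profile must be strictly positive except at the tail tip",
         call. = FALSE)
  dense <- lapply(midlines$midlines, function(m) {
    if (nrow(m$points) < 2) stop("zero-length midline", call. = FALSE)
    L <- m$arclen[length(m$arclen)]
    if (L <= 0) stop("zero-length midline", call. = FALSE)
    si <- seq(0, L, by = 1)
    cbind(approx(m$arclen, m$points[, 1], si)$y,
          approx(m$arclen, m$points[, 2], si)$y,
          halfwidth(si / L))
  })
  if (is.null(width) || is.null(height)) {
    xs <- range(unlist(lapply(dense, function(d) range(d[, 1]))))
    ys <- range(unlist(lapply(dense, function(d) range(d[, 2]))))
    rmax <- max(unlist(lapply(dense, function(d) max(d[, 3]))))
    if (is.null(width)) width <- ceiling(xs[2] + rmax + 2)
    if (is.null(height)) height <- ceiling(ys[2] + rmax + 2)
  }
  frames <- vector("list", length(dense))
  for (k in seq_along(dense)) {
    d <- dense[[k]]
    if (any(d[, 1] - d[, 3] < 1 | d[, 1] + d[, 3] > width |
              d[, 2] - d[, 3] < 1 | d[, 2] + d[, 3] > height))
      stop(sprintf("frame %d: midline leaves image bounds", k), call. = FALSE)
    frames[[k]] <- cpp_stamp_disks(height, width, d[, 1], d[, 2], d[, 3])
  }
  binary_stack(frames, fps = midlines$fps,
               px_per_BL = midlines$body_length_px)
}

#' Emit a pose-estimation style landmark track from a midline sequence
#'
#' Digitizes the nose (head end of the midline), tail tip, and both
#' pectoral fin tips. Fin tips sit at a lateral offset from the anterior
#' body (attachment at 15% BL); when the fins are in use the offset
#' oscillates at the fin beat frequency (antiphase left/right), otherwise
#' it is constant. Gaussian jitter of sd `jitter_sd` emulates digitization
#' noise; output is deterministic given `params$seed`.
#'
#' @param midlines a `midline_sequence` from [generate_midline_sequence()].
#' @param params the `swimmer_params` used to generate it.
#' @return a [point_track] with landmarks nose, tail, fin_left, fin_right.
#' @export
emit_tracks <- function(midlines, params) {
  stopifnot(inherits(midlines, "midline_sequence"))
  validate_swimmer_params(params)
  set.seed(params$seed)
  BL <- params$body_length_px
  nf <- length(midlines$midlines)
  d0 <- 0.10 * BL
  damp <- 0.05 * BL
  out <- list(nose = matrix(0, nf, 2), tail = matrix(0, nf, 2),
              fin_left = matrix(0, nf, 2), fin_right = matrix(0, nf, 2))
  for (k in seq_len(nf)) {
    m <- midlines$midlines[[k]]
    npt <- nrow(m$points)
    t <- (k - 1) / midlines$fps
    out$nose[k, ] <- m$points[1, ]
    out$tail[k, ] <- m$points[npt, ]
    ia <- which.min(abs(m$s_frac - 0.15))
    base <- m$points[ia, ]
    h <- m$points[1, ] - m$points[npt, ]       # heading (tailward -> nose)
    h <- h / sqrt(sum(h^2))
    nL <- c(h[2], -h[1])                       # fish-left normal
    if (params$fin_state == "On") {
      dl <- d0 + damp * sin(2 * pi * params$fin_freq * t)
      dr <- d0 + damp * sin(2 * pi * params$fin_freq * t + pi)
    } else {
      dl <- dr <- d0
    }
    out$fin_left[k, ] <- base + nL * dl
    out$fin_right[k, ] <- base - nL * dr
  }
  lm <- lapply(out, function(xy) {
    data.frame(
      x = xy[, 1] + rnorm(nf, 0, params$jitter_sd),
      y = xy[, 2] + rnorm(nf, 0, params$jitter_sd),
      confidence = runif(nf, 0.95, 1))
  })
  point_track(lm, fps = midlines$fps)
}

# numeric swimmer parameters that condition shifts / random intercepts act on
.shiftable <- c("swim_speed", "wave_freq", "wavelength", "tail_amp",
                "fin_freq")

#' Generate a full synthetic study with ground truth
#'
#' Draws per-trial swimmer parameters as base value + condition shifts +
#' per-fish random intercept (normal, sd `fish_sd`) + within-fish trial
#' deviation (normal, sd `trial_sd`), over a factorial [study_design()].
#' Viscosity, light and lateral line are labels only: their kinematic
#' consequences enter exclusively through `effects`.
#'
#' @param design data.frame from [study_design()].
#' @param base `swimmer_params` giving the baseline (intact, light, 1 cP).
#' @param effects named list of condition shifts; recognised names are
#'   `viscosity_40`, `dark`, `blocked`, each a named numeric over
#'   `swim_speed`, `wave_freq`, `wavelength`, `tail_amp`, `fin_freq`, and
#'   optionally `fin_off_prob` (added to the baseline probability that a
#'   trial has its fins off).
#' @param fish_sd named numeric, per-parameter sd of the per-fish intercept.
#' @param trial_sd named numeric, per-parameter sd of the trial-to-trial
#'   deviation within fish.
#' @param fin_off_prob baseline probability a trial is fins-off.
#' @param seed integer; the whole study is reproducible from it.
#' @param emit `"none"` (parameters and truth only), `"tracks"` (also
#'   generate midlines and landmark tracks per trial).
#' @return a `swim_study`: list with `truth` (one row per trial: metadata,
#'   true parameter values, per-trial seed), `params` (list of
#'   `swimmer_params`), and when requested `trials` (list of
#'   `list(midlines, track)`).
#' @export
generate_study <- function(design = study_design(), base = swimmer_params(),
                           effects = list(), fish_sd = numeric(0),
                           trial_sd = numeric(0), fin_off_prob = 0,
                           seed = 1L, emit = c("none", "tracks")) {
  emit <- match.arg(emit)
  validate_swimmer_params(base)
  bad <- setdiff(names(effects), c("viscosity_40", "dark", "blocked"))
  if (length(bad))
    stop("unknown effect names: ", paste(bad, collapse = ", "), call. = FALSE)
  for (e in effects)
    if (!all(is.finite(e))) stop("effect shifts must be finite", call. = FALSE)
  set.seed(seed)
  fish <- unique(design$fish_id)
  intercepts <- matrix(0, length(fish), length(.shiftable),
                       dimnames = list(fish, .shiftable))
  for (p in intersect(names(fish_sd), .shiftable))
    intercepts[, p] <- rnorm(length(fish), 0, fish_sd[[p]])
  n <- nrow(design)
  truth <- design
  truth$trial_id <- sprintf("%s_v%g_%s_%s_t%d", design$fish_id,
                            design$viscosity, design$light,
                            design$lateral_line, design$trial_index)
  for (p in .shiftable) truth[[p]] <- NA_real_
  truth$fin_state <- NA_character_
  truth$seed <- NA_integer_
  params <- vector("list", n)
  base_fin <- if (is.null(base$fin_freq)) NA_real_ else base$fin_freq
  for (i in seq_len(n)) {
    shifts <- setNames(numeric(length(.shiftable)), .shiftable)
    p_off <- fin_off_prob
    conds <- c(if (design$viscosity[i] == 40) "viscosity_40",
               if (design$light[i] == "dark") "dark",
               if (design$lateral_line[i] == "blocked") "blocked")
    for (cn in conds) {
      e <- effects[[cn]]
      if (is.null(e)) next
      for (p in intersect(names(e), .shiftable))
        shifts[p] <- shifts[p] + e[[p]]
      if ("fin_off_prob" %in% names(e)) p_off <- p_off + e[["fin_off_prob"]]
    }
    p_off <- min(1, max(0, p_off))
    val <- c(swim_speed = base$swim_speed, wave_freq = base$wave_freq,
             wavelength = base$wavelength, tail_amp = base$tail_amp,
             fin_freq = base_fin)
    val <- val + shifts + intercepts[design$fish_id[i], ]
    for (p in intersect(names(trial_sd), .shiftable))
      val[p] <- val[p] + rnorm(1, 0, trial_sd[[p]])
    fins_off <- is.na(val["fin_freq"]) || (runif(1) < p_off)
    tseed <- sample.int(.Machine$integer.max - 1L, 1)
    pr <- try(swimmer_params(
      body_length_px = base$body_length_px,
      swim_speed = val[["swim_speed"]], wave_freq = val[["wave_freq"]],
      wavelength = val[["wavelength"]], tail_amp = val[["tail_amp"]],
      amp_exponent = base$amp_exponent,
      fin_freq = if (fins_off) NULL else val[["fin_freq"]],
      fps = base$fps, duration = base$duration, jitter_sd = base$jitter_sd,
      halfwidth = base$halfwidth, start = base$start,
      seed = tseed), silent = TRUE)
    if (inherits(pr, "try-error"))
      stop(sprintf("trial %s: shifted parameters invalid (%s)",
                   truth$trial_id[i],
                   trimws(attr(pr, "condition")$message)), call. = FALSE)
    params[[i]] <- pr
    truth[i, .shiftable] <- as.list(val)
    if (fins_off) truth$fin_freq[i] <- NA_real_
    truth$fin_state[i] <- if (fins_off) "Off" else "On"
    truth$seed[i] <- tseed
  }
  trials <- NULL
  if (emit == "tracks") {
    trials <- lapply(params, function(pr) {
      ms <- generate_midline_sequence(pr)
      list(midlines = ms, track = emit_tracks(ms, pr))
    })
  }
  structure(list(truth = truth, params = params, trials = trials,
                 design = design), class = "swim_study")
}
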