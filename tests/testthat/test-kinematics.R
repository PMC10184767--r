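sine_track <- function(f = 2, duration = 2, fps = 500, amp = 30,
                       drift = 0, BL = 400) {
  t <- seq(0, duration - 1 / fps, by = 1 / fps)
  n <- length(t)
  mk <- function(x, y) data.frame(x = x, y = y, confidence = 1)
  point_track(list(
    nose = mk(100 + drift * t, rep(200, n)),
    tail = mk(100 + drift * t - BL, 200 + amp * sin(2 * pi * f * t))),
    fps = fps)
}

test_that("tail peaks of a sinusoid alternate sides at the right count", {
  tr <- sine_track(f = 2, duration = 2)
  lat <- tail_lateral(tr, cycle_s = 0.5)
  pk <- detect_tail_peaks(lat, 500)
  nL <- sum(pk$side == "left"); nR <- sum(pk$side == "right")
  expect_true(abs(nL - 4) <= 1 && abs(nR - 4) <= 1)
  expect_true(all(pk$side[-1] != pk$side[-nrow(pk)]))   # alternation
})

test_that("flat series and too-few cycles reject the trial", {
  tr <- sine_track(amp = 0)
  lat <- tail_lateral(tr, cycle_s = 0.5)
  expect_error(detect_tail_peaks(lat, 500), "rejected")
  short <- sine_track(f = 2, duration = 1.1)             # ~2 cycles
  ms <- make_wave_midlines(duration = 1.1, f = 2)
  res <- assemble_trial(short, ms)
  expect_false(res$accepted)
  expect_match(res$reject_reason, "cycles|rejected")
})

test_that("peak detection is stable under 5% noise", {
  base <- sine_track(f = 2, duration = 2)
  lat0 <- tail_lateral(base, cycle_s = 0.5)
  n0 <- nrow(detect_tail_peaks(lat0, 500))
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- base
    noisy$landmarks$tail$y <- noisy$landmarks$tail$y + rnorm(1000, 0, 1.5)
    lat <- tail_lateral(noisy, cycle_s = 0.5)
    lat <- lowpass_adaptive(lat, 500, 2)
    nrow(detect_tail_peaks(lat, 500)) == n0
  }, logical(1))
  expect_gte(sum(ok), 95)
})

test_that("swimming speed: net displacement over whole cycles per BL", {
  t <- seq(0, 1 - 1 / 500, by = 1 / 500)
  mk <- function(x, y) data.frame(x = x, y = y, confidence = 1)
  tr <- point_track(list(nose = mk(100 + 200 * t, rep(0, 500)),
                         tail = mk(500 + 200 * t, rep(0, 500))), fps = 500)
  expect_equal(swimming_speed(tr, 400), 200 / 400, tolerance = 1e-6)
  osc <- sine_track(f = 2, duration = 2, amp = 30, drift = 0)
  lat <- tail_lateral(osc, cycle_s = 0.5)
  pk <- detect_tail_peaks(lat, 500)
  expect_lt(swimming_speed(osc, 400, pk), 0.01 * 30 / 400 + 1e-3)
})

test_that("tail amplitude via the left-peak chord is drift-invariant", {
  # brute-force point-line oracle: amplitude a, drift d per cycle
  a <- 40; BL <- 400
  geom <- function(d) {
    pk <- data.frame(frame = c(1, 251, 501), time = c(0, 0.5, 1),
                     side = c("left", "right", "left"),
                     excursion = c(a, -a, a))
    xy <- matrix(0, 501, 2)
    xy[1, ] <- c(0, a)
    xy[251, ] <- c(d / 2, -a)
    xy[501, ] <- c(d, a)
    tail_amplitude(pk, xy, BL)
  }
  expect_equal(geom(0), a / BL, tolerance = 1e-10)
  expect_equal(geom(35), a / BL, tolerance = 1e-10)      # same with drift
})

test_that("body wave frequency is the mean same-side peak rate", {
  pk <- data.frame(frame = 1, time = c(0, 0.4, 0.8),
                   side = "left", excursion = 1)
  expect_equal(body_wave_frequency(pk), 2.5)
  pk2 <- data.frame(frame = 1, time = c(0, 0.4, 0.9),
                    side = "left", excursion = 1)
  expect_equal(body_wave_frequency(pk2), mean(c(2.5, 2)))
})

test_that("fin frequency from adduction minima; absence is NA, never zero", {
  t <- seq(0, 1 - 1 / 500, by = 1 / 500)
  mk <- function(x, y) data.frame(x = x, y = y, confidence = 1)
  mkfin <- function(d) point_track(list(
    nose = mk(rep(400, 500), rep(200, 500)),
    tail = mk(rep(100, 500), rep(200, 500)),
    fin_right = mk(rep(360, 500), 200 + d)), fps = 500)
  tr <- mkfin(25 + 10 * sin(2 * pi * 4 * t))
  expect_equal(pectoral_fin_frequency(tr, 300), 4, tolerance = 0.03)
  expect_equal(fin_state(pectoral_fin_frequency(tr, 300)), "On")
  cons <- mkfin(rep(25, 500))
  expect_true(is.na(pectoral_fin_frequency(cons, 300)))
  expect_equal(fin_state(NA_real_), "Off")
  set.seed(2)
  noisy <- mkfin(25 + rnorm(500, 0, 1))                  # jitter only
  expect_true(is.na(pectoral_fin_frequency(noisy, 300)))
})

test_that("wave speed recovers f*lambda on an envelope-free wave", {
  ms <- make_wave_midlines(lambda = 0.5, f = 2, amp = 0.05, p = 0,
                           duration = 1.5)
  cf <- curvature_field(ms)
  v <- body_wave_speed(cf)
  expect_equal(as.numeric(v), 100 * 2 * 0.5, tolerance = 0.10)
})

test_that("a standing flexion yields no transit and a missing value", {
  cf <- make_standing_field()
  expect_warning(v <- body_wave_speed(cf), "missing")
  expect_true(is.na(v))
})

test_that("wave speed is invariant to doubling the frame rate", {
  v1 <- body_wave_speed(curvature_field(
    make_wave_midlines(lambda = 0.5, f = 2, p = 0, fps = 500,
                       duration = 1.5)))
  v2 <- body_wave_speed(curvature_field(
    make_wave_midlines(lambda = 0.5, f = 2, p = 0, fps = 1000,
                       duration = 1.5)))
  expect_equal(as.numeric(v2), as.numeric(v1), tolerance = 0.02)
})

test_that("wavelength from curvature extrema on envelope-free waves", {
  ms <- make_wave_midlines(lambda = 0.6, amp = 0.05, p = 0, duration = 0.6)
  wl <- body_wavelength(curvature_field(ms))
  expect_equal(wl$wavelength, 0.6, tolerance = 0.10)
  for (A in c(0.02, 0.05, 0.08)) {
    ms <- make_wave_midlines(lambda = 0.6, amp = A, p = 0, duration = 0.6)
    wl <- body_wavelength(curvature_field(ms))
    expect_equal(wl$wavelength, 0.6, tolerance = 0.10)
  }
})

test_that("a straight fish has no wavelength", {
  ms <- make_wave_midlines(amp = 0, duration = 0.2)
  cf <- curvature_field(ms)
  expect_warning(wl <- body_wavelength(cf), "missing")
  expect_true(is.na(wl$wavelength))
})

test_that("assembled synthetic trial populates all seven variables", {
  p <- swimmer_params(seed = 17)
  ms <- generate_midline_sequence(p)
  tr <- emit_tracks(ms, p)
  res <- assemble_trial(tr, ms)
  expect_true(res$accepted)
  expect_true(all(is.finite(c(res$swim_speed, res$fin_freq, res$tail_amp,
                              res$wave_freq, res$wave_speed,
                              res$wavelength))))
  expect_equal(res$fin_state, "On")
  expect_gte(res$n_cycles, 3)
})

test_that("fins-off trials propagate missing fin frequency, never zero", {
  p <- swimmer_params(fin_freq = NULL, fin_state = "Off", seed = 18)
  ms <- generate_midline_sequence(p)
  tr <- emit_tracks(ms, p)
  res <- assemble_trial(tr, ms)
  expect_true(res$accepted)
  expect_true(is.na(res$fin_freq))
  expect_identical(res$fin_state, "Off")
})

test_that("BL-normalized outputs are invariant to uniform rescaling", {
  p <- swimmer_params(seed = 4)
  ms <- generate_midline_sequence(p)
  tr <- emit_tracks(ms, p)
  base <- assemble_trial(tr, ms)
  for (sc in c(0.5, 2)) {
    trs <- point_track(lapply(tr$landmarks, function(lm) {
      lm$x <- lm$x * sc; lm$y <- lm$y * sc; lm
    }), fps = tr$fps)
    mss <- swimkin:::new_midline_sequence(
      lapply(ms$midlines, function(m) midline(m$points * sc)),
      fps = ms$fps)
    res <- assemble_trial(trs, mss)
    for (v in c("swim_speed", "tail_amp", "wave_freq", "wave_speed",
                "wavelength"))
      expect_equal(res[[v]], base[[v]], tolerance = 0.02)
  }
})
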