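test_that("zero-amplitude, zero-speed swimmer is a frozen straight segment", {
  p <- swimmer_params(tail_amp = 0, swim_speed = 0, jitter_sd = 0,
                      fin_freq = NULL, duration = 1.5)
  ms <- generate_midline_sequence(p)
  ref <- ms$midlines[[1]]$points
  expect_true(all(abs(ref[, 2] - ref[1, 2]) < 1e-9))      # straight
  for (k in c(100, 400, 750))
    expect_equal(ms$midlines[[k]]$points, ref, tolerance = 1e-12)
})

test_that("tail-tip trace oscillates wave_freq * duration times at amplitude A*BL", {
  p <- swimmer_params(wave_freq = 2.5, duration = 2, jitter_sd = 0)
  ms <- generate_midline_sequence(p)
  taily <- vapply(ms$midlines, function(m) m$points[nrow(m$points), 2],
                  numeric(1))
  dev <- taily - mean(taily)
  n_osc <- sum(diff(sign(dev)) != 0) / 2
  expect_equal(n_osc, 2.5 * 2, tolerance = 0.21)          # 5 full cycles
  expect_equal(max(abs(dev)), 0.08 * 300, tolerance = 0.01)
})

test_that("curvature crest travels at f*lambda (dense differentiation oracle)", {
  # envelope-free wave: the crest of |kappa| is an exact phase tracer
  p <- swimmer_params(wave_freq = 2, wavelength = 0.5, tail_amp = 0.05,
                      amp_exponent = 0, duration = 2, jitter_sd = 0)
  ms <- generate_midline_sequence(p, n_points = 200)
  crest_s <- function(m, lo, hi) {
    pts <- m$points
    th <- atan2(diff(pts[, 2]), diff(pts[, 1]))
    th <- swimkin:::unwrap_angle(th)
    sarc <- m$arclen
    smid <- (sarc[-1] + sarc[-length(sarc)]) / 2
    kap <- diff(th) / diff(smid)[1]
    sfr <- smid[-1] / sarc[length(sarc)]
    a <- abs(kap[-1])
    sel <- sfr >= lo & sfr <= hi
    sfr[sel][which.max(a[sel])]
  }
  s0 <- crest_s(ms$midlines[[1]], 0.25, 0.45)
  pos <- numeric(0); tt <- numeric(0)
  cur <- s0
  for (k in seq(1, 250, by = 5)) {
    cur <- crest_s(ms$midlines[[k]], cur - 0.03, cur + 0.05)
    pos <- c(pos, cur); tt <- c(tt, (k - 1) / 500)
    if (cur > 0.85) break
  }
  slope <- coef(lm(pos ~ tt))[2]
  expect_equal(unname(slope), 2 * 0.5, tolerance = 0.02)  # BL s^-1
})

test_that("trials shorter than 3 locomotor cycles are refused", {
  p <- swimmer_params(wave_freq = 2.5, duration = 1)      # 2.5 cycles
  expect_error(generate_midline_sequence(p), "at least 3")
  expect_silent(generate_midline_sequence(
    swimmer_params(wave_freq = 2.5, duration = 1.21)))
})

test_that("same seed reproduces tracks bit for bit; nose is exact without jitter", {
  p <- swimmer_params(jitter_sd = 0, duration = 1.21)
  ms <- generate_midline_sequence(p)
  tr <- emit_tracks(ms, p)
  expect_identical(tr$landmarks$nose$x,
                   vapply(ms$midlines, function(m) m$points[1, 1],
                          numeric(1)))
  p2 <- swimmer_params(jitter_sd = 1, duration = 1.21, seed = 99)
  t1 <- emit_tracks(ms, p2)
  t2 <- emit_tracks(ms, p2)
  expect_identical(t1, t2)
  p3 <- swimmer_params(jitter_sd = 1, duration = 1.21, seed = 100)
  expect_false(identical(emit_tracks(ms, p3)$landmarks$nose$x,
                         t1$landmarks$nose$x))
})

test_that("digitization jitter has the Rayleigh mean displacement", {
  # |track - truth| of a 2D point with iid N(0, sd^2) coordinates is
  # Rayleigh; mean = sd * sqrt(pi / 2)
  p0 <- swimmer_params(jitter_sd = 0, duration = 2)
  ms <- generate_midline_sequence(p0)
  truth <- emit_tracks(ms, p0)
  d <- numeric(0)
  for (sd_seed in 1:3) {
    pj <- swimmer_params(jitter_sd = 1, duration = 2, seed = sd_seed)
    tj <- emit_tracks(ms, pj)
    for (lm in names(tj$landmarks))
      d <- c(d, sqrt((tj$landmarks[[lm]]$x - truth$landmarks[[lm]]$x)^2 +
                       (tj$landmarks[[lm]]$y - truth$landmarks[[lm]]$y)^2))
  }
  expect_gt(length(d), 1e4)
  expect_equal(mean(d), sqrt(pi / 2), tolerance = 0.05)
})

test_that("fins-off trials keep a constant fin-to-local-axis distance", {
  p <- swimmer_params(fin_freq = NULL, fin_state = "Off", jitter_sd = 0,
                      duration = 1.21)
  ms <- generate_midline_sequence(p)
  tr <- emit_tracks(ms, p)
  fin <- as.matrix(tr$landmarks$fin_right[, 1:2])
  # distance to the true local axis at the fin attachment (anterior body)
  d <- vapply(seq_along(ms$midlines), function(k) {
    m <- ms$midlines[[k]]
    i1 <- which.min(abs(m$s_frac - 0.10))
    i2 <- which.min(abs(m$s_frac - 0.20))
    a <- m$points[i1, ]; b <- m$points[i2, ]
    v <- b - a
    abs(v[1] * (fin[k, 2] - a[2]) - v[2] * (fin[k, 1] - a[1])) /
      sqrt(sum(v^2))
  }, numeric(1))
  expect_lt(diff(range(d)), 1.5)   # constant offset up to local-axis wobble
  # and the detector agrees: no fin frequency is reported
  expect_true(is.na(pectoral_fin_frequency(tr, 300)))
})

test_that("swimmer_params enforces its invariants", {
  expect_error(swimmer_params(wave_freq = -1), "wave_freq")
  expect_error(swimmer_params(wavelength = 0), "wavelength")
  expect_error(swimmer_params(tail_amp = -0.1), "tail_amp")
  expect_error(swimmer_params(fin_freq = NULL, fin_state = "On"), "fin")
  expect_error(swimmer_params(fin_freq = 3, fin_state = "Off"), "fin")
})

test_that("study design covers 5 fish x 8 conditions x 2 trials", {
  d <- study_design()
  expect_equal(nrow(d), 80)
  expect_equal(nrow(unique(d[, c("viscosity", "light", "lateral_line")])), 8)
  expect_equal(as.integer(table(d$fish_id)), rep(16L, 5))
})

test_that("generate_study applies shifts by construction and is reproducible", {
  st <- generate_study(effects = list(viscosity_40 = c(wave_freq = 0.5)),
                       seed = 11)
  tr <- st$truth
  expect_equal(mean(tr$wave_freq[tr$viscosity == 40]) -
                 mean(tr$wave_freq[tr$viscosity == 1]), 0.5)
  st0 <- generate_study(seed = 3)
  expect_true(all(vapply(st0$params[-1], function(q)
    identical(q[setdiff(names(q), c("seed", "halfwidth"))],
              st0$params[[1]][setdiff(names(q), c("seed", "halfwidth"))]),
    logical(1))))
  st2 <- generate_study(effects = list(viscosity_40 = c(wave_freq = 0.5)),
                        seed = 11)
  expect_identical(st$truth, st2$truth)
})

test_that("between-fish intercept sd propagates to between-fish variance", {
  # fish sd 0.2 with no trial noise: variance of per-fish mean truth
  # should average 0.04 across replicate studies
  vs <- vapply(1:200, function(sd_) {
    st <- generate_study(fish_sd = c(wave_freq = 0.2), seed = sd_)
    fm <- tapply(st$truth$wave_freq, st$truth$fish_id, mean)
    var(as.numeric(fm))
  }, numeric(1))
  expect_equal(mean(vs), 0.04, tolerance = 0.15)
})

test_that("invalid shifted parameters name the offending trial", {
  expect_error(
    generate_study(effects = list(dark = c(wave_freq = -5)), seed = 1),
    "trial .*dark.*invalid")
})
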