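# shared fixtures and independent oracles, built in code at test time

# midline sequence built directly from an explicit lateral-wave formula
# (independent of the swimmer generator): y = amp * BL * (s^p) * sin(2*pi*
# (f*t - s/lambda)) on a straight backbone, x-parameterized
make_wave_midlines <- function(lambda = 0.6, amp = 0.05, p = 0, f = 2,
                               BL = 300, fps = 500, duration = 1,
                               n_points = 100) {
  nf <- round(duration * fps)
  s <- seq(0, 1, length.out = n_points)
  mids <- lapply(seq_len(nf), function(k) {
    t <- (k - 1) / fps
    y <- amp * BL * s^p * sin(2 * pi * (f * t - s / lambda))
    midline(cbind(x = 500 - s * BL, y = 200 + y))
  })
  swimkin:::new_midline_sequence(mids, fps = fps, body_length_px = BL)
}

# brute-force point-to-polyline distance
dist_to_polyline <- function(p, poly) {
  d2 <- Inf
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    v <- b - a
    tt <- sum((p - a) * v) / sum(v * v)
    tt <- max(0, min(1, tt))
    q <- a + tt * v
    d2 <- min(d2, sum((p - q)^2))
  }
  sqrt(d2)
}

# independent exact-test oracle for 2x2 tables: hypergeometric enumeration
fisher_2x2_oracle <- function(tab) {
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2]); r1 <- sum(tab[1, ])
  a <- max(0, r1 - c2):min(c1, r1)
  probs <- dhyper(a, c1, c2, r1)
  pobs <- dhyper(tab[1, 1], c1, c2, r1)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# standing-flexion curvature field (no traveling wave)
make_standing_field <- function(fps = 500, duration = 1, n_points = 100,
                                BL = 300) {
  nf <- round(duration * fps)
  s <- seq(0, 1, length.out = n_points)
  g <- sin(2 * pi * s / 0.6) * 0.02
  kap <- outer(g, sin(2 * pi * 2 * (seq_len(nf) - 1) / fps))
  mids <- lapply(seq_len(nf), function(k)
    midline(cbind(x = 500 - s * BL, y = 200 + 0 * s)))
  structure(list(kappa = kap, s_frac = s, fps = fps, body_length_px = BL,
                 midlines = mids), class = "curvature_field")
}
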