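sim_table <- function(seed = 1, effects = list(
  viscosity_40 = c(wave_freq = 0.5), blocked = c(wave_freq = -0.2)),
  fish_sd = c(wave_freq = 0.2, swim_speed = 0.05),
  trial_sd = c(wave_freq = 0.1, swim_speed = 0.1)) {
  generate_study(effects = effects, fish_sd = fish_sd,
                 trial_sd = trial_sd, seed = seed)$truth
}

test_that("mixed model recovers simulated fixed effects and agrees with lme4", {
  tt <- sim_table(seed = 21)
  fit <- fit_variable_model(tt, "wave_freq", interactions = "none")
  fe <- fixed_effects(fit)
  expect_equal(unname(fe["viscosity40"]), 0.5, tolerance = 0.15)
  expect_equal(unname(fe["lateral_lineblocked"]), -0.2, tolerance = 0.25)
  vc <- variance_components(fit)
  expect_gt(vc$fish_sd, 0.05); expect_lt(vc$fish_sd, 0.5)
  expect_equal(vc$residual_sd, 0.1, tolerance = 0.35)
  skip_if_not_installed("lme4")
  lf <- lme4::lmer(
    wave_freq ~ swim_speed + viscosity + light + lateral_line +
      (1 | fish_id), data = as_trial_table(tt), REML = TRUE)
  expect_equal(unname(fe), unname(lme4::fixef(lf)), tolerance = 1e-4)
})

test_that("constant response degenerates to zero effects and variances", {
  tt <- sim_table(seed = 5)
  tt$wave_freq <- 2.5
  fit <- fit_variable_model(tt, "wave_freq")
  expect_true(fit$degenerate)
  expect_equal(variance_components(fit),
               list(fish_sd = 0, residual_sd = 0))
  expect_equal(unname(fixed_effects(fit)), 2.5)
})

test_that("varIdent weighting recovers a 4x residual variance ratio", {
  ratios <- vapply(1:40, function(s) {
    set.seed(s)
    tt <- sim_table(seed = s, trial_sd = c(wave_freq = 0.05))
    hi <- tt$viscosity == 40
    tt$wave_freq[hi] <- tt$wave_freq[hi] + rnorm(sum(hi), 0, 0.2)
    tt$wave_freq[!hi] <- tt$wave_freq[!hi] + rnorm(sum(!hi), 0, 0.1)
    fit <- fit_variable_model(tt, "wave_freq",
                              variance_groups = "viscosity")
    vs <- variance_components(fit)$group_residual_sd
    (vs[["40"]] / vs[["1"]])^2
  }, numeric(1))
  expect_gt(median(ratios), 2.5)
  expect_lt(median(ratios), 6)
})

test_that("EMMs equal raw group means on a balanced design with fixed covariate", {
  tt <- sim_table(seed = 31)
  tt$swim_speed <- 0.5                    # covariate carries no information
  fit <- fit_variable_model(tt, "wave_freq", interactions = "none")
  ct <- emmeans_contrasts(fit, factors = "viscosity")
  raw <- tapply(tt$wave_freq, tt$viscosity, mean)
  expect_equal(ct$estimate, unname(raw["1"] - raw["40"]), tolerance = 1e-8)
})

test_that("Bonferroni adjustment is the clamped product and order-preserving", {
  tt <- sim_table(seed = 41)
  fit <- fit_variable_model(tt, "wave_freq")
  ct <- emmeans_contrasts(fit)
  expect_equal(ct$p_adjusted, pmin(1, ct$p_raw * nrow(ct)))
  expect_true(all(ct$p_adjusted >= ct$p_raw))
  expect_equal(order(ct$p_raw), order(ct$p_adjusted))
  ct4 <- emmeans_contrasts(fit, n_comparisons = 4)
  i <- which.min(abs(ct4$p_raw - 0.01))
  expect_equal(ct4$p_adjusted, pmin(1, ct4$p_raw * 4))
})

test_that("exact contingency test matches closed forms and fisher.test", {
  expect_equal(fisher_exact(matrix(c(2, 2, 2, 2), 2))$p.value, 1)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p.value, 2 / 252,
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p.value,
                 fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  tab3 <- matrix(c(4, 1, 2, 3, 1, 4), 2)   # 2 x 3
  expect_equal(fisher_exact(tab3)$p.value,
               fisher.test(tab3)$p.value, tolerance = 1e-9)
})

test_that("exact test is symmetric under row and column permutation", {
  set.seed(11)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 4) + 1, 2)
    p <- fisher_exact(tab)$p.value
    expect_gt(p, 0); expect_lte(p, 1)
    expect_equal(fisher_exact(tab[2:1, ])$p.value, p, tolerance = 1e-12)
    expect_equal(fisher_exact(tab[, c(2, 1, 3)])$p.value, p,
                 tolerance = 1e-12)
  }
})

test_that("zero-margin tables carry no information", {
  expect_warning(r <- fisher_exact(matrix(c(3, 0, 5, 0), 2)), "margin")
  expect_equal(r$p.value, 1)
})

test_that("fin-state tables are built per factor and per condition", {
  tt <- sim_table(seed = 3)
  tt$fin_state <- rep(c("On", "Off"), length.out = nrow(tt))
  ft <- fin_state_table(tt)
  expect_equal(dim(ft$viscosity), c(2L, 2L))
  expect_equal(dim(ft$condition), c(2L, 8L))
  expect_equal(sum(ft$viscosity), nrow(tt))
})

test_that("outlier screening flags a planted extreme trial and only that", {
  tt <- sim_table(seed = 51)
  flags <- screen_outliers(tt, "wave_freq")
  expect_equal(nrow(flags), 0)
  tt2 <- tt
  fit <- fit_variable_model(tt2, "wave_freq")
  tt2$wave_freq[10] <- tt2$wave_freq[10] +
    6 * variance_components(fit)$residual_sd
  flags2 <- screen_outliers(tt2, "wave_freq")
  expect_true(any(flags2$flagged))
  flags3 <- screen_outliers(tt2, "wave_freq", threshold = Inf)
  expect_equal(nrow(flags3), 0)
})

test_that("clean tables are rarely flagged at threshold 3", {
  n_flagged <- sum(vapply(1:30, function(s) {
    tt <- sim_table(seed = 100 + s)
    nrow(screen_outliers(tt, "wave_freq")) > 0
  }, logical(1)))
  expect_lte(n_flagged, 4)
})

test_that("empty reference-grid cells are reported", {
  tt <- sim_table(seed = 61)
  tt <- tt[!(tt$viscosity == 40 & tt$light == "dark"), ]
  fit <- fit_variable_model(tt, "wave_freq", interactions = "none")
  expect_error(emmeans_contrasts(fit), "empty cells")
})
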