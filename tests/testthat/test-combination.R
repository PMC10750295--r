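test_that("fa conversion implements 1 - percent/100 with boundary clamps", {
  expect_equal(fa_from_viability(50), 0.5)
  expect_equal(quiet_sx(fa_from_viability(100)), 0.01)   # clamp low
  expect_equal(quiet_sx(fa_from_viability(0)), 0.99)     # clamp high
  expect_error(fa_from_viability(-5), "negative")
})

test_that("median-effect fit recovers exact and noisy parameters", {
  truth <- list(m = 2, Dm = 0.5)
  doses <- 0.5 * 2^seq(-3, 3)
  fa <- effect_at_dose(truth, doses)
  fit <- fit_median_effect(doses, fa)
  expect_equal(fit$m, 2, tolerance = 1e-10)
  expect_equal(fit$Dm, 0.5, tolerance = 1e-10)
  expect_equal(fit$r, 1, tolerance = 1e-10)
  # fa at Dm is 0.5 by definition under the fitted curve
  expect_equal(effect_at_dose(fit, fit$Dm), 0.5, tolerance = 1e-12)

  # replicates averaged on the fa scale
  fit_rep <- fit_median_effect(c(doses, doses[1], doses[1]),
                               c(fa, fa[1] + 0.01, fa[1] - 0.01))
  expect_equal(fit_rep$m, fit$m, tolerance = 1e-6)

  # noisy grid: within 10% of truth
  grid <- simulate_dose_response(truth, doses1 = doses,
                                 combo_pairs = data.frame(agent1_dose = doses[1],
                                                          agent2_dose = doses[1]),
                                 interaction = "sham", noise_sd = 0.02, seed = 2)
  single <- grid[grid$agent2_dose == 0, ]
  fitn <- fit_median_effect(single$agent1_dose, single$fa)
  expect_lt(abs(fitn$m - truth$m) / truth$m, 0.1)
  expect_lt(abs(fitn$Dm - truth$Dm) / truth$Dm, 0.1)

  expect_error(fit_median_effect(1, 0.5), ">= 2 distinct doses")
  expect_warning(fit_median_effect(c(1, 2), c(0.6, 0.4)), "m <= 0")
})

test_that("dose_for_effect inverts the fitted curve", {
  p <- list(m = 1, Dm = 1)
  expect_equal(dose_for_effect(p, 0.5), 1)
  expect_equal(dose_for_effect(p, 0.75), 3)
  p2 <- list(m = 2.3, Dm = 0.7)
  for (fa in c(0.1, 0.25, 0.5, 0.9)) {
    expect_equal(effect_at_dose(p2, dose_for_effect(p2, fa)), fa,
                 tolerance = 1e-9)
  }
  expect_error(dose_for_effect(p, 1), "inside")
})

test_that("combination index: sham identity, synergy factor, degenerate D2", {
  truth <- list(m = 1.8, Dm = 0.6)
  doses <- 0.6 * 2^seq(-2, 2)
  fa <- effect_at_dose(truth, doses)
  fit <- fit_median_effect(doses, fa)

  # sham self-combination at (d/2, d/2): CI = 1 and call additive
  for (d in doses) {
    fa_c <- effect_at_dose(truth, d)
    ci <- combination_index(fit, fit, d / 2, d / 2, fa_c)
    expect_equal(ci$CI, 1, tolerance = 1e-6)
    expect_equal(ci$call, "additive")
    # invariant: CI decomposes as D1/Dx1 + D2/Dx2
    expect_equal(ci$CI, ci$D1 / ci$Dx1 + ci$D2 / ci$Dx2, tolerance = 1e-12)
  }

  # D2 = 0 degenerates to single-agent consistency: CI = 1 at D1 = Dx1
  fa_c <- 0.4
  ci0 <- combination_index(fit, fit, dose_for_effect(fit, fa_c), 0, fa_c)
  expect_equal(ci0$CI, 1, tolerance = 1e-9)

  # synergy-factor-2 construction: CI ~ 0.5 across effect levels
  p1 <- list(m = 2, Dm = 0.5); p2 <- list(m = 1.5, Dm = 2)
  d1 <- 0.5 * 2^seq(-3, 3); d2 <- 2 * 2^seq(-3, 3)
  grid <- simulate_dose_response(p1, p2, d1, d2, interaction = "synergy",
                                 synergy_factor = 2, noise_sd = 0)
  surf <- ci_surface(grid)
  for (fa_lv in c(0.25, 0.5, 0.75)) {
    near <- surf[which.min(abs(surf$fa - fa_lv)), ]
    expect_lt(abs(near$CI - 0.5), 0.05)
  }
  expect_true(all(surf$call == "synergy"))

  # non-exclusive variant adds the cross term
  cin <- combination_index(fit, fit, 0.3, 0.3, 0.5, exclusive = FALSE)
  cie <- combination_index(fit, fit, 0.3, 0.3, 0.5)
  expect_equal(cin$CI, cie$CI + (0.3 * 0.3) / (cie$Dx1 * cie$Dx2),
               tolerance = 1e-12)
})

test_that("ci_surface handles additive grids, margins and replicates", {
  p1 <- list(m = 2, Dm = 1); p2 <- list(m = 1, Dm = 4)
  d1 <- 2^seq(-2, 2); d2 <- 4 * 2^seq(-2, 2)
  grid <- simulate_dose_response(p1, p2, d1, d2,
                                 interaction = "loewe_additive", noise_sd = 0)
  surf <- ci_surface(grid)
  expect_equal(nrow(surf), length(d1) * length(d2))
  expect_true(all(abs(surf$CI - 1) <= 0.1))

  # synergy grid: median CI < 1
  gs <- simulate_dose_response(p1, p2, d1, d2, interaction = "synergy",
                               synergy_factor = 1.5, noise_sd = 0)
  expect_lt(stats::median(ci_surface(gs)$CI), 1)

  # single interior cell (full margins kept)
  g1 <- grid[grid$agent1_dose == 0 | grid$agent2_dose == 0 |
               (grid$agent1_dose == d1[3] & grid$agent2_dose == d2[3]), ]
  expect_equal(nrow(ci_surface(g1)), 1L)

  # missing margins error
  expect_error(ci_surface(grid[grid$agent2_dose > 0, ]), "margins")

  # replicate interior cells averaged
  g2 <- rbind(grid, grid[grid$agent1_dose > 0 & grid$agent2_dose > 0, ][1, ])
  expect_equal(nrow(ci_surface(g2)), nrow(surf))

  # percent_of_control input converts through fa
  g3 <- grid
  g3$percent_of_control <- 100 * (1 - g3$fa)
  g3$fa <- NULL
  surf3 <- ci_surface(g3)
  expect_equal(surf3$CI, surf$CI, tolerance = 1e-9)
})

test_that("dose-scale equivariance: rescaling agent-1 doses cancels in CI", {
  p1 <- list(m = 2, Dm = 0.5); p2 <- list(m = 1.2, Dm = 3)
  d1 <- 0.5 * 2^seq(-2, 2); d2 <- 3 * 2^seq(-2, 2)
  grid <- simulate_dose_response(p1, p2, d1, d2,
                                 interaction = "loewe_additive", noise_sd = 0)
  surf <- ci_surface(grid)
  c_scale <- 1000
  grid2 <- grid
  grid2$agent1_dose <- grid2$agent1_dose * c_scale
  surf2 <- ci_surface(grid2)
  expect_equal(attr(surf2, "fit1")$Dm, attr(surf, "fit1")$Dm * c_scale,
               tolerance = 1e-9)
  expect_equal(surf2$CI, surf$CI, tolerance = 1e-9)
})

test_that("median-effect parameter recovery over random noisy grids", {
  # scaled-down version of the 200-grid sweep (full sweep in acceptance)
  set.seed(55)
  rel_err <- replicate(40, {
    m <- runif(1, 0.5, 3); Dm <- exp(runif(1, log(0.1), log(10)))
    doses <- Dm * 2^seq(-3, 3)
    grid <- simulate_dose_response(list(m = m, Dm = Dm), doses1 = doses,
                                   combo_pairs = data.frame(agent1_dose = doses[1],
                                                            agent2_dose = doses[1]),
                                   interaction = "sham", noise_sd = 0.02,
                                   seed = sample.int(1e6, 1))
    single <- grid[grid$agent2_dose == 0, ]
    fit <- fit_median_effect(single$agent1_dose, single$fa)
    max(abs(fit$m - m) / m, abs(fit$Dm - Dm) / Dm)
  })
  expect_lt(stats::median(rel_err), 0.1)
})
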