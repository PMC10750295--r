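test_that("correlate matches hand values, symmetry and affine invariance", {
  # perfect anticorrelation
  r1 <- correlate(1:5, -(1:5))
  expect_equal(r1$pearson_r, -1)
  expect_equal(r1$slope, -1)

  # frozen hand computation: cov 2.5, var_x 2.5, var_y 3.7
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  r2 <- correlate(x, y)
  expect_equal(r2$pearson_r, 0.822, tolerance = 1e-3)
  expect_equal(r2$r_p, stats::cor.test(x, y)$p.value, tolerance = 1e-10)
  expect_equal(r2$slope, 1)

  # r and p symmetric in (x, y); slope is not (OLS of y on x)
  r3 <- correlate(y, x)
  expect_equal(r3$pearson_r, r2$pearson_r)
  expect_equal(r3$r_p, r2$r_p)

  # invariant under positive affine maps of both axes
  r4 <- correlate(3 * x + 7, 0.5 * y - 2)
  expect_equal(r4$pearson_r, r2$pearson_r, tolerance = 1e-12)

  # missing pairs dropped and counted
  r5 <- correlate(c(x, NA), c(y, 1))
  expect_equal(r5$n, 5L)
  expect_equal(r5$n_dropped, 1L)

  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(correlate(1:2, 2:1), ">= 3")
})

test_that("stratified regression recovers noiseless and noisy planted lines", {
  # noiseless: wt y = 2 - 0.5x, mut y = 3 - 0.5x -> offset exactly 1
  x <- rep(seq(0, 10, length.out = 25), 2)
  strata <- rep(c("wild_type", "mutant"), each = 25)
  y <- ifelse(strata == "wild_type", 2 - 0.5 * x, 3 - 0.5 * x)
  fit <- stratified_regression(x, y, strata)
  expect_equal(fit$per_stratum$wild_type$intercept, 2, tolerance = 1e-12)
  expect_equal(fit$per_stratum$mutant$intercept, 3, tolerance = 1e-12)
  expect_equal(fit$per_stratum$mutant$slope, -0.5, tolerance = 1e-12)
  expect_equal(fit$offset_at_mean, 1, tolerance = 1e-12)

  # noisy: sd 0.2, n = 50/stratum -> offset within +-0.15 of 1
  set.seed(77)
  x2 <- rep(runif(50, 0, 10), 2)
  strata2 <- rep(c("wild_type", "mutant"), each = 50)
  y2 <- ifelse(strata2 == "wild_type", 2 - 0.5 * x2, 3 - 0.5 * x2) +
    rnorm(100, 0, 0.2)
  fit2 <- stratified_regression(x2, y2, strata2)
  expect_lt(abs(fit2$offset_at_mean - 1), 0.15)

  # unknown-status samples excluded and counted; small stratum skipped
  fit3 <- quiet_sx(stratified_regression(c(x, 1, 2), c(y, 5, 5),
                                         c(strata, "unknown", NA)))
  expect_equal(fit3$n_unknown, 2L)
  fit4 <- quiet_sx(stratified_regression(c(1:10, 1, 2), c(2 * (1:10), 5, 6),
                                         c(rep("wild_type", 10), "mutant", "mutant")))
  expect_null(fit4$per_stratum$mutant)
  expect_true(is.na(fit4$offset_at_mean))
})

test_that("dichotomize implements the median/quantile rule with ties low", {
  g <- dichotomize(1:10)
  expect_equal(sum(g == "high"), 5L)
  expect_equal(sum(g == "low"), 5L)

  # ties at the cutpoint go low
  g2 <- quiet_sx(dichotomize(c(1, 2, 5, 5, 5, 9, 10)))
  expect_equal(attr(g2, "cutpoint"), 5)
  expect_equal(attr(g2, "n_ties"), 3L)
  expect_equal(sum(g2 == "high"), 2L)

  g3 <- dichotomize(1:100, rule = "quantile", q = 0.75)
  expect_equal(sum(g3 == "high"), 25L)

  expect_error(dichotomize(rep(4, 10)), "identical")
  expect_error(dichotomize(1:3), ">= 4")
})

test_that("log-rank matches frozen hand/fixture oracles and survdiff", {
  # 6 subjects, all events, interleaved times; frozen from an independent
  # O-E/V evaluation (and survival::survdiff): chi2 = 0.4848762603
  res <- logrank_test(c(1, 3, 5, 2, 4, 6), rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(res$logrank_chi2, 0.4848762603, tolerance = 1e-6)

  # censored 6-subject fixture: chi2 = 0.0739030023, O_A = 2, E_A = 1.7333...
  res2 <- logrank_test(c(2, 4, 6, 3, 5, 7), c(1, 0, 1, 1, 1, 0),
                       rep(c("A", "B"), each = 3))
  expect_equal(res2$logrank_chi2, 0.0739030023, tolerance = 1e-6)
  expect_equal(res2$observed, 2)
  expect_equal(res2$expected, 1.7333333333, tolerance = 1e-9)

  # identical risk experience in both groups -> chi2 0, p 1
  res3 <- logrank_test(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(res3$logrank_chi2, 0)
  expect_equal(res3$logrank_p, 1)

  # invariant under group relabeling
  t4 <- c(1, 2, 4, 4, 5, 7, 8, 9); e4 <- c(1, 1, 0, 1, 1, 0, 1, 1)
  g4 <- rep(c("A", "B"), 4)
  swap <- ifelse(g4 == "A", "B", "A")
  expect_equal(logrank_test(t4, e4, g4)$logrank_chi2,
               logrank_test(t4, e4, swap)$logrank_chi2)

  # second route on a larger random instance: survival::survdiff
  skip_if_not_installed("survival")
  sim <- simulate_survival(40L, hazard_ratio = 2, censor_rate = 0.25, seed = 5)
  mine <- logrank_test(sim$time, sim$event, sim$group)
  ref <- survival::survdiff(survival::Surv(time, event) ~ group, data = sim)
  expect_equal(mine$logrank_chi2, ref$chisq, tolerance = 1e-9)

  expect_error(logrank_test(1:3, c(1, 1, 1), c("A", "A", "A")), "2 groups")
  expect_error(logrank_test(1:4, rep(0, 4), rep(c("A", "B"), 2)), "1 event")
})

test_that("KM curves start at 1 and are non-increasing", {
  sim <- simulate_survival(30L, hazard_ratio = 1.5, censor_rate = 0.3, seed = 8)
  res <- logrank_test(sim$time, sim$event, sim$group)
  for (km in res$km_curves) {
    expect_equal(km$surv[1], 1)
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(km$surv >= 0))
  }
})

test_that("median-split survival comparison wires dichotomize into log-rank", {
  set.seed(13)
  n <- 120
  score <- rnorm(n)
  # high score accelerates events: planted hazard link
  time <- rexp(n, rate = 0.05 * exp(0.8 * (score > stats::median(score))))
  res <- quiet_sx(survival_by_score(score, time, rep(1L, n)))
  expect_equal(res$cutpoint_rule, "median")
  expect_equal(res$n_high + res$n_low, n)
  expect_lt(res$logrank_p, 0.05)
})

test_that("planted score-response link is recovered within Fisher-z bounds", {
  # pipeline property: expression scores coupled to IC50 with r_true = -0.6
  # at the screened panel size (n = 58)
  set.seed(31)
  sets <- list(gene_set("sig", sprintf("sig%02d", 1:10)))
  cfg <- expr_sim_config(n_genes = 150L, gene_sets = sets,
                         n_samples_per_subtype = c(Luminal = 25, Basal = 22,
                                                   HER2 = 11))
  sim <- simulate_expression(cfg, seed = 31)
  score <- geneset_score(sim$expression, sets[[1]], kind = "z_sum")
  r_true <- -0.6
  xs <- scale(score$values)[, 1]
  y <- r_true * xs + sqrt(1 - r_true^2) * rnorm(58)
  got <- correlate(score, y, y_name = "z_ic50")
  ci <- atanh(r_true) + c(-1, 1) * stats::qnorm(0.995) / sqrt(58 - 3)
  expect_gt(atanh(got$pearson_r), ci[1])
  expect_lt(atanh(got$pearson_r), ci[2])
})
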