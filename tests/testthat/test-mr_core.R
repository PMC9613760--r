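test_that("Wald ratios apply the first-order delta method and drop zero exposure effects", {
  h <- make_harmonized(beta_x = c(1, -0.5, 0), se_x = c(0.1, 0.1, 0.1),
                       beta_y = c(-0.7, 0.2, 0.3), se_y = c(0.3, 0.1, 0.1))
  r <- suppressMessages(wald_ratios(h))
  expect_equal(nrow(r), 2)
  expect_equal(r$theta, c(-0.7, -0.4))
  expect_equal(r$se, c(0.3, 0.2))
  expect_equal(r$weight, 1 / r$se^2)
  expect_message(wald_ratios(h), "zero exposure effect")
})

test_that("IVW matches hand computation, including the unfloored random-effects SE", {
  r <- make_ratios(theta = c(1, 3), se = c(1, 1))
  fe <- mr_ivw(r, "fixed")
  expect_equal(fe$beta, 2)
  expect_equal(fe$se, 1 / sqrt(2))
  q <- cochran_q(r, fe$beta, 1)
  expect_equal(q$Q, 2)
  re <- mr_ivw(r, "random")
  expect_equal(re$beta, 2)
  expect_equal(re$se, (1 / sqrt(2)) * sqrt(2))   # = SE_fixed * sqrt(Q/(J-1))

  # underdispersion: random SE shrinks below fixed unless floored
  r2 <- make_ratios(theta = c(0.50, 0.501, 0.499, 0.5005),
                    se = c(0.3, 0.3, 0.3, 0.3))
  fe2 <- mr_ivw(r2, "fixed"); re2 <- mr_ivw(r2, "random")
  q2 <- cochran_q(r2, fe2$beta, 3)
  expect_lt(q2$Q / 3, 1)
  expect_lt(re2$se, fe2$se)
  expect_equal(re2$se, fe2$se * sqrt(q2$Q / 3), tolerance = 1e-14)
  floored <- mr_ivw(r2, "random", floor_dispersion = TRUE)
  expect_equal(floored$se, fe2$se)

  # equal weights reduce to the arithmetic mean; single ratio is degenerate
  r3 <- make_ratios(theta = c(0.1, 0.4, 0.7), se = c(0.2, 0.2, 0.2))
  expect_equal(mr_ivw(r3, "fixed")$beta, 0.4)
  single <- mr_ivw(make_ratios(0.5, 0.2), "random")
  expect_equal(single$beta, 0.5)
  expect_equal(single$se, 0.2)
  expect_true(attr(single, "degenerate"))
  expect_error(mr_ivw(make_ratios(numeric(0), numeric(0))), "no ratios")
})

test_that("IVW equals the weighted-regression-through-origin oracle and respects symmetries", {
  set.seed(7)
  h <- make_harmonized(beta_x = rnorm(15, 0.05, 0.02), se_x = runif(15, 0.003, 0.01),
                       beta_y = rnorm(15, -0.03, 0.05), se_y = runif(15, 0.03, 0.08))
  r <- wald_ratios(h)
  est <- mr_ivw(r, "fixed")
  fit <- lm(beta_y ~ beta_x - 1, data = h$pairs, weights = 1 / h$pairs$se_y^2)
  expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-12)
  expect_equal(est$se,
               unname(summary(fit)$coefficients[1, 2] / summary(fit)$sigma),
               tolerance = 1e-12)

  # ordering invariance and simultaneous sign-flip invariance
  perm <- sample(nrow(r))
  expect_equal(mr_ivw(r[perm, ], "random")$beta, mr_ivw(r, "random")$beta)
  flip <- sample(c(TRUE, FALSE), 15, replace = TRUE)
  h2 <- h
  h2$pairs$beta_x[flip] <- -h2$pairs$beta_x[flip]
  h2$pairs$beta_y[flip] <- -h2$pairs$beta_y[flip]
  expect_equal(mr_ivw(wald_ratios(h2), "fixed")$beta, est$beta,
               tolerance = 1e-12)
})

test_that("z-test p-values and OR transformation reproduce printed-precision anchors", {
  expect_equal(round(ztest_p(-0.039, 0.272), 3), 0.886)
  expect_equal(round(ztest_p(-0.248, 0.383), 3), 0.517)
  expect_equal(ztest_p(0, 1), 1)
  expect_error(ztest_p(1, 0), "se")

  orci <- to_odds_ratio(-0.731, 0.258)
  expect_equal(unname(round(orci, 2)), c(0.48, 0.29, 0.80))
  expect_equal(unname(to_odds_ratio(0, 0.3)[["or"]]), 1)
  oc <- to_odds_ratio(0, 0.3)
  expect_equal(oc[["ci_low"]] * oc[["ci_high"]], 1, tolerance = 1e-12)
  oc2 <- to_odds_ratio(0.5, 0.1)
  expect_equal(unname(oc2[["ci_low"]]), exp(0.5 - 1.959964 * 0.1))
  expect_equal(round(oc2[["ci_low"]], 4), 1.3553)
  expect_equal(round(oc2[["ci_high"]], 4), 2.0057)
  expect_error(to_odds_ratio(0.5, 0.1, level = 1.2), "level")
})

test_that("median estimators interpolate the cumulative-weight midpoints", {
  r <- make_ratios(theta = c(10, 1, 2), se = c(1, 1, 1))  # unsorted on purpose
  sm <- mr_median(r, weighted = FALSE, n_boot = 200, seed = 1)
  expect_equal(sm$beta, 2)

  # dominant weight pulls the estimate toward that SNP's ratio:
  # theta (0.1, 5, 9), weights (10, 1, 1)/12 -> s = (5, 10.5, 11.5)/12;
  # interpolating at 1/2 between (5/12, 0.1) and (10.5/12, 5) gives
  # 0.1 + 4.9 * (1/12)/(5.5/12) = 0.9909...
  rw <- data.frame(variant_id = c("a", "b", "c"), theta = c(0.1, 5, 9),
                   se = 1 / sqrt(c(10, 1, 1)), weight = c(10, 1, 1))
  wm <- mr_median(rw, weighted = TRUE, n_boot = 200, seed = 1)
  expect_equal(wm$beta, 0.1 + 4.9 / 5.5, tolerance = 1e-12)

  # equal weights: weighted estimator collapses onto the simple one, exactly
  set.seed(3)
  re <- make_ratios(theta = rnorm(9), se = rep(0.4, 9))
  expect_identical(mr_median(re, TRUE, n_boot = 50, seed = 2)$beta,
                   mr_median(re, FALSE, n_boot = 50, seed = 2)$beta)

  # bootstrap SE is seeded and reproducible
  a <- mr_median(re, TRUE, n_boot = 300, seed = 11)
  b <- mr_median(re, TRUE, n_boot = 300, seed = 11)
  expect_identical(a$se, b$se)
  expect_error(mr_median(make_ratios(c(1, 2), c(1, 1)), TRUE), "at least 3")
})

test_that("MR-Egger recovers an exact line and demands 3 SNPs", {
  bx <- c(0.02, 0.05, 0.08, 0.11)
  h <- make_harmonized(beta_x = bx, se_x = rep(0.01, 4),
                       beta_y = 0.01 + 0.5 * bx, se_y = rep(0.05, 4))
  e <- mr_egger(h)
  expect_equal(e$slope$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$intercept, 0.01, tolerance = 1e-10)
  expect_equal(e$q_egger, 0, tolerance = 1e-16)

  # negative exposure effects are re-oriented, leaving the fit unchanged
  h2 <- h
  h2$pairs$beta_x[2] <- -h2$pairs$beta_x[2]
  h2$pairs$beta_y[2] <- -h2$pairs$beta_y[2]
  e2 <- mr_egger(h2)
  expect_equal(e2$slope$beta, e$slope$beta, tolerance = 1e-12)
  expect_equal(e2$intercept, e$intercept, tolerance = 1e-12)

  expect_error(mr_egger(make_harmonized(c(1, 2), c(1, 1), c(1, 2), c(1, 1))),
               "at least 3")
})

test_that("Egger intercept p is near-uniform under balanced pleiotropy", {
  ps <- vapply(1:60, function(i) {
    sim <- simulate_summary_stats(simulation_config(n_instruments = 40,
      n_null_snps = 0, theta = -0.3, tau = 0.05, pleiotropy_mode = "balanced",
      pleiotropy_sd = 0.02, palindromic_fraction = 0, seed = 900 + i))
    h <- harmonize_tables(sim$truth$variant_id, sim$exposure, sim$outcome)
    mr_egger(h)$intercept_p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Cochran's Q matches the chi-square oracle and behaves on homogeneous data", {
  r0 <- make_ratios(theta = rep(0.4, 5), se = runif(5, 0.1, 0.3))
  q0 <- cochran_q(r0, 0.4, 4)
  expect_equal(q0$Q, 0)
  expect_equal(q0$p, 1)

  q1 <- cochran_q(make_ratios(c(1, 3), c(1, 1)), 2, 1)
  expect_equal(q1$Q, 2)
  expect_equal(q1$p, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(round(q1$p, 4), 0.1573)
  expect_error(cochran_q(r0, 0.4, 0), "df")

  # homogeneous simulation: Q/df concentrates near 1
  qs <- vapply(1:40, function(i) {
    sim <- simulate_summary_stats(simulation_config(n_instruments = 25,
      n_null_snps = 0, theta = -0.5, tau = 0.06, palindromic_fraction = 0,
      seed = 700 + i))
    h <- harmonize_tables(sim$truth$variant_id, sim$exposure, sim$outcome)
    r <- wald_ratios(h)
    q <- cochran_q(r, mr_ivw(r, "fixed")$beta, nrow(r) - 1)
    q$Q / q$df
  }, numeric(1))
  expect_lt(abs(mean(qs) - 1), 0.15)
})

test_that("run_all_methods returns the full battery with consistent bookkeeping", {
  sim <- simulate_summary_stats(simulation_config(n_instruments = 18,
    n_null_snps = 0, theta = -0.73, tau = 0.05, palindromic_fraction = 0,
    seed = 77))
  h <- harmonize_tables(sim$truth$variant_id, sim$exposure, sim$outcome)
  res <- run_all_methods(h, n_boot = 200, seed = 9)
  expect_setequal(res$estimates$method,
                  c("ivw_random", "ivw_fixed", "simple_median",
                    "weighted_median", "egger_slope"))
  expect_true(all(res$estimates$n_snp == 18))
  expect_true(all(res$estimates$or == exp(res$estimates$beta)))
  expect_true(all(res$estimates$ci_low < res$estimates$or &
                    res$estimates$or < res$estimates$ci_high))
  # the four main estimators agree in sign under a real effect, no pleiotropy
  main <- res$estimates[res$estimates$method != "egger_slope", ]
  expect_true(all(main$beta < 0))
  d <- res$diagnostics
  expect_equal(d$df_ivw, 17)
  expect_equal(d$df_egger, 16)
  expect_gte(d$q_ivw, 0)
  expect_equal(d$p_q_ivw, pchisq(d$q_ivw, 17, lower.tail = FALSE))
})
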