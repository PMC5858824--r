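test_that("microsimulation is reproducible and conserves persons", {
  sc <- scenario_cached("biased")
  oc1 <- simulate_cohort(sc, n = 2000, seed = 11)
  oc2 <- simulate_cohort(sc, n = 2000, seed = 11)
  expect_identical(oc1$counts, oc2$counts)
  oc3 <- simulate_cohort(sc, n = 2000, seed = 12)
  expect_false(identical(oc1$counts, oc3$counts))
  cls <- c("symptomatic-in-window", "screen-detected-in-window",
           "pre-window-detected", "never-case")
  expect_equal(rowSums(oc1$counts[, cls]), oc1$counts$n_onset)
  tab <- tabulate_two_by_two(oc1)
  expect_equal(sum(tab), sum(oc1$counts$n))
})

test_that("zero sensitivity makes factual and counterfactual ascertainment identical", {
  sc <- scenario_cached("biased")
  sc$policy <- screening_policy(0, screenage = 40)
  oc <- simulate_cohort(sc, n = 20000, seed = 5)
  expect_identical(oc$counts$factual_case, oc$counts$counterfactual_case)
  expect_identical(oc$counts$factual_case_capped, oc$counts$counterfactual_case)
  expect_true(all(oc$counts[["screen-detected-in-window"]] == 0))
  expect_true(all(oc$counts[["pre-window-detected"]] == 0))
})

test_that("microsimulation agrees with the analytic integrals within 3 MC SE", {
  sc <- scenario_cached("biased")
  analytic <- compute_bias(sc)$by_stratum
  oc <- simulate_cohort(sc, n = 40000, seed = 2026, allocation = "equal")
  df <- oc$counts
  for (k in seq_len(nrow(df))) {
    a <- analytic[analytic$stratum == df$stratum[k] &
                    analytic$age_stratum == df$age_stratum[k], ]
    n <- df$n[k]
    expect_lt(abs(a$G_U - df$G_U_hat[k]), 3 * df$se_G_U[k] + 1e-12)
    expect_lt(abs(a$G_S - df$G_S_hat[k]), 3 * df$se_G_S[k] + 1e-12)
    expect_lt(abs(a$part1 - df$part1[k] / n), 3 * df$se_part1[k] + 1e-12)
    expect_lt(abs(a$part2 - df$part2[k] / n), 3 * df$se_part2[k] + 1e-12)
    expect_lt(abs(a$part3 - df$part3[k] / n), 3 * df$se_part3[k] + 1e-12)
  }
})

test_that("poisson screen process lies near the geometric form at small expected counts", {
  # the two screen-process options bracket the continuous-rate ambiguity:
  # escape (1-xi)^N vs e^(-xi*N); they agree to first order in xi*N
  sc <- scenario_cached("biased")
  oc_g <- simulate_cohort(sc, n = 30000, seed = 9)
  oc_p <- simulate_cohort(sc, n = 30000, seed = 9, screen_process = "poisson")
  g <- sum(oc_g$counts$factual_case) / sum(oc_g$counts$n)
  p <- sum(oc_p$counts$factual_case) / sum(oc_p$counts$n)
  expect_equal(p, g, tolerance = 0.15)
})

test_that("symmetric strata give an odds ratio near 1, and correction recovers the null", {
  scn <- scenario_cached("null")
  ocn <- simulate_cohort(scn, n = 50000, seed = 21)
  tabn <- tabulate_two_by_two(ocn)
  or_n <- tabn[["a"]] * tabn[["d"]] / (tabn[["b"]] * tabn[["c"]])
  se_log <- sqrt(sum(1 / tabn))
  expect_lt(abs(log(or_n)), 3 * se_log)
  # differential screening: biased OR, corrected by the analytic rr
  scb <- scenario_cached("biased")
  rr <- compute_bias(scb)$rr
  ocb <- simulate_cohort(scb, n = 50000, seed = 22)
  tabb <- tabulate_two_by_two(ocb)
  fix <- correct_two_by_two(tabb[["a"]], tabb[["b"]], tabb[["c"]], tabb[["d"]], rr)
  expect_gt(fix$or_uncorrected, 1)
  se_log_b <- sqrt(sum(1 / tabb))
  expect_lt(abs(log(fix$or_corrected)), 3 * se_log_b)
})

test_that("overdiagnosis tagging matches the product rule and stays below the nominal weight", {
  sc <- scenario_cached("biased")
  sc$duration <- overdiagnosis_mixture(lognormal_duration(5, 3))
  eo <- effective_overdiagnosis(sc, n = 50000, seed = 4)
  expect_lt(eo$proportion, eo$nominal)
  # tagged fraction = weight x P(detected | minor), within binomial error
  p_det_minor <- eo$n_minor_detected / eo$n_minor
  prod_rule <- (eo$n_minor / eo$n_onset) * p_det_minor
  expect_equal(eo$proportion, prod_rule, tolerance = 1e-12)
  # the minor-component share of onsets is the nominal weight
  se_w <- sqrt(0.2 * 0.8 / eo$n_onset)
  expect_lt(abs(eo$n_minor / eo$n_onset - 0.2), 3 * se_w)
  expect_error(effective_overdiagnosis(scenario_cached("biased")),
               class = "ltbca_not_applicable_error")
})

test_that("unusable onset scaling is reported as a scenario error", {
  sc <- scenario_cached("biased")
  big <- sc$points
  big$rate_per_100k <- big$rate_per_100k * 50
  sc$curve_before <- fit_incidence_curve(big, "before")
  sc$curve_during <- fit_incidence_curve(big, "during")
  expect_error(simulate_cohort(sc, n = 100, seed = 1),
               class = "ltbca_scaling_error")
})
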