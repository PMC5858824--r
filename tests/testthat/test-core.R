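test_that("unscreened cumulative incidence vanishes for zero incidence and matches the point-mass limit", {
  win <- toy_window()
  f <- lognormal_duration(5, 3)
  # vanishing onset intensity drives G_U to zero linearly
  lo <- constant_curve(rate = 1e-6)
  expect_lt(cum_incidence_unscreened(lo, lo, f, win, 1), 1e-9)
  # near-point-mass sojourn at 5 y with constant onset intensity c:
  # G_U -> c * (aE - a0)
  cv <- constant_curve(rate = 200)
  tight <- lognormal_duration(5, 0.02)
  gu <- cum_incidence_unscreened(cv, cv, tight, win, 1, step = 0.01)
  expect_equal(gu, 200 / 1e5 * 3, tolerance = 1e-6)
})

test_that("screening terms vanish without sensitivity or screeners, bitwise", {
  sc <- scenario_cached("biased")
  mean_dur <- duration_mean(sc$duration)
  wb <- shift_to_preclinical(sc$curve_before, mean_dur)
  wd <- shift_to_preclinical(sc$curve_during, mean_dur)
  beh_b <- sc$behaviors[["exposed.before"]]
  beh_d <- sc$behaviors[["exposed.during"]]
  pol0 <- screening_policy(0, screenage = 40)
  parts <- screening_parts(wb, wd, sc$duration, beh_b, beh_d, pol0, sc$window, 2)
  expect_identical(unname(parts), c(0, 0, 0))
  nobody_b <- flat_behavior("exposed", "before", 0, 1)
  nobody_d <- flat_behavior("exposed", "during", 0, 1)
  parts2 <- screening_parts(wb, wd, sc$duration, nobody_b, nobody_d,
                            sc$policy, sc$window, 2)
  expect_identical(unname(parts2), c(0, 0, 0))
  obs <- cum_incidence_observed(wb, wd, sc$duration, nobody_b, nobody_d,
                                sc$policy, sc$window, 2)
  expect_identical(obs$G_S, obs$G_U)
})

test_that("screening only before the window removes cases: G_S < G_U", {
  sc <- scenario_cached("biased")
  mean_dur <- duration_mean(sc$duration)
  wb <- shift_to_preclinical(sc$curve_before, mean_dur)
  wd <- shift_to_preclinical(sc$curve_during, mean_dur)
  beh_b <- flat_behavior("exposed", "before", 0.6, 1)
  nobody_d <- flat_behavior("exposed", "during", 0, 0)
  obs <- cum_incidence_observed(wb, wd, sc$duration, beh_b, nobody_d,
                                sc$policy, sc$window, 2)
  expect_identical(obs$part1, 0)
  expect_identical(obs$part2, 0)
  expect_gt(obs$part3, 0)
  expect_lt(obs$G_S, obs$G_U)
})

test_that("halving the quadrature step leaves G_U and G_S unchanged to 1e-6 relative", {
  for (preset in c("biased", "null")) {
    sc <- scenario_cached(preset)
    r1 <- compute_bias(sc)
    sc$step <- sc$step / 2
    r2 <- compute_bias(sc)
    expect_equal(r2$by_stratum$G_U, r1$by_stratum$G_U, tolerance = 1e-6)
    expect_equal(r2$by_stratum$G_S, r1$by_stratum$G_S, tolerance = 1e-6)
  }
})

test_that("stratum aggregation is the weighted sum", {
  expect_equal(aggregate_strata(7, 1), 7)
  expect_equal(aggregate_strata(c(3, 3, 3, 3), rep(0.25, 4)), 3)
  expect_equal(aggregate_strata(1:4, rep(0.25, 4)), 2.5)
  expect_error(aggregate_strata(1:3, rep(0.25, 4)), class = "ltbca_domain_error")
})

test_that("bias RR is 1 under identical behaviour and inverts under stratum swap", {
  rn <- compute_bias(scenario_cached("null"))
  expect_equal(rn$rr, 1, tolerance = 1e-12)
  sc <- scenario_cached("biased")
  rb <- compute_bias(sc)
  expect_gt(rb$rr, 1)
  swapped <- sc
  swapped$strata <- rev(sc$strata)
  rs <- compute_bias(swapped)
  expect_equal(rs$rr, 1 / rb$rr, tolerance = 1e-12)
  expect_error(bias_rr(0.1, 0), class = "ltbca_degenerate_error")
})

test_that("two-by-two correction follows the c * rr rule", {
  same <- correct_two_by_two(120, 880, 100, 900, rr = 1)
  expect_equal(same$or_corrected, same$or_uncorrected)
  expect_equal(same$rr_corrected, same$rr_uncorrected)
  fix <- correct_two_by_two(120, 880, 100, 900, rr = 1.2)
  expect_equal(fix$or_corrected, 120 * 900 / (880 * 120))
  expect_equal(fix$table_corrected[["c"]], 120)
  und <- correct_two_by_two(120, 880, 0, 900, rr = 1.2)
  expect_true(is.na(und$or_uncorrected) && is.na(und$or_corrected))
  expect_error(correct_two_by_two(-1, 2, 3, 4, 1), class = "ltbca_domain_error")
  expect_error(correct_two_by_two(1, 2, 3, 4, 0), class = "ltbca_domain_error")
})

test_that("degenerate windows are rejected at construction", {
  expect_error(study_window(60, 60, 1), class = "ltbca_domain_error")
  expect_error(study_window(60, 63, 0.8), class = "ltbca_domain_error")
  expect_error(study_window(60, 105, 1, maxage = 100), class = "ltbca_domain_error")
})

test_that("literal line-1 form lowers the added incidence but keeps it nonnegative", {
  sc <- scenario_cached("biased")
  mean_dur <- duration_mean(sc$duration)
  wb <- shift_to_preclinical(sc$curve_before, mean_dur)
  wd <- shift_to_preclinical(sc$curve_during, mean_dur)
  beh_b <- sc$behaviors[["exposed.before"]]
  beh_d <- sc$behaviors[["exposed.during"]]
  pc <- screening_parts(wb, wd, sc$duration, beh_b, beh_d, sc$policy,
                        sc$window, 1, line1_form = "complement")
  pl <- screening_parts(wb, wd, sc$duration, beh_b, beh_d, sc$policy,
                        sc$window, 1, line1_form = "literal")
  expect_lt(pl[["part1"]], pc[["part1"]])
  expect_gte(pl[["part1"]], 0)
  expect_equal(pl[["part2"]], pc[["part2"]])  # line 1 form only affects part1
  expect_equal(pl[["part3"]], pc[["part3"]])
})
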