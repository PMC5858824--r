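test_that("expected screens integrate step rates exactly", {
  b <- flat_behavior("s", "during", k1 = 1, k2 = 1, lo = 50, hi = 60)
  expect_equal(expected_screens(b, 52, 55), 3)
  expect_equal(expected_screens(b, 57, 57), 0)
  pw <- screening_behavior("s", "during", c(50, 55), c(55, 60), c(1, 1), c(0.5, 1))
  expect_equal(expected_screens(pw, 52, 58), 0.5 * 3 + 1 * 3)  # 4.5 by hand
  # constant extrapolation outside the covered bins
  expect_equal(expected_screens(pw, 48, 50), 2 * 0.5)
  expect_equal(expected_screens(pw, 60, 62), 2 * 1)
  expect_error(expected_screens(pw, 58, 52), class = "ltbca_interval_error")
})

test_that("detection probability handles the trivial and single-screen cases", {
  b <- flat_behavior("s", "during", k1 = 1, k2 = 1, lo = 0, hi = 100)
  pol1 <- screening_policy(1, screenage = 50)
  # perfect test: any screen detects
  expect_equal(detection_probability(b, pol1, 55, 55, 60), 1)
  # one expected screen at the assumed chest x-ray sensitivity
  pol46 <- screening_policy(0.46, screenage = 50)
  expect_equal(detection_probability(b, pol46, 55, 55, 56), 0.46)
  # no screens before screenage
  expect_equal(detection_probability(b, pol46, 30, 30, 50), 0)
  # result bounded by k1 at the onset age
  bhalf <- flat_behavior("s", "during", k1 = 0.5, k2 = 2, lo = 0, hi = 100)
  expect_lte(detection_probability(bhalf, pol46, 55, 55, 90), 0.5)
})

test_that("detection probability is monotone in interval end, sensitivity and rate", {
  pol <- function(xi) screening_policy(xi, screenage = 45)
  beh <- function(k2) flat_behavior("s", "during", 0.8, k2, 0, 100)
  v_grid <- seq(50, 70, by = 2.5)
  d_v <- vapply(v_grid, function(v)
    detection_probability(beh(0.7), pol(0.46), 48, 48, v), numeric(1))
  expect_true(all(diff(d_v) >= 0))
  xi_grid <- seq(0.05, 1, by = 0.05)
  d_xi <- vapply(xi_grid, function(x)
    detection_probability(beh(0.7), pol(x), 48, 48, 60), numeric(1))
  expect_true(all(diff(d_xi) >= 0))
  k2_grid <- seq(0, 3, by = 0.25)
  d_k2 <- vapply(k2_grid, function(k)
    detection_probability(beh(k), pol(0.46), 48, 48, 60), numeric(1))
  expect_true(all(diff(d_k2) >= 0))
  expect_true(all(c(d_v, d_xi, d_k2) >= 0 & c(d_v, d_xi, d_k2) <= 1))
})

test_that("geometric escape is multiplicative over adjacent intervals", {
  pw <- screening_behavior("s", "during", c(50, 55, 60), c(55, 60, 65),
                           c(1, 1, 1), c(0.4, 0.9, 1.3))
  pol <- screening_policy(0.46, screenage = 40)
  for (w in list(c(50, 55, 65), c(51, 58, 63))) {
    d_full <- detection_probability(pw, pol, 45, w[1], w[3])
    N1 <- expected_screens(pw, w[1], w[2]); N2 <- expected_screens(pw, w[2], w[3])
    expect_equal(1 - d_full, (1 - 0.46)^N1 * (1 - 0.46)^N2, tolerance = 1e-12)
  }
})

test_that("survey counts convert by the stated arithmetic", {
  counts <- data.frame(stratum = "s", period = "before", age_lo = 55,
                       age_hi = 60, n_total = 100, n_screened_1 = 30,
                       n_screened_2plus = 10, window_years = 3)
  b <- behavior_from_survey(counts)
  expect_equal(k1_at(b, 57), 0.4)
  expect_equal(k2_at(b, 57), (30 + 10 * 2) / (40 * 3))
  # 2+ imputation knob
  b3 <- behavior_from_survey(counts, two_plus_value = 3)
  expect_equal(k2_at(b3, 57), (30 + 10 * 3) / (40 * 3))
  # nobody screened
  none <- transform(counts, n_screened_1 = 0, n_screened_2plus = 0)
  b0 <- behavior_from_survey(none)
  expect_equal(c(k1_at(b0, 57), k2_at(b0, 57)), c(0, 0))
})

test_that("inconsistent or empty survey bins are rejected or dropped", {
  counts <- data.frame(stratum = "s", period = "before",
                       age_lo = c(55, 60), age_hi = c(60, 65),
                       n_total = c(100, 0), n_screened_1 = c(30, 0),
                       n_screened_2plus = c(10, 0), window_years = 3)
  expect_warning(b <- behavior_from_survey(counts), "empty survey bin")
  expect_length(b$k1, 1L)
  bad <- transform(counts[1, ], n_screened_1 = 95, n_screened_2plus = 10)
  expect_error(behavior_from_survey(bad), class = "ltbca_validation_error")
})

test_that("behaviour validation enforces probability and bin structure", {
  expect_error(screening_behavior("s", "during", c(50, 60), c(60, 55),
                                  c(0.5, 0.5), c(1, 1)),
               class = "ltbca_data_error")
  expect_error(screening_behavior("s", "during", 50, 60, 1.2, 1),
               class = "ltbca_data_error")
  expect_error(screening_behavior("s", "during", 50, 60, 0.5, -1),
               class = "ltbca_data_error")
  expect_error(screening_policy(1.3), class = "ltbca_domain_error")
})

test_that("screening CSV round-trips the fixture tables unchanged", {
  beh <- make_screening_fixture(fixture_config())
  path <- withr::local_tempfile(fileext = ".csv")
  write_screening_csv(beh, path)
  back <- read_screening_csv(path)
  expect_setequal(names(back), names(beh))
  for (nm in names(beh)) {
    expect_identical(back[[nm]]$k1, beh[[nm]]$k1)
    expect_identical(back[[nm]]$k2, beh[[nm]]$k2)
    expect_identical(back[[nm]]$breaks, beh[[nm]]$breaks)
  }
})
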