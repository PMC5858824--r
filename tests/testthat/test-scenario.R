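write_scenario_yaml <- function(dir, mutate = identity) {
  make_fixtures(dir, preset = "biased", seed = 1)
  path <- file.path(dir, "scenario.yaml")
  cfg <- yaml::read_yaml(path)
  cfg <- mutate(cfg)
  yaml::write_yaml(cfg, path)
  path
}

test_that("a minimal scenario file loads with documented defaults", {
  dir <- withr::local_tempdir()
  path <- write_scenario_yaml(dir, function(cfg) {
    cfg$policy <- NULL; cfg$quadrature <- NULL; cfg$options <- NULL
    cfg$duration <- NULL; cfg$fit <- NULL
    cfg
  })
  sc <- load_scenario(path, quiet = TRUE)
  expect_equal(sc$policy$sensitivity, 0.46)
  expect_equal(sc$step, 0.05)
  expect_true(sc$gs_includes_baseline)
  expect_s3_class(sc$duration, "lognormal_duration")
  expect_equal(sc$duration$mode, 5)
})

test_that("validation collects all violations at once, with key paths", {
  dir <- withr::local_tempdir()
  path <- write_scenario_yaml(dir, function(cfg) {
    cfg$policy$sensitivity <- 1.3
    cfg$quadrature$step <- -1
    cfg$bogus <- TRUE
    cfg
  })
  err <- tryCatch(load_scenario(path, quiet = TRUE), error = identity)
  expect_s3_class(err, "ltbca_validation_error")
  expect_match(conditionMessage(err), "policy.sensitivity")
  expect_match(conditionMessage(err), "quadrature.step")
  expect_match(conditionMessage(err), "bogus")
})

test_that("weights not summing to one and missing inputs are rejected", {
  dir <- withr::local_tempdir()
  path <- write_scenario_yaml(dir, identity)
  w <- utils::read.csv(file.path(dir, "weights.csv"))
  w$weight[1] <- 0.5
  utils::write.csv(w, file.path(dir, "weights.csv"), row.names = FALSE)
  expect_error(load_scenario(path, quiet = TRUE), class = "ltbca_validation_error")
  unlink(file.path(dir, "incidence.csv"))
  expect_error(load_scenario(path, quiet = TRUE), class = "ltbca_validation_error")
})

test_that("overdiagnosis block in the config builds a mixture duration", {
  dir <- withr::local_tempdir()
  path <- write_scenario_yaml(dir, function(cfg) {
    cfg$duration$overdiagnosis_weight <- 0.2
    cfg$duration$overdiagnosis_mode_years <- 20
    cfg$duration$overdiagnosis_sd_years <- 3
    cfg
  })
  sc <- load_scenario(path, quiet = TRUE)
  expect_s3_class(sc$duration, "mixture_duration")
  expect_equal(sc$duration$weights, c(0.8, 0.2))
})

test_that("the pipeline writes deterministic full-precision results", {
  dir <- withr::local_tempdir()
  path <- write_scenario_yaml(dir, identity)
  sc <- load_scenario(path, quiet = TRUE)
  out1 <- file.path(dir, "r1.csv"); out2 <- file.path(dir, "r2.csv")
  res <- run_pipeline(sc, out1)
  run_pipeline(sc, out2)
  expect_identical(readLines(out1), readLines(out2))
  df <- utils::read.csv(out1, stringsAsFactors = FALSE)
  expect_equal(nrow(df), 9)  # 2 strata x 4 age strata + summary
  rr_row <- df[df$stratum == "summary", ]
  expect_equal(rr_row$rr, res$rr)  # full precision survives the round-trip
})

test_that("the null preset pipeline reports rr = 1", {
  dir <- withr::local_tempdir()
  make_fixtures(dir, preset = "null", seed = 1)
  sc <- load_scenario(file.path(dir, "scenario.yaml"), quiet = TRUE)
  res <- run_pipeline(sc, file.path(dir, "out.csv"))
  expect_equal(res$rr, 1, tolerance = 1e-9)
})

test_that("the CLI dispatches fixtures, simulation and curve fitting", {
  dir <- withr::local_tempdir()
  expect_equal(ltbca_cli(c("make-fixtures", "--preset", "biased",
                           "--seed", "1", "--out", dir)), 0L)
  out_csv <- file.path(dir, "bias.csv")
  expect_equal(suppressMessages(
    ltbca_cli(c("simulate", "--scenario", file.path(dir, "scenario.yaml"),
                "--out", out_csv))), 0L)
  expect_true(file.exists(out_csv))
  curve_json <- file.path(dir, "curve.json")
  expect_equal(ltbca_cli(c("fit-incidence", "--in",
                           file.path(dir, "incidence.csv"),
                           "--period", "before", "--out", curve_json)), 0L)
  expect_match(readLines(curve_json), "logcubic")
  # missing input: clean nonzero status, no exception
  expect_equal(suppressMessages(
    ltbca_cli(c("simulate", "--scenario", file.path(dir, "nope.yaml"),
                "--out", out_csv))), 1L)
  expect_equal(ltbca_cli(character()), 1L)
})
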