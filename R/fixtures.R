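# Synthetic input generators: registry-style incidence points, survey-style
# screening behaviour tables with a configurable exposed/unexposed
# differential, and birth-cohort weights. Every fixture is reproducible from
# its seed and passes the schema validation of its consuming module. The
# values emulate the *structure* of the US registry and trial-questionnaire
# inputs the model was designed around; they are synthetic, not extracted
# data.

# Truth curve for the incidence fixture: log-rate cubic through
# (20, -0.7), (40, 2.7), (70, 6.0), (85, 6.1) on the log(rate/100k) scale —
# near-zero incidence in the young, convex rise through midlife, peak
# ~500/100k near age 77 with a late plateau/decline, the characteristic
# adult lung-cancer shape.
fixture_truth_coef <- c(-4.115498575, 0.1576695157, 9.925925926e-4,
                        -1.686609687e-5)

#' Fixture configuration
#'
#' Bundles the knobs of the synthetic-input generators. The defaults define
#' the package's reference study conditions: four 5-year age strata covering
#' enrollment ages 55-74 with a 3-year ascertainment window opening 3 years
#' after entry, screening from age 40, a 10% lower incidence during the study
#' than before it, and a screening differential concentrated in the during-
#' study period (the exposed stratum screens substantially more once the
#' study is underway, with only a modest pre-study gap).
#'
#' @param seed Integer seed for any noise.
#' @param preset \code{"biased"} (default differential), \code{"null"}
#'   (identical behaviour in both strata) or \code{"intervention-like"}
#'   (large during-study differential).
#' @param noise_sd Multiplicative lognormal noise sd on incidence rates
#'   (0 = exact truth).
#' @param strata Two risk-factor stratum labels, exposed first.
#' @param during_scale Multiplier taking before-period incidence to
#'   during-period incidence.
#' @param stratum_specific_weights Use distinct birth-cohort weights per
#'   stratum in \code{\link{make_weights}}.
#' @return A list of class \code{fixture_config}.
#' @export
fixture_config <- function(seed = 1,
                           preset = c("biased", "null", "intervention-like"),
                           noise_sd = 0,
                           strata = c("exposed", "unexposed"),
                           during_scale = 0.9,
                           stratum_specific_weights = FALSE) {
  preset <- match.arg(preset)
  if (length(strata) != 2L)
    stop_ltbca("exactly two stratum labels are required", "ltbca_domain_error")
  structure(list(seed = seed, preset = preset, noise_sd = noise_sd,
                 strata = strata, during_scale = during_scale,
                 stratum_specific_weights = stratum_specific_weights,
                 truth_coef = fixture_truth_coef),
            class = "fixture_config")
}

#' Generate registry-style incidence points
#'
#' 5-year bands from 0 to the open-ended 85+ band, two periods; rates follow
#' the log-cubic truth curve (during-period rates scaled by
#' \code{during_scale}), with optional multiplicative lognormal noise. The
#' truth parameters are recorded in the \code{"truth"} attribute for
#' parameter-recovery tests.
#'
#' @param config A \code{fixture_config}.
#' @return An \code{incidence_points} data frame (36 rows).
#' @export
make_incidence_fixture <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  age_lo <- seq(0, 85, by = 5)
  age_hi <- c(seq(5, 85, by = 5), Inf)
  mid <- ifelse(is.finite(age_hi), (age_lo + age_hi) / 2, age_lo + 2.5)
  co <- config$truth_coef
  log_rate <- co[1] + co[2] * mid + co[3] * mid^2 + co[4] * mid^3
  before <- exp(log_rate)
  during <- config$during_scale * before
  if (config$noise_sd > 0) {
    set.seed(config$seed)
    before <- before * exp(stats::rnorm(length(before), 0, config$noise_sd))
    during <- during * exp(stats::rnorm(length(during), 0, config$noise_sd))
  }
  pts <- incidence_points(rep(age_lo, 2), rep(age_hi, 2), c(before, during),
                          rep(c("before", "during"), each = length(age_lo)))
  attr(pts, "truth") <- list(coef = co, during_scale = config$during_scale)
  pts
}

# per-preset screening levels: list(before, during), each a named list of
# c(k1, k2) per stratum role
preset_levels <- function(preset) {
  switch(preset,
    "null" = list(
      before = list(exposed = c(0.35, 0.6), unexposed = c(0.35, 0.6)),
      during = list(exposed = c(0.30, 0.5), unexposed = c(0.30, 0.5))),
    "biased" = list(
      before = list(exposed = c(0.45, 0.7), unexposed = c(0.35, 0.6)),
      during = list(exposed = c(0.70, 1.0), unexposed = c(0.30, 0.5))),
    "intervention-like" = list(
      before = list(exposed = c(0.45, 0.7), unexposed = c(0.35, 0.6)),
      during = list(exposed = c(0.95, 1.2), unexposed = c(0.25, 0.4))))
}

#' Generate a screening behaviour fixture
#'
#' Two strata by two periods over 5-year age bins 40-90. The \code{"biased"}
#' preset puts most of the exposed/unexposed gap in the during-study period —
#' the configuration under which lead-time-biased case ascertainment arises —
#' with a mild age gradient on \code{k1}; the \code{"null"} preset makes the
#' strata identical.
#'
#' @param config A \code{fixture_config}.
#' @return Named list of \code{screening_behavior} objects keyed
#'   \code{"<stratum>.<period>"}.
#' @export
make_screening_fixture <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  age_lo <- seq(40, 85, by = 5)
  age_hi <- age_lo + 5
  grad <- seq(-0.04, 0.04, length.out = length(age_lo))  # mild rise with age
  lv <- preset_levels(config$preset)
  out <- list()
  for (p in c("before", "during")) for (rk in 1:2) {
    s <- config$strata[rk]
    role <- c("exposed", "unexposed")[rk]
    base <- lv[[p]][[role]]
    k1 <- pmin(1, pmax(0, base[1] + grad))
    k2 <- rep(base[2], length(age_lo))
    out[[paste(s, p, sep = ".")]] <-
      screening_behavior(s, p, age_lo, age_hi, k1, k2)
  }
  out
}

#' Generate birth-cohort weight fixtures
#'
#' Four 5-year age strata. The default is uniform weights (0.25 each); with
#' \code{stratum_specific_weights = TRUE} the exposed stratum is weighted
#' toward the younger cohorts and the unexposed toward the older, each vector
#' summing to 1.
#'
#' @param config A \code{fixture_config}.
#' @return Data frame with columns \code{stratum}, \code{age_stratum},
#'   \code{weight}.
#' @export
make_weights <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  labs <- c("55-59", "60-64", "65-69", "70-74")
  if (config$stratum_specific_weights) {
    w <- rbind(c(0.30, 0.30, 0.25, 0.15), c(0.20, 0.25, 0.28, 0.27))
  } else {
    w <- rbind(rep(0.25, 4), rep(0.25, 4))
  }
  data.frame(stratum = rep(config$strata, each = 4L),
             age_stratum = rep(labs, 2L), weight = as.vector(t(w)),
             stringsAsFactors = FALSE)
}

#' Build a complete in-memory scenario from fixtures
#'
#' Generates the fixture inputs, fits the before/during incidence curves, and
#' assembles the scenario list consumed by \code{\link{compute_bias}},
#' \code{\link{simulate_cohort}} and \code{\link{run_grid}}. Enrollment-age
#' stratum midpoints are 57.5, 62.5, 67.5 and 72.5 years; the ascertainment
#' window for each stratum runs from 3 to 6 years after the stratum midpoint
#' (emulating a trial whose case-ascertainment period opens a few study-years
#' after entry).
#'
#' @param preset Fixture preset (see \code{\link{fixture_config}}).
#' @param duration A duration spec (default lognormal mode 5, sd 3).
#' @param sensitivity Screening sensitivity (default 0.46).
#' @param seed Fixture seed.
#' @param step Quadrature step in years.
#' @param ... Further arguments to \code{\link{fixture_config}}.
#' @return A scenario list.
#' @export
default_scenario <- function(preset = "biased",
                             duration = lognormal_duration(5, 3),
                             sensitivity = 0.46, seed = 1, step = 0.05, ...) {
  cfg <- fixture_config(seed = seed, preset = preset, ...)
  pts <- make_incidence_fixture(cfg)
  behaviors <- make_screening_fixture(cfg)
  wtab <- make_weights(cfg)
  mids <- c(57.5, 62.5, 67.5, 72.5)
  shared <- !cfg$stratum_specific_weights
  w_shared <- wtab$weight[wtab$stratum == cfg$strata[1L]]
  window <- study_window(a0 = mids + 3, aE = mids + 6,
                         weights = w_shared, screenage = 40, maxage = 100,
                         labels = unique(wtab$age_stratum))
  stratum_weights <- if (shared) NULL else
    split(wtab$weight, wtab$stratum)[cfg$strata]
  list(strata = cfg$strata,
       points = pts,
       curve_before = fit_incidence_curve(pts, "before"),
       curve_during = fit_incidence_curve(pts, "during"),
       behaviors = behaviors,
       window = window,
       stratum_weights = stratum_weights,
       policy = screening_policy(sensitivity, screenage = 40),
       duration = duration,
       step = step,
       line1_form = "complement",
       gs_includes_baseline = TRUE,
       preset = preset)
}

#' Write all fixture files to a directory
#'
#' Writes \code{incidence.csv}, \code{screening.csv}, \code{weights.csv} and
#' a matching \code{scenario.yaml} so the file-based pipeline
#' (\code{\link{load_scenario}}, \code{\link{run_pipeline}}) can run on them.
#'
#' @param dir Output directory (created if missing).
#' @param preset Fixture preset.
#' @param seed Fixture seed.
#' @param ... Further arguments to \code{\link{fixture_config}}.
#' @return The directory, invisibly.
#' @export
make_fixtures <- function(dir, preset = "biased", seed = 1, ...) {
  cfg <- fixture_config(seed = seed, preset = preset, ...)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_incidence_csv(make_incidence_fixture(cfg), file.path(dir, "incidence.csv"))
  write_screening_csv(make_screening_fixture(cfg), file.path(dir, "screening.csv"))
  wtab <- make_weights(cfg)
  wdf <- wtab
  wdf$weight <- format_full(wdf$weight)
  utils::write.csv(wdf, file.path(dir, "weights.csv"), row.names = FALSE,
                   quote = FALSE)
  sc <- list(
    strata = as.list(cfg$strata),
    incidence = "incidence.csv",
    screening = "screening.csv",
    weights = "weights.csv",
    window = list(mid_ages = c(57.5, 62.5, 67.5, 72.5),
                  entry_lag = 3, window_length = 3,
                  screenage = 40, maxage = 100),
    policy = list(sensitivity = 0.46, detection_form = "geometric"),
    duration = list(mode_years = 5, sd_years = 3),
    fit = list(family = "logcubic", scale = "log"),
    quadrature = list(step = 0.05),
    options = list(gs_includes_baseline = TRUE, line1_form = "complement",
                   shared_weights = !cfg$stratum_specific_weights))
  yaml::write_yaml(sc, file.path(dir, "scenario.yaml"))
  invisible(dir)
}
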