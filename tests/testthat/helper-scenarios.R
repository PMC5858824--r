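# Shared fixture scenarios, built once per test run.
memo <- new.env(parent = emptyenv())

scenario_cached <- function(preset, ...) {
  key <- paste(preset, ...)
  if (is.null(memo[[key]])) memo[[key]] <- default_scenario(preset, ...)
  memo[[key]]
}

# paper's sojourn sensitivity grid plus the overdiagnosis long component
sojourn_grid <- expand.grid(mode = c(1, 3, 5, 10), sd = c(1, 3, 5))
sojourn_grid <- rbind(sojourn_grid, data.frame(mode = 20, sd = 3))

# single-age-stratum window for hand-checkable integrals
toy_window <- function(a0 = 60, aE = 63, screenage = 40, maxage = 100)
  study_window(a0 = a0, aE = aE, weights = 1, screenage = screenage,
               maxage = maxage)

# constant-rate incidence curve fitted through the exported path
constant_curve <- function(rate = 200, period = "before") {
  pts <- incidence_points(seq(0, 85, 5), c(seq(5, 85, 5), Inf),
                          rep(rate, 18), rep(period, 18))
  fit_incidence_curve(pts, period)
}

# uniform screening behaviour over one wide bin
flat_behavior <- function(stratum, period, k1, k2, lo = 0, hi = 100)
  screening_behavior(stratum, period, lo, hi, k1, k2)
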