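# Individual-level Monte Carlo simulator of the same generative model as the
# analytic integrator. Serves as a brute-force oracle for G_U, the three
# screening terms and G_S, and generates two-by-two tables for end-to-end
# bias-correction checks.

# Build the (grid, cdf) pair for onset-age sampling on [0, aE]: density is
# wb on [0, a0) and wd on [a0, aE). a0 is forced onto the grid so the
# period discontinuity is represented exactly.
onset_sampler <- function(wb, wd, a0, aE, h = 0.01) {
  g1 <- seq(0, a0, by = h); if (g1[length(g1)] < a0) g1 <- c(g1, a0)
  g2 <- seq(a0, aE, by = h); if (g2[length(g2)] < aE) g2 <- c(g2, aE)
  grid <- c(g1, g2[-1L])
  dens <- c(incidence_intensity(wb, g1), incidence_intensity(wd, g2[-1L]))
  # trapezoid cumulative; treat the jump at a0 by splitting the two panels
  dg <- diff(grid)
  avg <- (dens[-1L] + dens[-length(dens)]) / 2
  # correct the panel straddling a0: left value must be wb, right wd; the
  # grid point at a0 belongs to the during period, so replace the last
  # before-panel's right-hand density with wb(a0)
  j <- length(g1) - 1L   # panel ending at a0
  avg[j] <- (incidence_intensity(wb, g1[j]) + incidence_intensity(wb, a0)) / 2
  cum <- c(0, cumsum(avg * dg))
  list(grid = grid, cum = cum, p_onset = cum[length(cum)])
}

sample_onset <- function(sampler, n_onset) {
  u <- stats::runif(n_onset, 0, sampler$p_onset)
  stats::approx(sampler$cum, sampler$grid, xout = u, ties = "ordered")$y
}

# detection draw for screeners over [u, v): expected_count mode uses the
# exact geometric escape on the real-valued expected screen count (the
# analytic estimand); poisson mode draws discrete screen times.
draw_detect <- function(behavior, policy, u, v, is_screener,
                        screen_process = "expected_count") {
  n <- length(u)
  det <- logical(n)
  idx <- which(is_screener & v > u)
  if (!length(idx)) return(det)
  N <- expected_screens(behavior, u[idx], v[idx])
  xi <- policy$sensitivity
  if (screen_process == "expected_count") {
    p <- 1 - escape_after(policy, N)
  } else {
    K <- stats::rpois(length(idx), N)
    p <- 1 - (1 - xi)^K
  }
  det[idx] <- stats::runif(length(idx)) < p
  det
}

#' Simulate an individual-level cohort for one scenario
#'
#' Simulates \code{n} persons per risk-factor stratum (allocated across age
#' strata by the birth-cohort weights) under the same generative model the
#' analytic integrator evaluates: preclinical onset drawn from the normalised
#' onset intensity over \eqn{[0, a_E]}, sojourn time from the duration spec
#' (with component tags for mixtures), screener status per period as
#' Bernoulli draws on \eqn{k_1} at the onset age, and screen detection with
#' per-screen sensitivity \eqn{\xi} over the expected screen counts. Factual
#' and counterfactual ascertainment are recorded for every person with common
#' random numbers.
#'
#' With \code{screen_process = "expected_count"} (default) each person's
#' detection over an interval is a single Bernoulli draw with probability
#' \eqn{1-(1-\xi)^{N}}, \eqn{N} the real-valued expected screen count over
#' the interval — exactly the estimand of the analytic geometric form, so the
#' oracle differs from the integrals only by binomial Monte Carlo error.
#' \code{"poisson"} instead draws a discrete screen count
#' \eqn{K \sim Pois(N)} with per-screen detection \eqn{\xi} (expected escape
#' \eqn{e^{-\xi N}}), bracketing the continuous-rate reading.
#'
#' @param scenario A scenario list (see \code{\link{default_scenario}}).
#' @param n Persons per risk-factor stratum.
#' @param seed Integer seed; results are reproducible given it.
#' @param screen_process \code{"expected_count"} or \code{"poisson"}.
#' @param allocation \code{"weights"} (default; split \code{n} across age
#'   strata by the stratum weights) or \code{"equal"} (simulate \code{n} in
#'   every age stratum).
#' @return An \code{observed_counts} object: per (risk stratum, age stratum)
#'   cell, counts and binomial standard errors for the ascertainment classes
#'   and the microsimulation estimates of \code{G_U}, \code{part1},
#'   \code{part2}, \code{part3}, \code{G_S}; plus overdiagnosis tagging
#'   totals when the duration spec is a mixture.
#' @export
simulate_cohort <- function(scenario, n, seed,
                            screen_process = c("expected_count", "poisson"),
                            allocation = c("weights", "equal")) {
  screen_process <- match.arg(screen_process)
  allocation <- match.arg(allocation)
  if (!is.numeric(n) || n < 1)
    stop_ltbca("`n` must be at least 1", "ltbca_domain_error")
  sc <- scenario
  mean_dur <- duration_mean(sc$duration)
  wb <- shift_to_preclinical(sc$curve_before, mean_dur)
  wd <- shift_to_preclinical(sc$curve_during, mean_dur)
  window <- sc$window
  I <- length(window$a0)
  cells <- list()
  od <- c(n_onset = 0, n_minor = 0, n_minor_detected = 0)
  is_mix <- inherits(sc$duration, "mixture_duration")
  minor_idx <- if (is_mix) length(sc$duration$weights) else NA_integer_
  for (r in seq_along(sc$strata)) {
    s <- sc$strata[r]
    beh_b <- sc$behaviors[[paste(s, "before", sep = ".")]]
    beh_d <- sc$behaviors[[paste(s, "during", sep = ".")]]
    w_r <- stratum_weights(sc, s)
    n_i <- if (allocation == "weights") round(n * w_r) else rep(n, I)
    for (i in seq_len(I)) {
      set.seed((seed %% 100000L) * 10000L + r * 100L + i)
      cell <- sim_cell(wb, wd, sc$duration, beh_b, beh_d, sc$policy, window,
                       i, n_i[i], screen_process, minor_idx)
      cell$counts$stratum <- s
      cell$counts$age_stratum <- window$labels[i]
      cells[[length(cells) + 1L]] <- cell$counts
      od <- od + cell$od
    }
  }
  counts <- do.call(rbind, cells)
  counts <- counts[, c("stratum", "age_stratum",
                       setdiff(names(counts), c("stratum", "age_stratum")))]
  structure(list(counts = counts, n_per_stratum = n,
                 allocation = allocation, screen_process = screen_process,
                 overdiagnosis = if (is_mix) as.list(od) else NULL,
                 seed = seed),
            class = "observed_counts")
}

sim_cell <- function(wb, wd, f, beh_b, beh_d, policy, window, i, n,
                     screen_process, minor_idx) {
  a0 <- window$a0[i]; aE <- window$aE[i]
  maxage <- window$maxage; screenage <- window$screenage
  sampler <- onset_sampler(wb, wd, a0, aE)
  if (sampler$p_onset >= 1)
    stop_ltbca("onset intensity integrates to >= 1 over the study horizon; rates are not usable as per-person probabilities at this scale",
               "ltbca_scaling_error")
  onset <- stats::runif(n) < sampler$p_onset
  m <- sum(onset)
  x <- sample_onset(sampler, m)
  dur <- duration_sample(f, m)
  z <- x + dur$t
  pre <- x < a0
  # screener status per period, Bernoulli on k1 at onset age
  S_b <- stats::runif(m) < k1_at(beh_b, x)
  S_d <- stats::runif(m) < k1_at(beh_d, x)
  # pre-window detection: screens in [max(x, screenage), min(a0, z))
  u_b <- pmax(x, screenage)
  v_b <- pmin(a0, z)
  det_before <- draw_detect(beh_b, policy, u_b, v_b, S_b & pre, screen_process)
  # in-window detection among those not already detected:
  # screens in [max(x, screenage, a0), min(aE, z))
  u_d <- pmax(x, screenage, a0)
  v_d <- pmin(aE, z)
  det_during <- draw_detect(beh_d, policy, u_d, v_d, S_d & !det_before,
                            screen_process)
  cf_case <- z > a0 & z <= aE
  class <- rep("never-case", m)
  class[cf_case & !det_before] <- "symptomatic-in-window"
  class[det_during] <- "screen-detected-in-window"
  class[det_before] <- "pre-window-detected"
  # analytic-term counterparts (counterfactual horizon capped at maxage)
  p1 <- pre & !det_before & det_during & z > aE & z <= maxage
  p2 <- !pre & det_during & z > aE & z <= maxage
  p3 <- det_before & cf_case
  factual_case <- (cf_case & !det_before) | det_during
  factual_case_capped <- sum(cf_case) + sum(p1) + sum(p2) - sum(p3)
  prop <- function(k) k / n
  se <- function(k) sqrt(prop(k) * (1 - prop(k)) / n)
  ks <- c(counterfactual_case = sum(cf_case),
          factual_case = sum(factual_case),
          factual_case_capped = factual_case_capped,
          part1 = sum(p1), part2 = sum(p2), part3 = sum(p3),
          `symptomatic-in-window` = sum(class == "symptomatic-in-window"),
          `screen-detected-in-window` = sum(class == "screen-detected-in-window"),
          `pre-window-detected` = sum(class == "pre-window-detected"),
          `never-case` = sum(onset) - sum(class != "never-case"))
  counts <- data.frame(n = n, n_onset = m, t(ks),
                       G_U_hat = prop(ks[["counterfactual_case"]]),
                       G_S_hat = prop(factual_case_capped),
                       se_G_U = se(ks[["counterfactual_case"]]),
                       se_G_S = se(ks[["factual_case_capped"]]),
                       se_part1 = se(ks[["part1"]]),
                       se_part2 = se(ks[["part2"]]),
                       se_part3 = se(ks[["part3"]]),
                       check.names = FALSE, stringsAsFactors = FALSE)
  od <- c(n_onset = m, n_minor = 0, n_minor_detected = 0)
  if (!is.na(minor_idx)) {
    minor <- dur$component == minor_idx
    od["n_minor"] <- sum(minor)
    od["n_minor_detected"] <- sum(minor & (det_before | det_during))
  }
  list(counts = counts, od = od)
}

#' @export
print.observed_counts <- function(x, ...) {
  cat(sprintf("Microsimulation counts: %d persons per risk stratum (%s allocation, %s screens)\n",
              x$n_per_stratum, x$allocation, x$screen_process))
  agg <- stats::aggregate(cbind(n, counterfactual_case, factual_case) ~ stratum,
                          data = x$counts, FUN = sum)
  print(agg, row.names = FALSE)
  if (!is.null(x$overdiagnosis))
    cat(sprintf("  overdiagnosis tagging: %d/%d minor-component onsets screen-detected (%.2f%% of onsets)\n",
                x$overdiagnosis$n_minor_detected, x$overdiagnosis$n_minor,
                100 * x$overdiagnosis$n_minor_detected /
                  max(1, x$overdiagnosis$n_onset)))
  invisible(x)
}

#' Assemble a two-by-two case-control table from simulated cohorts
#'
#' Cases are the factually ascertained in-window cases; noncases are, by the
#' default sampling rule, all persons not ascertained by the end of the
#' window.
#'
#' @param counts_exposed,counts_unexposed \code{observed_counts} from the same
#'   scenario, one per risk-factor stratum (each may contain both strata; the
#'   named stratum is extracted).
#' @param exposed,unexposed Stratum labels to use for the margins.
#' @return Named numeric vector \code{c(a, b, c, d)}.
#' @export
tabulate_two_by_two <- function(counts_exposed, counts_unexposed = counts_exposed,
                                exposed = NULL, unexposed = NULL) {
  pick <- function(oc, s) {
    df <- oc$counts
    if (!is.null(s)) df <- df[df$stratum == s, , drop = FALSE]
    if (!nrow(df)) stop_ltbca("no rows for requested stratum", "ltbca_data_error")
    c(cases = sum(df$factual_case), n = sum(df$n))
  }
  strata <- unique(counts_exposed$counts$stratum)
  if (is.null(exposed)) exposed <- strata[1L]
  if (is.null(unexposed)) unexposed <- if (length(strata) > 1L) strata[2L] else strata[1L]
  e <- pick(counts_exposed, exposed)
  u <- pick(counts_unexposed, unexposed)
  c(a = unname(e["cases"]), b = unname(e["n"] - e["cases"]),
    c = unname(u["cases"]), d = unname(u["n"] - u["cases"]))
}

#' Realized overdiagnosis fraction of a simulated sample
#'
#' With a mixture duration spec, the nominal overdiagnosis weight is the
#' fraction of the preclinical-case population whose sojourn is drawn from
#' the long component. Because screening sensitivity is below 100%, only the
#' screen-detected part of that component is realized as overdiagnosis in the
#' sample: the realized fraction equals (nominal weight) times P(screen
#' detected | long component) and is strictly below the nominal weight under
#' imperfect screening.
#'
#' @param scenario Scenario whose duration spec is a mixture.
#' @param n Persons per risk-factor stratum for the tagging microsimulation.
#' @param seed Integer seed.
#' @return List: \code{proportion} (minor-component screen-detected onsets /
#'   all onsets), \code{nominal} (mixture weight), \code{n_onset},
#'   \code{n_minor}, \code{n_minor_detected}.
#' @export
effective_overdiagnosis <- function(scenario, n = 200000, seed = 1) {
  if (!inherits(scenario$duration, "mixture_duration"))
    stop_ltbca("effective_overdiagnosis requires a mixture duration spec",
               "ltbca_not_applicable_error")
  oc <- simulate_cohort(scenario, n, seed)
  od <- oc$overdiagnosis
  list(proportion = od$n_minor_detected / max(1, od$n_onset),
       nominal = scenario$duration$weights[length(scenario$duration$weights)],
       n_onset = od$n_onset, n_minor = od$n_minor,
       n_minor_detected = od$n_minor_detected)
}
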