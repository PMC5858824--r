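#' Study window: age strata, ascertainment limits and weights
#'
#' The study population is divided into 5-year birth-cohort (age) strata. For
#' stratum \eqn{i}, \eqn{a_{0,i}} is the age at the beginning of the case
#' ascertainment period and \eqn{a_{E,i}} the age at its end. The stratum
#' weights \eqn{\omega_i} are the birth-cohort proportions of the sampled
#' population and must sum to 1.
#'
#' @param a0,aE Per-stratum ascertainment start and end ages (years),
#'   \code{a0 < aE <= maxage}.
#' @param weights Stratum weights in \eqn{[0, 1]} summing to 1 (within 1e-12).
#' @param screenage Age at which screening is assumed to begin.
#' @param maxage Upper age horizon of the model: counterfactual symptomatic
#'   diagnoses beyond it are treated as outside the modelled lifetime.
#' @param labels Optional stratum labels.
#' @return A \code{study_window} object.
#' @export
study_window <- function(a0, aE, weights, screenage = 40, maxage = 100,
                         labels = NULL) {
  I <- length(a0)
  if (!I || length(aE) != I || length(weights) != I)
    stop_ltbca("a0, aE and weights must be non-empty and equal length",
               "ltbca_domain_error")
  if (any(a0 >= aE))
    stop_ltbca("each age stratum needs a0 < aE", "ltbca_domain_error")
  if (any(aE > maxage))
    stop_ltbca("aE must not exceed maxage", "ltbca_domain_error")
  if (any(weights < 0 | weights > 1) || abs(sum(weights) - 1) > 1e-12)
    stop_ltbca("weights must lie in [0, 1] and sum to 1 (within 1e-12)",
               "ltbca_domain_error")
  if (is.null(labels))
    labels <- sprintf("%g-%g", a0, aE)
  structure(list(a0 = as.numeric(a0), aE = as.numeric(aE),
                 weights = as.numeric(weights), screenage = screenage,
                 maxage = maxage, labels = as.character(labels)),
            class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf("Study window: %d age strata, screenage %g, maxage %g\n",
              length(x$a0), x$screenage, x$maxage))
  for (i in seq_along(x$a0))
    cat(sprintf("  %s: a0 = %g, aE = %g, weight = %.4g\n",
                x$labels[i], x$a0[i], x$aE[i], x$weights[i]))
  invisible(x)
}

# Inner sojourn integral int_lo^hi f(z - x) dz as a CDF difference,
# vectorised over onset ages x. Zero duration support below 0 is automatic.
sojourn_window_prob <- function(f, x, lo, hi) {
  duration_cdf(f, hi - x) - duration_cdf(f, pmax(lo - x, 0))
}

#' Counterfactual unscreened cumulative incidence for one age stratum
#'
#' Evaluates, for age stratum \code{i} of the study window, the cumulative
#' incidence expected if nobody in the population were ever screened:
#' \deqn{G_U = \int_0^{a_0} w_b(x) \int_{a_0}^{a_E} f(z-x)\,dz\,dx +
#'       \int_{a_0}^{a_E} w_d(x) \int_{a_0}^{a_E} f(z-x)\,dz\,dx,}
#' where \eqn{w_b, w_d} are the preclinical onset intensities before and
#' during the study and \eqn{f} the sojourn density (zero for negative
#' durations). The outer integrals use composite Simpson quadrature on a
#' uniform age grid; the inner sojourn integral is a difference of CDF
#' values, which removes one integration dimension.
#'
#' @param wb,wd Preclinical onset curves (already back-shifted), before and
#'   during the study.
#' @param f A duration spec.
#' @param window A \code{study_window}.
#' @param i Age-stratum index.
#' @param step Quadrature step in years (default 0.05).
#' @return Cumulative incidence (probability scale).
#' @export
cum_incidence_unscreened <- function(wb, wd, f, window, i, step = 0.05) {
  a0 <- window$a0[i]; aE <- window$aE[i]
  before <- integrate_simpson(function(x)
    incidence_intensity(wb, x) * sojourn_window_prob(f, x, a0, aE), 0, a0, step)
  during <- integrate_simpson(function(x)
    incidence_intensity(wd, x) * sojourn_window_prob(f, x, a0, aE), a0, aE, step)
  before + during
}

# Escape-before-window probability for onset age x < a0: non-screeners escape
# trivially; screeners escape all expected screens in [max(x, screenage), a0].
escape_before_prob <- function(behavior_b, policy, x, a0,
                               line1_form = c("complement", "literal")) {
  line1_form <- match.arg(line1_form)
  k1 <- k1_at(behavior_b, x)
  L <- pmax(x, policy$screenage)
  N <- expected_screens(behavior_b, pmin(L, a0), a0)
  esc <- escape_after(policy, N)
  if (line1_form == "complement") (1 - k1) + k1 * esc else k1 * esc
}

#' The three screening adjustment terms of the observed cumulative incidence
#'
#' Computes, for age stratum \code{i}, the three components by which screening
#' perturbs in-window case ascertainment:
#' \itemize{
#'   \item \code{part1}: onset before the window, escape pre-window screens,
#'     screen-detected during the window, counterfactual symptomatic diagnosis
#'     after the window (but within \code{maxage}) — cases added to the study.
#'   \item \code{part2}: onset during the window, screen-detected during the
#'     window, counterfactual diagnosis after the window — also added.
#'   \item \code{part3}: onset and screen detection before the window,
#'     counterfactual diagnosis inside the window — cases removed from the
#'     study.
#' }
#' Detection and escape use the period-matched behaviours and the geometric
#' escape law of \code{\link{detection_probability}}; the pre-window escape
#' factor uses the complement form for non-screeners by default
#' (\code{line1_form = "complement"}), or the literal product form
#' (\code{"literal"}).
#'
#' @inheritParams cum_incidence_unscreened
#' @param behavior_b,behavior_d \code{screening_behavior} for the stratum,
#'   before and during the study.
#' @param policy A \code{screening_policy}.
#' @param line1_form Escape-before construction for the added-incidence term.
#' @return Named numeric vector \code{c(part1, part2, part3)}, all \eqn{\ge 0}.
#' @export
screening_parts <- function(wb, wd, f, behavior_b, behavior_d, policy, window,
                            i, step = 0.05,
                            line1_form = c("complement", "literal")) {
  line1_form <- match.arg(line1_form)
  a0 <- window$a0[i]; aE <- window$aE[i]; maxage <- window$maxage
  # the integrands step at the behaviour bin edges and kink at screenage;
  # split the outer quadrature there so each panel is smooth
  knots <- c(behavior_b$breaks, behavior_d$breaks, policy$screenage)
  # part1: pre-window onset, escape before, detected during, z in (aE, maxage]
  part1 <- integrate_simpson_knots(function(x) {
    esc <- escape_before_prob(behavior_b, policy, x, a0, line1_form)
    det <- detection_probability(behavior_d, policy, x, a0, aE)
    incidence_intensity(wb, x) * esc * det * sojourn_window_prob(f, x, aE, maxage)
  }, 0, a0, step, knots)
  # part2: in-window onset, detected during, z in (aE, maxage]
  part2 <- integrate_simpson_knots(function(x) {
    det <- detection_probability(behavior_d, policy, x, a0, aE)
    incidence_intensity(wd, x) * det * sojourn_window_prob(f, x, aE, maxage)
  }, a0, aE, step, knots)
  # part3: pre-window onset and detection, z in (a0, aE]
  part3 <- integrate_simpson_knots(function(x) {
    det <- detection_probability(behavior_b, policy, x, 0, a0)
    incidence_intensity(wb, x) * det * sojourn_window_prob(f, x, a0, aE)
  }, 0, a0, step, knots)
  c(part1 = part1, part2 = part2, part3 = part3)
}

#' Screening-adjusted cumulative incidence for one age stratum
#'
#' Combines the unscreened baseline with the three screening terms:
#' \eqn{G_S = G_U + part_1 + part_2 - part_3} (default), so that with no
#' screening \eqn{G_S = G_U} exactly and the bias relative risk of an
#' unbiased study is 1. Setting \code{gs_includes_baseline = FALSE} returns
#' only the net screening delta \eqn{part_1 + part_2 - part_3}.
#'
#' @inheritParams screening_parts
#' @param gs_includes_baseline Include the unscreened baseline term
#'   (default \code{TRUE}).
#' @return List with \code{G_U}, \code{part1}, \code{part2}, \code{part3},
#'   \code{G_S}.
#' @export
cum_incidence_observed <- function(wb, wd, f, behavior_b, behavior_d, policy,
                                   window, i, step = 0.05,
                                   line1_form = c("complement", "literal"),
                                   gs_includes_baseline = TRUE) {
  line1_form <- match.arg(line1_form)
  G_U <- cum_incidence_unscreened(wb, wd, f, window, i, step)
  parts <- screening_parts(wb, wd, f, behavior_b, behavior_d, policy, window,
                           i, step, line1_form)
  G_S <- if (gs_includes_baseline) G_U + parts[["part1"]] + parts[["part2"]] -
    parts[["part3"]] else parts[["part1"]] + parts[["part2"]] - parts[["part3"]]
  if (G_S < -1e-9)
    stop_ltbca(sprintf("adjusted cumulative incidence is negative (%.3e); model inconsistency",
                       G_S), "ltbca_model_error")
  list(G_U = G_U, part1 = parts[["part1"]], part2 = parts[["part2"]],
       part3 = parts[["part3"]], G_S = max(G_S, 0))
}

#' Aggregate per-age-stratum values with birth-cohort weights
#'
#' \eqn{G(r) = \sum_i \omega_i\,G(a_i; r)}.
#'
#' @param values One value per age stratum.
#' @param weights Weights \eqn{\omega_i} (e.g. \code{window$weights}).
#' @return Weighted sum.
#' @export
aggregate_strata <- function(values, weights) {
  if (length(values) != length(weights))
    stop_ltbca("values and weights must have equal length", "ltbca_domain_error")
  sum(weights * values)
}

#' Bias relative risk
#'
#' The ratio of the screening-adjusted cumulative incidences across the two
#' risk-factor strata. Under the joint null (neither the risk factor nor
#' screening affects underlying incidence) the true ratio is 1; any deviation
#' is lead-time-biased case ascertainment.
#'
#' @param G_S_exposed,G_S_unexposed Aggregated adjusted cumulative incidences
#'   for the exposed (numerator) and unexposed (denominator) strata.
#' @return The bias RR.
#' @export
bias_rr <- function(G_S_exposed, G_S_unexposed) {
  if (!is.finite(G_S_unexposed) || G_S_unexposed <= 0 ||
      !is.finite(G_S_exposed) || G_S_exposed < 0)
    stop_ltbca("bias_rr needs positive cumulative incidences (degenerate scenario?)",
               "ltbca_degenerate_error")
  G_S_exposed / G_S_unexposed
}

#' Correct a two-by-two table for lead-time-biased case ascertainment
#'
#' Given the cells of a case-control table — \code{a} exposed cases, \code{b}
#' exposed noncases, \code{c} unexposed cases, \code{d} unexposed noncases —
#' and the simulated bias RR, multiplies the unexposed case count by the bias
#' RR (making the expected rates equal across strata under the null) and
#' returns the corrected odds ratio \eqn{ad/(b\,c\,rr)} and risk ratio
#' \eqn{[a/(a+b)] / [c\,rr/(c\,rr + d)]} alongside the uncorrected values.
#' Cells that make an estimate undefined yield \code{NA} rather than an error.
#'
#' @param a,b,c,d Nonnegative counts.
#' @param rr Simulated bias relative risk (> 0).
#' @return List with \code{or_uncorrected}, \code{rr_uncorrected},
#'   \code{or_corrected}, \code{rr_corrected} and the corrected table.
#' @examples
#' correct_two_by_two(120, 880, 100, 900, rr = 1.2)
#' @export
correct_two_by_two <- function(a, b, c, d, rr) {
  if (any(c(a, b, c, d) < 0))
    stop_ltbca("table cells must be nonnegative", "ltbca_domain_error")
  if (!is.numeric(rr) || length(rr) != 1L || !is.finite(rr) || rr <= 0)
    stop_ltbca("`rr` must be a single positive number", "ltbca_domain_error")
  safe_ratio <- function(num, den) {
    if (is.na(num) || is.na(den) || den <= 0) NA_real_ else num / den
  }
  cs <- c * rr
  list(
    or_uncorrected = safe_ratio(a * d, b * c),
    rr_uncorrected = safe_ratio(safe_ratio(a, a + b), safe_ratio(c, c + d)),
    or_corrected = safe_ratio(a * d, b * cs),
    rr_corrected = safe_ratio(safe_ratio(a, a + b), safe_ratio(cs, cs + d)),
    table_corrected = c(a = a, b = b, c = cs, d = d))
}

#' Full bias computation for a scenario
#'
#' Runs the deterministic pipeline for every risk-factor stratum and age
#' stratum: unscreened baseline, the three screening terms, the adjusted
#' cumulative incidence, the weighted aggregation, and the bias RR of the
#' first (exposed) stratum relative to the second.
#'
#' @param scenario A scenario list as built by \code{\link{default_scenario}}
#'   or \code{\link{load_scenario}}.
#' @return A \code{bias_result}: list with \code{by_stratum} (data frame of
#'   per-cell values), \code{aggregate} (per risk stratum), and \code{rr}.
#' @export
compute_bias <- function(scenario) {
  sc <- scenario
  strata <- sc$strata
  if (length(strata) != 2L)
    stop_ltbca("compute_bias needs exactly two risk-factor strata", "ltbca_domain_error")
  mean_dur <- duration_mean(sc$duration)
  wb <- shift_to_preclinical(sc$curve_before, mean_dur)
  wd <- shift_to_preclinical(sc$curve_during, mean_dur)
  window <- sc$window
  rows <- list()
  agg <- stats::setNames(numeric(2), strata)
  aggU <- stats::setNames(numeric(2), strata)
  for (r in seq_along(strata)) {
    s <- strata[r]
    beh_b <- sc$behaviors[[paste(s, "before", sep = ".")]]
    beh_d <- sc$behaviors[[paste(s, "during", sep = ".")]]
    if (is.null(beh_b) || is.null(beh_d))
      stop_ltbca(sprintf("missing screening behaviour for stratum '%s'", s),
                 "ltbca_data_error")
    w_r <- stratum_weights(sc, s)
    vals <- lapply(seq_along(window$a0), function(i)
      cum_incidence_observed(wb, wd, sc$duration, beh_b, beh_d, sc$policy,
                             window, i, step = sc$step,
                             line1_form = sc$line1_form,
                             gs_includes_baseline = sc$gs_includes_baseline))
    for (i in seq_along(vals))
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, age_stratum = window$labels[i], weight = w_r[i],
        G_U = vals[[i]]$G_U, part1 = vals[[i]]$part1, part2 = vals[[i]]$part2,
        part3 = vals[[i]]$part3, G_S = vals[[i]]$G_S, stringsAsFactors = FALSE)
    agg[s] <- aggregate_strata(vapply(vals, `[[`, numeric(1), "G_S"), w_r)
    aggU[s] <- aggregate_strata(vapply(vals, `[[`, numeric(1), "G_U"), w_r)
  }
  structure(list(by_stratum = do.call(rbind, rows),
                 aggregate = data.frame(stratum = strata, G_U = unname(aggU),
                                        G_S = unname(agg),
                                        stringsAsFactors = FALSE),
                 rr = bias_rr(agg[[1L]], agg[[2L]])),
            class = "bias_result")
}

# per-risk-stratum age weights: shared window weights unless the scenario
# carries a stratum-specific weight table
stratum_weights <- function(scenario, stratum) {
  wtab <- scenario$stratum_weights
  if (is.null(wtab)) return(scenario$window$weights)
  w <- wtab[[stratum]]
  if (is.null(w)) scenario$window$weights else w
}

#' @export
print.bias_result <- function(x, ...) {
  cat("LTBCA bias result\n")
  cat(sprintf("  bias RR (%s / %s): %.6f\n", x$aggregate$stratum[1L],
              x$aggregate$stratum[2L], x$rr))
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}
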