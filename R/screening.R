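#' Age-specific screening behaviour for one stratum and period
#'
#' Screening behaviour is summarised by two step functions over half-open age
#' bins: \code{k1(age)}, the proportion of the stratum that ever screens, and
#' \code{k2(age)}, the screening rate (screens per year) among those who
#' screen. Outside the covered bins both functions extrapolate as the nearest
#' bin's constant.
#'
#' @param stratum Risk-factor stratum label.
#' @param period \code{"before"} or \code{"during"} (the study window).
#' @param age_lo,age_hi Contiguous, sorted half-open bin limits in years.
#' @param k1 Proportion ever screened per bin, in \eqn{[0, 1]}.
#' @param k2 Screens per year among screeners per bin, \eqn{\ge 0}.
#' @return A \code{screening_behavior} object.
#' @export
screening_behavior <- function(stratum, period, age_lo, age_hi, k1, k2) {
  n <- length(age_lo)
  if (!n || length(age_hi) != n || length(k1) != n || length(k2) != n)
    stop_ltbca("age_lo, age_hi, k1, k2 must be non-empty and equal length",
               "ltbca_data_error")
  if (is.unsorted(age_lo, strictly = TRUE) || any(age_hi <= age_lo))
    stop_ltbca("age bins must be sorted with age_lo < age_hi", "ltbca_data_error")
  if (n > 1L && any(abs(age_hi[-n] - age_lo[-1L]) > 1e-9))
    stop_ltbca("age bins must be contiguous (age_hi[j] == age_lo[j+1])",
               "ltbca_data_error")
  if (any(k1 < 0 | k1 > 1))
    stop_ltbca("k1 must lie in [0, 1] in every bin", "ltbca_data_error")
  if (any(k2 < 0))
    stop_ltbca("k2 must be nonnegative in every bin", "ltbca_data_error")
  if (!period %in% c("before", "during"))
    stop_ltbca("period must be 'before' or 'during'", "ltbca_data_error")
  structure(list(stratum = as.character(stratum), period = period,
                 breaks = as.numeric(c(age_lo, age_hi[n])), k1 = as.numeric(k1),
                 k2 = as.numeric(k2)),
            class = "screening_behavior")
}

#' Evaluate screening step functions at given ages
#'
#' @param behavior A \code{screening_behavior}.
#' @param age Ages in years (vectorised).
#' @return Proportion ever screened (\code{k1_at}) or screens/year among
#'   screeners (\code{k2_at}).
#' @export
k1_at <- function(behavior, age) {
  stopifnot(inherits(behavior, "screening_behavior"))
  step_lookup(behavior$breaks, behavior$k1, age)
}

#' @rdname k1_at
#' @export
k2_at <- function(behavior, age) {
  stopifnot(inherits(behavior, "screening_behavior"))
  step_lookup(behavior$breaks, behavior$k2, age)
}

#' Expected number of screens over an age interval
#'
#' \eqn{N(u, v) = \int_u^v k_2(y)\,dy}, evaluated exactly as a sum of
#' bin-width by rate overlaps (with nearest-bin constant extrapolation outside
#' the covered range). This is the quantity that enters the geometric escape
#' law.
#'
#' @param behavior A \code{screening_behavior}.
#' @param u,v Interval limits in years, \code{u <= v} (vectorised).
#' @return Expected screen counts.
#' @export
expected_screens <- function(behavior, u, v) {
  stopifnot(inherits(behavior, "screening_behavior"))
  if (any(v < u))
    stop_ltbca("expected_screens requires u <= v", "ltbca_interval_error")
  step_integral(behavior$breaks, behavior$k2, u, v)
}

#' Screening policy: test sensitivity, starting age and detection form
#'
#' @param sensitivity Per-screen probability \eqn{\xi \in [0, 1]} that an
#'   existing preclinical case is detected (0 is the degenerate
#'   no-detection case).
#' @param screenage Age (years) at which screening is assumed to begin for
#'   those who screen.
#' @param detection_form \code{"geometric"} (default): after an expected
#'   \eqn{N} screens the escape probability is \eqn{(1-\xi)^N}.
#'   \code{"linear"}: detection probability \eqn{\min(1, \xi N)}, the
#'   first-order expansion of the geometric form, clamped.
#' @return A \code{screening_policy} object.
#' @export
screening_policy <- function(sensitivity, screenage = 40,
                             detection_form = c("geometric", "linear")) {
  detection_form <- match.arg(detection_form)
  if (!is.numeric(sensitivity) || length(sensitivity) != 1L ||
      sensitivity < 0 || sensitivity > 1)
    stop_ltbca("`sensitivity` must be a single number in [0, 1]", "ltbca_domain_error")
  if (!is.numeric(screenage) || length(screenage) != 1L || screenage < 0)
    stop_ltbca("`screenage` must be a single nonnegative age", "ltbca_domain_error")
  structure(list(sensitivity = sensitivity, screenage = screenage,
                 detection_form = detection_form),
            class = "screening_policy")
}

# escape probability after an expected count N of screens, for a screener
escape_after <- function(policy, N) {
  xi <- policy$sensitivity
  if (policy$detection_form == "geometric") (1 - xi)^N
  else pmax(0, 1 - pmin(1, xi * N))
}

#' Probability that a preclinical case is screen-detected over an age interval
#'
#' For a person with preclinical onset at age \code{onset_age}, returns the
#' probability of being screen-detected by a screen falling in
#' \code{[u, v]}. Screens can only detect once detectable preclinical disease
#' exists and once screening has begun, so the effective lower bound is
#' \eqn{L = \max(onset\_age, screenage, u)}. With \eqn{N = N(L, v)} expected
#' screens, the geometric form returns
#' \eqn{k_1(onset\_age)\,\{1 - (1-\xi)^N\}}; the result always lies in
#' \eqn{[0, k_1(onset\_age)]}.
#'
#' @param behavior A \code{screening_behavior} (supplies \code{k1}, \code{k2}).
#' @param policy A \code{screening_policy}.
#' @param onset_age Age(s) at preclinical onset, years.
#' @param u,v Screening interval limits, \code{u <= v}.
#' @return Detection probabilities (vectorised over \code{onset_age}).
#' @export
detection_probability <- function(behavior, policy, onset_age, u, v) {
  stopifnot(inherits(policy, "screening_policy"))
  if (any(v < u))
    stop_ltbca("detection_probability requires u <= v", "ltbca_interval_error")
  L <- pmax(onset_age, policy$screenage, u)
  N <- expected_screens(behavior, pmin(L, v), v)
  k1_at(behavior, onset_age) * (1 - escape_after(policy, N))
}

#' Derive screening behaviour from survey counts
#'
#' Converts questionnaire-style counts — per age bin, the number of
#' respondents, the number screened exactly once and the number screened two
#' or more times over a recall window — into the \code{k1}/\code{k2} step
#' functions. The open "2+" category contributes a configurable imputed
#' screen count (default 2, a conservative floor).
#'
#' @param counts Data frame with columns \code{stratum}, \code{period},
#'   \code{age_lo}, \code{age_hi}, \code{n_total}, \code{n_screened_1},
#'   \code{n_screened_2plus}, \code{window_years}.
#' @param two_plus_value Imputed number of screens for the "2+" category.
#' @return A \code{screening_behavior} (counts must be for one stratum and
#'   period).
#' @export
behavior_from_survey <- function(counts, two_plus_value = 2) {
  need <- c("stratum", "period", "age_lo", "age_hi", "n_total",
            "n_screened_1", "n_screened_2plus", "window_years")
  if (!all(need %in% names(counts)))
    stop_ltbca(sprintf("survey counts must have columns %s",
                       paste(need, collapse = ", ")), "ltbca_data_error")
  if (length(unique(counts$stratum)) != 1L || length(unique(counts$period)) != 1L)
    stop_ltbca("survey counts must cover exactly one stratum and period",
               "ltbca_data_error")
  n_ever <- counts$n_screened_1 + counts$n_screened_2plus
  if (any(n_ever > counts$n_total))
    stop_ltbca("screened counts exceed totals in at least one bin",
               "ltbca_validation_error")
  if (any(counts$n_screened_1 < 0 | counts$n_screened_2plus < 0 | counts$n_total < 0))
    stop_ltbca("survey counts must be nonnegative", "ltbca_validation_error")
  keep <- counts$n_total > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d empty survey bin(s) (n_total = 0)", sum(!keep)))
    counts <- counts[keep, , drop = FALSE]
    n_ever <- n_ever[keep]
  }
  k1 <- n_ever / counts$n_total
  screens <- counts$n_screened_1 + two_plus_value * counts$n_screened_2plus
  k2 <- ifelse(n_ever > 0, screens / (n_ever * counts$window_years), 0)
  screening_behavior(counts$stratum[1L], counts$period[1L],
                     counts$age_lo, counts$age_hi, k1, k2)
}

#' Read and write screening behaviour tables
#'
#' CSV schema: columns \code{stratum}, \code{period}, \code{age_lo},
#' \code{age_hi}, \code{k1}, \code{k2}; one row per stratum, period, and age
#' bin.
#'
#' @param path File path.
#' @return \code{read_screening_csv}: a named list of
#'   \code{screening_behavior} objects keyed \code{"<stratum>.<period>"}.
#' @export
read_screening_csv <- function(path) {
  if (!file.exists(path))
    stop_ltbca(sprintf("screening file not found: %s", path), "ltbca_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stratum", "period", "age_lo", "age_hi", "k1", "k2")
  if (!all(need %in% names(df)))
    stop_ltbca(sprintf("screening CSV must have columns %s",
                       paste(need, collapse = ", ")), "ltbca_io_error")
  out <- list()
  for (s in unique(df$stratum)) for (p in unique(df$period[df$stratum == s])) {
    sub <- df[df$stratum == s & df$period == p, , drop = FALSE]
    sub <- sub[order(sub$age_lo), , drop = FALSE]
    out[[paste(s, p, sep = ".")]] <-
      screening_behavior(s, p, sub$age_lo, sub$age_hi, sub$k1, sub$k2)
  }
  out
}

#' @rdname read_screening_csv
#' @param behaviors Named list of \code{screening_behavior} objects.
#' @export
write_screening_csv <- function(behaviors, path) {
  rows <- lapply(behaviors, function(b) {
    n <- length(b$k1)
    data.frame(stratum = b$stratum, period = b$period,
               age_lo = format_full(b$breaks[-(n + 1L)]),
               age_hi = format_full(b$breaks[-1L]),
               k1 = format_full(b$k1), k2 = format_full(b$k2),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.screening_behavior <- function(x, ...) {
  cat(sprintf("Screening behaviour: stratum '%s', period '%s', %d age bins (%g-%g y)\n",
              x$stratum, x$period, length(x$k1), x$breaks[1L],
              x$breaks[length(x$breaks)]))
  cat(sprintf("  k1 range [%.3g, %.3g]; k2 range [%.3g, %.3g] screens/y\n",
              min(x$k1), max(x$k1), min(x$k2), max(x$k2)))
  invisible(x)
}
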