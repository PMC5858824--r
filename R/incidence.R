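#' Age-specific incidence points
#'
#' Validates a registry-style table of age-banded incidence rates. Bands are
#' half-open \code{[age_lo, age_hi)}; an open-ended final band ("85+") is
#' encoded with \code{age_hi = Inf} and is attached to \code{age_lo + 2.5}
#' years when fitting, consistent with 5-year registry bands.
#'
#' @param age_lo,age_hi Band limits in years.
#' @param rate_per_100k Incidence rate, cases per 100,000 person-years.
#' @param period Either \code{"before"} or \code{"during"}.
#' @return A \code{data.frame} of class \code{incidence_points}.
#' @export
incidence_points <- function(age_lo, age_hi, rate_per_100k, period) {
  df <- data.frame(age_lo = as.numeric(age_lo), age_hi = as.numeric(age_hi),
                   rate_per_100k = as.numeric(rate_per_100k),
                   period = as.character(period), stringsAsFactors = FALSE)
  if (any(is.na(df$age_lo)) || any(is.na(df$rate_per_100k)))
    stop_ltbca("incidence points contain missing ages or rates", "ltbca_data_error")
  if (any(df$age_lo >= df$age_hi, na.rm = TRUE))
    stop_ltbca("incidence bands must satisfy age_lo < age_hi", "ltbca_data_error")
  if (any(df$rate_per_100k < 0))
    stop_ltbca("incidence rates must be nonnegative", "ltbca_data_error")
  if (!all(df$period %in% c("before", "during")))
    stop_ltbca("period must be 'before' or 'during'", "ltbca_data_error")
  class(df) <- c("incidence_points", "data.frame")
  df
}

#' Read and write incidence point tables
#'
#' CSV schema: columns \code{age_lo}, \code{age_hi}, \code{rate_per_100k},
#' \code{period}. Numeric values are written with full decimal precision so
#' that reading back reproduces them exactly.
#'
#' @param path File path.
#' @return \code{read_incidence_csv}: an \code{incidence_points} data frame.
#' @export
read_incidence_csv <- function(path) {
  if (!file.exists(path))
    stop_ltbca(sprintf("incidence file not found: %s", path), "ltbca_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_lo", "age_hi", "rate_per_100k", "period")
  if (!all(need %in% names(df)))
    stop_ltbca(sprintf("incidence CSV must have columns %s",
                       paste(need, collapse = ", ")), "ltbca_io_error")
  incidence_points(df$age_lo, df$age_hi, df$rate_per_100k, df$period)
}

#' @rdname read_incidence_csv
#' @param points An \code{incidence_points} data frame.
#' @export
write_incidence_csv <- function(points, path) {
  df <- as.data.frame(points)
  df$age_lo <- format_full(df$age_lo)
  df$age_hi <- format_full(df$age_hi)
  df$rate_per_100k <- format_full(df$rate_per_100k)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# shortest decimal representation that round-trips exactly
format_full <- function(x) vapply(x, function(v) format(v, digits = 17), character(1))

band_midpoints <- function(df, open_band_halfwidth = 2.5) {
  ifelse(is.finite(df$age_hi), (df$age_lo + df$age_hi) / 2,
         df$age_lo + open_band_halfwidth)
}

#' Fit a continuous age-specific incidence intensity
#'
#' Fits a smooth, strictly positive intensity function to age-banded registry
#' rates, attached at band midpoints. The default family is the exponential of
#' a cubic polynomial in age ("log-rate cubic"): positive everywhere, four
#' parameters, and able to follow the convex rise and late plateau typical of
#' adult-cancer incidence. Fitting is least squares on the log-rate scale
#' (linear in the coefficients) or, optionally, nonlinear least squares on the
#' rate scale.
#'
#' Zero-rate points cannot be used on the log scale and are dropped with a
#' warning; at least 4 positive points are required.
#'
#' @param points An \code{incidence_points} data frame (may contain both
#'   periods).
#' @param period Which period to fit, \code{"before"} or \code{"during"}.
#' @param family \code{"logcubic"} (default) or \code{"logquadratic"}.
#' @param scale \code{"log"} (default; least squares on log rates) or
#'   \code{"rate"} (\code{\link[stats]{nls}} on the rate scale, started from
#'   the log-scale fit).
#' @param maxage Upper age limit of the curve's domain (years).
#' @return An \code{incidence_curve} object. Evaluate it with
#'   \code{\link{incidence_intensity}} (per person-year) or
#'   \code{\link{incidence_rate}} (per 100,000 person-years).
#' @export
fit_incidence_curve <- function(points, period = c("before", "during"),
                                family = c("logcubic", "logquadratic"),
                                scale = c("log", "rate"), maxage = 100) {
  period <- match.arg(period)
  family <- match.arg(family)
  scale <- match.arg(scale)
  df <- points[points$period == period, , drop = FALSE]
  if (nrow(df) == 0L)
    stop_ltbca(sprintf("no incidence points for period '%s'", period),
               "ltbca_fit_error")
  mid <- band_midpoints(df)
  rate <- df$rate_per_100k
  if (all(rate == 0))
    stop_ltbca("all incidence rates are zero; cannot fit a curve", "ltbca_fit_error")
  if (any(rate == 0)) {
    warning(sprintf("dropping %d zero-rate band(s); log-rate undefined",
                    sum(rate == 0)))
    mid <- mid[rate > 0]; rate <- rate[rate > 0]
  }
  degree <- if (family == "logcubic") 3L else 2L
  if (length(mid) < degree + 1L)
    stop_ltbca(sprintf("need at least %d positive-rate points for family '%s'",
                       degree + 1L, family), "ltbca_fit_error")
  X <- stats::poly(mid, degree = degree, raw = TRUE)
  fit <- stats::lm(log(rate) ~ X)
  coefs <- unname(stats::coef(fit))
  rss <- sum(stats::resid(fit)^2)
  if (scale == "rate") {
    dat <- data.frame(mid = mid, rate = rate)
    form <- if (degree == 3L)
      rate ~ exp(c0 + c1 * mid + c2 * mid^2 + c3 * mid^3)
    else rate ~ exp(c0 + c1 * mid + c2 * mid^2)
    start <- as.list(stats::setNames(coefs, paste0("c", 0:degree)))
    # Levenberg-Marquardt: robust where Gauss-Newton stalls (e.g. the
    # zero-residual case of noiseless points)
    nfit <- tryCatch(minpack.lm::nlsLM(form, data = dat, start = start,
                                       control = minpack.lm::nls.lm.control(maxiter = 500)),
                     error = function(e) stop_ltbca(
                       sprintf("rate-scale fit did not converge: %s", conditionMessage(e)),
                       "ltbca_numerical_error"))
    coefs <- unname(stats::coef(nfit))
    rss <- sum(stats::resid(nfit)^2)
  }
  structure(list(family = family, scale = scale, coef = coefs, period = period,
                 maxage = maxage, shift = 0, rss = rss,
                 n_points = length(mid)),
            class = "incidence_curve")
}

curve_log_rate <- function(curve, age) {
  co <- curve$coef
  eta <- co[1L]
  for (d in seq_len(length(co) - 1L)) eta <- eta + co[d + 1L] * age^d
  eta
}

#' Evaluate an incidence curve
#'
#' \code{incidence_intensity} returns the intensity per person-year (the
#' per-100,000 registry scale divided by 100,000 — the single place where that
#' conversion happens); \code{incidence_rate} returns cases per 100,000
#' person-years. If the curve has been back-shifted with
#' \code{\link{shift_to_preclinical}}, evaluation at age \eqn{x} returns the
#' underlying clinical curve at \eqn{x + shift}, clamped at \code{maxage}.
#'
#' @param curve An \code{incidence_curve}.
#' @param age Ages in years (vectorised).
#' @return Numeric vector of intensities.
#' @export
incidence_intensity <- function(curve, age) {
  incidence_rate(curve, age) / 1e5
}

#' @rdname incidence_intensity
#' @export
incidence_rate <- function(curve, age) {
  stopifnot(inherits(curve, "incidence_curve"))
  age_eff <- pmin(age + curve$shift, curve$maxage)
  exp(curve_log_rate(curve, age_eff))
}

#' Back-shift a clinical incidence curve to a preclinical onset intensity
#'
#' Preclinical onset is unobservable; the model obtains the onset intensity
#' \eqn{w(x)} by shifting the fitted clinical incidence backward by the mean
#' preclinical duration: the clinical incidence observed at age
#' \eqn{x + \bar{t}} becomes the preclinical onset intensity at age \eqn{x}.
#' Ages whose shifted argument exceeds \code{maxage} are clamped to the
#' curve's value there.
#'
#' @param curve An \code{incidence_curve}.
#' @param mean_duration Mean preclinical duration in years (>= 0).
#' @return The shifted \code{incidence_curve}.
#' @export
shift_to_preclinical <- function(curve, mean_duration) {
  stopifnot(inherits(curve, "incidence_curve"))
  if (!is.numeric(mean_duration) || length(mean_duration) != 1L ||
      !is.finite(mean_duration) || mean_duration < 0)
    stop_ltbca("`mean_duration` must be a single nonnegative number of years",
               "ltbca_domain_error")
  curve$shift <- curve$shift + mean_duration
  curve
}

#' @export
print.incidence_curve <- function(x, ...) {
  cat(sprintf("Incidence curve (%s, %s scale, period '%s')\n",
              x$family, x$scale, x$period))
  cat(sprintf("  coefficients: %s\n", paste(signif(x$coef, 6), collapse = ", ")))
  cat(sprintf("  back-shift: %.4g y; RSS: %.4g (%d points)\n",
              x$shift, x$rss, x$n_points))
  invisible(x)
}

#' @export
plot.incidence_curve <- function(x, points = NULL, ...) {
  age <- seq(0, x$maxage, length.out = 400)
  graphics::plot(age, incidence_rate(x, age), type = "l", xlab = "age (years)",
                 ylab = "incidence per 100,000 person-years", ...)
  if (!is.null(points)) {
    df <- points[points$period == x$period, , drop = FALSE]
    graphics::points(band_midpoints(df), df$rate_per_100k, pch = 19)
  }
  invisible(x)
}
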