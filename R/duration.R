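#' Lognormal preclinical duration distribution from its mode and standard deviation
#'
#' Constructs the sojourn-time (preclinical duration) distribution used
#' throughout the model: the time from detectable preclinical onset to
#' symptomatic diagnosis. The distribution is lognormal, parameterised by the
#' epidemiologically interpretable mode and standard deviation in years rather
#' than by its log-scale location and scale.
#'
#' Writing \eqn{s^2} for the log-scale variance, the mode constraint gives
#' \eqn{\mu = \log(mode) + s^2}, and substituting into the variance identity
#' reduces the problem to the one-dimensional equation
#' \eqn{(e^{s^2}-1)\,e^{3 s^2} = (sd/mode)^2}, whose left side is strictly
#' increasing in \eqn{s^2}. It is solved by bisection (\code{\link[stats]{uniroot}})
#' to near machine precision.
#'
#' @param mode Mode of the duration distribution, in years (> 0).
#' @param sd Standard deviation of the duration distribution, in years (> 0).
#' @return An object of class \code{c("lognormal_duration", "duration_spec")}
#'   with fields \code{mode}, \code{sd}, \code{meanlog}, \code{sdlog}.
#' @examples
#' spec <- lognormal_duration(mode = 5, sd = 3)
#' duration_mean(spec)
#' @export
lognormal_duration <- function(mode, sd) {
  if (!is.numeric(mode) || length(mode) != 1L || !is.finite(mode) || mode <= 0)
    stop_ltbca("`mode` must be a single positive number of years", "ltbca_domain_error")
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop_ltbca("`sd` must be a single positive number of years", "ltbca_domain_error")
  target <- (sd / mode)^2
  g <- function(s2) (exp(s2) - 1) * exp(3 * s2) - target
  upper <- 1
  while (g(upper) < 0 && upper < 700) upper <- upper * 2
  root <- tryCatch(
    stats::uniroot(g, c(1e-300, upper), tol = .Machine$double.eps^0.9),
    error = function(e) stop_ltbca(
      sprintf("could not solve lognormal parameters for mode = %g, sd = %g: %s",
              mode, sd, conditionMessage(e)),
      "ltbca_numerical_error"))
  s2 <- root$root
  structure(
    list(mode = mode, sd = sd, meanlog = log(mode) + s2, sdlog = sqrt(s2)),
    class = c("lognormal_duration", "duration_spec"))
}

#' Mixture preclinical duration distribution
#'
#' A finite mixture of lognormal duration components, used to model an
#' overdiagnosis-prone subpopulation with a very long sojourn time alongside
#' the main disease-natural-history component.
#'
#' @param components List of \code{lognormal_duration} specs.
#' @param weights Numeric mixture weights in \eqn{[0,1]} summing to 1
#'   (within 1e-12).
#' @return An object of class \code{c("mixture_duration", "duration_spec")}.
#' @seealso \code{\link{overdiagnosis_mixture}}
#' @export
mixture_duration <- function(components, weights) {
  if (!is.list(components) || !length(components) ||
      !all(vapply(components, inherits, logical(1), "lognormal_duration")))
    stop_ltbca("`components` must be a non-empty list of lognormal_duration specs",
               "ltbca_domain_error")
  if (length(weights) != length(components) || any(weights < 0) || any(weights > 1))
    stop_ltbca("`weights` must match components and lie in [0, 1]", "ltbca_domain_error")
  if (abs(sum(weights) - 1) > 1e-12)
    stop_ltbca("mixture weights must sum to 1 (within 1e-12)", "ltbca_domain_error")
  structure(list(components = components, weights = as.numeric(weights)),
            class = c("mixture_duration", "duration_spec"))
}

#' Overdiagnosis mixture around a base sojourn distribution
#'
#' Convenience constructor for the two-component mixture in which a fraction
#' of the preclinical-case population draws its sojourn from a very long
#' duration distribution (and is therefore liable to overdiagnosis when
#' screened), while the remainder follows the base distribution.
#'
#' @param base A \code{lognormal_duration} spec for the main component.
#' @param weight Overdiagnosis-component weight (default 0.2).
#' @param od_mode,od_sd Mode and sd (years) of the long component
#'   (defaults 20 and 3).
#' @return A \code{mixture_duration} spec; the long component is last.
#' @export
overdiagnosis_mixture <- function(base, weight = 0.2, od_mode = 20, od_sd = 3) {
  mixture_duration(list(base, lognormal_duration(od_mode, od_sd)),
                   c(1 - weight, weight))
}

#' Evaluate the preclinical duration density
#'
#' @param spec A duration spec.
#' @param t Durations in years (vectorised). Density is 0 for \code{t <= 0}.
#' @return Density values (per year).
#' @export
duration_density <- function(spec, t) UseMethod("duration_density")

#' @export
duration_density.lognormal_duration <- function(spec, t) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- stats::dlnorm(t[pos], spec$meanlog, spec$sdlog)
  out
}

#' @export
duration_density.mixture_duration <- function(spec, t) {
  out <- numeric(length(t))
  for (j in seq_along(spec$weights))
    out <- out + spec$weights[j] * duration_density(spec$components[[j]], t)
  out
}

#' Cumulative distribution function of the preclinical duration
#'
#' Used by the cumulative-incidence integrator to collapse the inner sojourn
#' integral \eqn{\int_a^b f(z-x)\,dz} into a difference of CDF values.
#'
#' @inheritParams duration_density
#' @return \eqn{P(T \le t)}, 0 for \code{t <= 0}.
#' @export
duration_cdf <- function(spec, t) UseMethod("duration_cdf")

#' @export
duration_cdf.lognormal_duration <- function(spec, t) {
  stats::plnorm(pmax(t, 0), spec$meanlog, spec$sdlog)
}

#' @export
duration_cdf.mixture_duration <- function(spec, t) {
  out <- numeric(length(t))
  for (j in seq_along(spec$weights))
    out <- out + spec$weights[j] * duration_cdf(spec$components[[j]], t)
  out
}

#' Mean of the preclinical duration distribution
#'
#' The clinical incidence curve is shifted backward by this mean to obtain the
#' preclinical onset intensity.
#'
#' @param spec A duration spec.
#' @return Mean duration in years.
#' @export
duration_mean <- function(spec) UseMethod("duration_mean")

#' @export
duration_mean.lognormal_duration <- function(spec) {
  exp(spec$meanlog + spec$sdlog^2 / 2)
}

#' @export
duration_mean.mixture_duration <- function(spec) {
  sum(spec$weights * vapply(spec$components, duration_mean, numeric(1)))
}

#' Mode and standard deviation recovered from a duration spec
#'
#' Round-trip accessors: recompute the distribution's mode and standard
#' deviation from the stored log-scale parameters.
#'
#' @param spec A \code{lognormal_duration} spec.
#' @return A number of years.
#' @export
duration_mode <- function(spec) {
  stopifnot(inherits(spec, "lognormal_duration"))
  exp(spec$meanlog - spec$sdlog^2)
}

#' @rdname duration_mode
#' @export
duration_sd <- function(spec) {
  stopifnot(inherits(spec, "lognormal_duration"))
  s2 <- spec$sdlog^2
  sqrt((exp(s2) - 1) * exp(2 * spec$meanlog + s2))
}

# Draw n sojourn times; for mixtures also return the component index so that
# overdiagnosis-prone individuals can be tagged in the microsimulation.
duration_sample <- function(spec, n) UseMethod("duration_sample")

#' @export
duration_sample.lognormal_duration <- function(spec, n) {
  list(t = stats::rlnorm(n, spec$meanlog, spec$sdlog),
       component = rep.int(1L, n))
}

#' @export
duration_sample.mixture_duration <- function(spec, n) {
  comp <- sample.int(length(spec$weights), n, replace = TRUE, prob = spec$weights)
  t <- numeric(n)
  for (j in seq_along(spec$weights)) {
    idx <- comp == j
    if (any(idx))
      t[idx] <- stats::rlnorm(sum(idx), spec$components[[j]]$meanlog,
                              spec$components[[j]]$sdlog)
  }
  list(t = t, component = comp)
}

#' @export
print.lognormal_duration <- function(x, ...) {
  cat(sprintf("Lognormal preclinical duration: mode %.4g y, sd %.4g y (mean %.4g y)\n",
              x$mode, x$sd, duration_mean(x)))
  invisible(x)
}

#' @export
print.mixture_duration <- function(x, ...) {
  cat("Mixture preclinical duration:\n")
  for (j in seq_along(x$weights))
    cat(sprintf("  %.3f x (mode %.4g y, sd %.4g y)\n", x$weights[j],
                x$components[[j]]$mode, x$components[[j]]$sd))
  cat(sprintf("  mean %.4g y\n", duration_mean(x)))
  invisible(x)
}

#' Plot duration densities
#'
#' @param x A duration spec.
#' @param tmax Upper plotting limit in years.
#' @param ... Passed to \code{\link[graphics]{plot}}.
#' @export
plot.duration_spec <- function(x, tmax = 30, ...) {
  t <- seq(0.001, tmax, length.out = 400)
  graphics::plot(t, duration_density(x, t), type = "l",
                 xlab = "preclinical duration (years)", ylab = "density", ...)
  invisible(x)
}
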