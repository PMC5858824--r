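# Internal numerical helpers: composite Simpson quadrature on uniform grids and
# exact integration / lookup for step functions on half-open age bins.

# Simpson nodes and weights on [a, b] with step <= h (forced even interval count).
# Returns NULL for empty intervals.
simpson_rule <- function(a, b, h) {
  if (b - a <= 0) return(NULL)
  n <- max(2L, as.integer(ceiling((b - a) / h)))
  if (n %% 2L == 1L) n <- n + 1L
  x <- seq(a, b, length.out = n + 1L)
  w <- c(1, rep_len(c(4, 2), n - 1L), 1)
  list(x = x, w = w * (x[2L] - x[1L]) / 3)
}

integrate_simpson <- function(f, a, b, h) {
  g <- simpson_rule(a, b, h)
  if (is.null(g)) return(0)
  sum(g$w * f(g$x))
}

# Simpson with the domain split at interior knots (step-function bin edges,
# screenage, ...) so each panel's integrand is smooth. Panel endpoints are
# nudged inward by a relative 1e-9 before evaluation so half-open step
# functions are sampled on the panel's own side of a jump.
integrate_simpson_knots <- function(f, a, b, h, knots) {
  pts <- sort(unique(c(a, b, knots[knots > a & knots < b])))
  tot <- 0
  for (j in seq_len(length(pts) - 1L)) {
    g <- simpson_rule(pts[j], pts[j + 1L], h)
    if (is.null(g)) next
    x <- g$x
    eps <- 1e-9 * max(1, abs(pts[j + 1L]))
    x[1L] <- x[1L] + eps
    x[length(x)] <- x[length(x)] - eps
    tot <- tot + sum(g$w * f(x))
  }
  tot
}

# Step-function lookup over half-open bins [lo, hi), constant extrapolation
# outside the covered range. `breaks` has length(values) + 1.
step_lookup <- function(breaks, values, x) {
  idx <- findInterval(x, breaks, rightmost.closed = FALSE, all.inside = TRUE)
  values[idx]
}

# Exact integral of a step function over [u, v] (vectorised over u, v), with
# constant extrapolation below breaks[1] and above breaks[length(breaks)].
step_integral <- function(breaks, values, u, v) {
  stopifnot(length(u) == length(v) || length(u) == 1L || length(v) == 1L)
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  out <- numeric(n)
  bad <- v < u
  # extended cover so extrapolation is an ordinary bin
  lo_ext <- min(breaks[1L], u[!bad], v[!bad], 0)
  hi_ext <- max(breaks[length(breaks)], u[!bad], v[!bad], 1)
  b <- c(lo_ext - 1, breaks, hi_ext + 1)
  vals <- c(values[1L], values, values[length(values)])
  for (j in seq_along(vals)) {
    ov <- pmax(0, pmin(v, b[j + 1L]) - pmax(u, b[j]))
    out <- out + ov * vals[j]
  }
  out[bad] <- NA_real_
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ltbca <- function(msg, class) {
  stop(structure(class = c(class, "ltbca_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
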