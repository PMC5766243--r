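# Two-dimensional dispersal location kernels and their radial distance
# distributions.
#
# A dispersal location kernel f(r) is the probability density of a propagule's
# post-dispersal position in the plane, expressed as a function of radial
# distance r from the source; it integrates to one over the plane,
# int_0^inf 2*pi*r f(r) dr = 1. The corresponding dispersal *distance* kernel
# is k(r) = 2*pi*r f(r), a univariate density on (0, Inf).

#' Names of the supported dispersal kernel families
#'
#' Seven classical two-dimensional dispersal location kernels: negative
#' exponential, Gaussian, power exponential, 2Dt, inverse Gaussian,
#' log-normal and Weibull. The negative exponential and Gaussian families
#' have a single scale parameter `a`; all others add one shape parameter `b`.
#'
#' @return Character vector of family names.
#' @export
#' @examples
#' kernel_families()
kernel_families <- function() {
  c("negative_exponential", "gaussian", "power_exponential",
    "twoDt", "inverse_gaussian", "lognormal", "weibull")
}

n_shape_params <- function(family) {
  if (family %in% c("negative_exponential", "gaussian")) 0L else 1L
}

#' Construct a parameterized dispersal kernel
#'
#' @param family One of [kernel_families()].
#' @param a Scale parameter in metres; must be positive.
#' @param b Shape parameter (dimensionless); required for all families except
#'   `"negative_exponential"` and `"gaussian"`, where it must be omitted.
#'   Must be positive; the 2Dt family additionally requires `b > 1`, otherwise
#'   its plane integral diverges.
#'
#' @return An object of class `kernel_params`.
#' @export
#' @examples
#' kernel_params("weibull", a = 8.5, b = 1.8)
#' kernel_params("gaussian", a = 3)
kernel_params <- function(family, a, b = NULL) {
  family <- match.arg(family, kernel_families())
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("scale parameter 'a' must be a single positive number", call. = FALSE)
  if (n_shape_params(family) == 0L) {
    if (!is.null(b))
      stop(sprintf("family '%s' takes no shape parameter 'b'", family),
           call. = FALSE)
  } else {
    if (is.null(b) || !is.numeric(b) || length(b) != 1L || !is.finite(b) ||
        b <= 0)
      stop(sprintf("family '%s' requires a single positive shape parameter 'b'",
                   family), call. = FALSE)
    if (family == "twoDt" && b <= 1)
      stop("the 2Dt family requires b > 1 (plane integral diverges otherwise)",
           call. = FALSE)
  }
  structure(list(family = family, a = as.numeric(a),
                 b = if (is.null(b)) NULL else as.numeric(b)),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  if (is.null(x$b))
    cat(sprintf("<dispersal kernel: %s, a = %g>\n", x$family, x$a))
  else
    cat(sprintf("<dispersal kernel: %s, a = %g, b = %g>\n",
                x$family, x$a, x$b))
  invisible(x)
}

stopifnot_kernel <- function(params) {
  if (!inherits(params, "kernel_params"))
    stop("'params' must be created with kernel_params()", call. = FALSE)
}

# Is the location density singular (infinite or undefined) at r = 0?
singular_at_origin <- function(params) {
  switch(params$family,
         lognormal = TRUE,
         inverse_gaussian = TRUE,
         weibull = params$b < 2,
         power_exponential = FALSE,
         FALSE)
}

#' Dispersal location kernel density
#'
#' Evaluates the two-dimensional location density f(r) (units: per square
#' metre) at radial distance `r` from the source. The closed forms are, with
#' scale `a` and shape `b`:
#' \describe{
#'   \item{negative exponential}{\eqn{e^{-r/a} / (2\pi a^2)}}
#'   \item{Gaussian}{\eqn{e^{-r^2/a^2} / (\pi a^2)}}
#'   \item{power exponential}{\eqn{b\,e^{-(r/a)^b} / (2\pi a^2 \Gamma(2/b))}}
#'   \item{2Dt}{\eqn{(b-1)/(\pi a^2) \,(1 + r^2/a^2)^{-b}}}
#'   \item{inverse Gaussian}{\eqn{\sqrt{b/(8\pi^3 r^5)}\,
#'     e^{-b(r-a)^2/(2a^2 r)}}}
#'   \item{log-normal}{\eqn{e^{-\ln^2(r/a)/(2b^2)} / ((2\pi)^{3/2} b r^2)}}
#'   \item{Weibull}{\eqn{b\,r^{b-2} e^{-(r/a)^b} / (2\pi a^b)}}
#' }
#' Each integrates to one over the plane. The log-normal, inverse Gaussian,
#' and Weibull (with `b < 2`) densities are singular at the origin; evaluating
#' them at exactly `r = 0` is an error. When a collector sits at distance
#' zero, substitute a small positive effective distance (see
#' [fit_control()]'s `r_eff`).
#'
#' @param params A [kernel_params()] object.
#' @param r Vector of nonnegative radial distances (m).
#' @return Numeric vector of densities (per m^2).
#' @seealso [distance_density()], [distance_cdf()], [distance_quantile()]
#' @export
#' @examples
#' location_density(kernel_params("gaussian", a = 1), 0)  # 1/pi
location_density <- function(params, r) {
  stopifnot_kernel(params)
  if (any(!is.finite(r)) || any(r < 0))
    stop("'r' must be finite and nonnegative", call. = FALSE)
  if (any(r == 0) && singular_at_origin(params))
    stop(sprintf(paste0("the %s location kernel is singular at r = 0; use a ",
                        "positive effective distance for source collectors ",
                        "(see fit_control()'s r_eff)"), params$family),
         call. = FALSE)
  a <- params$a; b <- params$b
  switch(params$family,
    negative_exponential = exp(-r / a) / (2 * pi * a^2),
    gaussian = exp(-(r / a)^2) / (pi * a^2),
    power_exponential =
      b * exp(-(r / a)^b) / (2 * pi * a^2 * gamma(2 / b)),
    twoDt = (b - 1) / (pi * a^2) * (1 + (r / a)^2)^(-b),
    inverse_gaussian =
      sqrt(b / (8 * pi^3 * r^5)) * exp(-b * (r - a)^2 / (2 * a^2 * r)),
    lognormal = {
      out <- exp(-(log(r / a))^2 / (2 * b^2)) / ((2 * pi)^1.5 * b * r^2)
      out
    },
    weibull = {
      # log-space evaluation keeps r^(b-2) stable for small r and large b
      exp(log(b) + (b - 2) * log(r) - (r / a)^b - log(2 * pi) - b * log(a))
    })
}

#' Dispersal distance kernel density
#'
#' The density of the radial dispersal distance, `k(r) = 2 pi r f(r)`, which
#' accounts for the growing circumference of the circle at distance `r` and
#' integrates to one on (0, Inf).
#'
#' @inheritParams location_density
#' @return Numeric vector of densities (per m).
#' @export
#' @examples
#' # negative exponential distance law is Gamma(shape 2, scale a)
#' distance_density(kernel_params("negative_exponential", a = 2), 1:3)
distance_density <- function(params, r) {
  stopifnot_kernel(params)
  if (any(!is.finite(r)) || any(r < 0))
    stop("'r' must be finite and nonnegative", call. = FALSE)
  out <- numeric(length(r))
  pos <- r > 0
  if (any(pos)) out[pos] <- 2 * pi * r[pos] * location_density(params, r[pos])
  if (any(!pos)) {
    # limit of 2*pi*r*f(r) as r -> 0+: zero for every family except the
    # Weibull with b < 1, whose distance density diverges at the origin
    out[!pos] <- if (params$family == "weibull" && params$b < 1) Inf else 0
  }
  out
}

# Adaptive quadrature of the distance density, split at r = a because the
# location-scale singularities (lognormal, inverse Gaussian) concentrate
# curvature near the origin.
integrate_distance_density <- function(params, lower, upper,
                                       rel.tol = 1e-10) {
  f <- function(r) distance_density(params, r)
  split <- params$a
  total <- 0
  if (lower < split && upper > split) {
    total <- total +
      stats::integrate(f, lower, split, rel.tol = rel.tol,
                       subdivisions = 400L)$value +
      stats::integrate(f, split, upper, rel.tol = rel.tol,
                       subdivisions = 400L)$value
  } else {
    total <- stats::integrate(f, lower, upper, rel.tol = rel.tol,
                              subdivisions = 400L)$value
  }
  total
}

# Wald / inverse-Gaussian distance CDF (mean a, shape b), with the
# exp(2b/a) tail term evaluated in log space to avoid overflow.
pwald <- function(r, a, b) {
  out <- numeric(length(r))
  pos <- r > 0
  rp <- r[pos]
  s <- sqrt(b / rp)
  out[pos] <- stats::pnorm(s * (rp / a - 1)) +
    exp(2 * b / a + stats::pnorm(-s * (rp / a + 1), log.p = TRUE))
  pmin(pmax(out, 0), 1)
}

#' Cumulative distribution of the dispersal distance
#'
#' Probability that a propagule settles within radial distance `r` of the
#' source, i.e. the integral of [distance_density()] over (0, r]. Closed
#' forms are used by default (the distance law of each family is a standard
#' univariate distribution: Gamma(2, a) for the negative exponential,
#' Rayleigh for the Gaussian, generalized Gamma for the power exponential,
#' a Pareto-type form for 2Dt, Wald for the inverse Gaussian, log-normal and
#' Weibull for their namesakes); `method = "numeric"` instead integrates the
#' distance density by adaptive quadrature, which serves as an independent
#' cross-check.
#'
#' @inheritParams location_density
#' @param method `"closed"` (default) or `"numeric"`.
#' @return Numeric vector of probabilities.
#' @export
#' @examples
#' distance_cdf(kernel_params("weibull", a = 2, b = 3), 2)  # 1 - exp(-1)
distance_cdf <- function(params, r, method = c("closed", "numeric")) {
  stopifnot_kernel(params)
  method <- match.arg(method)
  if (any(!is.finite(r) & !(r == Inf)) || any(r < 0))
    stop("'r' must be nonnegative", call. = FALSE)
  a <- params$a; b <- params$b
  if (method == "closed") {
    out <- switch(params$family,
      negative_exponential = stats::pgamma(r, shape = 2, scale = a),
      gaussian = -expm1(-(r / a)^2),
      power_exponential = stats::pgamma((r / a)^b, shape = 2 / b),
      twoDt = -expm1((1 - b) * log1p((r / a)^2)),
      inverse_gaussian = pwald(r, a, b),
      lognormal = stats::plnorm(r, meanlog = log(a), sdlog = b),
      weibull = stats::pweibull(r, shape = b, scale = a))
    return(out)
  }
  vapply(r, function(ri) {
    if (ri == 0) return(0)
    if (!is.finite(ri)) return(1)
    min(1, integrate_distance_density(params, 0, ri))
  }, numeric(1))
}

#' Quantiles of the dispersal distance
#'
#' The radial distance within which a proportion `q` of propagules settle;
#' `q = 0.5` gives the median dispersal distance and `q = 0.95` the
#' 95th-percentile (tail) distance. Closed-form inverses are used where the
#' distance law is a standard distribution (e.g. Weibull:
#' `a * (-log(1 - q))^(1/b)`; 2Dt: `a * sqrt((1 - q)^(1/(1 - b)) - 1)`).
#' With `method = "numeric"` the quantile is found by root-bracketing the
#' numerically integrated CDF on `[1e-12, a * 1e6]`, robust to heavy tails.
#'
#' @inheritParams location_density
#' @param q Vector of probabilities strictly between 0 and 1.
#' @param method `"closed"` (default) or `"numeric"`.
#' @return Numeric vector of distances (m).
#' @export
#' @examples
#' distance_quantile(kernel_params("weibull", a = 8.563, b = 1.802), 0.5)
distance_quantile <- function(params, q, method = c("closed", "numeric")) {
  stopifnot_kernel(params)
  method <- match.arg(method)
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    stop("'q' must lie strictly between 0 and 1", call. = FALSE)
  a <- params$a; b <- params$b
  if (method == "closed") {
    out <- switch(params$family,
      negative_exponential = stats::qgamma(q, shape = 2, scale = a),
      gaussian = a * sqrt(-log1p(-q)),
      power_exponential = a * stats::qgamma(q, shape = 2 / b)^(1 / b),
      twoDt = a * sqrt((1 - q)^(1 / (1 - b)) - 1),
      inverse_gaussian = NULL,  # no closed form; fall through to numeric root
      lognormal = stats::qlnorm(q, meanlog = log(a), sdlog = b),
      weibull = a * (-log1p(-q))^(1 / b))
    if (!is.null(out)) return(out)
    return(vapply(q, function(qi) quantile_root(params, qi, "closed"),
                  numeric(1)))
  }
  vapply(q, function(qi) quantile_root(params, qi, "numeric"), numeric(1))
}

quantile_root <- function(params, q, cdf_method) {
  lower <- 1e-12
  g <- function(r) distance_cdf(params, r, method = cdf_method) - q
  # grow the upper bracket geometrically from the scale parameter; gradual
  # doubling keeps the quadrature interval commensurate with the mass, where
  # a single huge interval would let adaptive quadrature miss it entirely
  upper <- max(params$a, 1)
  while (g(upper) < 0 && upper < 1e12) upper <- upper * 2
  stats::uniroot(g, c(lower, upper), tol = 1e-12)$root
}

#' Mean dispersal distance
#'
#' Expectation of the radial dispersal distance. Closed form for the Weibull
#' (`a * gamma(1 + 1/b)`), inverse Gaussian (`a`), negative exponential
#' (`2a`), Gaussian (`a * sqrt(pi)/2`) and log-normal (`a * exp(b^2/2)`)
#' families; numeric integration of `r * k(r)` otherwise. For the 2Dt family
#' the mean is finite only for `b > 3/2`.
#'
#' @inheritParams location_density
#' @return Mean distance (m).
#' @export
distance_mean <- function(params) {
  stopifnot_kernel(params)
  a <- params$a; b <- params$b
  closed <- switch(params$family,
    negative_exponential = 2 * a,
    gaussian = a * sqrt(pi) / 2,
    inverse_gaussian = a,
    lognormal = a * exp(b^2 / 2),
    weibull = a * gamma(1 + 1 / b),
    NULL)
  if (!is.null(closed)) return(closed)
  if (params$family == "twoDt" && b <= 1.5) return(Inf)
  f <- function(r) r * distance_density(params, r)
  stats::integrate(f, 0, params$a, rel.tol = 1e-10)$value +
    stats::integrate(f, params$a, Inf, rel.tol = 1e-10)$value
}
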