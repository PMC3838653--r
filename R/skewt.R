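#' Skew-t distribution parameters
#'
#' Container for the parameters of the (Azzalini-type) skew-t distribution
#' used for within-subject error terms: location \eqn{\xi}, scale
#' \eqn{\omega > 0}, skewness \eqn{\lambda} (any real; \eqn{\lambda = 0}
#' recovers the symmetric Student-t) and degrees of freedom \eqn{\nu > 0}
#' (\eqn{\nu \to \infty} recovers the skew-normal).
#'
#' @param omega scale (> 0), in outcome units (mmHg for blood pressure).
#' @param lambda skewness parameter (dimensionless).
#' @param nu degrees of freedom (> 0).
#' @param xi location, in outcome units.  Defaults to 0, the residual-error
#'   convention: the regression intercept absorbs the skew-induced mean shift.
#' @return An object of class \code{"skewt_params"}.
#' @examples
#' p <- skewt_params(omega = sqrt(5.65), lambda = 1.14, nu = 7.5)
#' skewt_delta(p)
#' @export
skewt_params <- function(omega, lambda = 0, nu = 30, xi = 0) {
  for (nm in c("omega", "lambda", "nu", "xi")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (omega <= 0) stop("`omega` must be > 0", call. = FALSE)
  if (nu <= 0) stop("`nu` must be > 0", call. = FALSE)
  structure(list(xi = xi, omega = omega, lambda = lambda, nu = nu),
            class = "skewt_params")
}

#' @export
print.skewt_params <- function(x, ...) {
  cat(sprintf("skew-t(xi = %g, omega = %g, lambda = %g, nu = %g)\n",
              x$xi, x$omega, x$lambda, x$nu))
  invisible(x)
}

#' Skewness-to-delta reparameterization
#'
#' Returns \eqn{\delta = \lambda / \sqrt{1 + \lambda^2} \in (-1, 1)}, the
#' slope of the latent half-normal component in the stochastic
#' representation.
#'
#' @param params a \code{skewt_params} object.
#' @return A number in (-1, 1).
#' @export
skewt_delta <- function(params) {
  stopifnot(inherits(params, "skewt_params"))
  params$lambda / sqrt(1 + params$lambda^2)
}

#' Skew-t density
#'
#' Density of the skew-t distribution,
#' \deqn{f(z) = \frac{2}{\omega}\, t_\nu(x)\,
#'   T_{\nu+1}\!\left(\lambda x \sqrt{\frac{\nu + 1}{\nu + x^2}}\right),
#'   \qquad x = (z - \xi)/\omega,}
#' with \eqn{t_\nu} the standard Student-t density and \eqn{T_{\nu+1}} the
#' Student-t distribution function.
#'
#' @param x vector of quantiles (finite).
#' @param params a \code{skewt_params} object.
#' @param log logical; return the log-density?
#' @return Numeric vector of (log-)density values.
#' @export
dskewt <- function(x, params, log = FALSE) {
  stopifnot(inherits(params, "skewt_params"))
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("`x` must be finite numeric", call. = FALSE)
  z <- (x - params$xi) / params$omega
  nu <- params$nu
  ld <- base::log(2) - base::log(params$omega) +
    stats::dt(z, df = nu, log = TRUE) +
    stats::pt(params$lambda * z * sqrt((nu + 1) / (nu + z^2)),
              df = nu + 1, log.p = TRUE)
  if (log) ld else exp(ld)
}

#' Skew-t distribution function
#'
#' Numeric CDF obtained by trapezoidal integration of \code{\link{dskewt}}
#' on a tail-adaptive grid (grid nodes placed at Student-t quantiles, so
#' resolution follows the probability mass).  Intended for goodness-of-fit
#' work; accuracy is ample for Kolmogorov-Smirnov comparisons at
#' \eqn{n \le 10^6}.
#'
#' @param q vector of quantiles.
#' @param params a \code{skewt_params} object.
#' @param n_grid number of integration nodes.
#' @return Vector of cumulative probabilities.
#' @export
pskewt <- function(q, params, n_grid = 50001L) {
  stopifnot(inherits(params, "skewt_params"))
  pr <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  # widen by a skewness-robust factor so the support of the skewed density
  # is covered even when |lambda| is large
  grid <- params$xi + params$omega * stats::qt(pr, df = params$nu) *
    (1 + abs(params$lambda))
  f <- dskewt(grid, params)
  inc <- diff(grid) * (f[-1L] + f[-n_grid]) / 2
  cdf <- c(0, cumsum(inc))
  fn <- stats::approxfun(grid, pmin(cdf, 1), yleft = 0, yright = 1)
  fn(q)
}

#' Skew-t random variates
#'
#' Draws from the skew-t distribution via its stochastic representation
#' \deqn{Z = \xi + \omega\,\frac{\delta |T_0| + \sqrt{1-\delta^2}\, T_1}
#'   {\sqrt{W/\nu}},}
#' with \eqn{T_0, T_1} independent standard normal and
#' \eqn{W \sim \chi^2_\nu}.
#'
#' @param n number of draws (>= 1).
#' @param params a \code{skewt_params} object.
#' @param seed optional integer; if supplied, \code{set.seed} is called
#'   first so the draw is reproducible.
#' @return Numeric vector of length \code{n}.
#' @export
rskewt <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "skewt_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- skewt_delta(params)
  t0 <- abs(stats::rnorm(n))
  t1 <- stats::rnorm(n)
  w <- stats::rchisq(n, df = params$nu) / params$nu
  params$xi + params$omega * (d * t0 + sqrt(1 - d^2) * t1) / sqrt(w)
}

#' Closed-form skew-t moments
#'
#' Mean and variance of the skew-t distribution.  With
#' \eqn{b_\nu = \sqrt{\nu/\pi}\,\Gamma((\nu-1)/2)/\Gamma(\nu/2)} and
#' \eqn{\delta = \lambda/\sqrt{1+\lambda^2}}:
#' mean \eqn{\xi + \omega \delta b_\nu} (requires \eqn{\nu > 1}) and
#' variance \eqn{\omega^2(\nu/(\nu-2) - \delta^2 b_\nu^2)} (requires
#' \eqn{\nu > 2}).
#'
#' @param params a \code{skewt_params} object.
#' @param which which moments to compute; the default computes both.
#' @return List with elements \code{mean} and \code{variance} (the latter
#'   \code{NULL} when not requested).
#' @export
skewt_moments <- function(params, which = c("both", "mean")) {
  stopifnot(inherits(params, "skewt_params"))
  which <- match.arg(which)
  nu <- params$nu
  if (nu <= 1)
    stop("moment undefined: mean requires nu > 1", call. = FALSE)
  b_nu <- sqrt(nu / pi) * exp(lgamma((nu - 1) / 2) - lgamma(nu / 2))
  d <- skewt_delta(params)
  m <- params$xi + params$omega * d * b_nu
  if (which == "mean") return(list(mean = m, variance = NULL))
  if (nu <= 2)
    stop("moment undefined: variance requires nu > 2", call. = FALSE)
  v <- params$omega^2 * (nu / (nu - 2) - d^2 * b_nu^2)
  list(mean = m, variance = v)
}
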