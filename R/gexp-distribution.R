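#' The generalised exponential distribution
#'
#' Density, distribution function, survival function, quantile function and
#' random generation for the two-parameter generalised (exponentiated)
#' exponential distribution with scale \code{theta} and shape \code{p},
#' \deqn{F(t) = (1 - e^{-\theta t})^p, \qquad t > 0,}
#' \deqn{f(t) = p\theta (1 - e^{-\theta t})^{p-1} e^{-\theta t}.}
#' The family reduces to the exponential distribution with rate \code{theta}
#' when \code{p = 1}; \code{theta} is in inverse-time units and \code{p} is
#' dimensionless.  Random generation uses the inverse-CDF transform
#' \eqn{T = -\log(1 - U^{1/p})/\theta} with \eqn{U \sim U(0,1)}.
#'
#' All functions are evaluated on the log scale internally so that
#' \eqn{(1 - e^{-\theta t})^p} does not underflow for large \eqn{\theta t}.
#'
#' @param x,q vector of non-negative quantiles.
#' @param u vector of probabilities in \eqn{[0, 1)}.
#' @param n number of draws.
#' @param theta positive scale parameter (inverse-time units).
#' @param p positive shape parameter.
#' @param log,log.p logical; return log-density / log-probability.
#' @param lower.tail logical; if \code{FALSE}, probabilities are
#'   \eqn{P(T > t)}.
#'
#' @return \code{dgexp} the density, \code{pgexp} the distribution function,
#'   \code{sgexp} the survival function, \code{qgexp} the quantile function,
#'   \code{rgexp} random deviates.
#'
#' @examples
#' pgexp(log(2), theta = 1, p = 1)        # 0.5: exponential median
#' qgexp(0.25, theta = 1, p = 2)          # log(2)
#' hist(rgexp(500, theta = 1, p = 2), breaks = 30)
#' @name gexp
NULL

#' @rdname gexp
#' @export
dgexp <- function(x, theta = 1, p = 1, log = FALSE) {
  check_params(theta, p)
  stopifnot(all(is.finite(x)))
  if (any(x <= 0)) stop("'x' must be strictly positive for density evaluation")
  xt <- theta * x
  ld <- base::log(p) + base::log(theta) + (p - 1) * log1mexp(xt) - xt
  if (log) ld else exp(ld)
}

#' @rdname gexp
#' @export
pgexp <- function(q, theta = 1, p = 1, lower.tail = TRUE, log.p = FALSE) {
  check_params(theta, p)
  stopifnot(all(is.finite(q)))
  if (any(q < 0)) stop("'q' must be non-negative")
  lF <- p * log1mexp(theta * q)              # log F, -Inf at q = 0
  lF[q == 0] <- -Inf
  if (lower.tail) {
    if (log.p) lF else exp(lF)
  } else {
    lS <- log1mexp(-lF)                      # log(1 - F)
    if (log.p) lS else exp(lS)
  }
}

#' @rdname gexp
#' @export
sgexp <- function(q, theta = 1, p = 1, log.p = FALSE) {
  pgexp(q, theta, p, lower.tail = FALSE, log.p = log.p)
}

#' @rdname gexp
#' @export
qgexp <- function(u, theta = 1, p = 1) {
  check_params(theta, p)
  stopifnot(all(is.finite(u)))
  if (any(u < 0 | u >= 1)) stop("'u' must lie in [0, 1)")
  # -log(1 - u^(1/p)) / theta, stable for u near 0 and 1
  -log1p(-exp(base::log(u) / p)) / theta
}

#' @rdname gexp
#' @export
rgexp <- function(n, theta = 1, p = 1) {
  check_params(theta, p)
  qgexp(stats::runif(n), theta, p)
}

# log(1 - exp(-a)) for a > 0, without catastrophic cancellation
log1mexp <- function(a) {
  out <- a
  small <- a <= base::log(2)
  out[small] <- base::log(-expm1(-a[small]))
  out[!small] <- log1p(-exp(-a[!small]))
  out[a == 0] <- -Inf
  out
}

check_params <- function(theta, p) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
    stop("'theta' must be a single positive finite number")
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0)
    stop("'p' must be a single positive finite number")
  invisible(TRUE)
}
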