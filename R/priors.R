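#' Gamma priors for the generalised exponential parameters
#'
#' Independent gamma priors \eqn{\pi_1(\theta) \propto \theta^{b-1}e^{-a\theta}}
#' and \eqn{\pi_2(p) \propto p^{d-1}e^{-cp}}.  Note the naming: \code{a} and
#' \code{c} multiply the parameter (gamma \emph{rates}), while \code{b} and
#' \code{d} enter as exponent + 1 (gamma \emph{shapes}) — conventions for
#' gamma hyperparameters vary, so check twice when eliciting.
#'
#' The all-zero setting \code{gexp_priors(0, 0, 0, 0)} is permitted and gives
#' the improper prior \eqn{\propto 1/(\theta p)}; the returned object carries
#' an \code{improper} flag (a gamma prior is proper only when both its rate
#' and shape are positive).  Posterior propriety under improper priors is an
#' empirical matter checked by the quadrature oracle, not assumed.
#'
#' @param a,b rate and shape hyperparameters for the scale \eqn{\theta}
#'   (non-negative).
#' @param c,d rate and shape hyperparameters for the shape \eqn{p}
#'   (non-negative).
#' @return An object of class \code{"gexp_priors"}.
#' @examples
#' gexp_priors()            # improper 1/(theta p), the noninformative default
#' gexp_priors(2, 3, 1, 1)
#' @export
gexp_priors <- function(a = 0, b = 0, c = 0, d = 0) {
  hp <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(hp)) || any(hp < 0))
    stop("hyperparameters must be finite and non-negative")
  structure(list(a = a, b = b, c = c, d = d,
                 improper = !(a > 0 && b > 0 && c > 0 && d > 0)),
            class = "gexp_priors")
}

#' @export
print.gexp_priors <- function(x, ...) {
  cat(sprintf("Gamma priors: theta ~ Gamma(shape = %g, rate = %g), p ~ Gamma(shape = %g, rate = %g)%s\n",
              x$b, x$a, x$d, x$c,
              if (x$improper) "  [improper]" else ""))
  invisible(x)
}

#' Log prior density and its derivatives
#'
#' \code{log_prior} returns \eqn{(b-1)\log\theta - a\theta + (d-1)\log p - cp}
#' (up to an additive constant); \code{log_prior_grad} returns the gradient
#' \eqn{\rho = ((b-1)/\theta - a,\; (d-1)/p - c)} used by the Lindley
#' expansion.
#'
#' @param priors a [gexp_priors()] object.
#' @param theta,p positive parameter values.
#' @return A scalar (\code{log_prior}) or a named length-2 vector
#'   (\code{log_prior_grad}).
#' @export
log_prior <- function(priors, theta, p) {
  stopifnot(inherits(priors, "gexp_priors"))
  check_params(theta, p)
  (priors$b - 1) * base::log(theta) - priors$a * theta +
    (priors$d - 1) * base::log(p) - priors$c * p
}

#' @rdname log_prior
#' @export
log_prior_grad <- function(priors, theta, p) {
  stopifnot(inherits(priors, "gexp_priors"))
  check_params(theta, p)
  c(theta = (priors$b - 1) / theta - priors$a,
    p     = (priors$d - 1) / p - priors$c)
}

# Hessian of the log prior (diagonal)
log_prior_hess <- function(priors, theta, p) {
  diag(c(-(priors$b - 1) / theta^2, -(priors$d - 1) / p^2), 2, 2)
}

#' LINEX point estimate from a posterior expectation
#'
#' Under the asymmetric LINEX loss \eqn{e^{k\Delta} - k\Delta - 1} the Bayes
#' estimator of a parameter \eqn{\alpha} is
#' \eqn{-\frac{1}{k}\log E[e^{-k\alpha}]}; \code{k > 0} penalises
#' overestimation more than underestimation.
#'
#' @param expectation the posterior expectation \eqn{E[e^{-k\alpha}]}
#'   (strictly positive).
#' @param k nonzero LINEX loss parameter.
#' @return The LINEX point estimate.
#' @export
linex_point <- function(expectation, k) {
  if (!is.finite(k) || k == 0) stop("'k' must be a nonzero finite number")
  if (!is.finite(expectation) || expectation <= 0)
    stop("approximated expectation of exp(-k alpha) is not positive; ",
         "the approximation is invalid here")
  -base::log(expectation) / k
}

# --- estimand transforms -----------------------------------------------------
#
# A transform bundles u(theta, p) with its first and second partials, as needed
# by the Lindley expansion, and the log of u, as needed by Tierney-Kadane
# (only for positive estimands). Cross second partials are zero for every
# estimand used here.

#' Estimand transforms for the posterior approximations
#'
#' Constructs the scalar function of \eqn{(\theta, p)} whose posterior
#' expectation is approximated, together with its first/second partial
#' derivatives (used by [lindley_expectation()]) and its logarithm with
#' derivatives (used by [tk_expectation()], which requires positivity).
#'
#' Kinds: \code{"identity"} (\eqn{u=\theta} or \eqn{u=p}; squared-error
#' loss), \code{"square"} (\eqn{u=\theta^2} or \eqn{p^2}; second moments for
#' posterior SDs), \code{"linex"} (\eqn{u=e^{-k\theta}} or \eqn{e^{-kp}}),
#' and \code{"product"} (\eqn{u=\theta p}; the joint-surface variant).
#'
#' @param kind one of \code{"identity"}, \code{"square"}, \code{"linex"},
#'   \code{"product"}.
#' @param param \code{"theta"} or \code{"p"} (ignored for \code{"product"}).
#' @param k LINEX loss parameter (required, nonzero, for \code{"linex"}).
#' @return An object of class \code{"gexp_transform"}: a list of functions
#'   \code{u(theta, p)}, \code{grad}, \code{hess}, \code{logu},
#'   \code{logu_grad}, \code{logu_hess}.
#' @export
gexp_transform <- function(kind = c("identity", "square", "linex", "product"),
                           param = c("theta", "p"), k = NULL) {
  kind <- match.arg(kind)
  param <- match.arg(param)
  i <- if (param == "theta") 1L else 2L
  e <- function(v) { z <- c(0, 0); z[i] <- v; z }
  E <- function(v) { m <- matrix(0, 2, 2); m[i, i] <- v; m }
  tr <- switch(kind,
    identity = list(
      u    = function(theta, p) if (i == 1L) theta else p,
      grad = function(theta, p) e(1),
      hess = function(theta, p) E(0),
      logu = function(theta, p) base::log(if (i == 1L) theta else p),
      logu_grad = function(theta, p) e(1 / (if (i == 1L) theta else p)),
      logu_hess = function(theta, p) E(-1 / (if (i == 1L) theta else p)^2)),
    square = list(
      u    = function(theta, p) (if (i == 1L) theta else p)^2,
      grad = function(theta, p) e(2 * (if (i == 1L) theta else p)),
      hess = function(theta, p) E(2),
      logu = function(theta, p) 2 * base::log(if (i == 1L) theta else p),
      logu_grad = function(theta, p) e(2 / (if (i == 1L) theta else p)),
      logu_hess = function(theta, p) E(-2 / (if (i == 1L) theta else p)^2)),
    linex = {
      if (is.null(k) || !is.finite(k) || k == 0)
        stop("LINEX transform requires a nonzero 'k'")
      list(
        u    = function(theta, p) exp(-k * (if (i == 1L) theta else p)),
        grad = function(theta, p) e(-k * exp(-k * (if (i == 1L) theta else p))),
        hess = function(theta, p) E(k^2 * exp(-k * (if (i == 1L) theta else p))),
        logu = function(theta, p) -k * (if (i == 1L) theta else p),
        logu_grad = function(theta, p) e(-k),
        logu_hess = function(theta, p) E(0))
    },
    product = list(
      u    = function(theta, p) theta * p,
      grad = function(theta, p) c(p, theta),
      hess = function(theta, p) matrix(c(0, 1, 1, 0), 2, 2),
      logu = function(theta, p) base::log(theta) + base::log(p),
      logu_grad = function(theta, p) c(1 / theta, 1 / p),
      logu_hess = function(theta, p) diag(c(-1 / theta^2, -1 / p^2), 2, 2)))
  structure(c(tr, list(kind = kind, param = param, k = k)),
            class = "gexp_transform")
}
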