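#' Fit the generalised exponential model to randomly censored data
#'
#' One front-end for all five estimators compared in the package: maximum
#' likelihood (\code{"ml"}), and approximate-Bayes estimation under gamma
#' priors via Lindley's expansion (\code{"lindley"}) or the Tierney-Kadane
#' Laplace ratio (\code{"tk"}), each under squared-error (\code{"sel"}) or
#' asymmetric LINEX (\code{"linex"}) loss.
#'
#' Maximum likelihood reports observed-information standard errors and Wald
#' intervals.  The Bayes methods report posterior means (SEL) or LINEX point
#' estimates \eqn{-\frac1k \log E[e^{-k\alpha}]}, posterior SDs obtained by
#' applying the same approximation to the second moments, and normal-form
#' credible intervals (estimate plus/minus a normal quantile times the
#' posterior SD).
#'
#' @param time observed times, or a \code{survival::Surv} object, or a
#'   data frame with \code{time} and \code{status} columns.
#' @param status event indicators (1 = failure, 0 = censored); ignored when
#'   \code{time} already carries them.
#' @param method \code{"ml"}, \code{"lindley"} or \code{"tk"}.
#' @param loss \code{"sel"} or \code{"linex"} (Bayes methods only).
#' @param k nonzero LINEX loss parameter; \code{k > 0} penalises
#'   overestimation more.  Default 0.7.
#' @param priors a [gexp_priors()] object; the default all-zero setting is
#'   the improper noninformative prior \eqn{1/(\theta p)}.
#' @param level confidence / credible level for intervals.
#' @param init optional \code{c(theta, p)} starting values for the ML search
#'   (by default a censored-exponential start with a small shape multistart).
#' @return An object of class \code{"gexp_fit"} with components
#'   \code{coefficients} (named vector \code{theta}, \code{p}), \code{se},
#'   \code{vcov} (ML only), \code{interval}, \code{level}, \code{method},
#'   \code{loss}, \code{k}, \code{priors}, \code{loglik}, \code{converged},
#'   \code{iterations}, \code{n}, \code{events} and the data.  Supports
#'   \code{print}, \code{summary}, \code{coef}, \code{vcov}, \code{confint}
#'   and \code{logLik}.
#' @examples
#' d <- gexp_cancer_data("breast")
#' fit <- gexp_fit(d$time, d$status)
#' coef(fit)
#' confint(fit)
#' gexp_fit(d$time, d$status, method = "tk", loss = "linex", k = 0.7)
#' @export
gexp_fit <- function(time, status = NULL,
                     method = c("ml", "lindley", "tk"),
                     loss = c("sel", "linex"), k = 0.7,
                     priors = gexp_priors(), level = 0.95, init = NULL) {
  method <- match.arg(method)
  loss <- match.arg(loss)
  cl <- match.call()

  if (inherits(time, "Surv")) {
    m <- unclass(time)
    status <- m[, "status"]
    time <- m[, "time"]
  } else if (is.data.frame(time)) {
    if (!all(c("time", "status") %in% names(time)))
      stop("data frame input must have 'time' and 'status' columns")
    status <- time$status
    time <- time$time
  }
  check_sample(time, status)
  if (loss == "linex" && (!is.numeric(k) || length(k) != 1L ||
                          !is.finite(k) || k == 0))
    stop("LINEX loss requires a nonzero finite 'k'")
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must lie strictly between 0 and 1")

  if (method == "ml") {
    fit <- ml_core(time, status, init = init)
    seinfo <- ml_se(fit$hessian)
    est <- c(theta = fit$theta, p = fit$p)
    out <- list(coefficients = est, se = seinfo$se, vcov = seinfo$vcov,
                interval = wald_interval(est, seinfo$se, level),
                converged = fit$converged, iterations = fit$iterations,
                loglik = fit$loglik)
    label <- "ML"
  } else {
    fitfun <- if (method == "lindley") fit_lindley else fit_tk
    fit <- fitfun(time, status, priors, loss, k, level)
    out <- list(coefficients = fit$estimate, se = fit$sd, vcov = NULL,
                interval = fit$interval,
                converged = fit$converged, iterations = fit$iterations,
                loglik = gexp_loglik(fit$estimate[1], fit$estimate[2],
                                     time, status))
    label <- paste0(if (method == "lindley") "Lindley-" else "TK-",
                    if (loss == "sel") "SEL" else sprintf("LINEX(k=%g)", k))
  }

  structure(c(out, list(
    method = method, label = label, loss = if (method == "ml") NULL else loss,
    k = if (method != "ml" && loss == "linex") k else NULL,
    priors = if (method == "ml") NULL else priors,
    level = level, n = length(time), events = sum(status),
    time = time, status = status, call = cl)), class = "gexp_fit")
}

#' @export
print.gexp_fit <- function(x, digits = 6, ...) {
  cat(sprintf("Generalised exponential fit (%s), n = %d, events = %d\n",
              x$label, x$n, x$events))
  tab <- cbind(estimate = x$coefficients, se = x$se)
  print(round(tab, digits))
  if (!x$converged) cat("Warning: estimator did not converge\n")
  invisible(x)
}

#' @export
summary.gexp_fit <- function(object, ...) {
  tab <- cbind(estimate = unname(object$coefficients),
               se = unname(object$se), object$interval)
  dimnames(tab) <- list(c("theta", "p"),
                        c("estimate", "se",
                          sprintf("%s %g%%", c("lower", "upper"),
                                  100 * object$level)))
  structure(list(fit = object, table = tab), class = "summary.gexp_fit")
}

#' @export
print.summary.gexp_fit <- function(x, digits = 6, ...) {
  f <- x$fit
  cat(sprintf("Generalised exponential distribution, random right censoring\n"))
  cat(sprintf("Estimator: %s    n = %d, events = %d, censored = %d\n",
              f$label, f$n, f$events, f$n - f$events))
  if (!is.null(f$priors)) print(f$priors)
  print(round(x$table, digits))
  cat(sprintf("log-likelihood at the point estimate: %.4f\n", f$loglik))
  invisible(x)
}

#' @export
coef.gexp_fit <- function(object, ...) object$coefficients

#' @export
vcov.gexp_fit <- function(object, ...) {
  if (is.null(object$vcov))
    stop("a full covariance matrix is only available for method = 'ml'")
  object$vcov
}

#' @export
logLik.gexp_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' @export
confint.gexp_fit <- function(object, parm = c("theta", "p"), level = NULL,
                             ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  lv <- if (is.null(level)) object$level else level
  ci <- wald_interval(object$coefficients, object$se, lv)
  ci[parm, , drop = FALSE]
}
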