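# Lindley's asymptotic expansion of posterior expectations.
#
# The expansion point is the MLE (the sigma matrix in the expansion is built
# from the log-likelihood Hessian alone, which is the MLE-centred variant of
# the method), and the full two-parameter form is used: all index
# combinations of the third-derivative term are summed, with sigma the
# complete negative-inverse Hessian (not only its diagonal).

#' Lindley approximation to a posterior expectation
#'
#' Approximates \eqn{E[u(\theta, p) \mid data]} under gamma priors by
#' Lindley's expansion about the maximum-likelihood estimate:
#' \deqn{E[u] \approx u + \tfrac12 \sum_{ij} (u_{ij} + 2 u_i \rho_j)
#'   \sigma_{ij} + \tfrac12 \sum_{ijkl} \ell_{ijk} \sigma_{ij} \sigma_{kl}
#'   u_l,}
#' with all quantities evaluated at the MLE: \eqn{u_i, u_{ij}} the estimand
#' derivatives, \eqn{\rho} the log-prior gradient, \eqn{\ell_{ijk}} the third
#' log-likelihood derivatives and \eqn{\sigma = (-\ell'')^{-1}} the
#' negative-inverse Hessian.  The error is \eqn{O(1/n)} relative to the
#' exact posterior expectation.
#'
#' With \code{fixed_p} the shape is held fixed and the one-parameter version
#' of the expansion is applied to \eqn{\theta} alone (the censored-exponential
#' sub-model when \code{fixed_p = 1}), which has a conjugate closed form
#' useful for validation.
#'
#' @inheritParams gexp_loglik
#' @param priors a [gexp_priors()] object.
#' @param transform a [gexp_transform()] object defining the estimand.
#' @param fixed_p optionally hold the shape fixed at this value.
#' @return The approximate posterior expectation (a scalar).
#' @seealso [gexp_fit()] with \code{method = "lindley"};
#'   [posterior_expectation_quad()] for the quadrature oracle.
#' @export
lindley_expectation <- function(time, status, priors, transform,
                                fixed_p = NULL) {
  stopifnot(inherits(priors, "gexp_priors"),
            inherits(transform, "gexp_transform"))
  ws <- lindley_workspace(time, status, priors, fixed_p)
  lindley_apply(ws, transform)
}

# everything that does not depend on the estimand, computed once
lindley_workspace <- function(time, status, priors, fixed_p = NULL) {
  if (is.null(fixed_p)) {
    fit <- ml_core(time, status)
    idx <- 1:2
  } else {
    check_params(1, fixed_p)
    fit <- ml_core_fixed_p(time, status, fixed_p)
    idx <- 1L
  }
  th <- fit$theta; p <- fit$p
  D <- gexp_loglik_deriv(th, p, time, status, order = 3)
  H <- D$hessian[idx, idx, drop = FALSE]
  sigma <- neg_inv(H)
  if (is.null(sigma))
    stop("Hessian at the MLE is not negative definite; ",
         "the Lindley expansion is invalid here")
  list(theta = th, p = p, idx = idx, sigma = sigma,
       rho = log_prior_grad(priors, th, p)[idx],
       third = D$third, fit = fit)
}

lindley_apply <- function(ws, transform) {
  idx <- ws$idx
  th <- ws$theta; p <- ws$p
  u0 <- transform$u(th, p)
  U1 <- transform$grad(th, p)[idx]
  U2 <- transform$hess(th, p)[idx, idx, drop = FALSE]
  L <- ws$third[idx, idx, idx, drop = FALSE]
  sigma <- ws$sigma
  term2 <- 0.5 * sum((U2 + 2 * outer(U1, ws$rho)) * sigma)
  # s3[k] = sum_ij l_ijk sigma_ij, then 0.5 * s3' sigma U1
  s3 <- vapply(seq_along(idx),
               function(k) sum(L[, , k] * sigma), numeric(1))
  term3 <- 0.5 * drop(s3 %*% sigma %*% U1)
  unname(u0 + term2 + term3)
}

# profile ML for theta with the shape held fixed
ml_core_fixed_p <- function(time, status, p_fix) {
  d <- sum(status)
  if (d < 1) stop("estimation requires at least one observed event")
  nll <- function(s) {
    v <- tryCatch(gexp_loglik(exp(s), p_fix, time, status),
                  error = function(e) -Inf)
    if (!is.finite(v)) 1e300 else -v
  }
  o <- stats::optim(base::log(max(d, 1) / sum(time)), nll, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-14))
  th <- exp(o$par)
  for (it in 1:30) {
    D <- gexp_loglik_deriv(th, p_fix, time, status, order = 2)
    g <- D$gradient[1]; h <- D$hessian[1, 1]
    if (abs(g) < 1e-10 || h >= 0) break
    step <- g / h
    cand <- th - step
    while (cand <= 0) { step <- step / 2; cand <- th - step }
    th <- cand
  }
  list(theta = unname(th), p = p_fix,
       loglik = gexp_loglik(th, p_fix, time, status),
       converged = TRUE, iterations = o$counts[["function"]] + it)
}

# negative-inverse of a Hessian, NULL unless -H is positive definite
neg_inv <- function(H) {
  ch <- tryCatch(chol(-H), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  chol2inv(ch)
}

# Lindley fit: point estimates, posterior SDs (second-moment convention) and
# normal-form intervals, under SEL or LINEX loss.
fit_lindley <- function(time, status, priors, loss, k, level) {
  ws <- lindley_workspace(time, status, priors)
  m1 <- c(theta = lindley_apply(ws, gexp_transform("identity", "theta")),
          p     = lindley_apply(ws, gexp_transform("identity", "p")))
  m2 <- c(lindley_apply(ws, gexp_transform("square", "theta")),
          lindley_apply(ws, gexp_transform("square", "p")))
  vr <- m2 - m1^2
  if (any(!is.finite(vr) | vr <= 0)) {
    warning("second-moment expansion gave a non-positive posterior variance; ",
            "posterior SDs reported as NA")
    sd <- c(theta = NA_real_, p = NA_real_)
  } else sd <- sqrt(vr)

  if (loss == "sel") {
    est <- m1
  } else {
    est <- c(
      theta = linex_point(
        lindley_apply(ws, gexp_transform("linex", "theta", k = k)), k),
      p = linex_point(
        lindley_apply(ws, gexp_transform("linex", "p", k = k)), k))
  }
  list(estimate = est, sd = sd,
       interval = wald_interval(est, sd, level),
       converged = ws$fit$converged, iterations = ws$fit$iterations,
       ml = ws$fit)
}
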