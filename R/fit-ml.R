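# Maximum-likelihood machinery.
#
# Optimisation runs on the log-parameter scale (log theta, log p), which
# enforces positivity without constraints; the analytic gradient is supplied
# through the chain rule.  The optimum is then polished by safeguarded Newton
# steps on the natural scale so the score really is below tolerance, and the
# observed (not expected) information at the optimum gives the covariance --
# the expected information under random censoring would require the unknown
# censoring law.

ml_control <- function(grad_tol = 1e-8, max_iter = 500L,
                       start_shapes = c(0.5, 1, 2)) {
  list(grad_tol = grad_tol, max_iter = max_iter, start_shapes = start_shapes)
}

# Maximise gexp_loglik; returns theta, p, loglik, gradient, hessian,
# converged, iterations.  `init` optionally c(theta, p).
ml_core <- function(time, status, init = NULL, control = ml_control()) {
  check_sample(time, status)
  d <- sum(status)
  if (d < 1) stop("estimation requires at least one observed event")

  negll <- function(s) {
    v <- tryCatch(gexp_loglik(exp(s[1]), exp(s[2]), time, status),
                  error = function(e) -Inf)
    if (!is.finite(v)) return(1e300)
    -v
  }
  neggr <- function(s) {
    th <- exp(s[1]); p <- exp(s[2])
    g <- tryCatch(gexp_loglik_deriv(th, p, time, status, order = 1)$gradient,
                  error = function(e) c(0, 0))
    if (any(!is.finite(g))) return(c(0, 0))
    -g * c(th, p)                       # chain rule onto the log scale
  }

  theta0 <- max(d, 1) / sum(time)
  starts <- if (is.null(init)) {
    lapply(control$start_shapes, function(p0) c(base::log(theta0), base::log(p0)))
  } else {
    list(base::log(init))
  }

  # each start is optimised and Newton-polished; the search stops at the
  # first start whose polished optimum has score below tolerance (the
  # likelihood surface is unimodal in practice), keeping the best otherwise
  best <- NULL
  iters <- 0L
  for (s0 in starts) {
    o <- tryCatch(
      stats::optim(s0, negll, neggr, method = "BFGS",
                   control = list(maxit = control$max_iter, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(o)) next
    iters <- iters + o$counts[["function"]]
    est <- exp(o$par)
    # Newton polish on the natural scale with step halving
    for (it in seq_len(30L)) {
      db <- gexp_loglik_deriv(est[1], est[2], time, status, order = 2)
      if (max(abs(db$gradient)) < control$grad_tol) break
      step <- tryCatch(solve(db$hessian, db$gradient), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      cand <- est - step
      half <- 0L
      while ((any(cand <= 0) ||
              !is.finite(ll <- gexp_loglik(cand[1], cand[2], time, status)) ||
              ll < db$loglik) && half < 20L) {
        step <- step / 2
        cand <- est - step
        half <- half + 1L
      }
      if (any(cand <= 0)) break
      est <- cand
      iters <- iters + 1L
    }
    db <- gexp_loglik_deriv(est[1], est[2], time, status, order = 2)
    if (is.null(best) || db$loglik > best$loglik)
      best <- list(est = est, db = db)
    if (max(abs(db$gradient)) < control$grad_tol) break
  }
  if (is.null(best)) stop("all optimiser starts failed")

  est <- best$est
  db <- best$db
  list(theta = unname(est[1]), p = unname(est[2]), loglik = db$loglik,
       gradient = db$gradient, hessian = db$hessian,
       converged = max(abs(db$gradient)) < max(control$grad_tol, 1e-6),
       iterations = iters)
}

# observed-information standard errors from the Hessian at the optimum
ml_se <- function(hessian) {
  v <- tryCatch(solve(-hessian), error = function(e) NULL)
  if (is.null(v) || any(diag(v) <= 0))
    return(list(vcov = NULL, se = c(theta = NA_real_, p = NA_real_)))
  list(vcov = v, se = sqrt(diag(v)))
}

wald_interval <- function(estimate, se, level) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must lie strictly between 0 and 1")
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(lower = estimate - z * se, upper = estimate + z * se)
}
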