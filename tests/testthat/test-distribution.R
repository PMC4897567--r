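test_that("distribution functions reduce to the exponential at p = 1", {
  tt <- c(0.05, 0.3, 0.7, 1.5, 4, 12)
  for (theta in c(0.4, 1, 2.7)) {
    expect_equal(pgexp(tt, theta, 1), stats::pexp(tt, theta), tolerance = 1e-12)
    expect_equal(dgexp(tt, theta, 1), stats::dexp(tt, theta), tolerance = 1e-12)
    expect_equal(qgexp(c(0, 0.2, 0.5, 0.9), theta, 1),
                 stats::qexp(c(0, 0.2, 0.5, 0.9), theta), tolerance = 1e-12)
  }
  expect_equal(pgexp(log(2), 1, 1), 0.5, tolerance = 1e-12)
  expect_equal(dgexp(1, 1, 1), exp(-1), tolerance = 1e-12)
})

test_that("cdf boundary, monotonicity and complementarity hold", {
  expect_identical(pgexp(0, 2, 3), 0)
  expect_identical(sgexp(0, 2, 3), 1)
  expect_equal(pgexp(log(2), 1, 2), 0.25, tolerance = 1e-12)
  grid <- seq(0, 20, length.out = 200)
  for (p in c(0.3, 1, 4)) {
    F <- pgexp(grid, 1.3, p)
    expect_true(all(diff(F) >= 0))
    expect_true(all(F >= 0 & F <= 1))
  }
  set.seed(5)
  t <- rexp(100, 0.5)
  expect_equal(pgexp(t, 0.8, 2.5) + sgexp(t, 0.8, 2.5), rep(1, 100),
               tolerance = 1e-12)
  expect_error(pgexp(-1, 1, 1), "non-negative")
  expect_error(dgexp(0, 1, 1), "positive")
  expect_error(dgexp(NA_real_, 1, 1))
  expect_error(pgexp(1, -1, 1), "theta")
})

test_that("density differentiates the cdf and integrates to one", {
  h <- 1e-6
  fd <- (pgexp(0.7 + h, 1.3, 2.4) - pgexp(0.7 - h, 1.3, 2.4)) / (2 * h)
  expect_equal(dgexp(0.7, 1.3, 2.4), fd, tolerance = 1e-6)
  q <- stats::integrate(function(t) dgexp(t, 2, 0.8), 0, Inf,
                        rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-8)
})

test_that("quantile function inverts the cdf", {
  expect_equal(qgexp(0.5, 1, 1), log(2), tolerance = 1e-12)
  expect_identical(qgexp(0, 3, 2), 0)
  expect_equal(qgexp(0.25, 1, 2), log(2), tolerance = 1e-12)
  u <- seq(0, 0.999, length.out = 50)
  for (p in c(0.5, 1, 3.2)) {
    expect_equal(pgexp(qgexp(u, 1.7, p), 1.7, p), u, tolerance = 1e-10)
  }
  expect_error(qgexp(1, 1, 1), "\\[0, 1\\)")
  expect_error(qgexp(-0.1, 1, 1), "\\[0, 1\\)")
})

test_that("censored log-likelihood matches closed forms and a brute-force product", {
  # complete data reduces to the sum of log densities
  set.seed(2)
  t <- rgexp(30, 1.1, 1.8)
  expect_equal(gexp_loglik(1.1, 1.8, t, rep(1, 30)),
               sum(dgexp(t, 1.1, 1.8, log = TRUE)), tolerance = 1e-12)
  # hand evaluation of the exponential closed form on {(1, event), (2, censored)}
  expect_equal(gexp_loglik(0.5, 1, c(1, 2), c(1, 0)),
               log(0.5) - 0.5 - 1, tolerance = 1e-12)
  # term-by-term product oracle on a small random censored sample
  set.seed(3)
  tt <- round(rexp(5, 0.8), 3) + 0.01
  ss <- c(1, 0, 1, 1, 0)
  direct <- prod(dgexp(tt[ss == 1], 0.9, 1.4)) *
    prod(sgexp(tt[ss == 0], 0.9, 1.4))
  expect_equal(gexp_loglik(0.9, 1.4, tt, ss), log(direct), tolerance = 1e-10)
  # events at time zero are rejected; censored zero times are not
  expect_error(gexp_loglik(1, 0.5, c(0, 1), c(1, 1)), "time 0")
  expect_silent(gexp_loglik(1, 0.5, c(0, 1), c(0, 1)))
  expect_error(gexp_loglik(1, 1, c(1, 2), c(1, 2)), "status")
})

test_that("likelihood survives extreme theta*t without underflow", {
  # data-2-like spread: theta*t spanning five orders of magnitude
  t <- c(1e-3, 0.1, 5, 40, 100)
  s <- c(1, 1, 1, 0, 0)
  v <- gexp_loglik(2, 3, t, s)
  expect_true(is.finite(v))
  D <- gexp_loglik_deriv(2, 3, t, s, order = 3)
  expect_true(all(is.finite(D$gradient)))
  expect_true(all(is.finite(D$hessian)))
  expect_true(all(is.finite(D$third)))
  # a censored record beyond double-precision survival support is signalled
  # as a non-finite likelihood, never a silent wrong number
  expect_true(!is.finite(gexp_loglik(2, 3, c(1, 400), c(1, 0))) ||
              gexp_loglik(2, 3, c(1, 400), c(1, 0)) < -700)
})

test_that("analytic derivatives match finite differences of every order", {
  smp <- make_censored_sample(20, theta = 1.3, p = 1.7, seed = 42)
  th <- 1.1; p <- 1.9; h <- 1e-5
  D <- gexp_loglik_deriv(th, p, smp$time, smp$status, order = 3)
  ll <- function(a, b) gexp_loglik(a, b, smp$time, smp$status)
  gr <- function(a, b) gexp_loglik_deriv(a, b, smp$time, smp$status, 1)$gradient
  he <- function(a, b) gexp_loglik_deriv(a, b, smp$time, smp$status, 2)$hessian

  expect_equal(D$loglik, ll(th, p), tolerance = 1e-12)
  fd_g <- c((ll(th + h, p) - ll(th - h, p)), (ll(th, p + h) - ll(th, p - h))) / (2 * h)
  expect_equal(unname(D$gradient), fd_g, tolerance = 1e-6)
  fd_h <- cbind((gr(th + h, p) - gr(th - h, p)), (gr(th, p + h) - gr(th, p - h))) / (2 * h)
  expect_equal(unname(D$hessian), unname(fd_h), tolerance = 1e-5)
  fd_t <- (he(th + h, p) - he(th - h, p)) / (2 * h)
  fd_p <- (he(th, p + h) - he(th, p - h)) / (2 * h)
  expect_equal(D$third[1, 1, 1], fd_t[1, 1], tolerance = 1e-4)
  expect_equal(D$third[1, 1, 2], fd_t[1, 2], tolerance = 1e-4)
  expect_equal(D$third[1, 2, 2], fd_p[1, 2], tolerance = 1e-4)
  expect_equal(D$third[2, 2, 2], fd_p[2, 2], tolerance = 1e-4)
  # stored tensor is exactly symmetric under index permutation
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    expect_identical(D$third[i, j, k], D$third[j, i, k])
    expect_identical(D$third[i, j, k], D$third[k, j, i])
  }
  expect_identical(D$hessian[1, 2], D$hessian[2, 1])
})

test_that("p = 1 score in theta has the exponential closed form", {
  smp <- make_censored_sample(25, theta = 0.7, p = 1, seed = 9)
  for (th in c(0.3, 0.7, 1.5)) {
    g <- gexp_loglik_deriv(th, 1, smp$time, smp$status, 1)$gradient
    expect_equal(unname(g[1]), sum(smp$status) / th - sum(smp$time),
                 tolerance = 1e-10)
  }
})

test_that("time rescaling maps the likelihood surface as theta -> theta/c", {
  smp <- make_censored_sample(30, theta = 1, p = 2, seed = 7)
  for (c in c(0.2, 3, 40)) {
    expect_equal(gexp_loglik(1.2, 1.6, smp$time, smp$status),
                 gexp_loglik(1.2 / c, 1.6, c * smp$time, smp$status) +
                   sum(smp$status) * log(c),   # density Jacobian of t -> ct
                 tolerance = 1e-9)
  }
})
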