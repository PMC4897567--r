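test_that("score vanishes and observed information is positive definite at the MLE", {
  datasets <- list(gexp_cancer_data("cervical"), gexp_cancer_data("breast"),
                   make_censored_sample(40, theta = 1, p = 0.8, seed = 21),
                   make_censored_sample(60, theta = 2, p = 3, seed = 22))
  for (d in datasets) {
    fit <- gexp_fit(d$time, d$status)
    expect_true(fit$converged)
    g <- gexp_loglik_deriv(coef(fit)[1], coef(fit)[2], d$time, d$status,
                           order = 1)$gradient
    expect_lt(max(abs(g)), 1e-6)
    H <- gexp_loglik_deriv(coef(fit)[1], coef(fit)[2], d$time, d$status,
                           order = 2)$hessian
    expect_true(all(eigen(-H, only.values = TRUE)$values > 0))
    expect_true(all(fit$se > 0))
  }
})

test_that("profile maximiser at p = 1 is the censored-exponential closed form", {
  smp <- make_censored_sample(50, theta = 1.4, p = 1, seed = 31)
  prof <- gexpcens:::ml_core_fixed_p(smp$time, smp$status, 1)
  expect_equal(prof$theta, sum(smp$status) / sum(smp$time),
               tolerance = 1e-8)
})

test_that("estimates are equivariant under time rescaling", {
  d <- gexp_cancer_data("breast")
  base <- coef(gexp_fit(d$time, d$status))
  for (c in c(10, 12, 0.5)) {
    sc <- coef(gexp_fit(d$time / c, d$status))
    expect_equal(unname(sc["theta"]), unname(base["theta"] * c),
                 tolerance = 1e-6)
    expect_equal(unname(sc["p"]), unname(base["p"]), tolerance = 1e-6)
  }
})

test_that("MLE is consistent on a large complete sample", {
  set.seed(77)
  t <- rgexp(5000, 1, 2)
  fit <- gexp_fit(t, rep(1, 5000))
  expect_lt(abs(coef(fit)["theta"] - 1), 0.1)
  expect_lt(abs(coef(fit)["p"] - 2), 0.1)
})

test_that("Wald intervals scale with the normal quantile", {
  d <- gexp_cancer_data("cervical")
  fit <- gexp_fit(d$time, d$status, level = 0.95)
  ci <- confint(fit)
  expect_equal(unname(ci[, "upper"] - ci[, "lower"]),
               unname(2 * qnorm(0.975) * fit$se), tolerance = 1e-10)
  # intervals contain the point estimates
  expect_true(all(ci[, "lower"] < coef(fit) & coef(fit) < ci[, "upper"]))
  # degenerate interval at zero standard error
  deg <- gexpcens:::wald_interval(c(theta = 1, p = 2), c(0, 0), 0.95)
  expect_equal(unname(deg[, "lower"]), c(1, 2))
  expect_equal(unname(deg[, "upper"]), c(1, 2))
  expect_equal(unname(gexpcens:::wald_interval(1, 0.1, 0.95)),
               cbind(1 - qnorm(0.975) * 0.1, 1 + qnorm(0.975) * 0.1),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(gexpcens:::wald_interval(1, 0.1, 1.2), "between 0 and 1")
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(gexp_fit(c(1, 2, 3), c(0, 0, 0)), "at least one observed event")
  expect_error(gexp_fit(c(1, -2), c(1, 1)), "non-negative")
  expect_error(gexp_fit(numeric(0), numeric(0)), "empty")
  expect_error(gexp_fit(c(1, 2), c(1, 0), loss = "linex", k = 0,
                        method = "tk"), "nonzero")
  expect_error(gexp_fit(c(1, 2), c(1, 0), level = 1.5), "between 0 and 1")
})

test_that("fit accessors and alternative data interfaces agree", {
  d <- gexp_cancer_data("cervical")
  fit <- gexp_fit(d$time, d$status)
  # data frame input
  expect_equal(coef(gexp_fit(d)), coef(fit))
  # Surv input
  skip_if_not_installed("survival")
  sv <- survival::Surv(d$time, d$status)
  expect_equal(coef(gexp_fit(sv)), coef(fit))
  expect_s3_class(fit, "gexp_fit")
  expect_equal(unname(stats::logLik(fit)),
               gexp_loglik(coef(fit)[1], coef(fit)[2], d$time, d$status),
               ignore_attr = TRUE)
  expect_equal(dim(vcov(fit)), c(2L, 2L))
  expect_output(print(fit), "Generalised exponential fit")
  expect_output(print(summary(fit)), "log-likelihood")
})
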