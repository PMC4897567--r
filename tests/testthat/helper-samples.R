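# simulated censored samples used across test files
make_censored_sample <- function(n, theta = 1, p = 2, censor_fraction = 0.25,
                                 seed = 1) {
  set.seed(seed)
  bound <- if (censor_fraction > 0)
    calibrate_censoring_bound(theta, p, censor_fraction) else Inf
  rgexp_censored(n, theta, p, bound)
}

# a raw estimand object outside the gexp_transform() catalogue
constant_transform <- function(value) {
  structure(list(
    u = function(theta, p) value,
    grad = function(theta, p) c(0, 0),
    hess = function(theta, p) matrix(0, 2, 2),
    logu = function(theta, p) 0,
    logu_grad = function(theta, p) c(0, 0),
    logu_hess = function(theta, p) matrix(0, 2, 2)),
    class = "gexp_transform")
}
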