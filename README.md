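# gexpcens

Parametric survival analysis under **random right censoring** with the
two-parameter **generalised (exponentiated) exponential distribution**,

```
F(t; θ, p) = (1 − e^{−θt})^p ,   f(t; θ, p) = p θ (1 − e^{−θt})^{p−1} e^{−θt} ,   t > 0,
```

where `θ > 0` is a scale (inverse-time units) and `p > 0` a dimensionless
shape; `p = 1` recovers the exponential distribution.  The family is a
standard alternative to the Weibull and gamma laws for biomedical
time-to-event data, with increasing (`p > 1`) or decreasing (`p < 1`)
hazard.

The package is written for biostatisticians comparing classical and
approximate-Bayes estimation on censored lifetime data.  Each subject
contributes a pair `(tᵢ, δᵢ)` with `tᵢ = min(Tᵢ, Cᵢ)` and `δᵢ = 1[Tᵢ ≤ Cᵢ]`
under independent (noninformative) censoring, giving the likelihood
`L = ∏ f(tᵢ)^{δᵢ} S(tᵢ)^{1−δᵢ}`.  Five estimators of `(θ, p)` are provided
behind one fitting front-end:

* **ML** — maximum likelihood (quasi-Newton on the log-parameter scale with
  analytic gradients, Newton-polished), observed-information standard
  errors, Wald intervals;
* **Lindley-SEL / Lindley-LINEX** — Bayes point estimates under independent
  gamma priors `π(θ) ∝ θ^{b−1}e^{−aθ}`, `π(p) ∝ p^{d−1}e^{−cp}` by
  Lindley's two-parameter asymptotic expansion about the MLE (uses analytic
  third log-likelihood derivatives), under squared-error loss (posterior
  mean) or asymmetric LINEX loss `exp(kΔ) − kΔ − 1` with estimator
  `−(1/k) log E[e^{−kα}]`;
* **TK-SEL / TK-LINEX** — the same posterior functionals by the
  Tierney–Kadane Laplace ratio `(det Σ*/det Σ)^{1/2} exp{n[ℓ*(α̂*) − ℓ(α̂)]}`,
  accurate to `O(1/n²)`.

A brute-force 2-D quadrature **oracle** for posterior expectations
(`posterior_expectation_quad`) serves as the correctness authority for both
approximations, and a **Monte-Carlo study** (`gexp_mc_study`) compares all
five estimators by mean squared error and mean absolute deviation under
calibrated uniform random censoring.  Two published cancer datasets
(16 cervical-cancer and 121 breast-cancer survival times) ship as
plain-text fixtures.

## Worked example

```r
library(gexpcens)
d <- gexp_cancer_data("breast")    # 121 survival times in months, 56 censored
fit <- gexp_fit(d$time, d$status)  # maximum likelihood
summary(fit)
#> Generalised exponential distribution, random right censoring
#> Estimator: ML    n = 121, events = 65, censored = 56
#>       estimate       se lower 95% upper 95%
#> theta 0.011768 0.002349  0.007165  0.016372
#> p     1.014238 0.152387  0.715564  1.312912
#> log-likelihood at the point estimate: -354.7116
```

The fitted shape `p̂ ≈ 1.01` says these data are close to exponential
(roughly constant hazard); the scale `θ̂ ≈ 0.0118` per month corresponds to
a characteristic survival time of about `1/θ̂ ≈ 85` months.  The shape
estimate is invariant to the time unit; the scale transforms as an inverse
time (`gexp_fit(d$time/12, d$status)` gives `12 θ̂` and the same `p̂`).

A Bayes fit under the improper noninformative prior `1/(θp)` and LINEX loss
with `k = 0.7` (overestimation penalised more):

```r
gexp_fit(d$time, d$status, method = "tk", loss = "linex", k = 0.7)
#> Generalised exponential fit (TK-LINEX(k=0.7)), n = 121, events = 65
#>       estimate       se
#> theta 0.011618 0.002333
#> p     0.998142 0.152224
```

Both Bayes point estimates sit slightly below the ML values, as they must:
the posterior mean under the `1/(θp)` prior is pulled down, and a positive
LINEX `k` shrinks further.  The quadrature oracle confirms the
approximations (posterior mean of `p` is 1.00635; Lindley gives 1.00642,
TK 1.00663).

A small simulation cell:

```r
gexp_mc_study(n_values = 25, true_p_values = 2, replicates = 100,
              estimators = "ml", seed = 1)
```

returns a tidy table of MSE and mean absolute deviation per estimator and
parameter, with the realised censoring fraction per cell as an attribute.

## Command line

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/gexpcens", package = "gexpcens"))')
Rscript $CLI fit --fixture breast --method tk --loss linex --k 0.7
Rscript $CLI simulate --replicates 100 --n 25 --p 2 --seed 1 --out study.csv
Rscript $CLI datasets
```

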