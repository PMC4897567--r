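---
title: "Methods: generalised exponential survival models under random censoring"
author: "gexpcens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generalised exponential survival models under random censoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gexpcens)
```

## The model

Lifetimes follow the generalised (exponentiated) exponential distribution
$$F(t;\theta,p) = (1-e^{-\theta t})^p,\qquad
  f(t;\theta,p) = p\,\theta\,(1-e^{-\theta t})^{p-1} e^{-\theta t},\qquad t>0,$$
with scale $\theta>0$ (inverse-time units) and shape $p>0$ (dimensionless).
At $p=1$ the family is the exponential distribution with rate $\theta$; the
hazard increases for $p>1$ and decreases for $p<1$.  Random generation uses
the inverse-CDF transform $T=-\log(1-U^{1/p})/\theta$, $U\sim U(0,1)$.

Each subject is observed as $(t_i,\delta_i)$ with $t_i=\min(T_i,C_i)$ and
$\delta_i = 1[T_i\le C_i]$, where the censoring time $C_i$ is independent of
$T_i$ (noninformative censoring).  The likelihood is
$$L(\theta,p) = \prod_{i=1}^n f(t_i)^{\delta_i}\,S(t_i)^{1-\delta_i},
  \qquad S = 1-F .$$
Ties between an event and a censoring time need no special handling:
$\delta$ is taken as given, with $\delta=1$ meaning $T\le C$.  An *event*
recorded at $t=0$ is rejected (the density boundary behaviour depends on
$p$); a *censored* record at $t=0$ is allowed and contributes $\log S(0)=0$.

## Maximum likelihood

`gexp_fit(..., method = "ml")` maximises the log-likelihood over
$(\log\theta,\log p)$ — positivity without constraints — by BFGS with the
analytic gradient, then polishes on the natural scale with safeguarded
Newton steps until the score's max-norm is below $10^{-8}$ (at most 500
quasi-Newton and 30 Newton iterations).  The default start is the
censored-exponential closed form $\theta_0=\sum\delta_i/\sum t_i$, $p_0=1$;
if that start's polished optimum fails the score tolerance, $p_0=0.5$ and
$p_0=2$ are tried and the best log-likelihood kept.  The surface has been
unimodal on every dataset and simulated sample examined, so the multistart
is a guard, not a need.

Standard errors come from the *observed* information (the expected
information under random censoring would require the unknown censoring
law), and intervals are Wald, $\hat\alpha \pm z_{1-\alpha/2}\,\mathrm{se}$.
Estimation requires at least one event; with no events the likelihood has
no interior maximum and an error is raised.

All likelihood quantities are built from `expm1`/`log1p` forms —
$\log(1-e^{-x})$, $\log(1-w^p)$ — so that $\theta t$ spanning several
orders of magnitude (the breast-cancer data span $0.3$ to $154$ months)
neither underflows nor cancels.  A censored record whose survival
probability underflows double precision (roughly $\theta t > 745$ at
$p\approx 1$) yields a $-\infty$ log-likelihood, signalled rather than
clipped.

The derivative bundle `gexp_loglik_deriv` carries the analytic gradient,
Hessian and all third partial derivatives.  The closed forms were derived
once from the stable building blocks ($u=\log(1-e^{-\theta t})$ and the
censored-tail ratios $Q = w^p/(1-w^p)$, $R=Q(1+Q)$) and are locked by
finite-difference tests at relative $10^{-4}$ or better; the stored tensor
is exactly symmetric in its indices.

## Priors and losses

Independent gamma priors
$\pi_1(\theta)\propto\theta^{b-1}e^{-a\theta}$,
$\pi_2(p)\propto p^{d-1}e^{-cp}$: note carefully that $a$ and $c$ are the
*rates* (they multiply the parameter) and $b$, $d$ the *shapes*.  The
all-zero setting — the package default — is the improper prior
$1/(\theta p)$, implemented literally through the log-prior gradient
$\rho = ((b-1)/\theta - a,\ (d-1)/p - c) = (-1/\theta, -1/p)$ and flagged
`improper`.  This prior is scale-invariant, which is what makes the
posterior of the shape parameter independent of the time unit.  Posterior
propriety under it is an empirical matter: the quadrature oracle verifies a
finite normalising integral for the sample at hand and errors otherwise,
rather than assuming it.

Two losses are supported.  Squared-error loss (SEL) estimates a parameter
by its posterior mean.  The asymmetric LINEX loss $e^{k\Delta}-k\Delta-1$
has Bayes estimator $-\tfrac1k\log E[e^{-k\alpha}]$; $k>0$ penalises
overestimation more.  **Units matter:** $k$ carries the inverse units of
the estimand, so a fixed $k=0.7$ paired with a rate measured per day is a
(much) weaker asymmetry than the same $k$ per year.  Meaningful LINEX
analysis of $\theta$ should use a time unit in which $\theta$ is of order
one; the shape parameter is dimensionless and unaffected.

## Lindley expansion

For an estimand $u(\theta,p)$ the posterior expectation is expanded about
the MLE:
$$E[u\mid\text{data}] \approx u
  + \tfrac12\sum_{i,j}(u_{ij} + 2u_i\rho_j)\,\sigma_{ij}
  + \tfrac12\sum_{i,j,k,l} \ell_{ijk}\,\sigma_{ij}\sigma_{kl}\,u_l ,$$
with $\ell_{ijk}$ the third log-likelihood derivatives and
$\sigma=(-\ell'')^{-1}$ the full negative-inverse Hessian.  Two conventions
deserve note.  First, the sum runs over *all* $2^4$ index combinations of
the third-order term with the complete $\sigma$ matrix (off-diagonal
included) — compressed displays of this expansion sometimes list only the
diagonal $\sigma_{11},\sigma_{22}$, but the full two-parameter form is the
one with $O(1/n)$ error.  Second, the expansion point is the MLE, not the
posterior mode, because $\sigma$ is built from the likelihood Hessian
alone; this is the MLE-centred variant of the method.

SEL uses the identity transforms ($u=\theta$: $u_1=1$, $u_{11}=0$; likewise
for $p$); LINEX uses $u=e^{-k\theta}$ ($u_1=-ke^{-k\theta}$,
$u_{11}=k^2e^{-k\theta}$, cross-derivatives zero) followed by
$-\tfrac1k\log(\cdot)$, with a positivity check on the approximated
expectation (a non-positive value is an approximation failure and is
raised, never clipped).

## Tierney–Kadane ratio

For a strictly positive estimand $v$, write $\ell = (\log\text{prior} +
\log\text{lik})/n$ and $\ell^* = \ell + \log v/n$.  Then
$$E[v\mid\text{data}] \approx
  \Big(\frac{\det\Sigma^*}{\det\Sigma}\Big)^{1/2}
  \exp\{n[\ell^*(\hat\alpha^*) - \ell(\hat\alpha)]\},$$
with $\hat\alpha$, $\hat\alpha^*$ the two maximisers and $\Sigma$,
$\Sigma^*$ the negative inverse Hessians there.  The leading Laplace errors
of numerator and denominator cancel, leaving $O(1/n^2)$.

Conventions: each tabulated quantity gets its **own** starred surface —
estimands $\theta$ and $p$ separately for SEL, $e^{-k\theta}$ and
$e^{-kp}$ separately for LINEX.  A single surface containing
$\log\theta+\log p$ approximates $E[\theta p]$, not the separate means; that
joint-product variant is available as `gexp_transform("product")` for
comparison but is not used for the reported estimates.  The starred
maximisation warm-starts from the posterior mode and normally needs only a
few Newton steps (the surfaces differ by $O(1/n)$); the determinant ratio
is computed in log space via Cholesky factors, which also certifies
negative-definiteness — an indefinite Hessian raises an approximation
error.

One structural property worth knowing: the $k\to 0$ limit of the TK-LINEX
estimate is *not* the TK-SEL value.  The limit is a Laplace-derivative
approximation of the posterior mean that differs from the SEL ratio value
by $O(1/n^2)$; both sit within their advertised accuracy of the exact
posterior mean (the test suite measures this against the quadrature
oracle), but their mutual gap at moderate $n$ (a few $10^{-4}$ at
$n\approx 120$) far exceeds machine precision.  The Lindley expansions, by
contrast, satisfy the $k\to 0$ collapse analytically.

## Posterior SDs and intervals

The study's tables report a dispersion for every Bayes estimator but no
formula; the package's convention, isolated in one place so it can be
changed coherently, is the *second-moment* route: apply the same
approximation to $u=\theta^2$, $u=p^2$ and report
$\sqrt{E[\alpha^2]-E[\alpha]^2}$.  A non-positive approximated variance is
reported as `NA` with a warning, not silently repaired.  Bayes intervals
are normal-form, estimate $\pm z\cdot$SD, at the same default level (0.95)
as the ML Wald intervals.  Both approximations use the identical
convention, so their SDs are directly comparable.

## The quadrature oracle

`posterior_expectation_quad` evaluates
$E[g] = \int\!\!\int g\,e^{\ell+\rho}\,/\,\int\!\!\int e^{\ell+\rho}$ by
nested adaptive quadrature in $(\log\theta,\log p)$.  The log scale makes
positivity automatic, and the Jacobian $\theta p$ exactly absorbs the
improper $1/(\theta p)$ prior.  The kernel is scaled by its value at the
posterior mode to avoid overflow; the integration box starts at the mode
$\pm 10$ curvature-based SDs per axis and is enlarged (factor 1.6, up to
six rounds) until the expectation changes by less than the requested
tolerance.  Failure to stabilise, or a non-positive normalising integral,
is an error — the oracle never returns a silently wrong number.  The
conjugate censored-exponential sub-model ($p$ fixed at 1, gamma prior on
$\theta$, posterior mean $(b+\sum\delta_i)/(a+\sum t_i)$ and LINEX
functional $((a+\sum t)/(a+\sum t+k))^{b+\sum\delta}$) provides closed
forms against which the oracle and both approximations are tested.

## The simulation study

`gexp_mc_study` emulates a clinical-trial-like censoring mechanism:
lifetimes $T_i\sim GE(\theta,p)$ by inverse-CDF sampling and independent
per-subject censoring times $C_i\sim U(0,b)$.  The bound $b$ is defined by
the *expected censoring fraction*,
$$P(C<T) = \frac1b\int_0^b S(c)\,dc = \text{target},$$
solved by bracketing root search to relative $10^{-8}$ — the unique
definition that depends only on the lifetime law and the target fraction.
The realised fraction per cell is logged in the result for audit.

Defaults mirror the study conditions: $n\in\{25,50,100\}$, $\theta=1$,
$p\in\{0.8,1.2,2.0\}$, 25% censoring, 1000 replicates, LINEX $k=\pm0.7$,
all-zero hyperparameters.  Per cell and replicate, all requested estimators
are fitted and $(\hat\alpha-\alpha)^2$ and $|\hat\alpha-\alpha|$
accumulated ("absolute bias" here is the Monte-Carlo mean absolute
deviation, as the study tables use the term).  Replicates with fewer than
two events or a failed estimator are dropped from that estimator's averages
and counted in `failures`; a cell with more than 20% failures warns.

Seeding: each $(n,p)$ cell derives a 31-bit seed deterministically from the
master seed and the cell labels, then draws one seed per replicate.  A
cell's results are therefore bit-reproducible and independent of which
other cells run — the property the tests verify.

What the generator does *not* emulate: covariates, informative or
administrative (fixed-date) censoring, tied or grouped measurement times,
and model misspecification.  Passing Monte-Carlo checks therefore says the
estimators behave as advertised *under the model*, not that the model fits
any particular dataset.

## Numerical choices, in one place

* Optimisation on $(\log\theta,\log p)$; analytic gradients everywhere;
  score tolerance $10^{-8}$ (ML) and $10^{-10}$ (posterior surfaces);
  multistart $p_0\in\{0.5,1,2\}$ with first-success early exit.
* Stable $\log(1-e^{-x})$ evaluated as `log(-expm1(-x))` below $\log 2$ and
  `log1p(-exp(-x))` above.
* Cholesky factorisation certifies negative-definite Hessians; determinant
  ratios in log space.
* Censoring-bound root search brackets by doubling/halving around
  $1/\theta$.
* Oracle tolerance defaults to $10^{-6}$ absolute on the expectation.
* Degenerate inputs: no events — error; $k=0$ under LINEX — error;
  non-positive approximated expectations/variances — error/`NA` with
  warning, never silent repair.

## Validation scale

The test suite validates the pieces at sizes chosen to keep the full run in
minutes on one CPU: derivative checks at $n=20$; oracle-agreement checks at
$n\in\{25,50,100,400\}$; consistency at $n=5000$ complete samples; the full
five-estimator Monte-Carlo grid at the default 1000 replicates; conjugate
closed-form checks at $n\in\{40,100,200\}$.  The acceptance script refits
both packaged datasets and reruns the two headline Monte-Carlo cells at
1000 replicates.

## Known limitations

* Two parameters only; no covariates, no competing risks, no
  hazard-function or reliability estimands beyond those expressible as
  $u(\theta,p)$.
* The Lindley route needs a negative-definite observed information at the
  MLE; very small samples ($d\le 2$ events) can fail it, and such failures
  are raised, counted and excluded in the simulation study.
* TK requires strictly positive estimands; signed estimands would need the
  fully exponential variant, which is out of scope.
* LINEX comparisons of the scale parameter are unit-dependent (see
  *Priors and losses*); the packaged day-scale cervical data make the
  $k=\pm0.7$ tilt on $\theta$ numerically unresolvable, so scale-side LINEX
  orderings are checked in years.
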