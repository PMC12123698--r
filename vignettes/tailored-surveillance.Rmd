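---
title: "Estimating tailored surveillance-biopsy rules from interval-censored cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tailored surveillance-biopsy rules from interval-censored cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailoras)
```

## The decision problem

An active-surveillance (AS) cohort monitors patients with low-grade cancer
by periodic biopsies. At each decision landmark $s$ a stabilized rule
$d(\boldsymbol Z_s) \in \{+1, -1\}$, applied to the patient's most recent
covariates, decides whether a biopsy should be performed at $s + \tau$
($\tau$ is set by the protocol; 24 months in the package's simulation
defaults). The rule's operating characteristics over the window
$(s, s+\tau]$ are the time-varying true positive rate
$\mathrm{TPR}(d;s,\tau) = P\{d(\boldsymbol Z_s)=+1 \mid s < T \le s+\tau\}$
and true negative rate
$\mathrm{TNR}(d;s,\tau) = P\{d(\boldsymbol Z_s)=-1 \mid T > s+\tau\}$,
where $T$ is the progression time. They are combined into the
weighted-benefits value
$$\Phi(d) = \frac1J \sum_{j=1}^J \left\{ \mathrm{TPR}(d;t_j,\tau)
  + \xi(t_j)\,\mathrm{TNR}(d;t_j,\tau) \right\},$$
with $\xi(s) = \{1-\rho(s;\tau)\}/\{\rho(s;\tau)\, r\}$ and
$\rho(s;\tau) = P(s < T \le s+\tau \mid T > s)$. Under this choice a rule
with a higher value wastes fewer unnecessary biopsies than the $r$ per
detected progression the clinic is willing to spend.

## What is observed, and why standard estimators fail

Progression status is revealed only at biopsies: at scheduled times
$N_1 < N_2 < \cdots$ one observes $\Delta_k = 1\{T \le N_k\}$, subject to
loss to follow-up before $N_k$ (terminal), occasional missed appointments,
and — crucially — *immediate dropout*: after the first observed positive
biopsy no further biopsies exist. Hence whether a positive biopsy is
observed depends on earlier results, which invalidates both
current-status-panel estimators (which assume patients keep being examined)
and right-censoring IPCW estimators (which treat the first observed
positive time as the event time; it is systematically late).

The package assumes, as the estimators require:

* biopsy times are random and independent of $T$ and of the covariate
  process (compliance-driven jitter around a protocol);
* censoring and missed appointments are non-informative;
* covariates are available at the decision landmarks.

## The kernel estimators

**TNR** uses every observed negative biopsy. Each subject receives weight
$W_{-1,t} \propto \sum_k (1-\Delta_k)\zeta_k\delta_k K_h(N_k - t)$ at
$t = s + \tau$, normalized to mean one over the *eligible* subjects (those
whose last observed biopsy falls after $s+\tau$), and
$\widehat{\mathrm{TNR}} = E_n[1\{d=-1\} W_{-1,s+\tau}]$ over that subset.
Negative biopsies are observed regardless of dropout, so this estimator is
unaffected by it. The eligibility restriction is applied to the TNR side
only; the TPR weights below are averaged over the full cohort, since the
adjacent-pair construction already conditions correctly.

**TPR** cannot use positive biopsies directly (dropout makes their
observation outcome-dependent). Instead it uses *adjacent
negative–positive pairs*: consecutive observed biopsies with results
$(0,1)$. The pair bracketing the event is observed whenever neither of its
two biopsies is censored or missed — dropout cannot remove it, because
dropout happens only after it. Conditional on the pair's times being
$(s, s+\tau)$, the joint law of the decision and of the event
$\{\Delta_{(k)}=0, \Delta_k=1\}$ identifies
$P\{d = a,\ s \le T \le s+\tau\}$. Smoothing the observed pairs with the
product Epanechnikov kernel
$\widetilde K_{\tilde h}(N_k - s - \tau,\ N_{(k)} - s)$ yields per-subject
weights $W_{1,s}$ (at most one pair per subject; the confirmatory biopsy at
time 0 acts as the initial negative), and
$\widehat{\mathrm{TPR}} = E_n[1\{d=+1\} W_{1,s}]$. The test suite verifies
the identification numerically: with biopsies forced at exactly
$(s, s+\tau)$ in a $10^5$-subject simulation, the observed pair frequencies
match truth-computed probabilities to Monte-Carlo accuracy.

Both weight systems average to exactly one by construction, which gives the
exact identities $\widehat{\mathrm{TPR}}(\pm 1) \in \{0,1\}$ and
$\widehat{\mathrm{TPR}}(d) + \widehat{\mathrm{TPR}}(-d) = 1$ used as test
anchors.

### Bandwidths

$h = C_b n^{-1/5}$ (one-dimensional) and $\tilde h = C_b n^{-1/6}$
(two-dimensional) are the rates that balance the squared-bias and variance
terms of the generalization-error bound for a second-order kernel; the
Epanechnikov family is chosen precisely because it is second-order with
compact support. $C_b$ is in months and must scale with the design's time
resolution: the package default is $C_b = 48$ for the baseline design
(biopsy gap $T_{\text{gap}} = 24$ months), and the study functions default
to $C_b = 2\,T_{\text{gap}}$, since the two-dimensional smoother needs
windows of the order of the gap between biopsies to see any pairs at all.
For the learner, `cv_osf_i()` selects $(\lambda, C_b)$ by subject-level
cross-validation on the held-out estimated value, which is how the method
is meant to be tuned in applications. No boundary correction is applied to
the weight systems; a warning is emitted when more than 20% of kernel mass
falls outside the observed biopsy-time range.

### The conditional progression probability

$\rho(s;\tau)$ enters only through the scalar trade-off $\xi(s)$, so it is
a smooth marginal functional rather than a local regression target. Three
estimators are provided:

* `"pch"` (default): each subject's progression time is bracketed by the
  last observed negative and first observed positive biopsy — an
  interval-censored observation that survives dropout. A piecewise-constant
  hazard with bins of width $\tau$ spanning the study window is fitted to
  these brackets by maximum likelihood, and
  $\hat\rho = 1 - \hat S(s+\tau)/\hat S(s)$. This remains stable even when
  biopsy gaps are much wider than $\tau$, where any pair-local smoother
  must extrapolate. (The unregularized nonparametric interval-censoring
  MLE was considered and rejected: with gaps of 24–72 months its pointwise
  values are ill-determined; the binned hazard is exactly that estimator
  regularized to the resolution the data support.)
* `"ll"`: conditional on an adjacent negative-first pair at times
  $(s, s+\tau)$, the second result is Bernoulli with mean $\rho(s;\tau)$,
  so $\rho$ is the local-linear regression of the second result on
  (first time, gap). Anisotropic bandwidths ($2\tilde h$ in the gap
  coordinate, $6\tilde h$ in first time) reflect that $\rho$ varies slowly
  in $s$ while the gap coordinate carries a support boundary: scheduled
  gaps never fall below $T_{\text{gap}}$, so when $\tau \approx
  T_{\text{gap}}$ the evaluation point sits on the edge of the pair
  distribution and a plain kernel average sees only windows wider than
  $\tau$ — a first-order bias the local-linear fit removes.
* `"nw"`: the plain kernel-ratio of negative–positive against
  negative–negative pair mass at $(s, s+\tau)$, kept as the reference
  construction; subject to the boundary bias just described.

Estimates are clipped to $[10^{-6}, 1-10^{-6}]$ so $\xi$ stays finite.

## The OSF-I learner

Maximizing $\widehat\Phi$ is equivalent to minimizing a weighted 0–1
classification risk with per-(subject, landmark) weights
$W_{1,t_j} - \xi(t_j) W_{-1,t_j+\tau}$ split into positive and negative
parts. Replacing the indicator by the logistic loss $\phi$ gives the convex
program
$$\min_f\ \frac1J\sum_j E_n\!\left[ W_{+}\,\phi\{f(\boldsymbol Z_{t_j})\})
  + W_{-}\,\phi\{-f(\boldsymbol Z_{t_j})\} \right] + \lambda \lVert f\rVert^2,$$
with $f$ linear, i.e. a weighted logistic regression with a ridge penalty.
Implementation choices:

* Each subject contributes one signed row per landmark (label = sign of the
  weight difference, weight = its absolute value); the stacked
  $(W_+, W_-)$ two-row formulation yields an identical objective, which the
  tests check to $10^{-10}$.
* Weights are rescaled to mean one within each landmark before fitting, so
  $\lambda$ has a stable interpretation across sample sizes and bandwidths
  (the minimizer is invariant to the scaling up to $\lambda$).
* The intercept is not penalized (standard ridge-logistic practice).
* Features at $t_j$ are the $p$ current covariates plus intercept and no
  time feature — the stabilized rule is one function applied at every
  landmark.
* The solver is a damped Newton iteration on the exact objective (analytic
  gradient and Hessian, step-halving line search); convexity makes the
  optimum unique for $\lambda > 0$, and the fit is verified against an
  independent general-purpose optimizer to $10^{-6}$ in objective value.
  A ridge-penalized GLM routine could fit the same model, but its internal
  objective scaling and standardization differ from the expression above,
  which the equivalence test pins down exactly.
* Ties $f(\boldsymbol Z) = 0$ decide $+1$ (biopsy) — conservative for
  patient safety.
* `cv_osf_i()` uses subject-level (never row-level) folds to respect
  within-subject correlation; 5 folds by default, selection by mean
  held-out estimated value, ties resolved toward the smaller
  $(\lambda, C_b)$ grid point. Fold count and criterion are choices of this
  package; the tuning prescription itself (cross-validating $\lambda$ and
  $C_b$) follows the method.

The IPCW comparator (`osf_ipcw()`) swaps the kernel weight systems for
inverse-censoring-probability weights built from the surrogate
right-censored event time (first observed positive biopsy, Kaplan–Meier
censoring distribution) and resolves $\xi$ from an IPCW prevalence
estimate, so the two learners differ *only* in the weighting scheme. It is
deliberately a reduced-fidelity stand-in for full right-censoring-based
rule learners: it isolates the consequence of ignoring interval censoring.

## The simulator

`simulate_cohort()` generates the conditions of the package's studies:

* $p = 4$ latent covariate processes
  $W_l(t) = a_{0,l} + a_{1,l}\log(t/\nu)$, $\nu = 30$ months, with
  $(a_{0,l}, a_{1,l})$ bivariate normal (means $-0.1$, variances $0.82^2$
  and $0.13^2$, covariance $-0.005$) and observed values carrying fresh
  Gaussian measurement error of variance $0.1$ — at biopsies and at
  landmarks alike, so the learner sees noisy inputs as in a real study.
* Progression time $T = 12 + \nu\left[\tilde T\, \gamma\,
  \nu_{\text{shape}}^{-1} \exp\{-\boldsymbol a_0^\top\boldsymbol\beta -
  r_{\text{nl}}(a_{0,1}+a_{0,2})^2\}\right]^{1/\gamma}$ with
  $\tilde T \sim \mathrm{Exp}(1)$,
  $\gamma = \nu_{\text{shape}} + \boldsymbol a_1^\top\boldsymbol\beta +
  r_{\text{nl}}(a_{1,1}+a_{1,2})^2$, $\nu_{\text{shape}} = 1.4$ and
  $\boldsymbol\beta = (-0.7, 0.8, -1.3)$ on processes 2–4; process 1 is a
  pure noise covariate. Scenario 1 sets $r_{\text{nl}} = 0$ (linear
  log-hazard), Scenario 2 sets $r_{\text{nl}} = 0.1$. Draws with
  $\gamma \le 10^{-3}$ (probability essentially zero under these moments)
  are resampled, with a hard failure after 100 rounds. The closed form is
  the authoritative definition; the tests integrate the hazard it implies,
  $\lambda(t) = (\nu_{\text{shape}}/\nu)\, e^{\eta_0}
  \{(t-12)/\nu\}^{\gamma-1}$, numerically and check the sampler against it.
* Censoring $C \sim U[12, 150]$, terminal; biopsy schedules start uniform
  on $[12, 3T_{\text{gap}}]$ with subsequent gaps uniform on
  $[T_{\text{gap}}, 3T_{\text{gap}}]$ until the next gap would pass 150
  months; per-biopsy missingness with probability `miss_prob` (0 by
  default); immediate dropout after the first retained positive (a
  `dropout = FALSE` switch produces panel current-status data, used to
  validate the current-status comparator in its own habitat).
* The landmark grid $\{24, 48, 72, 96\}$ with $\tau = 24$ spans the biopsy
  horizon; the source design leaves these unstated, so they are package
  defaults rather than reproduced constants.

What the simulator does *not* emulate: covariate-dependent biopsy
scheduling, informative censoring, imperfect biopsy sensitivity, irregular
real-world covariate panels, and the much lower progression prevalence of
real AS cohorts (the simulated conditional progression probability within a
24-month window is roughly 0.3–0.5, versus the order of 0.1 in practice).
Tests passing on these cohorts therefore certify the estimators' internal
correctness and their behaviour under outcome-dependent dropout — not
calibration on any real population.

## Degenerate inputs and error policy

Kernel estimators raise a classed `noSupportError` when no observation
carries kernel mass; `estimate_value()` and `build_weighted_sample()` drop
such landmarks with a warning and reduce $J$, failing only when every
landmark is unsupported. Cross-validation skips unsupported folds the same
way. The Newton solver reports an `optimizationError` with diagnostics
instead of returning an unconverged fit. Cohort generation is a pure
function of `(n, config, seed)` and all study drivers derive per-replicate
seeds from a single base seed, so every result in the package is
bit-reproducible.

## Known limitations

* **Gap boundary at $\tau \approx T_{\text{gap}}$.** Scheduled gaps never
  fall below $T_{\text{gap}}$, so when the decision horizon equals the
  minimum gap the two-dimensional smoother sits on the edge of the pair
  distribution. The TPR weights keep the printed estimator form and
  therefore carry this one-sided smoothing bias at finite $n$; the
  acceptance suite documents where the 0.05 consistency band is met (TNR
  at all landmarks, TPR at the earliest landmark at $n = 2000$) and where
  it is not.
* **Sparse pair support at wide gaps.** With $T_{\text{gap}} = 48$ and
  $\tau = 24$ only a corner of the pair distribution informs the TPR
  weights; estimates at late landmarks are unbiased in the mean but
  variance-dominated at $n = 500$, and landmarks can lose support
  entirely. This is an information limit of the design, not of the
  implementation — the same code with interior $\tau$ (e.g.
  $T_{\text{gap}} = 12$) tracks the oracle closely, which the unit tests
  assert.
* **Degenerate optima at large $r$.** When $r$ is large relative to the
  (high) simulated progression prevalence, the optimal rule approaches
  always-biopsy; a comparator whose bias pushes it toward that constant can
  then match or marginally exceed the unbiased learner's value, so
  value-ordering comparisons at large $r$ are uninformative under these
  generator conditions.
* Pointwise confidence intervals for the kernel estimates are not
  provided, and biopsy-time distributions on discrete grids would call for
  discrete kernels — both outside the package's scope.

## Study problem sizes

The packaged studies default to 100 replicates (estimator comparison;
evaluation cohorts of $n = 500$) and 50 replicates (policy comparison;
training $n = 500$, independent truth-bearing test cohorts of $n = 1000$),
with scenario, gap, trade-off grid and replicate count configurable through
`study_config()` up to the full factorial. These sizes are the package's
default desk-scale choice; all ordering statements computed by
`scripts/acceptance.R` are made at exactly these sizes.
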