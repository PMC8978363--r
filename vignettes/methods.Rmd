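---
title: "Evaluating multiple-imputation strategies for missing covariates in case-cohort studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multiple-imputation strategies for missing covariates in case-cohort studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a case-cohort study, an expensive exposure is measured only for the
cases and for a random *subcohort* drawn from the inception cohort with
selection probability $\pi$. The analysis uses the cases and subcohort
only, weighting records by the inverse probability of selection to undo
the oversampling of cases: with stratified (Borgan) weights, $w_i = 1$
for cases and $w_i = n_0/m_0$ for non-case subcohort members, where
$n_0$ and $m_0$ count non-cases in the full cohort and subcohort. When
some *covariates* are additionally missing by chance, multiple
imputation (MI) is the natural remedy — but a weighted analysis model
means the imputation model should somehow reflect the weights, and it is
not obvious how. Because this design has exactly two weight classes,
perfectly collinear with the outcome, several accommodations are
plausible:

* **weight proxy (WO)** — include the outcome (a proxy for the weight)
  as a predictor in the imputation model;
* **weight interactions (WX)** — additionally include two-way
  interactions between the outcome and every other analysis variable;
* **stratum-specific (SS)** — impute cases and non-cases separately,
  dropping the outcome from the model;
* **weighted model (WM)** — fit the imputation model itself by weighted
  maximum likelihood (available only under chained equations).

`ccmisim` implements a fully reproducible simulation study comparing
these accommodations under two imputation frameworks — fully conditional
specification (FCS) and joint multivariate-normal imputation (MVNI) —
against complete-case analysis (CCA) and a complete-data benchmark.

## The target analysis

The outcome model is either a log-link Poisson regression with robust
(sandwich) variance, estimating the adjusted risk ratio
$\exp(\theta_1)$,

$$\log \Pr(Y=1) = \theta_0 + \theta_1\,\mathrm{vdi} + \theta_2\,\mathrm{cauc}
 + \theta_3\,\mathrm{petown} + \theta_4[\mathrm{nsib}=1] +
 \theta_5[\mathrm{nsib}=2] + \theta_6\,\mathrm{antevd} +
 \theta_7\,\mathrm{hxfamall},$$

or the analogous logistic model for the adjusted odds ratio
$\exp(\beta_1)$. The Poisson device (rather than log-binomial) avoids
well-known convergence failures; validity of the SE rests on the
sandwich estimator, here the weighted HC0 form
$A^{-1}\!\left(\sum_i U_i U_i^\top\right) A^{-1}$ with
$A = X^\top W X$ and weighted scores $U_i = w_i (y_i - \mu_i) x_i$. The
test suite verifies this equals `sandwich::vcovHC(type = "HC0")` and
agrees with a nonparametric bootstrap within 15%.

## The synthetic cohort

Cohorts of 1000 infants mimic a population-derived birth cohort studying
vitamin D insufficiency (VDI) at birth and food allergy at one year.
Covariates are generated sequentially along a causal DAG: Caucasian
ethnicity (Bernoulli, 0.72) → maternal age (normal, mean 32.1, SD 4.78)
→ socioeconomic tertile (baseline-category logit; marginals 0.254,
0.194, 0.552) → family history of allergy (logistic, 0.861) → number of
siblings (baseline-category logit; 0.421/0.357/0.222) → pet ownership
(logistic, 0.805) → antenatal vitamin D use (logistic, 0.788) → VDI
(logistic, 0.445). Category 0 is the reference for all
baseline-category logits and maternal age enters untransformed, in
years.

The published source for this design does not include its numeric
coefficient table, so the registry in `R/params.R` is a stand-in
constructed as follows and fully exposed as configuration: slopes were
fixed a priori at modest conditional effects ($|\beta| \le 0.5$ per
unit or per year, signs chosen for plausibility, e.g. supplement use
lowers insufficiency), and every intercept was then tuned once — by
deterministic monotone root-finding against a 400,000-record forward
simulation — so the marginals above are reproduced. Outcome intercepts
were tuned the same way to a prevalence of 8% for the observed-strength
family and to 20.4% (risk-ratio generation) / 18.4% (odds-ratio
generation) for the extreme family. The exposure coefficient is
$\log(1.16)$ (RR) or $\log(1.18)$ (OR) under the observed association
and $\log 2$ under the enhanced association; intercepts are not re-tuned
when the association is switched to enhanced (prevalence then drifts
slightly upward), but they can be overridden via
`outcome_spec(intercept = )`.

The **extreme** variant doubles the maternal-age slopes of the pet
ownership, antenatal vitamin D and exposure models (`strengthen = 2`,
configurable) and re-tunes those three intercepts so the covariate
marginals stay fixed — stress-testing the auxiliary variable's role
without moving the rest of the design. Under the log link the generator
verifies that every reachable covariate pattern implies an event
probability below 1 and aborts with the offending pattern otherwise.

What the generator does *not* emulate: measurement error, within-family
clustering, missingness in the outcome or unintended missingness in the
exposure, formula-feeding variables, and real-data deviations from the
assumed DAG. Passing tests therefore certify the methods under a known,
recoverable mechanism — not performance on real data.

## Missingness

Missingness is confined to pet ownership and antenatal vitamin D use.
The target is $p\%$ of records incomplete overall ($p = 15$ or $30$),
half of them missing both covariates and the remaining half split
evenly between the two singleton patterns. Three mechanisms:

* **independent** — exact pattern counts assigned uniformly at random
  (counts, not Bernoulli draws, so realized proportions match the
  targets deterministically);
* **DMO** — indicators drawn from logistic models on the outcome,
  ethnicity and maternal age (slopes 0.5, −0.3, 0.05 per year; defaults,
  configurable), with the antenatal-vitamin-D indicator additionally
  depending on the realized pet-ownership indicator, which is what
  controls the both-missing overlap;
* **DME** — the same structure with every slope exactly doubled.

The intercepts $\nu_0, \tau_0$ and the indicator-dependence coefficient
$\tau_4$ are calibrated, not fixed: on a 200,000-record calibration
cohort the three free parameters solve, by monotone `uniroot` on exact
model expectations (no Bernoulli noise), the system
$P(M_\mathrm{pet}) = P(M_\mathrm{ant}) = 3p/400$ and
$P(\mathrm{both}) = p/200$. The ordering matters and makes each step
one-dimensional: the antevd-only mass does not involve $\tau_4$, so
$\tau_0$ can be solved before $\tau_4$. With all slopes at zero the
system has a closed form (e.g. $\nu_0 = \mathrm{logit}(0.225)$ at
$p=30$), which the test suite checks the root-finder against.
Calibrations are cached per parameter set; per-replicate realized
proportions then vary stochastically around the target.

## Imputation engines

Both engines treat the case-cohort sample (where the exposure is
complete by construction) and never alter observed cells.

**FCS** cycles through the incomplete variables in the fixed order
petown → antevd for 10 cycles (default). Each step refits a logistic
model for the target on the records where it is observed, draws a
coefficient vector from the approximate posterior
$N(\hat\beta, \hat V)$, and redraws the missing values from
Bernoulli(expit$(x\beta^*)$). WX interactions are *passively* recomputed
within every cycle; SS runs the cycles separately per outcome stratum;
WM fits each conditional model by weighted maximum likelihood and draws
from that fit's model-based covariance (the weighted-sandwich
alternative for the draw step is a documented open choice — the
model-based form matches mainstream chained-equations software). A fit
that fails to converge, is rank-deficient, or has non-finite curvature
marks the whole imputation non-converged; this is the engine's analogue
of perfect-prediction failure and feeds the replicate-level convergence
bookkeeping.

**MVNI** models all analysis variables jointly normal: binaries as 0/1
columns, the two categorical variables as indicator pairs, and (under
WX) the outcome-by-variable products as "just another variable"
columns. Each imputation is an independent data-augmentation chain:
given current completed data, draw $\Sigma \sim$
Inv-Wishart$(n-1, S)$ and $\mu \sim N(\bar y, \Sigma/n)$ (Jeffreys
prior), then redraw the missing entries from their conditional normal
given the observed entries, pattern by pattern; after 200 burn-in
iterations (default) the state is the imputation. Imputed values are
continuous and are carried into the analysis *without rounding*.
Singular covariance draws trigger a ridge-stabilized retry
($S + \epsilon\,\overline{\mathrm{diag}}(S) I$, $\epsilon = 10^{-6}$
then $10^{-3}$) before flagging non-convergence. SS runs a separate
sampler per outcome stratum.

With $m$ defaulting to 30 (matching the larger missingness percentage),
estimates from the $m$ completed datasets are pooled by Rubin's rules:
$\bar\theta$, $T = \bar W + (1+1/m)B$, and the classical large-sample
degrees of freedom $(m-1)\left(1 + \bar W/((1+1/m)B)\right)^2$
($\infty$ when $B=0$). The small-sample Barnard–Rubin correction is
deliberately omitted: with analysis samples in the hundreds and
$m = 30$ it is negligible here, and the classical form keeps the
pooled CI analytically checkable. Non-MI analyses use normal-quantile
CIs.

## Scenario orchestration and performance measures

A scenario crosses DGP variant, association, estimand, mechanism, $p$
and $\pi \in \{0.20, 0.30, 0.40\}$; the default grid has 78 scenarios
(72 observed-variant cells plus 6 extreme ones: enhanced association,
DME at 30%, both estimands, three $\pi$). Each replicate generates a
cohort, induces missingness, draws one subcohort indicator that serves
both the missing-data and complete-data analyses, and runs CCA, the
seven MI strategies and the complete-data benchmark. A replicate is
retained only if *every* method converges; a scenario executes
replicates in fixed seed order until `nsim` (default 2000) are retained
or the buffer (default 10% above `nsim`) is exhausted. Convergence
rates are reported over the replicates actually executed — once
retention is met, further buffer replicates would only change that
denominator, so they are not run.

Performance per method: relative bias
$100(\overline{\hat\theta}-\theta)/\theta$, empirical SE, model-based SE
$\sqrt{\overline{\widehat{SE}^2}}$, and coverage of the nominal 95% CI,
each with its Monte Carlo standard error under the standard
(Morris–White–Crowther) conventions; e.g. the MCSE of a 95% coverage at
2000 replicates is 0.49%, giving the Monte Carlo interval 94.0–96.0%.

Every stochastic operation takes an explicit seed; replicate $k$ of a
scenario derives its stream as a fixed multiplicative fold of (root
seed, scenario-id hash, $k$), so any replicate is independently
reproducible.

## Problem sizes used by the shipped checks

The packaged test suite and acceptance script run at desk scale, chosen
as the smallest sizes at which each property is a sharp test:
large-cohort checks (marginals, coefficient recovery, risk-ratio
recovery, missingness calibration) use $n = 200{,}000$; the qualitative
replication of the study's findings runs one extreme-condition scenario
(RR estimand, DME at 30%, $\pi = 0.3$) at the reduced preset
`nsim = 300`, `m = 10`, `fcs_cycles = 5`, `mvni_burnin = 50`. The
reduced engine settings are adequate because only two binary covariates
are incomplete — both samplers stabilize within a few iterations — and
the full-size defaults (10 cycles, 200 burn-in) remain the package
defaults for real runs. Monte Carlo intervals quoted by those checks
are computed from the run itself, not assumed.

## Known limitations

* The coefficient registry is a constructed stand-in reproducing the
  published marginal distributions, not the (unpublished) generating
  values; exact printed results of the original study's figures are
  therefore not reproducible, only its directional and indifference
  findings.
* The weighted-model (WM) posterior draw uses the model-based
  covariance of the weighted fit; a sandwich-based draw is a plausible
  alternative and a worthwhile sensitivity analysis.
* MVNI's joint-normal assumption is formally misspecified for binary
  covariates; that is intrinsic to the method under study, not a defect
  of the implementation.
* The by-design missing exposure is handled by weighting only;
  imputing it, survival-type designs with time-varying weights, and
  missingness in outcome or exposure are out of scope.
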