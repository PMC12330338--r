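---
title: "Bootstrap-then-impute internal validation: models, mechanisms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap-then-impute internal validation: models, mechanisms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivalid)
```

## The procedure in one paragraph

Given a single cohort with right-censored survival outcomes and covariates
that are missing at random, `bivalid` develops a Cox proportional-hazards
risk model and internally validates it by bootstrapping the *incomplete*
data: each resample is imputed independently (deterministic regression
imputation, outcome excluded), the model is refit, and its horizon-specific
performance — time-dependent AUC and Brier score at $\tau$ — is measured in
the resample, on the original imputed dataset, and on the out-of-bag rows of
the original imputed dataset. From these, four estimators are assembled:
apparent, Harrell bootstrap-corrected, 0.632 and 0.632+. Bootstrapping
*before* imputation matters: imputing once and resampling the completed data
would leak information from the development step into the validation step.

## Synthetic cohort model

The generator emulates a post-mastectomy breast-cancer cohort. Eleven
covariates are drawn from a multivariate normal with the means and covariance
estimated from that cohort; the eight binary covariates are the latent draws
dichotomized at 0.5 (strictly greater maps to 1). Death times use
inverse-transform sampling from a Weibull proportional-hazards model,

$$t_i = b\left(\frac{-\log u_i}{\exp(\beta'X_i)}\right)^{1/a},
\qquad u_i \sim U(0,1),$$

with shape $a = 1.6$ and scale $b = 122$ years at linear predictor zero, and
$\beta$ the log hazard ratios (0.80, 1.05, 1.25, 1.54, 1.18, 1.45, 1.10,
0.76, 0.64, 1.25, 0.48 on the hazard-ratio scale). Censoring times are
Weibull with shape 2.6 and scale 8.2 years, independent of covariates. Both
Weibulls use the parameterization $S(t) = \exp(-(t/\text{scale})^{\text{shape}})$
— the only one under which the inverse-transform formula is self-consistent
($u = S(t)$ at $\beta'X = 0$); uniforms are drawn on the open interval so
$\log u$ is finite. Observed time is $s_i = \min(t_i, c_i)$ and a tie counts
as a death. Under the defaults roughly 18% of participants die during
follow-up, matching the motivating cohort, and a Cox fit on $n = 50\,000$
generated rows recovers every hazard ratio within 5% relative error.

What the generator does *not* emulate: covariate distributions other than
(thresholded) Gaussian, non-proportional hazards, competing risks, and
covariate-dependent censoring. Tests passing on these data therefore say
nothing about, e.g., robustness to misspecified outcome models.

## The missingness mechanism

Missingness is imposed covariate by covariate through

$$P(M_{ij} = 1) = \mathrm{logistic}\!\left(\gamma_{0j} + \gamma_{1j} M_{ik_j}
 + \gamma_{2j} X_{il_j}\right),$$

where $k_j$ indexes a covariate whose *missingness* drives $j$'s and $l_j$
one whose *value* does ($\gamma_2$ values are fixed constants of the design).
$\gamma_{1j}$ is the log odds ratio implied by the marginal targets
$(\pi_j, \pi_{k_j})$ and their joint target, computed from the 2×2
cross-tabulation $OR = p_{00}p_{11}/(p_{10}p_{01})$; the intercept is the
plug-in solution $\gamma_{0j} = \mathrm{logit}(\pi_j) - \gamma_{1j}
P(M_{ik_j}{=}1) - \gamma_{2j}\bar X_{il_j}$, with $\bar X_{il_j}$ the sample
mean in the cohort being masked and $P(M_{ik_j}{=}1)$ the *target* marginal
of the driver. Because the expectation of a logistic is not the logistic of
the expectation, realized marginals deviate from targets by up to a few
percentage points (about +0.01 at a 5% target with the wide-variance driver
X2); the package asserts 0.03 absolute agreement at $n = 100\,000$ rather
than exactness.

Design choices made where the mechanism description left room:

* Imposition order is the topological order of the driver graph
  (X1, X3, X4, X7, X10, X11), so each driver's missingness indicator exists
  when needed.
* When a driver covariate carries no missingness under the active pattern
  (X5 driving X10, in every pattern), $\gamma_1 := 0$ and
  $P(M_{ik}{=}1) := 0$: the cross-tabulation is degenerate and the term is
  inert.
* Joint targets are looked up by the unordered pair of marginals. The guided
  example fixes the (X3, X4) joint at 0.075 while the simulation grid's
  table gives 0.07 for the (0.15, 0.30) pair; `guided_example_spec()` uses
  0.075 and `build_missingness_spec()` defaults to the grid value, with
  `joint_overrides` to switch.
* Value-drivers (X2, X5, X6, X8, X9) never acquire missingness themselves,
  and outcome columns are untouched, so the mechanism is MAR by
  construction; `impose_missingness()` refuses specs that would mask a
  value-driver.

## Deterministic imputation

One independent GLM per partially missing covariate, fit on the rows where
that covariate is observed: logit link for binary targets, identity for
continuous ones. "All other complete variables" is read as: covariates with
*zero* missing entries in the dataset currently being imputed — independent
(non-sequential) models cannot use partially missing covariates without
their own imputations. The survival outcome is excluded structurally (the
predictor set simply never contains `time` or `event`), which the tests
assert.

Binary missing values are imputed as the predicted *probability* (the
conditional mean), not thresholded to 0/1 — deterministic regression
imputation replaces a missing value with its model-predicted response. A
`threshold_binary` switch exists for sensitivity analysis. The Cox model
downstream accepts fractional values without complaint.

The three imputation scopes evaluate their thresholds on the dataset at hand
(original or resample), not on population targets: `impute_gt10` imputes only
covariates missing in >10% of the rows *of this dataset* and then drops rows
still incomplete; `impute_le2` first drops rows missing three or more
covariates and fits/imputes on the remainder. Rows left incomplete by a
scope are dropped before outcome-model fitting, since a Cox fit needs
complete predictors.

## Horizon metrics

The validated quantities are the time-dependent AUC (cumulative cases,
dynamic controls) and the Brier score at $\tau = 5$ years. The validation
procedure itself does not fix estimator formulas for these metrics;
`bivalid` implements the standard IPCW estimators with reverse Kaplan-Meier
censoring weights, the field's common choice and the one substantive
methodological decision taken from general survival-metrics practice rather
than from the procedure being validated. Cases ($s_i \le \tau$, $\delta_i = 1$) weigh $1/G(s_i^-)$, subjects
at risk past $\tau$ weigh $1/G(\tau)$, subjects censored by $\tau$ weigh 0.
Ties in predicted risk get half credit in the AUC. On uncensored data both
estimators reduce exactly to their binary counterparts, which the tests check
against brute-force pair counting.

Absolute risks come from the Breslow baseline:
$\text{risk}_i = 1 - \exp(-H_0(\tau))^{\exp(lp_i)}$ with the linear predictor
centered at the fitting-data covariate means. The Cox fit uses Breslow tie
handling so that baseline is the exact partial-likelihood companion;
simulated times are continuous, making this numerically identical to Efron.

A fit "fails" when: fewer complete rows than covariates plus two, zero
events, a singular design (`NA` coefficients), or the partial-likelihood
optimizer reports non-convergence or a monotone likelihood ("coefficient may
be infinite"). Failures are structured conditions, counted by the simulation
machinery rather than aborting it. An events-per-variable floor was
deliberately *not* added: with the sparsest missingness pattern at $n = 750$
the median complete-case subset has ~8 events for 11 covariates, yet a
majority of such fits converge, and failing them wholesale would roughly
double the complete-case failure rate relative to what the optimizer itself
reports.

## Estimators and numerical choices

With apparent performance $A$, per-resample in-sample performance $P_b$,
performance of resample $b$'s model on the original imputed data $Q_b$, and
mean out-of-bag performance $\bar T$:

* Harrell: $A - \overline{(P_b - Q_b)}$.
* 0.632: $0.368\,A + 0.632\,\bar T$.
* 0.632+: $R = (\bar T - A)/(N - A)$ with no-information value $N$ (0.5 for
  AUC, 0.25 for Brier), clamped to $[0, 1]$; $w = 0.632/(1 - 0.368 R)$;
  estimate $(1-w)A + w\bar T$. Clamping keeps $w \in [0.632, 1]$ and the
  estimate between $A$ and $\bar T$ in boundary cases the formulas do not
  otherwise cover. Identical arithmetic is applied to both metrics.

Out-of-bag evaluation uses rows of the *original imputed dataset* absent
from the resample (mapped through any rows the strategy dropped). Strategy
filtering and imputation are applied independently inside each resample, so
dropped-row counts differ across resamples. Resamples whose fit fails are
excluded from all averages and counted in the report.

## Simulation study

`run_single_sim()` pairs a full-data reference with each missing-data
approach on the *same* generated cohort, so bias — full-data value minus
approach value, estimator matched against the same estimator — isolates the
missing-data handling. Individual prediction bias averages predicted 5-year
survival on the complementary log-log scale, $\log(-\log p)$ (clipped to
$[10^{-12}, 1-10^{-12}]$), back-transforms, and differences the two
averages; for complete-case arms the approach average necessarily runs over
complete cases only, since no predictions exist for incomplete rows. One
master seed spawns independent per-replicate seeds, keeping arms paired and
runs order-independent.

The guided example assumes $n = 3500$ (the motivating dataset has 3532
patients and the simulation grid uses 750/3500; the larger value matches the
printed performance closely). Study scale is 1000 replicates × 500
bootstraps; package defaults are desk-scale (`n_sim = 200`, `B = 100`), and
the test suite exercises the directional findings at `n_sim = 20`,
`B = 15` for patterns E and H — sizes chosen so the full suite completes in
minutes while the complete-case-versus-imputation ordering, which is large
relative to its Monte Carlo noise, remains decisive. The acceptance script
runs the guided example at the full $B = 500$.

## Known limitations

* The intercept equation is plug-in, not iteratively calibrated, so realized
  missingness marginals carry a small systematic deviation from their
  targets (documented above and bounded in tests).
* Deterministic imputation is biased under MNAR mechanisms; nothing here
  addresses outcome-dependent or self-dependent missingness.
* No multiple imputation, sequential/chained imputation, competing risks,
  calibration curves, or external validation; the metrics are
  horizon-specific, not global concordance.
* The published guided-example values do not pin down which specific
  time-dependent AUC estimator produced them (conservative versus
  inverse-weighted control weighting differ slightly); the reproduction
  tolerances (±0.02 AUC, ±0.01 Brier) absorb that estimator-choice
  difference.
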