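---
title: "Methods: censored-normal trajectory modeling of ICF disability scores"
author: "icftraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censored-normal trajectory modeling of ICF disability scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icftraj)
```

## The instrument and its score

The package analyses a 20-item disability assessment instrument drawn
from the ICF framework. Items span three functional areas — self-care and
activities (11 items: walking, moving around, exercise tolerance,
defecation, urination, toileting, daily routine, washing, caring for body
parts, dressing, eating), cognition and perception (5 items: orientation,
memory, seeing, hearing, interpersonal interactions) and emotion and
spirit (4 items: energy/drive, emotional functions, pain, sleep). Each is
scored 0–10 on a numerical rating scale (0 = no problem), the four
somatic items self-reported and the rest observer-rated, so the total
score lies on 0–200 with higher values meaning worse function. Assessments
are collected at admission and then fortnightly until the episode ends;
the package treats the last available assessment as the endpoint
regardless of why the episode ended (discharge, referral, death, end of
study), because the inclusion rules define a single endpoint notion.

Item-level summaries (`item_cohort_summary()`) count dysfunction as an
admission score strictly greater than 0 and improvement as an endpoint
score strictly below the admission score (ties are "no improvement").
Score means are taken over **all** patients, not only the dysfunctional
ones: under that convention the improvement rate equals the mean
improvement divided by the mean admission score, which is the only
convention consistent with the rates such instruments report; the
percentage improved, by contrast, is taken over the dysfunctional
patients. Both choices are deliberate and fixed.

## The trajectory model

`gbtm()` fits a finite mixture of polynomial trajectories with a
censored-normal (CNORM) outcome: conditional on latent group $k$, the
latent score is normal about the group's polynomial in scaled time, and
the observed score is that latent value censored to the instrument scale.
For observation $y_{it}$ at scaled time $t = \text{day}/100$:

$$\log L = \sum_i \log \sum_k \pi_k \prod_t f_{\text{cnorm}}(y_{it} \mid
x_{it}'\beta_k, \sigma),$$

where $f_{\text{cnorm}}$ is the normal density in the interior of the
scale, $\Phi((s_{\min}-\mu)/\sigma)$ at the floor and
$1-\Phi((s_{\max}-\mu)/\sigma)$ at the ceiling. Assumptions worth
stating: observations are independent over time given group (no
within-patient serial correlation beyond the shared curve), the residual
SD $\sigma$ is shared across groups and time, and group membership does
not depend on covariates (covariates are analysed downstream instead).

Key parameters and defaults:

* `bounds = c(0, 200)` — the censoring limits default to the instrument's
  scale ends, the standard CNORM convention; no other limits are implied
  by the instrument.
* `orders = 2` — quadratic curves for every group by default (orders 0–3
  are available per group). Recovery-then-plateau shapes are captured well
  by quadratics, and the source analysis reports no orders.
* `time_scale = 100` — time enters as days/100 purely to condition the
  optimisation; `coef(fit, scale = "day")` returns per-day coefficients.
* `shared sigma` — one residual SD, on the total-score scale (points).
* BIC is reported as $\log L - \tfrac12 k \ln N_{\text{subjects}}$, a
  negative number where "closer to 0" is better; the subject-count
  convention matches the magnitudes that trajectory-model reports quote,
  and the observation-count variant is also stored (`bic_obs`).

### Numerical strategy

The EM E-step computes posterior membership via log-sum-exp. The M-step
updates $\pi_k$ in closed form; for $(\beta, \sigma)$ it uses
posterior-weighted least squares (the exact maximiser) whenever no
observation sits at a bound, and otherwise a warm-started BFGS ascent of
the weighted censored-normal objective with analytic gradients (inverse
Mills ratios evaluated on the log scale). Because the M-step never moves
to a point worse than its warm start, the algorithm is a generalised EM
and the observed-data log-likelihood is non-decreasing — asserted per
iteration in the tests. Convergence is declared at relative
log-likelihood change below `1e-8` or 500 iterations.

Initialisation is a quantile split of per-patient mean scores into K
blocks, plus `n_starts − 1` seeded perturbations that randomly reassign
20% of patients; all starts are deterministic given `seed`, and the best
local optimum is kept. Heavy ties in patient means fall back to a
rank-based split. Fitted groups are relabelled in increasing order of
day-0 mean so "group 1" is always the mildest trajectory — this also
makes fits invariant (up to numerical tolerance) to patient order.
Posterior ties in assignment break toward the lower group index. A group
attracting less than one patient-equivalent of posterior mass sets a
`degenerate` flag.

### Model selection

`select_gbtm()` applies the conventional three-part rule: admissibility
requires every group's average posterior probability of assignment
(Avepp) above 0.7 and every group share at least 5%; among admissible
candidates the BIC closest to 0 wins; if nothing is admissible the
best-BIC candidate is returned flagged. Empty groups yield an `NA` Avepp
rather than a silent pass.

## Group comparisons and ordinal regression

Univariate comparisons (`compare_groups()`) follow the usual rule for
sparse epidemiological tables: Pearson χ² (no continuity correction)
unless some expected cell count falls below 5, in which case a
Fisher-type exact r×c test is used. The exact test enumerates every table
consistent with the observed margins — their multivariate hypergeometric
probabilities must total 1, which the tests assert — and sums the
probabilities of tables no more probable than the observed one; above an
enumeration budget it falls back to Monte-Carlo sampling of the
conditional null (Patefield's algorithm) with a reported standard error.
Continuous covariates use one-way ANOVA (age-like, approximately normal)
or Kruskal–Wallis with midrank tie correction (skewed durations). All
p-values are two-sided.

`ordinal_logit_fit()` fits the cumulative-logit proportional-odds model
with the link oriented so a positive coefficient means greater odds of a
*more severe* trajectory group. Per term it reports the Wald
χ² $(\beta/SE)^2$ and the odds ratio $e^\beta$ with Wald interval; at
model level the LR χ² against the intercept-only fit, a parallel-lines
test (LR of the proportional-odds fit against the level-specific-slopes
baseline-category model, df = the parameter-count difference — reporting
conventions for this df vary, so it is stated alongside), and deviance
and Pearson goodness-of-fit over distinct covariate patterns (cells with
essentially zero expectation excluded). A 4-level outcome has three
thresholds; all three are reported rather than a single "intercept".
Quasi-separation — a covariate level observed only in the extreme groups,
which in practice produces astronomically large odds ratios — is
detected (|β| > 15 or SE > 50) and the coefficient reported capped at
|β| = 15 with a flag, since its Wald statistic is meaningless.

## Cost-effectiveness indices

All four indices are ratios of **group means**: daily cost = mean
cost / mean length of stay; effect index = 100 × mean improvement / mean
admission score (%); efficiency index = effect index / mean LOS (% per
day); benefit index = mean cost / mean improvement (currency per point).
The ratio-of-means convention is what per-group summary tables in this
literature tabulate; `per_patient = TRUE` switches to means of
per-patient ratios for sensitivity analysis. Currency is treated as
opaque; there is no discounting. A group with zero mean improvement has
an undefined benefit index (`NA` with a warning), not an infinite one.

## The synthetic cohort generator

No patient-level data accompany the motivating study, so
`default_cohort_config()` encodes its reported structure as a generative
model and every downstream stage is tested against cohorts drawn from it:

* group shares (0.1789, 0.3579, 0.2737, 0.1895);
* quadratic mean curves in days/100 anchored to the reported recovery
  narratives: (25, −19.1, 0), (61, −41.93, 15), (88, −37.14, 7.14),
  (116, −38.17, 8.2) — i.e. ≈25→12 over 68 days with a steady rate,
  ≈61→35 over 93 days fastest in the first 60, ≈88→58 by day 100 then
  →40 by day 280, and ≈116→82 by day 120 then ≈72 by day 210;
* residual SD 10 points — not reported by the study; chosen once as a
  realistic within-group residual given reported between-patient SDs of
  ≈13 within groups, and not revisited;
* lengths of stay from log-normals matched to the reported per-group
  means/SDs (31.9/18.1, 49.4/27.6, 87.6/74.0, 88.9/49.4 days), truncated
  at 14 days so every patient has the required two assessments;
* costs = LOS × per-group daily cost (484.73, 531.28, 546.12, 633.53)
  × log-normal noise with cv 0.25;
* covariates drawn per group from the reported frequencies (dysphagia,
  urine bag/diaper use, assistive-device need, cognitive impairment,
  surgery, education, hemiplegic side, ...), ages from per-group normals,
  disease course from log-normals matched to the reported median and
  quartiles. Covariates are **independent given group** — the study
  reports only margins, so the joint dependence structure is assumed,
  and any analysis sensitive to covariate correlations within group is
  outside what these simulations can validate.

Item scores are apportioned from the simulated total with a fixed weight
vector proportional to the instrument's admission-score profile
(largest-remainder rounding under the per-item 0–10 clamp, overflow
redistributed greedily), which preserves the total exactly while giving
the instrument module realistic item-level variation. The generator does
**not** emulate: death/referral processes, item-level longitudinal
correlation beyond the shared total, measurement drift, or seasonal
admission effects. Passing tests therefore demonstrate correctness of the
algorithms under the stated generative assumptions, not fidelity of any
particular clinical claim on real cohorts.

Reproducibility: a master seed draws per-patient sub-seeds, so cohorts
are byte-identical across runs of the same seed and patients are
re-generable independently.

## Test problem sizes

The simulation-based checks use the cohort sizes the package's own
defaults target: parameter recovery and model selection run on n = 1000
patients (about 5,000 assessments) over 5 and 10 seeds respectively,
where group shares recover within ±4 percentage points and day-0 means
within ±5 points of the generating values, and the selection rule must
pick 4 groups in at least 8 of 10 seeds; ordinal-coefficient recovery
uses 100 replicates at n = 2000 with four binary risk-factor predictors
(prevalences 0.50/0.30/0.40/0.25, coefficients 0.8/−0.5/0.6/−0.4),
binary because the membership model's covariates are binary flags and
Wald intervals for binary predictors are well calibrated at this size.
Unit tests use small cohorts (tens of patients) throughout.

## Known limitations

* No covariate-dependent group membership (the two-stage
  classify-then-regress approach ignores classification uncertainty).
* No serial correlation or dropout/missingness model; the censored-normal
  independence-given-group likelihood is taken at face value.
* Wald intervals for quasi-separated ordinal terms are reported capped
  and flagged rather than replaced by penalised or exact alternatives.
* The parallel-lines test's df follows the parameter-count difference of
  the two fitted models; published reports sometimes use other
  conventions, so only the statistic's construction — not its printed
  df — should be compared across sources.
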