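# icftraj

Trajectory and cost-effectiveness analysis of longitudinal disability
scores from a 20-item ICF-based assessment instrument.

## The problem

Inpatient stroke rehabilitation produces repeated functional assessments:
here, a 20-item instrument derived from the WHO International
Classification of Functioning, Disability and Health (ICF), each item
scored 0–10 on a numerical rating scale (0 = no problem, 10 = complete
dysfunction), giving a total disability score on 0–200 where higher is
worse. Patients enter with very different functional status and recover at
very different rates, so a single mean recovery curve is misleading.
`icftraj` is for rehabilitation researchers and biostatisticians who want
to (i) identify latent recovery-trajectory subgroups from such scores,
(ii) find the admission covariates that predict membership in a more
severe trajectory, and (iii) compare the cost-effectiveness of
rehabilitation across subgroups.

## The model

The core is a censored-normal group-based trajectory model (GBTM). With
`Y_it` the total score of patient `i` at time `t` (days since admission,
internally rescaled to `t/100`), the model assumes K latent groups with
mixing proportions `π_k` and polynomial mean curves:

    Y*_it | k  ~  Normal( β_k0 + β_k1 t + β_k2 t² , σ² )
    Y_it  =  min(max(Y*_it, 0), 200)          (censoring at the scale ends)

    L  =  Σ_i log Σ_k π_k Π_t f_cnorm( y_it | x_it'β_k , σ )

`gbtm()` maximises this likelihood by EM (closed-form weighted
least-squares M-step away from the bounds, quasi-Newton Tobit updates
otherwise; the observed-data log-likelihood is non-decreasing every
iteration) and returns a classed fit with `print`, `summary`, `coef`,
`predict`, `plot`, `simulate`, `residuals` and `logLik` methods. The
number of groups is chosen by `select_gbtm()` with the conventional rule:
every group's average posterior probability of assignment (Avepp) > 0.7,
every group holding ≥ 5% of patients, and among admissible candidates the
BIC — reported as `logL − 0.5·k·ln(N_subjects)`, a negative number —
closest to 0.

Around the model sit: item-level dysfunction/improvement summaries
(`item_cohort_summary()`); trajectory-group comparisons — Pearson χ²,
exact r×c tests by full enumeration or Monte Carlo, one-way ANOVA,
Kruskal–Wallis (`compare_groups()`) — and a proportional-odds ordinal
regression of group membership with Wald, likelihood-ratio,
parallel-lines and goodness-of-fit statistics (`ordinal_logit_fit()`);
and per-group cost-effectiveness indices (`group_cost_table()`):

    daily cost        = mean cost / mean LOS
    effect index      = 100 · mean improvement / mean admission score   (%)
    efficiency index  = effect index / mean LOS                        (%/day)
    benefit index     = mean cost / mean improvement        (yuan per point)

Because no patient-level data are deposited for the motivating study, a
synthetic-cohort generator (`simulate_cohort()`,
`default_cohort_config()`) reproduces its reported structure — four
groups with shares 17.89/35.79/27.37/18.95%, admission means ≈
25/61/88/116, fortnightly assessments, group-specific lengths of stay,
costs and covariate frequencies — so the entire pipeline is testable.

## Worked example

```r
library(icftraj)

cfg    <- default_cohort_config(n_patients = 95)
cohort <- simulate_cohort(cfg, seed = 20)

fit <- gbtm(total ~ day | patient_id, cohort$assessments,
            ngroups = 4, n_starts = 2, seed = 20)
print(fit)
#> Censored-normal group-based trajectory model
#>    4 groups, 95 patients, 468 assessments
#>   log-likelihood: -1851.007   BIC: -1887.438
#>   sigma: 9.709
#>        share    pi avepp mean_day0
#> group1 0.158 0.158 0.999      27.4
#> group2 0.389 0.386 0.990      61.5
#> group3 0.295 0.298 0.997      87.9
#> group4 0.158 0.159 1.000     114.1
```

Each row is one latent trajectory: `share` is the fraction of patients
assigned to it, `avepp` the average posterior probability of those
assignments (all ≫ 0.7, i.e. clean separation), and `mean_day0` the
fitted admission-day mean total score — the mild (~27), moderate (~61),
severe (~88) and extremely severe (~114) trajectories. Costs per group:

```r
assign <- predict(fit, type = "class")
group_cost_table(cohort$assessments, cohort$episodes, assign)
#>   group  n admission_mean improvement los_mean daily_cost effect_index
#> 1     1 15          27.00        7.27    42.93     471.94        26.91
#> 2     2 37          61.76       16.84    51.68     532.76        27.26
#> 3     3 28          86.64       18.64    78.96     519.84        21.52
#> 4     4 15         115.60       21.53    74.73     636.92        18.63
#>   efficiency_index benefit_index
#> 1             0.63       2788.35
#> 2             0.53       1635.06
#> 3             0.27       2201.84
#> 4             0.25       2210.50
```

so e.g. the severest group improves 18.6% of its admission deficit at
0.25% per hospital day, and every 1-point improvement costs ≈ 2,210 yuan.
`run_pipeline()` chains all stages (validation, item summaries, model
selection, group comparisons, ordinal regression, cost table) and writes
each as CSV with a checksummed manifest; `plot(fit)` draws the fitted
curves over the observed trajectories.

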