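# todclock

Biological-clock-based estimation of the time of death from cardiac
clock-gene expression.

## The problem

Classical forensic methods (body cooling, rigor mortis, corneal opacity)
estimate the time *since* death and depend strongly on the environment of
the corpse. The circadian clock offers a complementary signal: the core
clock genes *BMAL1* (*ARNTL*) and *NR1D1* (Rev-Erbα) oscillate in
antiphase in peripheral tissues, and their expression is frozen at the
moment of death. The ratio of the two genes in heart tissue,

- **N/B** = *NR1D1* / *BMAL1*, peaking around **6:00**, and
- **B/N** = *BMAL1* / *NR1D1*, peaking around **18:00**,

amplifies the oscillation of each gene and cancels any common
normalization factor (reference gene, RNA input, uniform postmortem
degradation). High N/B indicates a morning death; high B/N an evening
death. Fixed thresholds turn the ratios into predicted clock-time
windows:

| rule | window |
|------|--------|
| N/B > 25 | death between 1:00 and 10:00 |
| N/B > 40 | death between 3:00 and 9:00 |
| B/N > 1.5 | death between 14:00 and 22:00 |
| B/N > 4 | death between 15:00 and 20:00 |

Low ratios make *no* statement — they never exclude a morning or evening
death.

`todclock` implements this method end-to-end for forensic statisticians
and method developers: quantification from expression or Ct values,
assignment to the four 6-h time domains (morning 3:00–8:59, noon
9:00–14:59, evening 15:00–20:59, night 21:00–2:59), per-domain mean ± SEM
summaries with Scheffé post-hoc multiple comparisons and unpaired Student
t-tests, subgroup analyses (sex, age group, postmortem-interval group,
cause of death, acute vs chronic brain injury), and the threshold
classifier with yield/coverage evaluation. Because the underlying autopsy
data are not publicly deposited, the package ships a seeded
synthetic-cohort generator — a log-scale cosinor model of the two genes
with the documented cohort composition (318 cases, 224 male / 94 female,
mean age 58.7 y, mean PMI 22.3 h, the published cause-of-death mix) — so
every analysis is testable end to end.

## Worked example

```r
library(todclock)

cfg    <- cohort_config(n_cases = 318, seed = 7)  # defaults = study conditions
cohort <- generate_cohort(cfg)
q      <- quantify_cohort(cohort)                 # adds nb_ratio, bn_ratio, time_domain

domain_summary(q, "nb")
#>    domain   n  mean  sem
#> 1 morning  72 41.00 4.87
#> 2    noon  82 10.97 2.24
#> 3 evening 101  4.98 1.26
#> 4   night  63  8.81 1.99
```

The N/B ratio is highest in the morning domain (mean ± SEM 41.0 ± 4.9
versus 5.0–11.0 elsewhere). Scheffé comparisons confirm the morning peak:

```r
scheffe_pairwise(split(q$nb_ratio, factor(q$time_domain, levels = time_domains())))
#>   group_i group_j statistic  p_value significance
#> 1 morning    noon    58.379 1.35e-11       p<0.01
#> 2 morning evening    92.129 1.96e-17       p<0.01
#> 3 morning   night    58.800 1.13e-11       p<0.01
#> 4    noon evening     2.749 4.33e-01           ns
#> 5    noon   night     0.281 9.63e-01           ns
#> 6 evening   night     0.963 8.10e-01           ns
```

Morning differs from every other domain at p < 0.01; the non-peak domains
do not differ from each other. Applying the decision rules:

```r
ev <- evaluate_predictions(q)
#> predicted 133/318 (41.8%), coverage 0.82
```

133 cases exceed some threshold and receive a time window; 82% of those
windows contain the true time of death. Coverage is below 1 in the
simulation because 15% of synthetic cases are "arrhythmic" (uniform
personal clock phase, the shift-worker mechanism); such cases can exceed
a threshold at the wrong time of day. The whole pipeline — simulate or
ingest, quantify, group statistics, classify — runs as one call:

```r
run_pipeline(pipeline_config(simulate = cfg, output_dir = "run1"))
```

writing `quantified.csv`, `domain_summaries.csv`, `comparisons.csv`,
`predictions.csv`, `evaluation.json`, a log, and a manifest from which
the run is fully reproducible. A thin command-line wrapper is installed
at `inst/scripts/todclock.R`.

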