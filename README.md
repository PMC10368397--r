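# onearmtte

Design, analysis and simulation of **single-arm time-to-event trials with
joint non-inferiority (NI) and superiority objectives**, for statisticians
planning proof-of-concept or de-escalation studies in oncology where a
randomized comparison is not feasible and a historical control anchors the
hypotheses.

The package implements, end to end:

- **Fixed-margin NI margin.** From the historical active-vs-placebo hazard
  ratio's CI lower bound *L* and a retention fraction *f*:
  NIM = *L*^(1−*f*). The NI null is the control median divided by the NIM
  (equivalently the control hazard multiplied by it).
- **Exponential sample size** under uniform accrual, minimum follow-up and
  dropout: required events
  d = (z₁₋α + z₁₋β)² / (ln HR)², per-patient event probability
  P = 1 − e^(−λf)(1 − e^(−λa))/(λa), patients n = ⌈d / P / (1 − r)⌉.
- **Final analysis** by the one-sample exponential ML test,
  z = √d (ln λ₀ − ln λ̂), p = 1 − Φ(z), applied hierarchically: NI first,
  then superiority at the same unadjusted α; conclusions rank as
  *superior* > *non-inferior only* > *inconclusive*.
- **A nonparametric path**: the same ranked decision from the Kaplan–Meier
  median CI lower bound against the two thresholds.
- **Monte Carlo operating characteristics** from a patient-level trial
  simulator (uniform accrual, exponential events and dropout,
  administrative censoring), with reproducible per-replicate RNG streams.

## Worked example

A standard therapy gives a median progression-free survival of 12 months;
we want to detect an improvement to 18 months with 90% power at one-sided
α = 0.10, accruing for 12 months, following up 24 months, expecting 10%
dropout, with an NI margin from a historical HR of 2.4 (95% CI 1.44–3.56):

```r
library(onearmtte)
nim <- fixed_margin_nim(historical_effect(2.4, 1.44, 3.56, retention = 0.5))
design <- onearm_design(control = surv_summary(median = 12),
                        alternative = surv_summary(median = 18),
                        alpha = 0.1, sided = "one", power = 0.9,
                        accrual = 12, followup = 24, dropout_rate = 0.1,
                        nim = nim)
design
#> Single-arm exponential time-to-event design
#>
#>   control:       median 12 months (hazard 0.0578/month)
#>   alternative:   median 18 months (hazard 0.0385/month)
#>   hazard ratio:  0.667
#>   alpha:         0.1 (one-sided), power 0.9
#>   accrual 12 m, follow-up 24 m, dropout 10%
#>
#>   required events:    39.96 -> 40
#>   P(event):           0.682
#>   patients:           58.6 -> 65.1 after dropout -> 66
#>
#>   NIM 1.2: NI null median 10 m (hazard 0.0693/month)
#>   superiority null median 12 m (hazard 0.0578/month)
```

So the trial needs 40 events, which (each patient having a 68.2% chance of
an observed event) takes 66 patients after dropout inflation. Suppose the
trial ends with 54 events and a fitted median of exactly 12 months:

```r
fit <- onearm_fit(rep(12 / log(2), 54))   # 54 events, median 12
dual_test(fit, control = surv_summary(median = 12), nim = nim, alpha = 0.1)
#> Hierarchical NI/superiority decision (alpha = 0.1, NIM = 1.2)
#>
#>   non-inferiority: p = 0.09016 (null median 10 m)
#>   superiority:     p = 0.5 (null median 12 m)
#>
#>   conclusion: non_inferior_only
```

The NI null (median ≤ 10 months) is rejected (p = 0.090 < 0.1) but the
superiority null (median ≤ 12) is not (p = 0.5), so the treatment is
declared non-inferior to — but not better than — the historical control:
exactly the kind of graded conclusion this design exists to deliver.

Real data enter as vectors, as `Surv(time, event) ~ 1` formulas, or as CSV
through `read_trial_data()`; `km_decision()` gives the nonparametric
version of the same decision.

## Command-line interface

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "onearmtte", package = "onearmtte"))')
Rscript $CLI design --mpfs0 12 --mpfs1 18 --alpha 0.1 --power 0.9 \
        --accrual 12 --followup 24 --dropout 0.1 --nim 1.2 --out design.json
Rscript $CLI simulate --config design.json --replicates 10000 --seed 1
Rscript $CLI analyze --data patients.csv --mpfs0 12 --nim 1.2 --alpha 0.1
```

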