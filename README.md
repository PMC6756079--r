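# medcoi

Monte Carlo cost-of-illness modelling of Mediterranean-diet adherence
and cardiovascular disease (CVD) costs in the United States and Canada.

## What it does

Close to US$400 billion and Can$14 billion are spent each year on CVD
management. `medcoi` estimates how much of that would be saved if more
of the population ate a Mediterranean-style diet (MedDiet), propagating
the uncertainty in published risk estimates instead of reporting only
best/worst-case scenarios. It reproduces a published three-step
analysis:

1. **Adherence.** Cohort studies report the share of people in low /
   medium / high MedDiet-score tertiles. Their unweighted average is
   the baseline distribution; scenarios shift $f_{LM}$ percentage
   points of the population low→medium and $f_{MH}$ medium→high
   (bundled: a 20% increase, $f_{LM}=9.3, f_{MH}=18.8$, and an 80%
   increase, $f_{LM}=35.5, f_{MH}=48.3$).
2. **Risk.** Five cohorts report hazard ratios / relative risks of CVD
   for higher adherence. The risk ratio is sampled 10,000 times from a
   study-level mixture: pick a study with weight $w_i$, then draw
   $\mathrm{RR} \sim N(\mathrm{RR}_i, \mathrm{SE}_i)$ with
   $\mathrm{SE}_i$ derived from the 95% CI as
   $(\mathrm{upper}-\mathrm{lower})/(2 \times 1.96)$. The mean
   high-vs-low reduction $1-\mathrm{RR}$ is 25%.
3. **Costs.** Per-draw incidence reductions $R_i$ scale the 2017 cost
   tables: short-term savings are
   $C_c \times R_i \times v_c$ per category ($v_c$ = short-run variable
   share, 0.165 for hospital-type costs, 1 otherwise); long-term
   savings treat all costs as variable and discount ten years of
   CPI-growing savings at 1.8%,
   $C_{tot} \times R_i \times \sum_{t=0}^{10}((1+g)/(1+d))^t$.

Results are Monte Carlo means with 2.5/97.5 percentile intervals. See
`vignettes/meddiet-cost-model.Rmd` for the model's assumptions,
calibration and known limitations.

## Worked example

```r
library(medcoi)
fit <- meddiet_coi(seed = 42)   # bundled tables, 10,000 draws
fit
#> Mediterranean-diet cost-of-illness model
#>   10000 Monte Carlo draws (seed 42), equal study weights, raw scale, select mode
#> Adherence tertiles (% of population): low 36.2, medium 36.5, high 27.3
#>   Mean low-to-high CVD reduction: 24.9% (sd 8.7 pp)
#>   20% scenario, United States: annual savings US$ 8.18 billion (95% CI 2.25-13.38), 2.2% of total CVD cost
#>   20% scenario, Canada: annual savings Can$ 317.11 million (95% CI 87.34-518.46), 2.2% of total CVD cost
#>   80% scenario, United States: annual savings US$ 31.01 billion (95% CI 8.54-50.70), 8.4% of total CVD cost
#>   80% scenario, Canada: annual savings Can$ 1201.46 million (95% CI 330.89-1964.30), 8.4% of total CVD cost
```

A 20% adherence increase saves about US$8.2 billion a year (2.2% of
total US CVD costs); 80% saves about US$31 billion (8.4%). Per-category
tables:

```r
fit$results[["20%"]]$us$short
#> Short-term CVD cost savings, United States, scenario 20% (US$ billion)
#>                                             category     kind mean ci_low ci_high
#>                             Hospital inpatient stays   direct 0.59   0.16    0.97
#>                       Hospital emergency room visits   direct 0.07   0.02    0.11
#>  Hospital outpatient or office-based provider visits   direct 0.30   0.08    0.49
#>                                      Home healthcare   direct 0.78   0.21    1.27
#>                                 Prescribed medicines   direct 1.28   0.35    2.09
#>                          Lost productivity/mortality indirect 5.17   1.42    8.45
#>                                         Total direct          3.02   0.83    4.93
#>                                       Total indirect          5.17   1.42    8.45
#>                                        Total savings          8.18   2.25   13.38
#> Mean decrease in total 2017 CVD cost: 2.2%
```

The intervals are wider than the published ones: the published
reduction distribution cannot be reconstructed as narrow as described,
so this package reports the intervals its stated construction actually
implies (see the vignette's limitations section). `summary(fit)` prints
all eight scenario/country/horizon tables, `plot(fit)` histograms the
total-savings draws, `simulate(fit)` redraws risk ratios, and
`predict(fit, newdata = <cost_table>)` applies the fitted reductions to
a new cost table.

Whole runs, with CSV/JSON outputs and a text report:

```r
m <- run_pipeline(out_dir = "out", seed = 42)        # bundled inputs
cat(render_report(m), sep = "\n")
```

or from a shell: `Rscript inst/cli/medcoi-run.R run --out-dir out
--seed 42`. Custom or synthetic input sets (same CSV/YAML schemas) are
loaded with `load_model_inputs(dir)` and generated with
`generate_risk_studies()`, `generate_adherence_studies()` and
`generate_cost_table()`.

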