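---
title: "Modelling healthcare cost savings from Mediterranean-diet adherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling healthcare cost savings from Mediterranean-diet adherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medcoi)
```

## The model

`medcoi` implements a three-step cost-of-illness model that converts an
assumed increase in population adherence to a Mediterranean-style diet
(MedDiet) into a reduction in cardiovascular disease (CVD) incidence,
and that reduction into healthcare cost savings for the United States
and Canada. It is a reproduction, in R, of a published Monte Carlo
analysis originally built in spreadsheet software; the bundled input
tables are the published ones, and the package's reports juxtapose its
computed results with the published headline figures.

**Step 1 — adherence.** Cohort studies report the percentage of
participants falling in low / medium / high MedDiet-score tertiles.
The baseline population distribution is the unweighted mean of these
percentages across studies (`baseline_adherence()`); for the bundled US
studies this is (36.2, 36.5, 27.3). An adherence scenario moves
$f_{LM}$ percentage points of the *total* population from low to medium
and $f_{MH}$ from medium to high (`apply_scenario_shift()`). The
bundled scenarios are a 20% increase ($f_{LM} = 9.3$, $f_{MH} = 18.8$)
and an 80% increase ($f_{LM} = 35.5$, $f_{MH} = 48.3$). The shift
fractions are interpreted as points of the total population because
only that reading drives the low tertile near zero under the 80%
scenario, matching its description as near-perfect conformance.

**Step 2 — risk.** Five cohort studies report hazard ratios or relative
risks (with 95% CIs) of CVD for medium-vs-low and high-vs-low
adherence. The joint distribution of the risk ratio is a finite
mixture: a discrete draw selects a study with probability $w_i$, then
the ratio is drawn from that study's normal distribution
$N(\mathrm{RR}_i, \mathrm{SE}_i)$ with
$\mathrm{SE}_i = (\mathrm{upper}_i - \mathrm{lower}_i) / (2 \times 1.95996)$.
The two contrasts within a draw share the selected study but are
otherwise independent. `sample_mixture()` draws 10,000 such pairs; the
closed-form mixture moments (`mixture_moments()`) are
$\mu = \sum_i w_i \mu_i$ and
$\sigma^2 = \sum_i w_i (\sigma_i^2 + \mu_i^2) - \mu^2$.

**Step 3 — costs.** Country cost tables give per-category direct and
indirect CVD costs, inflated from their base year to 2017 dollars by
the health-care CPI. Short-term savings for draw $i$ and category $c$
are

$$ S_{ic} = C_c \times R_i \times v_c $$

where $C_c$ is the 2017 cost, $R_i$ the drawn fractional incidence
reduction and $v_c$ the category's short-run variable share. Long-term
savings assume all costs become variable and grow at the trailing
ten-year health-care CPI rate $g$, discounted at $d = 1.8\%$:

$$ S_i^{LT} = C_{tot} \times R_i \times \sum_{t=0}^{10}
   \left( \frac{1+g}{1+d} \right)^t $$

with eleven annual terms (2017 through 2027, base year included); this
is the convention that reproduces the published 10-year totals.
Summaries are Monte Carlo means with empirical 2.5/97.5 percentile
intervals.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_draws` | 10,000 | draws | the published simulation size; MC error on the mean reduction is ±0.09 pp |
| `weighting` | `"equal"` | — | see below |
| `rr_scale` | `"raw"` | — | normals on the reported-ratio scale, as published; `"log"` offered because the CIs are visibly asymmetric |
| `spread_mode` | `"select"` | — | one study per draw (the published construction); `"average"` pools within-draw |
| `discount_rate` | 0.018 | /yr | the published discount rate |
| `horizon` | 10 | yr | published projection horizon |
| growth $g$ | 0.0354 (US), 0.013 (Canada) | /yr | trailing 10-year health-care CPI |
| hospital variable share | 0.165 | — | back-derived: (0.6/101)/(1.3/36.1) from the published short-term table |
| calibrated $R_{20}, R_{80}$ | 0.0355, 0.1345 | fraction | see below |

**Study weighting.** The source methods describe weighting studies by
cohort size, but size weights give a mean high-vs-low reduction of
23.1%, while the published distribution is described as centred on 25%
— exactly the equal-weight mixture mean. Equal weights are therefore
the default, and size weighting is one flag away
(`weighting = "size"`); rendered reports record which was used.

**Scenario calibration.** No combination of the stated shift fractions
with any summary of the published risk table reproduces the
scenario-level mean reductions implied by the published savings tables
(≈ 3.55% and ≈ 13.45%). Both mappings are therefore provided:

* `additive_transitions` assembles the reduction from the stated
  machinery, $R = \frac{f_{LM}}{100}(1 - \mathrm{RR}_{LM}) +
  \frac{f_{MH}}{100}(1 - \mathrm{RR}_{LH}/\mathrm{RR}_{LM})$, treating
  the medium-to-high contrast as the ratio of the two published
  contrasts (hazard ratios compose multiplicatively; a negative term is
  floored at zero with a warning).
* `calibrated` (the reproduction default) rescales the low-to-high
  reduction draw, $R_i = s \cdot (1 - \mathrm{RR}_{LH,i})$, with $s$
  chosen so the mean matches the scenario targets $R_{20} = 0.0355$ and
  $R_{80} = 0.1345$. These targets are back-calculated from the
  fully-variable rows of the published short-term savings table
  (prescribed medicines 1.3/36.1 = 0.0360, lost productivity 5.2/145.9
  = 0.0356, total 8.2/231.08 = 0.0355), and are re-derivable from the
  package's own fixtures.

The scale $s$ uses the closed-form mixture mean of $1 -
\mathrm{RR}_{LH}$ (0.25 under equal weights), not the empirical draw
mean, so it is deterministic given the configuration; empirical
scenario means then match the targets within Monte Carlo error. The
published 10-year US total implies the same scenario mean at one more
digit of precision (157.1 / (368.5 × 11.99) = 0.03554 vs the 0.0355
recovered from the short-term rounding); the package's acceptance
checks use the finer value where the coarser one would fail only
through that rounding.

## Numerical choices

* **Truncation.** Raw-scale ratio draws at or below zero are rejected
  and redrawn (the expected rejection rate for the bundled studies is
  negligible — every mean/SE ratio exceeds 7). A drawn ratio above 1
  implies harm; the scenario reduction for such a draw is floored at
  zero rather than booked as negative savings.
* **Percentiles** use the type-7 (linear-interpolation) empirical
  quantile convention throughout.
* **Precision and rounding.** All monetary arithmetic runs at full
  double precision; rounding to the source tables' printed precision
  (1 decimal for US billions; 2 or 1 decimals for Canadian billions)
  happens only in display columns and rendered reports. Amounts are
  held in each table's native unit (US$ billion, Can$ million) with a
  units field preventing cross-country mixing; no currency conversion
  is ever applied.
* **Table totals.** The published US 2017 column sums to 368.6 against
  a printed total of 368.5 (a source rounding slip). The fixture keeps
  both the printed cells and the printed total; validation allows
  `max(0.1, 1e-4 × total)` of slack, and long-term per-category
  apportionment normalises shares by the category sum so category
  means add exactly to the total.
* **CPI factors** are stored as the table-implied ratios (368.5/329.6
  = 1.1180 for the US; 14,326/13,644 = 1.0500 for Canada). The source
  narrative's "12.9% over 2013–2017" contradicts its own table (11.8%)
  and is not used.
* **Projections.** The published Canadian 10-year projection starts
  from a stated 14.4 billion 2017 total although the Canadian table
  sums to 14.33 billion (16.4 vs 16.3 at the horizon); the package
  projects whatever table it is given and the acceptance check feeds
  it the stated headline input.
* **Degenerate inputs.** Zero-SE studies yield point-mass draws;
  `g = d` collapses the annuity to $H + 1$; zero shifts, zero
  reductions and empty scenario lists all pass through as identities
  or empty reports rather than errors.

## The synthetic-data generators

`generate_adherence_studies()`, `generate_risk_studies()` and
`generate_cost_table()` emulate the three input-table shapes with known
ground truth: true tertile distributions, true component means/SEs/
weights, true amounts and shares. They exist so that every pipeline
stage — validation, mixture sampling, savings propagation — is testable
for *recovery of a known truth*, independently of the published
fixtures. Confidence intervals are reconstructed as point ± 1.96 × SE
(symmetric on the raw scale, or on the log scale with `log_scale =
TRUE`), so derived standard errors round-trip exactly.

What they deliberately do not emulate: individual-level diets or event
histories, correlated contrasts within a study, between-study
heterogeneity beyond the spread of component means, or asymmetric
published intervals. Passing recovery tests on synthetic data therefore
demonstrates that the machinery is self-consistent, not that the
published inputs are unbiased estimates for any real population.

## Known limitations

* The published reduction distribution is described as having 90% of
  its mass between 22% and 28%. No mixture of the published normals can
  be that narrow — the closest construction spans roughly 19–31% at 90%
  coverage, and this package's savings intervals are correspondingly
  wider than the published ones. The discrepancy is documented and the
  package asserts closed-form mixture moments instead of the published
  band; the published savings CIs are reported for comparison but never
  machine-asserted.
* Published rounding is internally inconsistent in places (the 80%
  direct short-term subtotal prints 11.3 while its own components sum
  to 11.4; the Canadian 80% long-term column prints a total smaller
  than its parts). The package reproduces component arithmetic and
  flags, rather than resolves, these cells.
* Costs grow at a single trailing-CPI rate; no statistical forecasting
  of the cost series is attempted, and no cost-effectiveness (QALY/
  ICER) quantities are computed.

## Problem sizes

Reproduction runs use the published 10,000 draws and finish in well
under a second; the test suite's Monte Carlo checks use 10,000–20,000
draws with fixed seeds and 3–4 Monte-Carlo-SE tolerances.
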