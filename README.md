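# metsmarkov

Multistate Markov modelling of the natural history of metabolic
syndrome (MetS), for epidemiologists and modellers working with
two-wave cohort panels.

MetS is present when at least three of five components co-occur:
abdominal obesity, high triglycerides, low HDL cholesterol, high blood
pressure, high fasting glucose. The package collapses the 32 possible
component combinations into a reversible 8-state discrete-time Markov
chain — *no component*, five *isolated-component* states, a
*2-component* state, and *MetS* — with a one-year cycle and no
absorbing state, and provides:

- **Classification**: sex-specific clinical cutoffs mapping raw
  measurements to component profiles and states
  (`classify_components()`, `component_state()`).
- **Estimation**: annual incidence rates from two-wave panels,
  r<sub>ij</sub> = n<sub>ij</sub>/PY<sub>i</sub>, annualized via
  P = 1 − exp(−rt) into a row-stochastic annual transition matrix
  (`estimate_transition_matrix()` and friends).
- **Projection**: deterministic yearly-cycle occupancy trajectories by
  matrix powering (`project_occupancy()`, `occupancy_at()`).
- **Microsimulation**: individual-level Monte-Carlo cohorts with
  reproducible seed substreams and percentile intervals
  (`simulate_cohort()`, `occupancy_interval()`).
- **Synthetic data**: two-wave panel and raw-measurement generators
  with known ground truth for parameter-recovery testing
  (`generate_panel()`, `generate_measurements()`).
- **Validation**: projected prevalence vs empiric cohort proportions
  with exact binomial intervals (`validate_against_empiric()`).

Published sex-specific annual transition matrices from a five-year
Taiwanese population-based follow-up (2,247 adults aged 18–45) ship as
plain-text fixtures (`mets_fixture_matrix("men")` / `"women"`), with
row renormalization of the rounded printed percentages on load.

## Worked example

```r
library(metsmarkov)

men <- mets_fixture_matrix("men")
traj <- project_occupancy("no_component", men, 15)
out <- traj[traj$year %in% c(1, 5, 10, 15), ]
out[-1] <- round(100 * out[-1], 2)   # occupancy in percent
print(out, row.names = FALSE)
#>  year no_component abdominal_obesity high_tg low_hdl high_bp high_fpg two_components  mets
#>     1        92.90              0.91    1.08    0.74    1.99     0.20           1.73  0.45
#>     5        71.92              3.29    3.71    2.39    6.79     0.76           7.64  3.51
#>    10        56.21              4.67    4.94    3.00    8.90     1.12          12.87  8.29
#>    15        46.77              5.28    5.26    3.08    9.31     1.31          16.32 12.67
```

Starting from no component, a young man has a 12.7% modelled risk of
developing MetS within 15 years and a 16.3% risk of carrying two
components, while only 46.8% remain component-free. Alternative starts
are one call away:

```r
100 * occupancy_at("abdominal_obesity", "mets", men, 15)
#> [1] 24.60563
```

and a microsimulated interval around a projection:

```r
res <- simulate_cohort(men, "no_component", n_individuals = 10000,
                       horizon_years = 15, n_replicates = 200, seed = 42)
occupancy_interval(res, "mets", 15)
#>     lower     upper
#> 0.1199975 0.1337050
```

A thin command-line wrapper with `project`, `simulate`, `generate` and
`validate` subcommands lives at `inst/cli/metsmarkov.R`.

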