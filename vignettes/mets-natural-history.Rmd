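---
title: "Modelling the natural history of metabolic syndrome with a reversible 8-state Markov chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the natural history of metabolic syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsmarkov)
```

## The model

Metabolic syndrome (MetS) is diagnosed when at least three of five
components are present: abdominal obesity, high triglycerides (TG), low
HDL cholesterol, high blood pressure (BP), and high fasting plasma
glucose (FPG).  Tracking all 32 component combinations and their 1,024
transitions is impractical with cohort-sized data, so this package works
on a collapsed, mutually exclusive and collectively exhaustive 8-state
space: *no component*, the five *isolated single-component* states, a
single *2-component* state (any pair), and the *MetS* state (any three
or more components).

Progression is modelled as a discrete-time Markov chain with a one-year
cycle.  The chain is *reversible* in the epidemiological sense: every
state can transition to every other state, components can resolve as
well as accumulate, and there is no absorbing state.  Three assumptions
carry the model:

1. **Markov property** — future progression depends only on the current
   state, with no memory of how it was reached.
2. **Time homogeneity** — the annual transition matrix is constant over
   the projection horizon (transition risks in reality rise with age;
   this is a known limitation, not a feature).
3. **Yearly evolution** — individuals may change state exactly once per
   annual cycle, including out of the MetS state.

Mortality is deliberately excluded: over 15-year horizons in adults
under 50 the competing risk of death is small, but cumulative MetS
incidence is consequently a slight overestimate.

## From panel data to an annual matrix

Two-wave cohort panels record a baseline state, a follow-up state, and
the elapsed interval for each subject.  `count_transitions()` tallies
the 8×8 event counts and origin-state person-years, attributing each
subject's whole interval to their baseline state — with only two waves
nothing is known about intermediate states, so this is the simplest
attribution consistent with an annual incidence rate, and it is
documented as an approximation.  Person-time defaults to the exact
per-subject intervals; a `mean_interval` override supports designs where
only the cohort mean (say 5.4 years) is trusted.

`estimate_rates()` converts counts to annual incidence rates
$r_{ij} = n_{ij} / \mathrm{PY}_i$, and the annualization
$$P_{ij} = 1 - e^{-r_{ij} t}, \qquad t = 1\ \text{year}$$
turns each off-diagonal rate into a one-cycle probability
(`annualize_probability()`).  The diagonal is the residual
$P_{ii} = 1 - \sum_{j \neq i} P_{ij}$, which makes every row sum to 1 by
construction; a row whose competing annualized risks already exceed 1 is
refused rather than silently rescaled, because per-cell annualization is
only coherent when exits from a state are jointly modest.  This per-cell
exponential annualization sidesteps the general embedding problem (no
matrix logarithm of a multi-year empirical matrix is attempted; that is
out of scope by design).

Zero-count cells yield probability 0 by default.  Published tables of
this kind often avoid exact zeros, so `continuity = TRUE` adds 0.5
events to empty cells of observed rows; it is off by default because it
biases small samples and the default should match the plain estimator.
Sex strata are always estimated separately — the two matrices differ
enough that a pooled matrix has no meaning here.

## Published matrices as fixtures

The package bundles the published sex-specific annualized transition
matrices from a five-year Taiwanese population-based follow-up (2,247
adults aged 18–45 at entry, mean follow-up 5.4 years) as plain-text CSV
fixtures, bit-exact to the printed percentages.  Printed rows are
rounded to two decimals and rarely sum to exactly 100, so
`load_printed_matrix()` accepts row sums within 99.5–100.5, renormalizes
each row onto the simplex, and keeps the original row sums for
provenance.  Projection refuses unrenormalized input, so every
trajectory in the package starts from an exactly row-stochastic matrix.

```{r fixtures}
men <- mets_fixture_matrix("men")
round(men$printed_row_sums, 2)
```

## Projection and what it reproduces

`project_occupancy()` is plain matrix powering: the year-$k$ occupancy
row vector is the initial distribution times the $k$-th power of the
annual matrix.  Cycles are whole years and no half-cycle correction is
applied — the published year-1 projections equal the matrix rows
exactly, which is only consistent with uncorrected powering.

```{r project}
traj <- project_occupancy("no_component", men, 15)
round(100 * traj[traj$year %in% c(1, 5, 10, 15), ], 2)
```

Because printed inputs are rounded to two decimals, rounding compounds
over 15 multiplications.  A perturbation estimate (±0.005 pp on every
cell) moves 15-year occupancies by up to a few tenths of a percentage
point, so reproduction checks use ±0.5 pp at years 5–15 while year-1
values are required to match the loaded matrix row to printed precision.
The observed agreement with the published 15-year values is within
0.07 pp everywhere.

## Microsimulation and intervals

`simulate_cohort()` realizes the same chain at the individual level:
each person's next state is a multinomial draw from their current row.
Individuals are exchangeable, so the implementation redistributes the
occupants of each state with one multinomial draw per state per year —
distributionally identical to per-individual draws and far faster.
Replicates rerun the whole cohort on deterministically derived seed
substreams (one master seed in, bit-identical results out, any single
replicate reproducible alone), and `occupancy_interval()` reports
nonparametric percentile intervals across replicates.

The source study printed confidence intervals without stating their
method, so printed bounds are treated as plausibility references only.
Intervals here are instead validated by *coverage*: across 200
simulated replicate-sets under a known matrix, the 95% percentile
interval contains the analytic (matrix-power) occupancy in well over
90% of sets.

## The synthetic-data generator

`generate_panel()` emulates a two-wave cohort with known ground truth:
baseline states drawn from a configurable distribution, follow-up states
drawn from the true annual matrix compounded over
`round(interval_years)` integer cycles (default 5.4 years, a typical
cohort mean; the chain itself is annual, so fractional compounding is
not defined).  Optional per-subject interval jitter exercises exact
person-time handling.  The default baseline distribution is uniform over
the 8 states — chosen once so that every origin row receives roughly
$n/8$ subjects and all 64 cells are estimable; a realistic cohort is far
more concentrated in the no-component state, which simply starves the
rare rows of events.

`generate_measurements()` draws raw clinical values from documented
truncated-normal ranges placed strictly on either side of each clinical
cutoff, with a 0.5-unit guard band, so that classification recovers the
requested state under either boundary convention.  The ranges are
package constants, not fitted to any cohort table.  What the generator
deliberately does *not* emulate: the joint correlation structure among
components (beyond threshold consistency), within-person measurement
drift between waves, and medication-driven abnormality.  Passing
round-trip and recovery tests therefore demonstrates correctness of the
classification and estimation machinery, not realism of the synthetic
measurements.

## Numerical and design choices

* **Cutoff boundaries.** The consensus definition reads as inclusive at
  the numeric cutoffs, so the default is ≥ for TG, BP and FPG, strictly
  below for HDL and strictly above for waist; `boundary = "strict"`
  switches the three inclusive cutoffs to strict for sensitivity
  analyses.  The BP criterion is an OR over systolic ≥ 130 and
  diastolic ≥ 85 (or antihypertensive use); lipid-lowering medication is
  *not* part of the TG/HDL criteria, mirroring the source cohort's data
  collection.
* **Row-stochasticity tolerances.** Constructed matrices must have rows
  summing to 1 within 1e-9; residual-diagonal construction achieves
  1e-12 in practice, and trajectory conservation is asserted at 1e-12
  over 100-year horizons.
* **Validation interval.** Model-vs-cohort consistency uses the exact
  (Clopper–Pearson) binomial interval in its beta-quantile closed form,
  chosen because the empiric CI method of the source cohort is unstated
  and the exact interval is conservative at small counts.
* **Degenerate inputs.** Empty panels return zero tables with a warning;
  origin states with no observations get all-zero rates plus a warning;
  events recorded against zero person-time are an error, as are
  trajectories requested from non-integer horizons or non-simplex
  initial distributions.
* **Problem sizes.** The test suite runs parameter recovery at
  n ∈ {500, 5,000, 50,000} one-year panels, large-cohort agreement at
  n = 100,000 individuals, goodness-of-fit at n = 50,000 subjects over
  5 compounded cycles, coverage at 200 replicate-sets of 30 replicates ×
  400 individuals, and round-trip classification at 250 seeds per
  state × sex.  These sizes make the Monte-Carlo assertions sharp while
  keeping the whole suite under a minute on a laptop.

## Known limitations

Time-homogeneous probabilities understate age effects over long
horizons; person-time attribution to the baseline state biases rates
when intervals are long relative to state sojourns (visible as a small
bias when estimating from 5.4-year panels rather than 1-year panels);
mortality is excluded; and the 2-component state deliberately discards
which pair of components is present, so component-specific pathways
through it are not identifiable.
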