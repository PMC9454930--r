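---
title: "Model and methods of the asbscreen screening analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods of the asbscreen screening analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asbscreen)
```

## Purpose and scope

`asbscreen` evaluates the cost-effectiveness of organised low-dose CT (LDCT)
lung-cancer screening against usual care in populations with past
occupational asbestos exposure. It compares strategies by incremental cost
per quality-adjusted life year (QALY) over a lifetime horizon, with
deterministic base cases, probabilistic sensitivity analysis (PSA), one-way
tornado analyses, scenario grids over eligibility strata / start ages /
screen intervals, and cost-effectiveness acceptability curves (CEACs).

## Model structure

A discrete-time Markov cohort model with 1-year cycles and five states:
`healthy`, `localized` (stage I–II lung cancer), `disseminated`
(stage III–IV), `false_positive`, `dead`.

Structural assumptions:

- **Event ordering within a cycle.** From `healthy`: background death first
  (life-table probability $q_x$); then, among survivors, lung-cancer
  diagnosis with probability $p_{lc} = \min(1, (1 - e^{-r})\,m)$, where $r$
  is the stratum incidence per person-year and $m$ the arm's overdiagnosis
  multiplier; then, among surviving undiagnosed subjects in a screening
  cycle, a false positive at the per-screen rate. The events are mutually
  exclusive, so every row of the transition matrix sums to one for any
  $q_x \in [0,1]$.
- **Cancer states exit only to death.** Cure, progression and cancer death
  are pooled into a single stage-specific exit hazard: the annual death
  probability in a cancer state is $1-(1-q_x)^{HR}$, which is exactly the
  background hazard scaled by $HR$. A "linear" alternative
  ($\min(1, HR\,q_x)$) is available in `lc_death_prob()`.
- **False positives are transient.** A false-positive finding incurs its
  work-up cost in the event cycle and returns to `healthy` after one cycle
  unless background mortality intervenes; in the base case it carries no
  disutility (utility 1.000), which makes its fitted beta distribution a
  boundary case handled as a point mass.
- **Whole-cohort entry at the programme start age.** The reference analyses
  enter the entire cohort at the start age (default 55, the first screen)
  with the both-sex ("total") life-table column, rather than spreading
  entries over the observed age distribution. This convention reproduces the
  reference programme's per-person screen counts, which an age- and
  sex-blended entry cannot; `run_trace()` still accepts an explicit cohort
  tibble when per-profile mixing is wanted.
- **Constant stratum incidence.** The all-ages stratum rate is applied at
  every age by default; age-band rates are available via
  `use_age_bands = TRUE` (bands <60, 60–75, >75, with a documented fallback
  where a band was not observed).

## Screening arms

- **Annual screening**: stage fractions 70.2% localized / 29.8%
  disseminated per diagnosis, overdiagnosis multiplier 1.13, screens (189
  EUR) and false positives (1.2% per screen) every cycle.
- **Biennial screening** is derived from three constants rather than
  asserted: a screen-detected : interval-cancer ratio of 2.8 (from yields of
  7.69 vs 2.76 per 1000 scans), a per-screen detection-yield factor of 1.5,
  and the annual multiplier 1.13. The fraction $2.8/3.8$ of diagnoses
  carries the screening stage split and $1/3.8$ the usual-care split; the
  effective overdiagnosis multiplier is
  $\min(\max(1,\; 1.13 \times 1.5/2),\; 1.13)$, i.e. bounded below by 1
  (a lifetime programme cannot diagnose fewer cancers than arise) and above
  by the annual arm. At the defaults the lower bound binds, so biennial
  screening carries the full stage-shift benefit of its screen-detected
  share with no net overdiagnosis — the model's explanation for why biennial
  ICERs undercut annual ones. Screens and false positives occur on even
  cycles only.
- **Usual care**: no screens, no false positives, usual-care stage
  fractions, multiplier 1.

## Parameters

All defaults are returned by `default_parameters()` and shipped as
`inst/extdata/default_params.yaml`; each uncertain input is a `dist_spec`
(family, deterministic value, low/high bounds read as a 95% interval, so
`se = (high - low)/3.92`, fitted by the method of moments).

| Parameter | Default (low–high) | Units / family |
|---|---|---|
| Stage fraction localized, usual care | 0.181 (0.171–0.191) | normal |
| Stage fraction localized, screening | 0.702 (0.694–0.710) | normal |
| Overdiagnosis hazard ratio | 1.13 | fixed |
| False-positive rate per screen | 0.012 | fixed (0.233 as scenario) |
| Death HR, localized / disseminated | 2.68 / 8.38 | fixed |
| Usual respiratory care | 26 (26–73) | EUR/year, gamma |
| Screening round | 189 (147–232) | EUR, gamma |
| Localized surgery (one-off) | 13,390 (6,337–20,443) | EUR, gamma |
| Post-surgical care | 19,057 (16,770–21,429) | EUR/2 years, gamma |
| Disseminated care | 33,132 (29,357–34,305) | EUR/2 years, gamma |
| False-positive work-up | 2,110 (1,716–2,271) | EUR, gamma |
| Utility healthy / localized / disseminated | 1.0 / 0.825 / 0.573 | beta |
| Utility false positive | 1.000 (0.970–1.000) | beta (point mass) |
| Discount rate | 0.03 | per year, both costs and QALYs |

Stratum lung-cancer incidence per 1000 person-years
(`subgroup_incidence()`): whole cohort 2.30; current smokers 6.04; ever
smokers 2.78; high exposure 2.90; intermediate 2.20; high-exposure smokers
7.07; pleural plaques 2.31; asbestosis 5.00 — with age-band variants where
observed.

In PSA draws, within-arm stage-fraction pairs are renormalized to sum to
one, utilities are clipped to $[0,1]$ and costs to $\ge 0$; fixed parameters
repeat their value. The point estimate reported alongside any PSA is always
the deterministic run and is independent of the seed.

## Life table

Background mortality is a synthetic Gompertz–Makeham period table
($\mu(x) = a + b\,e^{gx}$, closed with $q_{110} = 1$) calibrated so period
life expectancy at 60 is 23.3 / 27.5 / 25.6 years (male / female / total),
approximating French 2019 levels. The both-sex column is the default for
the reference analyses. The table ships as
`inst/extdata/lifetable_fr2019_gm_synthetic.tsv`; `read_life_table()`
accepts any `(age, sex, qx)` table, and the economic results' sensitivity
to the table choice is visible by re-running with a substitute.

## Accounting conventions

Costs and QALYs accrue on start-of-cycle occupancy, discounted by
$(1+0.03)^{-t}$ with $t$ the 0-based cycle index; there is no half-cycle
correction. Event costs (surgery, false-positive work-up) are charged in
the event cycle; per-2-year care costs are annualised (divided by 2) on
state occupancy; the usual-care cost applies to `healthy` occupancy in both
arms; screens are counted on start-of-cycle `healthy` occupancy in
screening cycles.

## Synthetic cohort generator

`generate_cohort()` emulates a post-occupational surveillance cohort
(default n = 14,218): 94.8% male; entry-age bands <60 / 60–75 / >75 at
23.4 / 73.8 / 2.8% (drawn uniformly on 55–59, 60–75, 75–85); exposure
low / intermediate / high at 7.5 / 67.9 / 24.5%; smoking never / former /
current at 30.0 / 61.5 / 8.5%. Attributes are drawn independently across
axes because the economic model consumes stratum-level incidence, not joint
risk profiles. Pleural-plaque (17%) and asbestosis (2%) prevalences are
package defaults from the surveillance literature, not tabulated targets.
`simulate_incidence()` is the generator's parameter-recovery harness:
exponential times to diagnosis at the stratum rate, censored at the
follow-up horizon, with exact Poisson intervals that should cover the input
rate at their nominal level.

## Numerical choices and problem sizes

- The engine is vectorised across PSA draws: a 10,000-draw lifetime run is
  one 56-cycle loop over length-10,000 state vectors (well under a second),
  so the full PSA + CEAC pipeline is desk-scale.
- Occupancy conservation is asserted every cycle at $10^{-6}$; the engine
  is validated against a brute-force path-enumeration oracle on short
  horizons at $10^{-10}$.
- Lifetime horizons run to age 110 (the life table's closure age); finite
  horizons (e.g. 10 cycles) are supported per strategy.

## Decisions on open questions

- **Both-sex life table for the reference analyses** instead of a
  94.8%-male blend: the programme's per-person screen volume and
  false-positive yield are only mutually consistent under the both-sex
  table with whole-cohort entry at the start age, so that convention
  defines the reference runs; sex-specific columns and explicit blends
  (`sex_weights`) remain available.
- **Biennial overdiagnosis floor.** Applying the raw detection-flow ratio
  (1.5 per-screen yield at half the frequency, i.e. 0.75 of the annual
  flow) to the annual multiplier would push the biennial multiplier below
  one — fewer lifetime diagnoses than usual care — which is inconsistent
  with a lifetime horizon; hence the $\max(1,\cdot)$ floor described above.
- **Degenerate beta at a utility of 1.0** is treated as a point mass rather
  than an error, matching the no-disutility base case for false positives.
- **Band fallback** for strata with unobserved old-age incidence uses the
  60–75 band with a warning rather than extrapolating.

## Limitations

- The life table is synthetic: printed-value comparisons inherit its
  approximation, so headline numbers carry tolerance while the structural
  properties (conservation, oracle agreement, monotonicities, null
  intervention) are exact.
- One homogeneous incidence per stratum; no individual risk modelling, no
  correlation between generator axes, no smoking cessation or exposure
  dynamics.
- Cancer states pool cure, progression and death into one exit hazard; no
  explicit treatment pathways or stage migration after diagnosis.
- Costs are payer-perspective unit costs in euro; no productivity losses,
  no cost inflation, single discount rate for costs and effects (scenario
  values available via `set_parameters()`).
- Overdiagnosis is a constant incidence multiplier, not a modelled reservoir
  of indolent disease.

This vignette states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` compute from the model itself.
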