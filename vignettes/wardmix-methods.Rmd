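---
title: "Methods: colocation contact networks and patient mixing matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colocation contact networks and patient mixing matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wardmix)
```

## The estimand

`wardmix` treats patient-to-patient exposure in hospitals as a
*colocation* process: two admissions recorded in the same unit on the
same calendar day are assumed to be in contact for that day, whether
directly or mediated by staff, instruments, or the environment. This is
the central modelling assumption, and its two corollaries shape
everything downstream:

* a unit-day with *k* patients contributes all `choose(k, 2)` pairwise
  contacts — contact opportunity scales quadratically with census;
* a patient present for *d* days contributes on *d* days — repeated
  contacts add linearly, so contact weight is length-of-stay (LOS)
  weighted, not headcount weighted.

Each *admission* (not patient) is a node: readmissions are distinct
nodes, and networks never span hospitals.

## Conventions that had to be chosen

Several conventions are not forced by the estimand; the package fixes
them explicitly and states them in its outputs.

**Inclusive days.** Dates are day-granular and stay intervals are
inclusive: a stay `[d, d]` contributes day `d`. A transfer whose
outgoing and incoming stays share a boundary day places the patient on
*both* units' rosters that day, and a pair co-located in two units on
one day yields two contact events (one per unit). This double count
keeps unit-level matrices additive; `build_network(...,
dedupe_same_day = TRUE)` collapses it to one event per pair per day for
sensitivity analyses.

**Ordered pairs.** Mixing matrices use the symmetric double-count
convention: an event between classes *i* and *j* increments both
`(i, j)` and `(j, i)`, and a same-class event adds 2 to the diagonal.
Under this convention every matrix is symmetric by construction, the
grand total equals twice the number of classified events, and row sums
read as per-class contact exposure — which is what the consistency test
against network weighted degrees checks.

**Axes.** Age runs 0–90 with ages above 90 top-coded to 90 by the
generator and *flagged* (not silently clamped) by the validator. The
comorbidity axis runs 0–16 inclusive: the stated score range requires 17
levels, and the package uses all 17.

**Antibiotic classification.** Exposure is recorded per (admission,
day, rank). The default `per_day` policy classifies each event by the
ranks active on that day; `whole_stay` uses ranks recorded at any time
during the admission. A patient on several ranks the same day
contributes the full cross-product of the two class sets — this is what
lets combination empirical therapy (e.g. ampicillin + gentamicin in
neonatal units) appear as symmetric off-diagonal mass rather than being
collapsed to the broadest rank (`collapse = "highest"` provides the
collapse as an alternative). Events where either patient is unexposed
are excluded from the 4×4 matrix but tallied, and analyzed separately
by `abx_none_ratio()`: unexposed patients are a population, not noise.

**Normalization.** `normalize_mixing()` applies min–max scaling over
the whole matrix. For a constant matrix the formula is 0/0; the package
returns all zeros with `normalization_flag = "constant"`, preserving
"minimum maps to 0".

## Network measures

Degree, density, diameter, betweenness and closeness are computed on
the simple unweighted graph underlying the weighted network. Monthly
hospital networks are often disconnected, so diameter, betweenness and
closeness are taken on the largest connected component; closeness is
normalized `(n−1)/Σd` so it lies in [0, 1]. A one-node network has
density and diameter 0; an edgeless network reports modularity `NA`
with a flag. Modularity uses greedy modularity maximization on the
weighted graph; no single community-detection method is canonical here,
so the choice is recorded in the `community_method` output column for
comparability rather than treated as interchangeable.

The association between a measure and hospital size (unique patients in
the window) is fit by ordinary least squares — a Gaussian
identity-link model, matching the linear-slope-with-symmetric-CI
reporting convention — and rescaled per 100 patients with a t-based 95%
interval. The suite verifies exact recovery on noise-free input and
nominal CI coverage (≥ 90/100 seeded replicates) under
`density = 0.5 − 0.0002·size + N(0, 0.005²)` across 24 hospitals.

## Significance testing

`contingency_test()` follows Cochran's rule: Pearson's chi-squared
without continuity correction when every expected cell count is at
least 5, otherwise Fisher's exact test; all tests two-sided at
α = 0.05. The Fisher branch is validated against exhaustive
hypergeometric enumeration on 2×2 tables, and the null rejection rate
is checked to sit in [0.03, 0.07] over 1000 simulated tables. No
multiple-testing correction is applied; users comparing many units
should apply their own.

## What the synthetic generator emulates

The generator produces encounter bundles with the statistical structure
the analysis assumes, at desk scale, so every stage is testable without
protected hospital data.

Per unit, the tunable quantities (all set in `unit_profile()`) are:

| Parameter | Units / range | Default rationale |
|---|---|---|
| `bed_pressure` | mean daily census (patients) | scales admission allocation via turnover (census ÷ mean LOS) |
| `los` | log-normal meanlog/sdlog, days | heavy right tail reproduces LOS-driven hotspots; ED ≈ 1 day, wards ≈ 3–4, NICU ≈ 10 |
| `age_model` | mixture of normals truncated/top-coded to 0–90, optional per-component `los_mult` | unit case mix; `los_mult = 10` on a 90+ component expresses the long-stay elderly subgroup |
| `elix_model` | `p_zero` ∈ [0,1], Poisson λ capped at 16 | most patients have score 0; ICUs shift up (λ 4–5) |
| `abx_model` | daily probability per rank, independent | independence across ranks lets one patient carry several ranks a day (combination therapy) |
| `transfer_out_prob` | [0,1] per stay end | produces multi-unit chains; destinations weighted by the destination's age density at the patient's age, EDs excluded as destinations |

Arrivals are a homogeneous Poisson process conditioned on the target
admission count (i.e. uniform over the window); stays truncate at the
window end. Randomness uses one stream per hospital split
deterministically per unit, so identical configs are byte-identical and
editing one unit leaves the others' draws unchanged.

Four archetypes (`archetype_config()`) encode qualitative hospital
patterns: `uniform_adult` (flat adult mixing), `young_skew`
(obstetric/behavioral-health heavy), `elderly_small` (3 units, elderly
case mix, an 8%-weight 90+ component — a normal at mean 92, SD 2,
top-coded to 90 — with 10× LOS in one shared medical ward), and
`academic_pediatric` (pediatric units including a NICU with daily
narrow and extended probabilities of 0.5 each, and a pediatric ward
prescribing narrow, broad and extended agents). All parameter values
are plausibility choices for these patterns, labelled as such; none are
estimates from any particular hospital system.

**What it does not emulate** — and hence what passing tests do not show
about real data: occupancy constraints (census can fluctuate freely),
readmission (patient ids are one-to-one with admissions), seasonal or
weekday structure, correlated antibiotic courses (exposure days are
independent given the unit, so course lengths are geometric rather than
regimen-shaped), unit-definition drift, and any misclassification of
unit type or demographics. Tests on generated data validate the
*machinery* (enumeration, weighting, conventions, recovery of
configured structure), not the epidemiology of any real hospital.

## Numerical and degenerate-input choices

* Validation reports violations (ordered by table, record key, rule)
  instead of throwing, so one pass surfaces every problem; structural
  errors (missing columns, unparseable dates, dangling foreign keys,
  unknown enum levels) do throw, with the offending column/line/key
  named.
* Roster cells, events and edges are sorted canonically
  (`admission_a < admission_b`), making outputs byte-stable.
* `multiward_summary()` on an edgeless network reports the edge
  percentage as 0 with an explicit flag rather than NaN.
* Transfer chains are capped at 8 stays to bound pathological
  configurations; at archetype transfer probabilities the cap is
  effectively never reached.
* Regression requires n ≥ 3 and non-constant sizes; a constant design
  is a named error, not an NA slope.

## Problem sizes used in the checks

The verification suite runs at sizes chosen to keep the full suite
around a minute while leaving the checked contrasts far from their
thresholds: oracle equivalence on 20 bundles of 20–100 admissions in
2–10 units over 30 days; metric oracles on ≤ 50-node graphs;
conservation/symmetry on 150-admission bundles of all four archetypes;
the elderly hotspot at 800 admissions (where the normalized (90,90)
cell exceeds the modal-age diagonal with a median margin of several
fold across seeds); the NICU pattern at 600 admissions; slope recovery
and test calibration at 100 and 1000 replicates respectively.

## Limitations

Colocation is an exposure proxy, not observed contact; same-day unit
sharing may overstate contact in large units and understate brief
cross-unit encounters. The day is the time quantum — within-day
ordering, and events shorter than a day, are invisible. Mixing matrices
inherit every upstream misclassification (unit type, age, scores, rank
assignments are taken as given). The modularity value depends on the
stated community-detection choice and should be compared only across
runs using the same method.
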