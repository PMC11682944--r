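---
title: "Methods: dietary risk quotients and colony profit under pesticide exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary risk quotients and colony profit under pesticide exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beecotox)
```

## The problem

Honey bee colonies placed in or near intensively managed crops such as
highbush blueberry collect pollen and nectar carrying residues of the
pesticides applied to the target crop and to surrounding fields. Two
questions follow. First, do the measured residue concentrations pose an
acute or chronic dietary risk to the bees? Second, if exposure does impair
or kill colonies, what does that cost the beekeeper? `beecotox` implements
both calculations as a reusable, seeded, fully testable pipeline.

## Dietary risk quotients

A risk quotient compares the estimated daily dietary intake of a compound
with a toxicity endpoint. With residue concentrations $C$ in µg/kg and
fixed daily consumption of 140 mg nectar and 9.6 mg pollen per bee,

$$RQ_{acute} = \frac{C_{nectar}\cdot 140\times10^{-6} +
  C_{pollen}\cdot 9.6\times10^{-6}}{LD_{50}},\qquad
RQ_{chronic} = \frac{C_{nectar}\cdot 140\times10^{-6} +
  C_{pollen}\cdot 9.6\times10^{-6}}{LC_{50}\ \mathrm{or}\ LDD_{50}}$$

where the acute endpoint is the single-exposure oral LD50 (µg/bee) and the
chronic endpoint a 10-day oral LC50 or LDD50 (µg/bee/day). The quotient is
dimensionless, non-negative, linear in the residues, and antitone in the
endpoint; RQ = 1 means the daily intake equals the dose killing half a test
population. These properties are what the test suite verifies, since the
formula itself is closed-form.

Quotients are computed per compound for each site, year and time point with
any detection (`compute_site_rqs()`), summed additively across compounds
within a site and time point (`total_rq()`), and compared against levels of
concern: acute cage RQ = 0.4, acute field RQ = 0.2, chronic RQ = 0.03
(`rq_thresholds()`, `exceedance_report()`).

Numerical and policy choices:

* **Non-detects contribute zero intake.** RQs are defined for compounds
  *detected* at a site; no imputation rule is implied by that definition.
  A `censoring_policy = "half_lod"` option substitutes LOD/2 for
  below-detection records when a user prefers a conservative bound.
* **Chronic endpoint tie-break.** When both an LC50 and an LDD50 exist the
  smaller (more conservative, larger RQ) is used; `chronic_policy` can force
  either endpoint.
* **Missing matrix = residue 0.** The intake numerator sums a nectar and a
  pollen term; in a pooled apiary-level design an unsampled matrix is
  indistinguishable from a non-detect.
* **Strict exceedance.** Thresholds are levels of concern *above* which
  effects are expected; `rq > threshold`, and boundary equality is a
  non-exceedance. Flags are recomputed idempotently from the stored RQs.
* **Skipped compounds are reported, not fatal.** A detected compound with no
  usable acute endpoint (as happens when an LD50 cannot be determined from
  the literature) is listed in the `skipped` attribute and omitted.
* Near-versus-far hypothesis testing (Gamma GLM/GLMMs with post-hoc
  contrasts) is routine statistical-package work and out of scope here.

## The synthetic residue generator

The raw residue measurements behind analyses of this kind live in
supplementary datasets; the package therefore ships a generator whose
defaults encode the study design it emulates: 20 apiaries (10 within 1.5 km
of highbush blueberry, 10 beyond), one pooled sample per apiary, matrix
(pollen, nectar) and sampling occasion, two occasions per season (T2 during
bloom, T3 at the end of bloom) in each of 2020 and 2021, and the 20
compounds of the packaged toxicity table.

Each record is a non-detect with probability $1 - p_{detect}$; otherwise the
concentration is lognormal — positive, right-skewed, heavily censored, the
standard shape of residue data — with per-compound, per-matrix parameters,
multiplied at far sites by a `far_site_multiplier` (3 for clothianidin,
2.5 for thiamethoxam, 1 otherwise, reflecting the elevated far-site
neonicotinoid concentrations observed in this system). Values below the
limit of detection are stored as 0 and flagged `below_lod`; values between
LOD and the limit of quantification keep their value flagged `below_loq`.

Parameter choices, made once:

* Detection probabilities are calibrated as (per-compound detection
  instances) / (160 pooled samples), using the detection frequencies
  reported for this system — e.g. flupyradifurone in 50 of 160 samples,
  thiamethoxam in 15, clothianidin in 6.
* Median concentrations are order-of-magnitude realistic for pollen/nectar
  residues (tens of µg/kg for common fungicides, around 1 µg/kg for
  neonicotinoids) with a common log-scale standard deviation of 0.9.
  Under the defaults this yields chronic exceedances at several sites for
  thiamethoxam and fewer for clothianidin, and no acute exceedances of the
  cage threshold.
* A compound's `detect_sites` field pins detection deterministically to a
  named set of sites at the compound's median concentration. Bernoulli
  detection cannot hit an exact site count, so this is the hook tests use to
  plant a known exceedance pattern (chronic exceedance at exactly 8 of 20
  sites for thiamethoxam and 3 of those 8 for clothianidin) and verify the
  counting logic.

What the generator does *not* emulate: spatial structure and land cover,
correlation between compounds or across time points within a site,
year effects, and measurement error in the analytical chemistry. Passing
tests therefore demonstrate the correctness of the RQ arithmetic, censoring
handling and exceedance counting — not distributional claims about real
residue data.

The packaged toxicity table is a labelled synthetic placeholder: endpoints
are at realistic orders of magnitude (e.g. LD50s of a few ng/bee for
neonicotinoids, >100 µg/bee for many fungicides), but real analyses must
substitute literature values.

## The profit model

Per-colony seasonal profit for a beekeeper earning honey and blueberry
pollination revenue is

$$\pi = (1-h)\,P\,Q + RF_{bl} - (C_{op} + C_{rep})$$

with honey price $P$, effective honey yield $Q$, pollination rental fee
$RF_{bl}$, operating cost $C_{op}$ and replacement cost $C_{rep}$ (zero
unless the colony dies). The health variable $h \in [0,1]$ captures
indirect behavioural/physiological impairment and scales down honey revenue
only — the rental fee is earned before effects manifest; reduced rental
income from chronically weakened colonies enters instead through the
sensitivity analysis.

Default parameters: $8.42/lb × 59 lbs, $124 rental fee, $400 operating
cost; replacement $240 (package), $55 (split + purchased queen), $28.75
(split + in-house queen). Direct honey effects by scenario: −30% for
summer-sublethal (impairment all season), −7% for fall-sublethal, −18.5%
(the mid-point) for a fall death, total loss for a summer death. A summer
death also fixes h = 1; a fall death leaves h free because the colony
produced at reduced capacity before dying. Replacement cost does not depend
on timing (a split costs the same labour whenever it is made; a package is
bought at spring market price either way).

Numerical choices that matter for exactness:

* **Pound basis.** Revenue is computed as $/lb × whole pounds
  (8.42 × 59 = 496.78). The rounded metric figures often displayed alongside
  (e.g. $18.56/kg × 27 kg = 501.12) do not reproduce cent-exact results and
  are treated as display values.
* **Whole-pound yields, half-up.** Reduced yields are rounded half-up to
  whole pounds before revenue: 41, 55, 48 lbs at the default reductions;
  6, 30, 53 lbs for the 10/50/90% sensitivity fractions. Note
  round-half-up, not round-to-even: 29.5 → 30.
* **Integer cents.** All currency arithmetic is carried in integer cents,
  so printed profits are exact and free of binary-float drift.
* **Break-even health.** $h^* = 1 - (C_{op} + C_{rep} - RF_{bl})/(P\,Q)$.
  The reported value is rounded half-up to 4 decimals; the unrounded
  solution is returned alongside (`h_exact`) and zeroes the profit to within
  half a cent. (At fall-sublethal revenue a 4-decimal h can leave a residual
  of up to about one cent, which is why both are returned.) Sentinels:
  `"none (<0)"` when even h = 0 loses money, `"any"` when even h = 1 is
  profitable.

### Scenario grid and sensitivity analysis

`scenario_grid()` evaluates the no-effect baseline plus
{early summer, fall} × {sublethal, lethal} × replacement methods, reporting
profit at h = 0 and h = 1 and the break-even h per cell. Summer-lethal
cells are only defined at h = 1, so their h = 0 profit and break-even are
reported as not applicable; the fall-sublethal prose figure of "$187.00"
circulating for this model is a rounding of the tabulated $187.10
(= 8.42 × 55 + 124 − 400), which this package reproduces.

`sensitivity_analysis()` re-evaluates the grid under one-at-a-time
overrides, all else at defaults: honey output at 10%, 50% or 90% of the
full crop; rental fee at $62 or $93; replacement by split with an in-house
queen. A design choice was genuinely open here: sensitivity tables for this
model quote sublethal and fall-lethal yields in rounded kilograms that are
mutually inconsistent with the pound-basis prose (24 kg fall-sublethal vs.
the 6/30/53 lb fractions). We take the pound fractions as authoritative and
apply the honey fraction to *every* direct-effect reduction — the colony
produces fraction × full crop whenever it produces at all — which keeps the
reduction ordering invariant (fall-sublethal ≤ fall-lethal ≤
summer-sublethal) intact and matches the 50%-fraction fall-lethal yield of
30 lbs (14 kg) quoted for the sensitivity parameterization.

### From exposure to scenarios

`flag_sites_for_scenarios()` bridges the two halves: a site is flagged when
any chronic RQ there strictly exceeds 0.03, the condition under which some
colony mortality plus sublethal effects on survivors are assumed. Which h
value a flagged site implies is deliberately left to the user: no empirical
mapping from exceedance magnitude to impairment exists, and hard-coding one
would manufacture precision.

## The pipeline

`run_pipeline()` ties the stages together deterministically: simulate (or
load) residues → RQs → totals and exceedance report → flagged sites →
scenario grid and sensitivity table, written as unit-labelled CSVs plus a
JSON run summary embedding the configuration hash, package version and
headline numbers, so a single artifact carries everything a downstream
check needs. Any stage failure is re-raised with the stage name. A YAML
config file (`read_run_config()`) drives the run; the CLI front end wraps
the same functions.

## Problem sizes and test design

Every published profit figure is closed-form and reproduced exactly at desk
scale. The stochastic parts of the test suite use deliberately modest
sizes: the far/near multiplier convergence check uses 640 sites × 8
records (≈5,000 draws), the brute-force oracle comparisons use ≤100-record
tables where an independent per-record loop is feasible, and full-design
runs use the study-sized 3,200-record table. The whole suite runs in a few
seconds.

## Limitations

* RQ values from the packaged toxicity table are placeholders; only their
  mathematical properties, not their magnitudes, are meaningful.
* Additive total RQs ignore synergistic mixture effects.
* The profit model is single-colony, single-season: no apiary portfolio,
  overwintering dynamics, stochastic mortality, or queen-rearing economics
  beyond the three replacement constants.
* The health variable compresses heterogeneous sublethal biology into one
  scalar multiplying honey revenue; it is a modelling device, not a
  measurable quantity.
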