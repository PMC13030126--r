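---
title: "Size-resolved, bioaccessibility-adjusted risk assessment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size-resolved, bioaccessibility-adjusted risk assessment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granrisk)
```

## The model

`granrisk` estimates children's non-carcinogenic risk from incidental
ingestion of metal-contaminated soil when contamination, solubility in
the gut and actual exposure all depend on particle size. Three
size-dependent quantities enter the calculation:

1. **Concentration** $C_i$ (mg·kg⁻¹) of each metal in sieve fraction
   $i$ (<63, 63–150, 150–250, 250–352 μm by default). Around smelters
   the fines are enriched, because stack emissions deposit as fine
   particles and because fine particles carry more sorptive surfaces.
2. **Bioaccessibility** $BA_i$, the fraction of total metal
   solubilized in a two-stage in vitro digestion (PBET: gastric pH
   2.5, then intestinal pH 7.0). From the extract concentration $C$
   (mg·L⁻¹), reactor volume $V$ (L), total content $T$ (mg·kg⁻¹) and
   soil mass $M$ (kg): $BA = CV/(TM)$. BA is stored as a unitless
   fraction throughout; percentages appear only at I/O, because the
   dose equation consumes the fraction directly.
3. **Exposure weight** $\Delta m_i$, the mass share of fraction $i$ in
   the soil a child actually ingests. Hand-rinse dust is the standard
   proxy for ingested soil, and its size distribution is strongly
   shifted toward fines relative to ambient soil (selective
   adherence).

The per-fraction average daily dose is

$$ADD_i = \frac{C_i \cdot IR_S \cdot CF \cdot BA_i \cdot EF \cdot
ED}{BW \cdot AT},$$

combined across fractions as $ADD = \sum_i \Delta m_i \, ADD_i$, and
converted to a hazard quotient $HQ = ADD/RfD$ per metal; the hazard
index is the sum of the per-metal HQs. Everything downstream of
$ADD_i$ is linear, which the package exploits: weighting commutes with
the RfD division, contribution shares are invariant to row rescaling,
and the Monte Carlo mean converges to the deterministic point estimate
under symmetric input noise.

### Exposure parameters

| symbol | meaning | unit | default |
|---|---|---|---|
| `IR_S` | soil ingestion rate | mg·d⁻¹ | 103 (mode of the triangular 66/103/161) |
| `CF` | mass conversion | kg·mg⁻¹ | 1e-6 |
| `EF` | exposure frequency | d·y⁻¹ | none — user supplied |
| `ED` | exposure duration | y | none — user supplied |
| `BW` | body weight | kg | none — user supplied |
| `AT` | averaging time | d | none — user supplied (`ED × 365` for non-carcinogens) |

`EF`, `ED`, `BW` and `AT` are population-specific and deliberately
have no defaults: a wrong silent default is worse than an explicit
argument. The package's own examples, fixtures and acceptance runs
use `EF = 350`, `ED = 6`, `BW = 20`, `AT = 2190` — standard
residential-child screening values. Reference doses default to the
IRIS-style oral RfDs (Cd 1e-3, Cr 3e-3, Cu 4e-3, Ni 2e-3, Pb
1.4e-3 mg·(kg·d)⁻¹); Cr is assessed as total Cr against the Cr(VI)
RfD (conservative, and flagged in reports), and Pb through the HQ
framework as a screening surrogate for blood-lead modelling (also
flagged).

### Which weight vector?

Two natural choices of $\Delta m_i$ ship as presets. The hand-dust
vector (0.643, 0.309, 0.0431, 0.0049) represents what children
actually ingest and is the conceptually correct exposure weighting.
The sieved-soil vector (0.446, 0.309, 0.149, 0.096) is the vector
under which the bundled reference HQ table's per-fraction values
reproduce its published Total row and contribution percentages; the
deterministic pipeline therefore defaults to it for consistency with
that table, and `weights = "hand"` (or any custom
`fraction_weights()`) switches to the exposure-faithful vector. The
two give materially different totals — the hand vector upweights the
enriched fines — so the choice is surfaced as an explicit argument and
recorded in every output's provenance field rather than buried.

## Numerical conventions

* **Percentile diameters** (D10/D50/D90) interpolate cumulative mass
  linearly in $\log_{10}$(diameter) within the containing bin, the
  laser-diffraction convention; a lower bin edge of 0 is floored at
  0.01 μm for interpolation only. A percentile landing exactly on a
  bin boundary returns the boundary.
* **Rebinning** splits a measurement bin straddling a sieve edge in
  proportion to linear diameter width — the simplest rule that
  conserves mass exactly, verified against a 1-μm brute-force
  discretization in the tests.
* **Cohort pooling** averages per-subject *proportions* (each subject
  normalized first) and renormalizes, so unevenly scaled instrument
  exports cannot bias the pooled weights. The population D50 is the
  arithmetic mean of individual D50s, not the D50 of the pooled curve.
* **QC order**: blank deduction (clipped at zero, with a warning),
  then LOD/√2 substitution, then the BA mass balance. BA > 1 is kept
  but warned about — measurement noise near complete release can
  legitimately exceed the total — while BA > 1.5 in the dose equation
  is an error, since it almost always means a percentage was passed
  where a fraction was expected.
* **Monte Carlo truncation**: draws from unbounded families are
  rejected-and-resampled into $[0, \infty)$ for concentrations and
  $[0, 1]$ for BA. Rejection (rather than clamping) avoids probability
  mass piling up at the bounds; with realistic CVs the acceptance rate
  is near 1 and the induced mean shift negligible.
* **Reproducibility**: every stochastic routine takes a seed, and the
  simulation derives an independent 31-bit substream per
  `(seed, metal, fraction, variable)` by hashing, so per-variable
  draws are invariant to metal ordering. One shared ingestion-rate
  stream serves all metals, since a child ingests the same soil for
  every metal. Runs with equal seeds are bitwise identical.
* **Degeneracy**: all-`fixed` specs reproduce the deterministic HQ
  bitwise; the simulation deliberately applies the dose-model
  operations in the same order as the deterministic code path.

## Distribution fitting

The probabilistic layer fits per-(metal, fraction) concentration and
BA distributions across sites and selects among normal, lognormal,
triangular, uniform, gamma and Weibull candidates — the standard
exposure-assessment palette — by minimum Anderson–Darling $A^2$, with
deterministic tie-breaking by candidate order. Normal and lognormal
use closed-form ML; gamma and Weibull use `MASS::fitdistr`; uniform
uses the sample range; triangular uses the range with a moment-based
mode ($3\bar{x} - \min - \max$, clipped into the range).

Acceptance at $\alpha = 0.05$ uses the parameters-estimated critical
values where tabulated: 0.752 on $A^2(1 + 0.75/n + 2.25/n^2)$ for
normal/lognormal, 0.757 on $A^2(1 + 0.2/\sqrt n)$ for Weibull (also
applied to gamma, for which no simple table exists), and the
all-parameters-known value 2.492 for uniform and triangular, whose
range-based fits match no tabulated estimated-parameter case; the
looser value makes these two families easier to *accept* but plays no
role in *selection*, which compares raw $A^2$.

A known identifiability limit: families that can mimic each other are
not reliably distinguished at survey sample sizes. A gamma with large
shape is practically a normal, so a generating normal with small
positive CV is sometimes claimed by gamma or Weibull instead.
The recovery guarantees in the test suite therefore use
clearly separated cases (standard normal, which has negative support;
lognormal with $\sigma = 0.5$; uniform), where recovery exceeds 90%.
For risk percentiles this ambiguity is benign — the competing fits are
numerically near-identical over the data range.

## The synthetic-data generator

The generator produces a survey with the structure of a smelter-area
field study — 17 sites × 4 fractions × 5 metals, a 30-child hand-dust
cohort, PBET extracts in both phases — with every latent quantity
recorded as ground truth. Defaults are the bundled survey summary
statistics: metal means 18.5/67.9/565/26.2/432 mg·kg⁻¹ (Cd/Cr/Cu/Ni/Pb),
gastric BA means 49.1/9.93/32.1/14.9/24.1%, intestinal
26.3/8.61/28.0/12.6/20.1%, hand-dust fractions 64.3/30.9/4.31/0.490%,
soil fractions 44.6/30.9/14.9/9.6%, fine/coarse concentration ratios
inside 1.3–1.9 (Cd 1.9, Cr 1.7, Cu 1.5, Ni 1.3, Pb 1.8, ordered by the
strength of the fine-particle enrichment each metal shows), and a 50%
fine-to-coarse BA decline (midpoint of the observed 40–60% band).

Design choices, made once:

* **Fraction-level means interpolate geometrically** between the fine
  and coarse anchors, scaled so the across-fraction average hits the
  configured metal mean. Only the two anchors are empirically
  constrained; a geometric ladder is the smoothest monotone choice.
* **Site-to-site noise is mean-preserving lognormal with CV 0.15** for
  both concentrations and BA. The survey publishes no site variances
  (only figure error bars); 0.15 is a moderate between-site spread
  for courtyard soils around a single point source, small enough that
  a 17-site panel estimates the regional mean to a few percent —
  consistent with the survey's ability to resolve fraction effects.
* **Per-child fraction vectors are logistic-normal** perturbations of
  the mean vector with spread 0.17, calibrated so the finest-fraction
  SD is ≈ 5 percentage points (the cohort's mass-fraction variability
  is reported as low, which is also why the simulation holds
  $\Delta m_i$ fixed).
* **Within-fraction mass is log-uniform over six sub-bins.** The
  finest hand-dust fraction spans $[L, 63)$ μm with $L$ solved
  analytically so the mean-vector PSD has D50 = 46.5 μm (≈ 16 μm at
  the defaults) — adhered dust carries essentially no mass below the
  tens-of-micrometre range, and anchoring $L$ to the observed median
  keeps the whole cumulative curve realistic.
* **Phase ordering is enforced in realization**: each intestinal draw
  is capped at the same site's gastric draw, so the gastric ≥
  intestinal invariant holds in every record, not just in expectation.
  For metals whose two phase means are close (Cr), the cap shaves a
  little off the realized intestinal mean; the capped
  draws are the ground truth the pipeline is compared against, so the
  round-trip tests are unaffected.
* **Extract concentrations are exact inversions** of the (noisy)
  latent BA through the mass-balance equation with the standard
  reactor geometry (V = 0.05 L, M = 0.0005 kg): the site-level noise
  lives in the latent BA, so a zero-noise bundle reproduces its
  ground truth exactly and `summarize_ba` recovers latent means by
  construction. The gastric-phase supernatant removal (5 mL) is not
  modelled as a change to V or M for the intestinal phase; both phases
  use the nominal geometry.

What the generator does *not* emulate: spatial gradients around the
source, inter-metal correlations at a site, analytical replicate
structure (it draws one value per site × fraction), censoring at the
LOD, and any systematic deviation of real PSDs from the log-uniform
sub-bin shape. Tests passing on synthetic data therefore validate the
pipeline's arithmetic, invariants and reproducibility — not the
field realism of any particular distributional assumption.

## Problem sizes

The test suite and acceptance script run the deterministic surface on
the bundled 5 × 4 reference table, generator round-trips at the
default 17 × 4 × 5 / 30-child sizes, Monte Carlo contracts at 10,000
iterations, and family-recovery checks over 50 seeded trials at
n = 500 — the sizes the methods are designed for in practice.

## Known limitations

* The HQ treatment of Pb is a screening device; regulatory practice
  prefers blood-lead (IEUBK-type) modelling. Reports carry the caveat.
* Total Cr against the Cr(VI) RfD overstates risk where Cr(III)
  dominates; speciation data would refine it.
* Input correlations (e.g. concentration–BA coupling across sites) are
  not modelled in the Monte Carlo layer, matching the source survey's
  choice at n = 17; with correlated inputs the variance of the HQ
  distribution would change while the mean would not.
* Only the oral route is covered — no dermal or inhalation pathways,
  and no carcinogenic slope-factor endpoint.
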