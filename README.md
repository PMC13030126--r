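# granrisk

Size-resolved, bioaccessibility-adjusted health-risk assessment for
heavy metals in soil.

## The problem

Children ingest soil mainly through hand-to-mouth contact, and the dust
that adheres to hands is not a random sample of the soil they play on:
fine particles (<63 μm) adhere preferentially, and the same fine
particles carry both higher metal concentrations and higher
gastrointestinal bioaccessibility. A risk assessment that uses bulk
soil concentrations in a single size cut therefore misattributes risk
across particle sizes — overweighting coarse particles that rarely
reach the mouth, underweighting the enriched fines that do.

`granrisk` implements the full size-resolved workflow for assessors,
exposure scientists and environmental epidemiologists working on
metal-contaminated sites:

* **Particle-size distributions** — laser-diffraction style binned
  PSDs, rebinning onto a sieve scheme (<63, 63–150, 150–250,
  250–352 μm by default), D10/D50/D90 by log-linear interpolation,
  cohort pooling into normalized exposure weights Δmᵢ, and
  selective-adherence enrichment ratios (hand dust vs ambient soil).
* **Bioaccessibility** — physiologically based extraction test (PBET)
  gastric/intestinal bioaccessible fractions, BA = C·V/(T·M), with the
  standard QC operations: blank deduction, LOD/√2 substitution for
  censored values, CRM recovery and replicate RSD checks.
* **Deterministic risk** — per-fraction average daily dose
  ADDᵢ = Cᵢ·IRₛ·CF·BAᵢ·EF·ED/(BW·AT), mass-fraction-weighted total
  ADD = Σ Δmᵢ·ADDᵢ, hazard quotients HQ = ADD/RfD, the hazard index,
  and contribution decompositions by size fraction and by metal.
* **Probabilistic risk** — per-cell distribution fitting with
  Anderson–Darling selection across
  normal/lognormal/triangular/uniform/gamma/Weibull candidates, a
  triangular ingestion rate (66/103/161 mg·d⁻¹), and a seeded,
  bit-reproducible 10,000-iteration Monte Carlo layer with percentile
  and P(HQ > 1) reporting.
* **Synthetic data** — a generator that emulates a 17-site × 4-fraction
  × 5-metal smelter survey with a 30-child hand-dust cohort and known
  ground truth, so every stage is testable end to end.

## Worked example

The package bundles the point-estimate hazard-quotient table of a
smelter-area survey (five metals × four size fractions) together with
the sieved-soil weight vector that reproduces its published totals:

```r
library(granrisk)
ref <- smelter_hq_reference()
hq_table_from_matrix(ref$hq, weights = ref$weights)
#> Hazard quotients (soil weights):
#>        <63  63-150 150-250 250-352   Total
#> Cd 0.02100 0.01250 0.00851 0.00667 0.01510
#> Cr 0.00666 0.00441 0.00387 0.00265 0.00516
#> Cu 0.13200 0.09080 0.06400 0.04830 0.10100
#> Ni 0.00478 0.00415 0.00387 0.00319 0.00430
#> Pb 0.22900 0.17000 0.12900 0.07900 0.18100
#> Hazard index: 0.307 (below 1: acceptable)
```

Every column is a sieve fraction in μm; each cell is the hazard
quotient (dose over reference dose, unitless) a child would incur if
all ingested soil came from that fraction, and the Total column weights
the fractions by their mass shares. The hazard index 0.307 is below
the conventional threshold of 1: no non-carcinogenic effect is
expected, but the decomposition shows where the risk sits:

```r
round(metal_share_of_hi(hq_table_from_matrix(ref$hq, ref$weights)$totals), 1)
#>   Cd   Cr   Cu   Ni   Pb
#>  4.9  1.7 32.9  1.4 59.1          # Pb and Cu dominate the HI
signif(fine_coarse_ratio(ref$hq)$ratio, 3)
#>   Cd   Cr   Cu   Ni   Pb
#> 3.15 2.51 2.73 1.50 2.90          # finest vs coarsest fraction HQ
round(enrichment_ratio(hand_dust_weights(), soil_weights()), 3)
#>     <63  63-150 150-250 250-352
#>   1.442   1.000   0.289   0.051  # fine particles enrich on hands
```

Lead accounts for 59% of the hazard index; the <63 μm fraction carries
1.5–3.1 times the per-mass risk of the 250–352 μm fraction; and hand
dust holds 1.44 times more fine-fraction mass than the courtyard soil
it came from — the selective-adherence effect that motivates
size-resolved weighting.

A full pipeline run on synthetic data:

```r
p   <- generator_params(seed = 7)
fx  <- end_to_end_fixture(p, seed = 7)       # soil panel + PBET + PSDs
tab <- run_deterministic(fx$panel, fx$extracts, psd = fx$psds,
                         params = exposure_params(EF = 350, ED = 6,
                                                  BW = 20, AT = 2190),
                         weights = "hand")
mc  <- run_probabilistic(fx$panel, fx$extracts, psd = fx$psds,
                         params = fx$params, weights = "hand",
                         n_iter = 10000, seed = 7)
```

A thin command-line wrapper with the same functionality ships in
`exec/granrisk` (subcommands `psd`, `ba`, `risk`, `mc`, `simulate`).

## Vignette

`vignettes/size-resolved-risk.Rmd` documents the model, its
assumptions, the defaults of the synthetic-data generator, the
numerical conventions (interpolation, truncation, tie-breaking) and
known limitations.
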