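---
title: "Census-based reef carbonate budgets: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Census-based reef carbonate budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefcarb)
```

## The accounting model

`reefcarb` computes a census-based carbonate budget at the level of a
2-m benthic transect paired with a 0.25-m² urchin quadrat, with
parrotfish erosion estimated from 25 × 5 m belt transects and averaged
to the site × depth cell. Net production is

$$C_i = G_i + \mathrm{sgn}(x)\,S - B_i$$

in kg CaCO₃ m⁻² y⁻¹. Every term is an empirical rate model driven by
what a diver records: centimetre-resolution benthic intercepts, urchin
test diameters, fish fork lengths, and the contoured/planar tape ratio
(rugosity).

Assumptions worth stating explicitly:

- **Planar proportions are per unit of contoured tape.** Intercepts are
  recorded per contour centimetre, so the proportions feeding the
  calcification and boring models are per unit of surveyed surface;
  rugosity multiplies only where the gross-production and boring
  equations say so. Double-counting rugosity is the classic error here.
- **The sedimentation term is a constant with a sign rule**, not a
  measurement: +0.53 kg m⁻² y⁻¹ (a Hawaiian literature value) when the
  terrigenous load is below 0.05 kg m⁻² d⁻¹, negative otherwise. Both
  numbers live in `sedimentation_config()`.
- **Parrotfish erosion is a cell-level rate broadcast to transects.**
  Belt transects cannot be paired one-to-one with 2-m benthic tapes, so
  the mean over the cell's belts (six by design; the mean generalizes to
  the belts present, with a warning) applies to every transect of that
  cell.
- **The *Porites* growth model switches branches at 6 m** — linear
  `(13.37 − 0.21·depth)/10` below, exponential `16.2·e^{−0.032·depth}/10`
  at or beyond — and the two branches do not meet exactly (1.211 vs
  1.337 cm y⁻¹ at 6 m). The implementation applies the published rule
  verbatim rather than smoothing it, and the tests pin both one-sided
  values.
- **Growth uses the transect's standardized MSL depth**, not its design
  depth label; tide offsets are per-cell configuration values defaulting
  to 0.
- The parrotfish bite-rate equation
  `60·|(4.31 + brc − 0.355) − 0.045·bitetime·length|` is reproduced
  as published, absolute value and all; its constants are not
  re-derivable from first principles here, so they are configuration,
  not code.
- The urchin equations' trailing 0.25 is implemented as division by
  quadrat area — the per-m² normalization that makes a 15-urchin quadrat
  a 60 m⁻² density — matching the ×4 scaling used in published density
  summaries. *Diadema* and *Echinothrix* share one coefficient set;
  *Tripneustes gratilla* erodes nothing.
- Macroborable substrate includes coralline algae (crusts do not protect
  the carbonate beneath); microborable substrate excludes both coral and
  CCA, whose net rates already account for microboring. The
  category-to-availability mapping is a config table, not code.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| sedimentation rate | kg m⁻² y⁻¹ | 0.53 | Hawaiian literature value; site-specific |
| sedimentation sign threshold | kg m⁻² d⁻¹ | 0.05 | smothering load cutoff |
| CCA calcification | g cm⁻² y⁻¹ | 0.036 | central-Pacific shallow-reef mean |
| *Halimeda* calcification | kg m⁻² y⁻¹ | 1.694 | a 20-m rate, applied wherever *Halimeda* occurs |
| grazing time | h d⁻¹ | 10 | parrotfish daylight grazing assumption |
| macro/micro boring | kg m⁻² y⁻¹ | 0.21 / 0.20 | 1–18 m central-Pacific means |
| accretion coefficient | — | −0.01949 | published quadratic best fit |
| urchin power laws (a, b) | g d⁻¹ per mm^b | per group | Diadematidae (3e−6, 3.2887), *Echinometra* (3e−4, 1.9671), other (3e−5, 2.6414) |

Taxon-level values (morphology coefficients, skeletal densities, growth
rates, bite-rate constants) ship as editable CSVs under
`inst/extdata/lookups/`. These are *synthetic representative defaults* —
plausible Indo-Pacific magnitudes assembled for a working engine, marked
as such in their filenames and `source` columns — because the calibrated
tables used in any given study are data, not method. Resolution follows a
species → genus → default fallback chain with warnings; an unresolvable
taxon is fatal.

## The threshold model

The live-coral-cover threshold model is a Gaussian additive mixed model:
an O'Sullivan spline of cover, a categorical depth effect, and a site
random intercept. Design choices made where the method was genuinely
open:

- **Basis and penalty.** Cubic B-splines with 5 interior knots at
  quantiles of the observed cover, boundary knots at 0 and 100% so
  posterior curves can be evaluated over the whole percent range, and the
  exact integrated-squared-second-derivative penalty (Simpson per
  inter-knot interval, which is exact for the piecewise-quadratic
  integrand). The penalized part enters the sampler through the
  Demmler–Reinsch transform as i.i.d. random effects, so a straight line
  is never shrunk.
- **Priors.** "Diffuse" is concretized as N(0, 10⁶) for fixed effects
  and half-Cauchy(0, 25) for the three standard deviations. The
  half-Cauchy is implemented by inverse-gamma parameter expansion, which
  keeps every Gibbs update conjugate. All are overridable in
  `gam_config()`.
- **Sampler.** One blocked multivariate-normal update for all
  coefficients (fixed + spline + site) per iteration, then the three
  variance updates. Defaults: 3 chains × 20,000 iterations, 5,000
  burn-in, thinning 5; convergence requires split-chain R̂ < 1.1 on every
  parameter, otherwise the fit is flagged and thresholds are marked
  unreliable. The test suite cross-checks the sampler against a
  closed-form Bayesian regression posterior and against an independent
  MCMC engine (JAGS) on a reduced model.
- **Threshold extraction.** Per posterior draw, the depth-specific curve
  (site effect at its population mean of zero) is evaluated on a cover
  grid (default step 0.01%, with linear interpolation inside grid cells)
  and the *smallest* negative-to-positive crossing is taken; the point
  estimate is the crossing of the posterior-mean curve and the credible
  interval the 2.5/97.5 percentiles of the per-draw crossings. Draws with
  no crossing are censored at 0 (everywhere positive) or 100 (everywhere
  negative) and included in the percentiles; the censored share is
  reported. Per-draw roots were chosen over credible-band crossings
  because they give a genuine posterior for the threshold; the
  alternative answers a different question.

## The upscaling procedure

Collinearity screening drops the lower-priority member of any predictor
pair with |r| ≥ 0.7 (priority is configuration: cover first, since cover
is what the mapped product provides). Outliers are flagged at three times
the mean Cook's distance of the full OLS fit, then excluded. The PLSR
component check (k = 10 folds, seeded) documents the effective
dimensionality. Candidate OLS models are fitted on a single seeded 70:30
split; within each candidate, predictors with p ≥ 0.05 are dropped
iteratively and the model refitted; the lowest test-RMSE candidate wins
and is refitted on all non-outlier data. Predictions over a cover raster
are not truncated: negative predicted production is meaningful (net
erosion). Raster I/O uses the Esri ASCII grid text format; the container
carries georeferencing and CRS as opaque metadata.

## What the synthetic generator emulates — and what it does not

`generate_survey()` reproduces the *design* of a Hawaiian depth-gradient
campaign: 2 sites × depths {2, 3, 6, 9, 17} m × 15 paired
quadrat/transect replicates, 6 belts per cell. Its defaults are the study
conditions: per-depth urchin group means from published density tables
(e.g. *Echinometra* 15.13 per quadrat at 2 m), negative-binomial counts
with dispersion 3.5 (the published standard errors imply variance ≈ 3–5×
the mean at n = 30), per-depth mean coral cover from the published
surveyed-cover column (23–35%), shifted-lognormal rugosity (median
≈ 1.6), and sparse parrotfish (Poisson mean 2 per belt). Benthic tapes
are tiled deterministically by largest-remainder apportionment so
realized proportions equal the Dirichlet draw exactly, isolating
downstream numerics from multinomial noise.

What it does **not** emulate: taxonomic richness beyond a five-species
coral pool, within-transect spatial patchiness along the tape,
observer error in size and length estimation, or any coupling between
cover and urchin density. Consequently, passing recovery tests show the
*pipeline arithmetic and inference* are correct under known truth — they
do not validate the rate models against real reefs. One visible
difference from the field data: in synthetic surveys rugosity carries
genuine signal for net production (it multiplies both calcification and
boring), so model selection may legitimately retain it, whereas the
field analysis found cover alone sufficient.

`generate_lcc_raster()` produces a Gaussian random field (kernel
smoothing of white noise) mapped to exact Beta marginals, clipped to a
nodata border, with the latent linear cover→production truth stored for
round-trip tests. It does not simulate classification error or depth
attenuation of the airborne product.

## Numerical choices and problem sizes

- Proportions partition to 1 within 1e−9 by construction (1-cm tiling).
- Budget identities (`net = gross + sed − bioerosion`;
  `accretion = Cp − 0.01949·Cp²`; component sums) hold to 1e−12 and are
  asserted at that tolerance.
- Report tables round half-up at 2 decimals (base R's round-half-even
  would turn 2.285 into 2.28).
- Aggregate accretion applies the quadratic to the *mean* net production
  (the canonical published convention); the mean of per-transect
  accretions is also emitted for comparison, and single-transect cells
  report SE = 0 with a flag. The accretion SE is computed from
  transect-level accretions; whether published summary SEs were derived
  that way is not stated, so both conventions are visible in the output.
- Test-suite problem sizes are deliberate: sampler checks run 2 chains ×
  1,500–4,000 iterations on n = 100–150 (split-R̂ < 1.1 throughout);
  threshold-coverage uses 20 replicates, scaling-recovery 50; the
  equation oracles use 1,000 random inputs at 1e−9. These sizes give
  stable verdicts for conjugate samplers and OLS at this n; production
  analyses should use the 3 × 20,000 defaults.
- Partial-centimetre intercepts are not modelled: the tape is assumed to
  tile at exactly 1 cm (validation rejects anything else).

## Known limitations

- No ocean-acidification or physical-erosion terms: estimates are upper
  bounds on realized net production.
- No *Acanthaster* (crown-of-thorns) erosion term.
- Non-*Porites* growth rates are depth-invariant by default (a
  depth-scaling hook exists but is off, for lack of calibration data).
- The 70:30 split makes test metrics split-dependent; only the
  full-data refit is reported as the final model.
- GeoTIFF is not read directly; convert cover products to Esri ASCII
  grid (one `gdal_translate -of AAIGrid` away) for the raster stages.
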