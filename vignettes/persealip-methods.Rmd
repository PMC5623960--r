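---
title: "persealip: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{persealip: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persealip)
```

# What this package models

Avocado (*Persea americana*) fruit accumulates aliphatic acetogenins —
odd-chain, often acetylated fatty-alcohol derivatives such as Persin,
Persenone A and the avocatins — alongside a bulk lipidome dominated by
triacylglycerols. `persealip` re-implements, as a tested pipeline, two
layers of analysis of this system:

* a **targeted layer**: HPLC-UV (220 nm) quantification of seven
  acetogenin species against per-compound calibration curves, total
  acetogenin concentration (TAC), profile shares, fresh/dry-weight
  conversion, and fatty-acid table summaries;
* an **untargeted layer**: ESI-TOF positive-mode LC-MS lipidomics — 2D
  baseline correction, grid-based peak detection, isotopologue grouping,
  RANSAC retention-time alignment, gap filling, co-elution grouping by
  trace correlation, adduct-hypothesis annotation against a local lipid
  database with hierarchical class-composition weighting, and downstream
  multivariate statistics.

No raw data accompany the source study, so every stage is driven by a
**synthetic-data module** whose defaults encode the study's printed effect
sizes. The synthetic world is a first-class, tested component: each
simulated map carries a ground-truth ledger that downstream tests use as an
oracle.

# The synthetic world

## Tissue profiles

`generate_sample_profile()` draws one biological replicate of a tissue
(mesocarp, idioblast-enriched fraction, or seed) at a stage (growth stages
labelled by fruit fresh weight, 45–300 g, or postharvest ripening stages
unripe/breaker/ripe). The printed facts it encodes:

* mesocarp acetogenin shares are stage-invariant, with Persenone A at
  52.7% and the co-eluting Persin/Persenone B peak at 25.8%;
* seed profiles switch between a *young* regime (fruits ≤ 90 g;
  AcO-avocadene 53.7%, AcO-avocadenyne 7.85%, UPA 14.6%, Persin/Persenone
  B 4.51%) and a *mature* regime (36.3%, 4.99%, 5.54%, 17.4%);
* mean seed TAC (dry-weight basis) steps up 4.5-fold between the two
  regimes;
* the idioblast fraction captures 98.1% (sd 0.8%) of its source mesocarp's
  acetogenins at the ripe stage.

Replicate noise is multiplicative lognormal per analyte with unit mean;
coefficients of variation are taken as printed-sd / printed-mean of the
corresponding shares where the study prints them, 0.10 otherwise, plus a
whole-sample TAC factor (CV 0.08 mesocarp, 0.15 seed — the study describes
seed tissue as highly variable but prints no TAC CV). `noise_cv = 0`
returns the configured means exactly, which is what the exactness tests
rely on.

Two quantities are *not* printed in the extracted text (the relevant table
and figure are images): absolute TAC levels and the shares of the minor
analytes. We chose mesocarp TAC 6 mg/gDW and seed TAC 0.8 (young) and 3.6
(mature) mg/gDW — the ratio, not the level, is the tested claim — and
filled the remaining share mass so each pool sums to one, using the 12%
AcO-avocadene figure for mature green mesocarp that the study's discussion
quotes. These were chosen once and are not tuned by any test.

**Pairing.** Idioblast samples are generated *paired*: the same seed
produces the identical underlying mesocarp sample, and the idioblast
profile is that sample scaled by a capture fraction (0.981 at ripe, sd
0.008). This mirrors the paired fractionation experiment; an unpaired
design would make the ±1-percentage-point recovery of the 98.1% figure
statistically unattainable at n = 3.

## Scan maps

`synthesize_scan_map()` emits, per analyte × adduct, a symmetric Gaussian
chromatographic peak at the analyte's nominal retention time with an M+1
isotopologue at +1.00336/z (abundance ≈ 1.1% per carbon), plus persistent
background "rails" with a slow sinusoidal drift and additive Gaussian
noise. Acquisition defaults mirror the study: m/z 150–1500, 0.94 scans/s,
65-min gradient. Retention-time regions (acetogenins 8–20 min, DAGs 25–40,
TAGs 45–60) mirror the study's cloud-plot structure; per-compound retention
times are not printed anywhere, so these are placeholders, not claims.

**Peak width.** The study states that its trace-correlation threshold of
0.9 "is equivalent to a shift of one scan". Computing the Pearson
correlation of a Gaussian with its one-scan-shifted copy over the
full-width-at-quarter-maximum (FWQM) window at 0.94 scans/s gives r = 0.91
at 12 s FWHM but r = 0.88 at 10 s. We therefore default the simulated peak
width to **10 s FWHM**, the widest round value at which the study's own
equivalence claim holds; at 12 s the claim is numerically false. This was
derived from the closed-form oracle before the grouping tests were
written.

**Dropout.** Bernoulli per (analyte, sample), default p = 0.1. The default
mode (`"detection"`) keeps the signal in the raw map and only flags the
ledger — the pipeline then removes the affected detections — so gap
filling can be held to the true area. `"synthesis"` mode removes the
signal entirely and exercises the fill-with-zero path.

## UV areas and the growth series

UV synthesis is exactly linear (`area = slope × mg/mL (+ noise)`), with
extraction-volume factors reconstructed from the extraction protocol (15 mL
solvent over 2 g mesocarp, 1 g seed, or the idioblast fraction from 5 g of
mesocarp). Persin and Persenone B co-elute and are always emitted as one
merged analyte quantified with the Persenone B curve; UPA is quantified in
Persenone A equivalents (shared slope). Quantification is therefore the
exact inverse of the generator at zero noise — a deliberate property that
the tests assert.

`generate_seed_growth_series()` simulates TAC = a·DW^b·ε with defaults
a = 32.7, b = 2.246 (the study's printed seed regression) and lognormal
noise CV 0.40. The CV was fixed by simulation so that the fitted
coefficient of determination matches the printed R² ≈ 0.73 on the default
7-stage × 3-replicate grid (DW 0.13–0.45); it is part of the stated world,
not a free parameter.

# Processing parameters

Every stage defaults to the study's printed processing values:

| stage | parameters |
|---|---|
| baseline | 0.01 Da × 1.5 min cells, 40% quantile |
| detection | min height 1000 counts, m/z tol 0.05, duration 0.1–2.5 min, smoothing 0.1 min, similarity ratio 0.5 |
| isotopes | 0.001 Da or 10 ppm, RT tol 0.25 min, charge ≤ 2, monotonic envelope, lowest m/z representative |
| alignment | 0.025 Da or 50 ppm, RT tol 2 min before / 1.5 min after correction, ≥ 25% inliers below 1 min |
| gap filling | 0.025 Da or 50 ppm |
| grouping | FWQM overlap candidacy, Pearson r > 0.9 (strict) |
| annotation | window = 3 × m/z sd × charge + 25 ppm; isotope window = sd/r² + 5% of intensity |

Interpretations the source leaves open, decided here:

* **Baseline quantile with implicit zeros.** Cell estimates are quantiles
  over *all scans in the cell's retention window*, counting scans that
  contribute no centroid as zeros. On dense profile data the two readings
  coincide; on sparse centroided data the naive reading would dock an
  isolated peak its own 40% quantile. Correction output is clamped at zero
  and is idempotent up to quantile-estimation error.
* **Similarity ratio** is read as the minimum allowed intensity ratio
  between consecutive scans along a peak flank (the cited grid algorithm's
  exact semantics are not restated in the source). Peak areas are
  trapezoidal integrals over the full flank extent (down to 0.5% of apex),
  not just the FWQM window, so noise-free areas match the analytic
  Gaussian integral within 2%.
* **"RT tolerance of 0.25"** is read as minutes, consistent with the
  neighbouring values.
* **RANSAC**: 1000 seeded iterations (count unstated in the source); a
  linear consensus model refined by a monotone loess on the inliers, with
  identity fallback and a warning below the inlier floor.
* **Grouping closure** is single linkage over admitted pairs; correlations
  are computed on raw intensities over the common FWQM scans, require ≥ 4
  common scans, and ties at exactly 0.9 are excluded ("above" is strict).
* **Adduct arithmetic** subtracts cation masses (electron included —
  immaterial inside a 25+ ppm window, but correctness is free). Doubly
  charged features enumerate all 4 × 4 ordered component pairings to honor
  the printed count of 16; mass-degenerate pairings are flagged as
  duplicates rather than dropped.
* **Tukey letters** are maximal cliques of the non-significance graph at
  α = 0.05, ordered by decreasing group mean — equivalent to the classic
  insert-and-absorb display, and tested against a brute-force
  studentized-range oracle.
* **Normalization** follows the printed order: quantile normalization
  (ties receive the mean of the tied-rank reference values), natural log
  with +1 offset on zeros (base and offset unstated in the source),
  feature-wise centering and scaling. Constant rows are flagged and left
  unscaled. PCA on the scaled matrix makes the covariance/correlation
  distinction moot.
* **Divergent-group selection** thresholds |loading| at the 0.95 per-sign
  quantile (the study selects from score/loading plots without a printed
  cutoff), lowering stepwise if a side comes out empty.

# The annotation worked example

The study's worked example assigns the feature at mean m/z 421.2893 two
formulas, quoted as [C25H40O + H]⁺ and [C27H42O + K]⁺, with 12 candidate
compounds (1 + 11) whose second-level classes count ST04:1, ST03:3, ST01:8,
giving the approximate composition 8.3% / 25% / 66.7% and a fixed [ST] at
level 1. The first formula is typographically inconsistent with the printed
m/z: [C25H40O + H]⁺ computes to 357.32, while [C27H42O + K]⁺ matches
421.29. The fixture database keeps the printed formula for the single ST04
record (its stored mass honors the mass-from-formula invariant), which
means a faithful 3σ + 25 ppm search at 421.2893 returns 11 candidates, not
12. `worked_example_candidates()` assembles the printed 12-record set
directly from the database cluster, and the class-composition arithmetic —
the part of the example that is internally consistent — is reproduced
exactly from it. We deliberately did not bend the search window or the
record mass to force the 12th hit.

# Power-law fitting

`fit_power_law()` fits TAC = a·DW^b by nonlinear least squares on the
original scale, initialized from the log–log linear fit, with R² always on
the original scale; `method = "loglog"` exposes the spreadsheet-trendline
estimator (ordinary least squares in log space), which is what the study's
own tooling computes and the maximum-likelihood estimator under the
generator's multiplicative lognormal noise. At the default noise (CV 0.40,
matching the printed R²), the original-scale NLS estimator of b has a
median absolute error around 0.36 — noise on the largest seeds dominates
the original-scale objective — while the log-space estimator achieves
about 0.14. The stochastic recovery test therefore uses the log-space
estimator; the noise-free exactness test uses the default NLS path.

# What a green test does and does not establish

The simulator produces symmetric, isolated Gaussian peaks with ideal
isotope envelopes, stationary backgrounds and strictly lognormal replicate
noise. Green tests establish that the implementation honors its printed
parameters and contracts and that the end-to-end pipeline is an unbiased
round trip on such data. They do not establish performance on real
chromatography: tailing and fronting peaks, co-eluting isomers,
detector saturation, batch drift, and real Lipid MAPS-scale databases
(thousands of near-isobaric records) are all outside the simulated world.
The study's dataset-specific feature counts (5333 idioblast features, 3648
seed features, PC1 = 41%) depend on its unavailable raw data and are not
reproduction targets; they guided the synthetic data's scale only.

# Known limitations

* mzML support is a minimal hand-rolled reader/writer (64-bit
  little-endian, uncompressed, MS1 only) because no mzML library is
  available in the target environment; the long-format CSV is the primary
  interchange format.
* The RANSAC correction model is monotone-affine-plus-loess; severe
  non-monotone warps fall back to identity with a warning.
* Isotope envelopes are truncated at M+2 and carbon-driven; sulfur/chlorine
  isotope structure is not modelled.
* The UV layer models areas, not chromatograms; peak integration of real
  UV traces is out of scope.
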