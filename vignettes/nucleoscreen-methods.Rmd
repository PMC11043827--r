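---
title: "Methods: simulating and quantifying mtDNA nucleoid screens"
author: "nucleoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying mtDNA nucleoid screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoscreen)
```

# The assay this package models

Fibroblasts from patients with mitochondrial DNA (mtDNA) depletion syndrome
are co-stained with a DNA dye (PicoGreen-like) and a membrane-potential dye
(TMRM/CMXRos-like) and imaged on a high-content microscope.  In the DNA
channel the nucleus appears as one large object and each mtDNA nucleoid as a
diffraction-limited punctum, so a single channel yields both a nuclear-DNA
readout and an mtDNA readout, separated purely by object size.  The
quantities of interest per cell are:

* **nucleoid count** and **summed puncta area** (the mtDNA content proxies),
* **integrated densities** — object area ($\mu m^2$) times mean
  background-subtracted intensity, summed over an object class — for the
  nuclear DNA signal, the puncta, and the membrane-potential channel
  (the polarized mitochondrial mass proxy),
* **reticulum length**, the summed skeleton length of the thresholded
  membrane-potential signal,
* a **Rho-0 flag** (cells void of detectable mtDNA) and a **ploidy class**
  (G1 vs S/G2 by nuclear DNA content).

Treatment screens compare each nucleoside-supplement condition against a
DMSO vehicle baseline in the same run / cell line / serum context; the
companion analyses are a qPCR depletion–recovery time course and a
heavy-isotope label-dilution readout of endogenous nucleoside pools.

No imaging data are publicly deposited for this assay, so the package pairs
every analysis stage with a synthetic generator that produces the same data
structures with known ground truth.  All tests and the acceptance script run
on that synthetic data.

# The synthetic field generator

`field_spec()` + `render_field()` draw a two-channel field:

* **Geometry.** Cell centres are placed by rejection sampling with a minimum
  separation of $0.72\sqrt{A/n}$ pixels; each cell's territory is the disc of
  half that separation, so territories never overlap and the nearest-nucleus
  rule downstream recovers them essentially exactly.  The default field
  (768 px at 0.35 µm/px, 20 cells) gives territories of roughly
  1000–3000 µm², i.e. sparsely plated, well-spread fibroblasts.  Cell shape
  is deliberately simple: the goal is a geometry that exposes every metric
  the pipeline computes, not optical realism.
* **Nuclei** are 2-D Gaussian blobs with log-normally drawn area
  (mean 100 µm², 15% cv).  The *controlled* quantity is nuclear DNA content:
  G1 cells draw a content factor with 10% cv, S/G2 cells the same times two,
  and peak intensity compensates the drawn area so that *integrated density*
  (not brightness or size alone) carries the ploidy signal.  This mirrors the
  use of integrated nuclear dye signal as a DNA-content readout.
* **Nucleoids** are isotropic Gaussian spots (default $\sigma$ = 0.35 µm)
  placed uniformly in the annulus between the nucleus margin and the
  territory edge.  Counts are drawn per cell as a zero-truncated Poisson
  whose mean carries a log-normal cell-to-cell factor (30% cv).  Rho-0 cells
  — exactly `round(rho0_fraction * n_cells)` per field — carry zero puncta;
  the exact composition (rather than a Bernoulli draw) makes the configured
  fraction the exact ground truth of every field, which is what a recovery
  benchmark needs.  The truth "summed area" of a spot is its half-maximum
  footprint $\pi(1.177\sigma)^2$.
* **Reticulum.** 2–6 smooth random curves per cell (unit-step random walks
  with a smoothly diffusing heading, folded back at the territory edge),
  rasterised by bilinear point-splatting and a single Gaussian blur.  Each
  cell's curve points carry equal mass summing to its
  `mito_polarized_mass`, so summed channel-2 intensity above background
  equals the summed ground-truth mass exactly before noise — the
  conservation property the tests assert.
* **Noise** is additive Gaussian read noise only; the spot signal-to-noise
  ratio is `spot_intensity / noise_sd` (default 200/20 = 10).  Shot noise,
  photobleaching, uneven illumination and 3-D structure are deliberately out
  of scope, so SNR stays a single interpretable dial.

Identical spec + seed yields bit-identical output; every generator routine
runs under an isolated RNG state and restores the caller's.

**What passing tests do and do not show.** Because cells are convex,
non-overlapping and mononucleated, segmentation accuracy here is an upper
bound on real-data performance: the benchmarks validate the *measurement
logic* (size gates, background subtraction, linearity, classification
rules), not robustness to touching cells, debris or focus drift.

# Segmentation and per-cell quantification

All thresholds are relative, so every mask is invariant to global
multiplicative intensity scaling — and integrated densities are then exactly
homogeneous of degree 1 in intensity (a property tested to machine
precision).

* **Nuclei**: Gaussian smoothing ($\sigma$ = 1 px), Otsu threshold on the
  min–max-normalised image, connected components with area ≥ 30 µm²
  (`nucleus_min_area`; smaller objects are left for nucleoid detection),
  border-touching components removed.  If the mask floods more than 25% of
  the field the channel is treated as empty: that only happens when Otsu
  splits pure noise mid-histogram in a field with no cells.
* **Territories**: simultaneous seeded region growing from the nuclei
  (Voronoi partition), giving a one-to-one nucleus–territory correspondence
  with no extra parameters.
* **Nucleoids**: difference of Gaussians at $(\sigma, 2\sigma)$ with
  $\sigma$ = `puncta_sigma` / pixel size, thresholded at median + 5 MAD of
  the filtered image, with a floor of 10% of the band-pass maximum so the
  threshold stays defined in near-noiseless images.  Touching spots are
  split at intensity saddles by watershed (tolerance 40% of the threshold
  excess).  Candidates overlapping a nucleus footprint or larger than 2 µm²
  are rejected.  The resolution limit is documented and tested: two spots
  closer than ~1$\sigma$ merge into one object, spots beyond ~4$\sigma$ are
  always resolved; at 40 nucleoids per cell and default geometry this costs
  about 5% of counts, which is why count recovery is benchmarked at ±10%
  with cell-wise correlation > 0.9.
* **Reticulum**: median + 3 MAD threshold on the membrane-potential channel
  (same relative floor), Zhang–Suen thinning to a one-pixel skeleton
  (compiled kernel), and path length per territory counting orthogonal steps
  as 1 px and diagonal steps as $\sqrt 2$ px, skipping diagonals that merely
  shortcut an orthogonal connection.  A straight 100-px filament therefore
  measures 99 steps — within the documented 2-px-equivalent tolerance.
* **Background** is the median intensity outside all objects, per channel.
* **Rho-0 rule**: nucleoid count ≤ 2 *and* summed puncta area ≤ 0.5 µm².
  "Void of mtDNA" has no numeric definition in the assay description; the
  conjunction tolerates the occasional isolated noise detection (single
  pixels, ~0.1 µm²) without ever passing a real mtDNA-positive cell, whose
  dozens of spots fail both gates.  With this rule the false-positive rate
  at SNR 10 is far below the 2% budget, so no minimum puncta area is needed
  (`nucleoid_min_area` defaults to 0).
* **Ploidy**: per culture, the G1 mode of nuclear integrated density is the
  highest kernel-density peak; cells above 1.5× that mode (halfway to the 2×
  S/G2 mode on a log scale) are called S/G2.  Cultures under 10 cells are
  degenerate and fall back to all-G1 with a warning.

# Screen statistics

* **Summaries** compute mtDNA content on $\log_{10}$ summed puncta area
  *excluding Rho-0 cells* (zero area has no logarithm); Rho-0 cells still
  count towards cell counts and the Rho-0 proportion.  Raw-scale means are
  kept alongside because the headline display of a screen is the *percent
  change vs baseline* on the raw scale, while hypothesis tests run on the
  log scale.  Percentages use means, not medians.
* **Test gate**: Shapiro–Wilk on each sample at $\alpha$ = 0.05; if either
  sample rejects (or is degenerate), a two-sided Mann–Whitney U (exact for
  both $n \le 20$ without ties, otherwise normal approximation with tie and
  continuity correction), else a two-sided Welch t-test.  The gate is a pure
  function of the two samples.  Complete-tie degeneracy returns p = 1.
* **Mixed models**: `log10(area) ~ treatment + (1 | run)` (plus `(1 | line)`
  across lines) absorbs run-level shifts — the generator plants exactly such
  log-normal run intercepts — and estimates the treatment effect within
  runs.  Singular fits fall back to run fixed effects with a warning.
  Calibration is verified by simulation: the gated test holds 5% ± 1 point
  over 3000 null draws and the mixed model stays ≤ 7% over 400 null screens.
* No multiple-testing correction is applied to the headline per-condition
  p-values; a Benjamini–Hochberg column is emitted alongside for reference.

# Depletion–recovery and pool inference

Relative copy number from a Ct pair is $2^{Ct_{B2M} - Ct_{mt}} \times 2$
(B2M is present at two copies per diploid genome; 100% efficiency is assumed
for both targets — normalised results are insensitive to both choices).

The recovery curve is $C(t) = C_0\,(d + (1-d)(1 - e^{-rt}))$ with residual
fraction $d$ after depletion (default 0.5) and rate $r$ per day.  Because
the curve approaches baseline only asymptotically, "reaches baseline by day
$T$" is operationalised by `recovery_rate_to_baseline()` as
$C(T) = 0.99\,C_0$ — a 1% shortfall, well inside qPCR noise.  Both arms of
an experiment are normalised to one *shared* pre-depletion untreated
reference, as the split-flask design implies; normalising each arm to its
own reference would turn the reference's measurement error into a coherent
per-arm shift and inflate the two-way ANOVA's false-positive rate several-
fold (we measured ~32% vs the nominal 5%).

The treatment test is a two-way ANOVA blocking time
(`rel ~ treatment + factor(day)`, no interaction term given the minimal
replication), plus per-day Welch t-tests where both arms have ≥ 2
replicates.  Its null calibration is verified by simulation.  A caveat the
simulations make explicit: with two replicates per arm/day and ~5% qPCR
noise, the design's power to detect a rate doubling at p < 0.01 is low
(~0.1–0.2), because the treatment-by-time curvature of the two converging
exponentials sits in the residual.  The per-day means and the pool-size
readout below are the stronger evidence in this design.

Heavy-isotope labelling: a supplement carrying a 10% heavy isotopologue
fraction is diluted by the endogenous pool before incorporation, so for
nucleoside $N$ the heavy fraction in new DNA is
$h \cdot \phi_N / (\phi_N + P_N)$ (flux $\phi$, pool $P$), and the observed
specific activity of total DNA is that times the fraction of DNA newly
synthesised.  `specific_activity()` is the heavy molar fraction
heavy/(heavy+light), assuming equal instrument response of isotopologues
(only the ratio is used).  `infer_pools()` normalises patient activities to
the control *median*, reports reciprocals as relative pool-size indices, and
calls the limiting nucleoside as the highest patient activity; candidates
within 5% (configurable) are reported jointly (e.g. `"dT/dG"`), since such
differences are below measurement resolution.  The default generator pools
(dA 8, dC 4, dG 2, dT 1 with flux 0.5) order the pools purines-largest /
thymidine-limiting and space adjacent specific activities ~1.7–1.9× apart,
which is what makes the limiting call reliable (≥ 95%) at the assay's 10%
measurement cv; more compressed pools are statistically unresolvable at that
noise level.

# Pipeline and reproducibility

`run_pipeline()` executes simulate → screen statistics → recovery → pools
under a single validated configuration (`pipeline_config()`; unknown keys
are rejected before any computation).  Every CSV is stamped with the
configuration's FNV-1a hash and `read_pipeline_table()` refuses to mix
hashes.  Re-running with the same config and seed reproduces every output
byte for byte; the manifest records hash, seed, package version and the
output list (and no timestamps, precisely so it too is reproducible).

# Problem sizes used in the tests

The packaged benchmarks use 9 fields × 20 cells at SNR 10 for count
recovery, ≥ 500 analysed cells per Rho-0 fraction (dense 512-px fields —
Rho-0 calling needs many cells, not resolved counts), 20 simulated screens
for effect recovery, 3000/400/600 simulations for the three null
calibrations, and 100 noisy tables for the limiting-nucleoside call.  These
sizes put Monte-Carlo error comfortably inside each asserted tolerance.

# Known limitations

* The generator's cells are convex, isolated and mononucleated; there is no
  optical PSF model, shot noise, illumination gradient or 3-D structure.
* Segmentation undercounts by the documented merge limit at high nucleoid
  density; summed-area readouts are correspondingly conservative.
* qPCR efficiency is fixed at 100% and the diploid ×2 factor is a
  convention; only normalised quantities should be interpreted.
* The reciprocal-activity "pool size" and the "synthesis rate" proxy are
  the same number viewed two ways; the package exposes both names and does
  not resolve which interpretation is intended.
* Dose–response modelling and hit-calling beyond percent change + test
  flags are out of scope.
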