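---
title: "Resting-state relative cerebrovascular reactivity: model, pipeline and design choices"
author: "rsCVR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state relative cerebrovascular reactivity: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsCVR)
```

## The measurement model

The BOLD signal mixes neuronal activity with vascular physiology. Arterial
CO2 is a potent vasodilator, and during natural breathing its slow
fluctuations (respiratory volume variation, roughly 0.02–0.04 Hz) drive
coherent, brain-wide BOLD fluctuations. Cerebrovascular reactivity (CVR) is
the vasodilatory response per unit vasoactive stimulus; without gas
challenges or CO2 recordings, an *absolute* CVR (%BOLD/mmHg) is out of
reach, but a *relative* CVR (rCVR) is not:

1. take the whole-brain (GM + WM + CSF) mean BOLD signal, band-limited to
   0.02–0.04 Hz, as a surrogate for arterial CO2 fluctuation;
2. regress each voxel's preprocessed series on (intercept, surrogate); the
   slope $\beta_v$ is the local BOLD response per unit global vasodilatory
   drive;
3. normalize: $\mathrm{rCVR}_v = \beta_v / \bar\beta_{\mathrm{WM}}$, where
   $\bar\beta_{\mathrm{WM}}$ averages $\beta$ over non-excluded white-matter
   voxels. White matter has far less vasculature than gray matter (on the
   order of 70–75% less), so it provides a stable, low-reactivity
   within-subject reference; a whole-brain ("global") reference is available
   as a variant.

Because numerator and denominator scale together, rCVR is invariant to any
global rescaling of the data and largely robust to motion — properties the
test suite asserts exactly.

Voxels whose inverse temporal SNR (temporal SD / temporal mean) exceeds the
98th percentile of in-mask voxels are excluded before normalization and
averaging; these are dominated by large vessels, CSF pulsation or artifact.
The percentile uses linear interpolation between order statistics and a
strict ">" rule, so on degenerate (tied) inputs nothing is excluded.

## Pipeline stages and parameters

`pipelineConfig()` carries every tunable with its default:

| parameter | default | unit | role |
|---|---|---|---|
| `bandCvrHz` | 0.02–0.04 | Hz | CO2-surrogate pass band |
| `bandFcHz` | 0.008–0.1 | Hz | FC pass band |
| `fdThresholdMm` | 0.25 | mm | frame-censoring threshold (strict >) |
| `maxCensoredFraction` | 0.25 | – | inclusion: censored fraction must be below this |
| `minRemainingMinutes` | 4 | min | inclusion: retained data after censoring |
| `smoothingFwhmMm` | 8 | mm | Gaussian smoothing kernel |
| `itsnrPercentile` | 98 | – | inverse-tSNR exclusion (100 disables) |
| `normalizationMode` | white_matter | – | rCVR reference (`global` variant) |
| `headRadiusMm` | 50 | mm | FD rotation-to-arc conversion |

Preprocessing expands the 6 rigid-body parameters to 18 regressors (the 6
parameters, their backward-difference derivatives, and their squares — the
count of 18 forces reading "squares" as squares of the base parameters),
adds an intercept, a linear trend and one one-hot spike regressor per
censored frame, and residualizes every voxel, retaining each voxel's
temporal mean so tSNR stays defined. Spike regression is algebraically
equivalent to deleting the censored frames (a property test verifies this
to 1e-8), which is why censoring "by regression" is sound. Framewise
displacement uses the standard sum-of-absolute-backward-differences
convention with rotations scaled by a 50 mm head radius; the formula is a
convention choice, consistent with the 0.25 mm threshold it is used with.
Mean FD — the subject-level motion covariate — is computed over all frames,
pre-censoring, since it indexes overall subject motion.

Smoothing is a separable 3D Gaussian with
$\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$, renormalized by the smoothed
mask so constant images are preserved inside the mask exactly.

The surrogate is extracted from the *fully preprocessed* data (regression,
then smoothing, then global mean), matching the stage order of the
preprocessing description; the stage is configurable. Band-pass filtering
is a 4th-order Butterworth applied forward–backward (zero phase) after a
linear detrend.

Functional connectivity adds white-matter and CSF mean series (over
one-voxel-eroded masks, limiting gray-matter partial-volume leakage) to the
nuisance design, band-passes residuals to 0.008–0.1 Hz, averages within
atlas regions, and reports seed-to-target Fisher-z values
$z = \mathrm{atanh}(r)$ with $|r|$ clipped at $1 - 10^{-12}$. Regression
precedes filtering by default; the reverse order is a flag.

Harmonization of the subjects-by-regions feature tables (regional rCVR and
seed-FC z, always in separate models) is empirical-Bayes location/scale
adjustment: per-feature standardization by covariate-adjusted mean and
pooled SD, per-site location ($\gamma$) and scale ($\delta^2$) estimates
shrunk toward parametric site-level priors (normal / inverse-gamma,
method-of-moments hyperparameters, iterative conditional updates to 1e-4).
Diagnosis, sex and mean-centered age are preserved as biological
covariates; the diagnosis-by-sex interaction can be added by flag but is
off by default, following the covariate list the analysis specifies. The
fit/transform split is exposed (`combatFit()` / `combatTransform()`) with
JSON persistence, and the implementation is cross-checked in the test suite
against `sva::ComBat` to near machine precision.

Group models use ordinary least squares with effect coding: diagnosis
ASD = −1 / non-autistic = +1, sex M = −1 / F = +1, interaction = product.
Under this coding and balanced cells the interaction coefficient equals the
cell-mean contrast $(\mu_{MA}+\mu_{FN}-\mu_{FA}-\mu_{MN})/4$, which the
tests reproduce exactly on noiseless designs. The region scan
(`regionEffects()`) reports signed betas and *uncorrected* p-values by
default — the scan is exploratory and that is an explicit flag — whereas
the rCVR–FC association family (`cvrFcAssociation()`) always applies
Benjamini–Hochberg FDR across targets within each subgroup. Age is
re-centered within each fitted sample (full cohort or stratum); mean FD
enters in raw millimetres. All p-values are two-sided.

## The synthetic cohort generator

`makeSubject()` builds a nested-sphere head phantom (CSF core, WM shell, GM
shell partitioned into 91 spatially coherent parcels by default) and
synthesizes, per gray-matter voxel in parcel $r$,

$$ y_{v,t} = B\,(1 + g_r s_t + a\,n_{r,t} + m_t u_{v}) + \varepsilon_{v,t}, $$

with baseline $B = 1000$, vascular gain $g_r$ (white matter uses
$g_{\mathrm{WM}} = 0.004$ with a mean GM:WM ratio of 3.5), surrogate $s_t$
(unit-variance filtered Gaussian noise, 0.02–0.04 Hz), band-limited
(0.008–0.1 Hz) neuronal signals $n_{r,t}$ with a network-structured
correlation (13 blocks of 7 regions, within-block $\rho = 0.3$ — resting
networks are internally coherent, not brain-wide coherent), motion
artifacts $m_t u_v$ active only at spike frames with an independent spatial
pattern per movement event, and i.i.d. noise
$\varepsilon \sim N(0, 20)$ (tSNR $\approx$ 50). The default acquisition is
150 frames at TR 2.5 s (inside the 2–3 s harmonization window) on a
20×20×20 grid of 4 mm voxels — a desk-scale problem that runs in fractions
of a second per subject. The amplitude of the vascular signal relative to
noise is deliberately a parameter, not a constant: it is not an empirically
pinned quantity in children.

`makeCohort()` generates subject-level regional rCVR features directly:
$\text{base}_r + b_{dx} x + b_{sex} y + b_{int} xy + \text{site}_{add} +
\text{site}_{mult}\,\epsilon$, under the same ±1 coding as the models, with
additive site offsets and multiplicative site factors applied to the
subject noise — exactly the location/scale structure the harmonization
model assumes, injected on regional summary features because that is what
harmonization operates on. A complete `cohortTruth` manifest (JSON-lossless)
records every injected quantity. `referenceCohortConfig()` reproduces the
reference cohort composition — 79/16/125/74 subjects in the male-autistic /
female-autistic / male-non-autistic / female-non-autistic cells across 8
sites — and can inject a female-specific diagnostic elevation in two
regions (design magnitudes 0.19 and 0.14, both as diagnosis and interaction
coefficients with negative sign under the coding above, so females differ
by diagnosis and males do not). With `images = TRUE` the biological
feature values are converted to voxel gains so the full voxel-level
pipeline can recover them.

**Noise calibration.** The subject-level regional noise SD defaults to
0.75 rCVR units. This was set analytically from the design: the standard
error of the ±1-coded interaction coefficient with cells $(79, 16, 125,
74)$ is $\sigma/4\sqrt{\sum 1/n_c} \approx 0.0777\,\sigma$, so
$\sigma = 0.75$ gives a detection $z \approx 3.26$ for a 0.19 interaction —
about 90% two-sided power at $\alpha = 0.05$. The generator's defaults are
the study conditions of every recovery experiment in the test suite and
acceptance script and are not tuned per test.

## What the generator emulates — and what it does not

It emulates: band-separated vascular and neuronal dynamics; gray–white
reactivity contrast; network-structured inter-regional correlation; motion
spikes with image-level artifacts; additive/multiplicative site batch
structure on regional features; and group effects under the models' own
coding. It does not emulate scanner k-space artifacts, susceptibility
distortion, slice timing, anatomical variability, registration error, or
hemodynamic-delay heterogeneity. Passing recovery tests therefore
demonstrates the *estimators* are correct under the stated signal model,
not that real pediatric multi-site data meet that model.

## Numerical choices and degenerate inputs

- Butterworth order 4, forward–backward (squared magnitude response);
  series shorter than three filter lengths are rejected. The surrogate
  generator filters twice so that ≥95% of periodogram power sits inside
  the requested band even for short runs.
- Percentile: linear interpolation (type-7 quantile); exclusion strictly
  above; non-positive voxel means auto-excluded with a warning.
- Censoring boundary: FD exactly at threshold is kept ("greater than" is
  strict). Spike columns are exactly one-hot; exactly collinear design
  columns are pruned with a message, and rank deficiency after pruning is
  an error naming the offending columns.
- Reference degeneracy: a white-matter mean beta at or below 1e-6 of the
  in-mask beta spread aborts normalization (no vascular signal present).
- Regions with no surviving voxels are NA (missing), never zero.
- Every stochastic function takes a seed and restores the caller's RNG
  state; cohort generation derives per-subject child seeds, all below
  2^31.

## Recovery experiments: design and problem sizes

The acceptance experiments (reproduced by `scripts/acceptance.R` and
asserted in `tests/testthat/test-acceptance.R`) use: 10 + 10 subjects for
noiseless/noisy gain recovery; one subject for scale-invariance and
censoring experiments (8 spikes of 2 mm — strong enough that the artifact,
not sampling noise, dominates the censoring comparison); 100 cohort
replicates (294 subjects each) for the motion-QC null; 100 correlation-pair
replicates at T = 150 for Fisher-z calibration; 2 sites × 500 subjects for
harmonization (sampling noise in per-site feature means is ~14% of the
feature SD at 100 subjects/site, which would mask the harmonization
itself); 1000 random instances for the OLS and FDR oracles; 20 null
cohorts × 91 regions for type-I error; and 25 reference-cohort replicates for
the end-to-end interaction pattern.

Two recovery experiments are run with smoothing off and exclusion off
(`smoothingFwhmMm = 0`, `itsnrPercentile = 100`): smoothing deliberately
mixes neighbouring parcels, and on noiseless phantoms the exclusion rule
removes the highest-gain parcel wholesale (every voxel of the top parcel
ties above the percentile), so the analytic identity
rCVR = gain ratio only characterizes the unsmoothed estimator. The
defaults themselves are unchanged.

The noisy gain-recovery experiment sets the neuronal amplitude to zero and
measures recovery under thermal noise. With the neuronal component active,
per-subject recovery saturates near $r \approx 0.9$ regardless of thermal
noise: over a 375 s run the 0.02–0.04 Hz band holds only ~7 independent
Fourier components, so the sample correlation between the surrogate and
each region's (independent) neuronal signal is $O(0.25)$, producing
region-specific slope contamination. This is a genuine property of
narrow-band surrogate regression — short resting runs yield noisy
individual rCVR maps — and is documented here rather than hidden by the
test design, which isolates it from estimator error.

## Known limitations

- Parametric empirical-Bayes harmonization is *not* idempotent: shrinkage
  toward site-level priors leaves feature-varying residuals, and a second
  pass re-adjusts sampling noise (at the 1e-3–1e-2 relative level at these
  cohort sizes). The reference implementation (`sva::ComBat`), which this
  package matches to ~1e-15, behaves identically. Refitting on harmonized
  data does return near-null site effects, which is the meaningful
  invariant and is what the module tests assert.
- Registration, segmentation and realignment are out of scope: all inputs
  must share one grid, and motion traces are taken as given.
- The global-signal surrogate conflates CO2 with any other systemic
  process occupying 0.02–0.04 Hz (cardiac/autonomic drift); nothing in the
  mathematics distinguishes them.
- rCVR is relative: between-group differences in the *reference* tissue
  would masquerade as parenchymal differences. The white-matter reference
  is chosen precisely because its reactivity is low and stable.

## A minimal run

```{r example, eval = FALSE}
cohort <- makeCohort(
  cohortConfig(cells = c(MA = 3, FA = 3, MN = 3, FN = 3), nSites = 2,
               nRegions = 8),
  seed = 1, images = TRUE,
  acq = acquisitionConfig(gridShape = c(12L, 12L, 12L)))
manifest <- runPipeline(cohort, pipelineConfig(), outDir = "run1")
head(manifest$regionStats)
```
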