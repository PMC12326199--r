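---
title: "Methods: predator-vision camouflage quantification in chromatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predator-vision camouflage quantification in chromatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromatch)
```

`chromatch` quantifies how well a colour-changing animal matches an
experimental background, as seen by an avian predator, and how that match
evolves over the minutes a physiological colour change takes. This vignette
is the package's own account of the models it implements, the parameters
that matter, the numerical choices behind them, and what the synthetic
validation does and does not demonstrate.

## Calibration

Cameras do not record reflectance. The measurement path therefore starts
from a `multiband_image` in state `"raw"` and enforces a strict state
machine: `raw → linear → reflectance`.

* `linearize()` inverts a user-supplied monotone camera response per band.
  The default is the identity because the intended inputs — synthetic
  renders and pre-linearized exports from RAW workflows — are already
  linear; a power-law response (`response_gamma()`) and arbitrary
  forward/inverse pairs are available. Monotonicity is checked on a grid of
  the image's value range and violations are an error, not a warning,
  because a non-monotone response silently corrupts everything downstream.
* `normalize_to_reflectance()` uses two grey standards photographed in the
  scene — 8.6% and 95.8% diffuse reflectance by default — to fit, per band,
  the unique affine map sending measured standard values onto their known
  reflectances. Affine maps can overshoot: values below zero are clipped
  (zero catch is the physical floor), values above one are kept but counted
  in a warning, since specular highlights are real data a caller may wish
  to mask rather than destroy.

ROI summaries are arithmetic means of masked pixels per band
(`extract_roi_mean()`). Masks are single-band rasters (nonzero = inside),
pixel coordinates are 0-based, row-major, origin top-left. Discrimination
operates on ROI mean catches — one value per region per image — not on
pixel-wise distances averaged afterwards; region means are the quantity the
receptor-noise model is defined on here.

## The receptor set and noise model

The default receiver is a violet-sensitive trichromat (ultraviolet
excluded) with a double cone for achromatic vision. Channel noise follows
the receptor-noise convention: the Weber fraction of the most abundant
chromatic class is the reference `w = 0.05`, and other classes scale as

$$e_i = w \sqrt{\eta_{\mathrm{ref}} / \eta_i},$$

with $\eta_i$ the relative abundances. The shipped abundances
(sw 1.9, mw 2.2, lw 2.1) are implementer-supplied values drawn from
published peafowl retinal data; they are explicitly configuration, not a
measurement this package can vouch for, and `receptor_set()` takes
replacements freely. The double-cone channel carries its own Weber fraction
(default 0.05).

The camera-to-receptor mapping (`catch_mapping()`) is deliberately plain: a
non-negative matrix applied to band means. The default is the identity on
three chromatic bands plus a double-cone row averaging the two
longer-wavelength bands. Fitting a real camera's spectral mapping is out of
scope; the mapping is exercised by every pipeline run but never estimated.

## Discrimination

`chromatic_jnd()` implements the trichromatic receptor-noise-limited
distance on log-transformed catches, $\Delta f_i = \ln(q_{A,i}/q_{B,i})$:

$$\Delta S = \sqrt{\frac{e_1^2(\Delta f_3-\Delta f_2)^2 +
e_2^2(\Delta f_3-\Delta f_1)^2 + e_3^2(\Delta f_1-\Delta f_2)^2}
{(e_1e_2)^2+(e_1e_3)^2+(e_2e_3)^2}}.$$

Log contrasts (rather than the small-signal linear approximation) are the
appropriate form for the large natural-scene contrasts this pipeline
measures. Three consequences are exploited as tests: symmetry in the two
stimuli, invariance to a pure intensity change ($\Delta S(cA, B) =
\Delta S(A, B)$), and exact inverse scaling in the noise vector. The
trichromatic form is hard-coded; dichromat or tetrachromat inputs raise an
error rather than silently generalizing, because the receiver model is a
scientific commitment, not a dimension parameter. The achromatic distance
is $\Delta S_L = |\ln(q_{A,\mathrm{dbl}}/q_{B,\mathrm{dbl}})|/w_{\mathrm{dbl}}$.

Zero catches are rejected everywhere (`chromatch_zero_catch_error`): the
log-ratio model is undefined at zero, and flooring silently would bias
distances. The record table reports both the raw double-cone catch (the
luminance used by the trend models) and $\Delta S_L$, covering both common
readings of an achromatic axis.

The validation suite cross-checks the closed form against an independent
oracle: $\Delta S$ equals the noise-weighted Euclidean distance from
$\Delta f$ to the achromatic line $\{(c,c,c)\}$, which the tests compute by
1-D numerical minimization. Agreement is required to a relative $10^{-10}$
on 1,000 random catch pairs.

## Granularity (pattern) analysis

Patterning is measured on the double-cone luminance image as energy per
spatial scale. Scales form a geometric ladder: 2 px, multiplier 1.414,
truncated at 724 px (18 scales). The 724 px cap corresponds to the smallest
animal-flank extent in the motivating assay at 18 px/mm; callers analysing
other data should cap the ladder at their smallest ROI extent
(`build_scale_series(max_scale = ...)`), and `energy_spectrum()` refuses
ladders larger than the image.

The bandpass is a difference of Gaussian low-pass transfer functions in the
frequency domain, with spatial standard deviations proportional to the two
bounding scales; scale $s_k$'s band spans $(s_k/1.414,\, s_k]$. The
proportionality constant is calibrated analytically:
$\sigma(s) = s\sqrt{\ln 2}/\pi$ makes the continuum response of band $s$
to a sinusoid of period $P$ peak exactly at $s = P$ (for the $\sqrt2$
multiplier, the band response $e^{-a s^2/2} - e^{-a s^2}$, with
$a = 2\pi^2\sigma_1^2 f^2 s^{-2}$, is maximized when $a s^2 = 2\ln 2$).
Tests confirm horizontal square waves of period 4–32 px peak exactly at
their period, period 64 within one ladder step, and an 8-px checkerboard
within one step of 8 (its strongest Fourier component is the diagonal at
$16/\sqrt2 \approx 11.3$ px).

Two numerical choices matter:

* The full image is mirror-padded (by the largest scale) and filtered
  whole; the ROI mask restricts only the standard-deviation computation.
  Filtering a cut-out ROI directly would leak boundary ringing into the
  energy estimate.
* Energy is the sample SD of filtered values over masked pixels. Since the
  transfer function vanishes at zero frequency, energy is invariant to
  adding a constant to the image and homogeneous of degree 1 in contrast —
  both tested exactly.

A $\sqrt2$-spaced difference-of-Gaussians band transmits at most 1/4 of a
sinusoid at its centre and has soft shoulders, so band energies are *not*
comparable to an ideal-annulus decomposition: in a period-16 square wave
the 2-px band legitimately receives the 7th harmonic (period 2.29 px), and
the 16-px band exceeds it by a factor ≈3.5, not the order of magnitude an
ideal filter would give. The tests freeze that factor from a direct-DFT
oracle of the same filter. Likewise, random square-patch mosaics (see
below) carry most of their variance *above* the patch scale — runs of
same-coloured patches merge into larger structures — so their dominant
scale sits at roughly 2–3× the patch edge; the tests assert strict ordering
in patch size rather than equality with it.

`dominant_scale()` is the energy argmax with ties broken toward the
smaller scale (a deterministic convention; ties are measure-zero on real
data). The pattern distribution difference is the unnormalized sum of
absolute energy differences across scales — the simplest aggregate
consistent with "difference in pattern energy across scales". It is a
pseudometric (non-negative, symmetric, triangle inequality), which the
suite verifies on random spectra. Whether to normalize spectra (e.g. by
total energy) before differencing is a genuinely open choice; normalization
would make PDD contrast-invariant but blind to overall pattern strength,
and absolute PDD magnitudes are not comparable across implementations that
choose differently, or across bit-depth conventions.

## Trend models

The statistical stage consumes one record per photograph (individual,
trial, treatment, time in minutes, plus responses) and fits

```
response ~ time_min * treatment + (1 | individual_id) [+ (1 | trial)]
```

with `lmerTest`. Conventions:

* Slopes, their standard errors, Satterthwaite degrees of freedom, 95%
  confidence limits and t-ratios come from REML fits via single-degree
  contrasts (`slope_table()`, also the `tidy()` method). If the
  Satterthwaite computation fails the code falls back to residual df — the
  validation compares estimates, SEs and t-ratios, not df, because
  fractional df are approximation-method-dependent.
* The interaction test refits both nested models with ML (REML
  log-likelihoods are not comparable across fixed structures) and reports
  the likelihood-ratio chi-square with df equal to the fixed-parameter
  difference.
* Pairwise slope contrasts are differences of the per-treatment slope
  contrasts, with Benjamini–Hochberg adjustment (`bh_adjust()`, a
  validated wrapper over `stats::p.adjust`) across the family of pairs.
* Time is a continuous covariate in minutes. The two photographic grids —
  0, 1, 3, then 3-minute steps to 21; and a short second trial at
  0, 1, 3, 6, 9 — are pooled with trial as a random intercept. The second
  trial and its random term apply to the uniform colour treatments only;
  greyscale trials are analysed with the individual intercept alone
  (whether a trial term belongs there is ambiguous in the motivating
  design; the package exposes `random_terms` so either choice is one
  argument away).
* The hue analysis uses chromatic JND as response; the greyscale analysis
  uses the raw double-cone catch (brightness), so its slopes are in catch
  units per minute.
* `pdd_matching_anova()` is a one-way ANOVA of PDD by an exposed /
  non-exposed label, run within one colour family at a time (black/white;
  green/yellow), testing whether animals match the pattern scale they
  actually sat on more closely than the other candidate scales.

`emmeans::emtrends` is deliberately *not* the implementation: it serves as
an independent cross-check in the test suite, which requires agreement of
slopes, SEs, df and confidence limits.

## The synthetic-experiment generator

The generator defines the study conditions under which the pipeline is
validated. Its defaults:

* 10 individuals; 13 treatments — four uniform hues (yellow, yellow-green,
  orange, blue-green), three greyscale levels (black, grey, white, sharing
  chromatic ratios and differing only in brightness), and six random
  square-patch mosaics (black/white and green/yellow at 16, 45 and 128 px
  patch edges, well separated on the scale ladder).
* Band reflectances for the palette are package configuration chosen to be
  colourful but plausible; yellow-green and blue-green sit close to the
  resting animal colour (starting chromatic JND ≈ 3), yellow and orange
  far from it (≈ 18–21 JND), mirroring the regime of the motivating assay.
* Colour change is an exponential approach per receptor,
  $q_i(t) = b_i + (q_i(0) - b_i)e^{-\lambda t}$, with mean-one
  multiplicative lognormal observation noise (`noise_cv`, default 0.05)
  and per-band lognormal individual intercepts (`individual_sd`, default
  0.10). This is the simplest smooth model consistent with minutes-scale
  physiological colour change; it is a stand-in, not a mechanistic claim.
  Default per-minute rates are calibrated so the default experiment shows
  changes of realistic magnitude: strongest on yellow
  (λ = 0.003) and black (0.015), moderate on orange (0.002) and white
  (0.008), weak where the animal already matches, zero on the grey
  control.
* `render_trial_images()` produces the image-path version: a raw-state
  image per time point with a background region (uniform or mosaic), a
  rectangular animal patch following the same trajectory, and two embedded
  grey-standard patches behind a linear synthetic camera
  (`gain × reflectance + offset`), so calibration is exercised end to end.
  `generate_records()` is the fast record-level path through the identical
  vision/discrimination code.

What the generator does *not* emulate: animal movement and pose (ROIs are
fixed rectangles), non-uniform lighting and vignetting, specularities,
ultraviolet reflectance, textured animals by default, or any behavioural
response. Passing the closure tests therefore demonstrates that the
*measurement and inference machinery* is correct under the generative
model's assumptions — it cannot certify performance on photographs whose
artefacts the generator omits.

## Validation design and problem sizes

The suite validates each stage against an independent route and the whole
against known ground truth, at sizes chosen to keep a full run to a few
minutes: 1,000 random catch pairs for the RNL oracle; 128×128 textures for
dominant-scale recovery with an explicit DFT-matrix oracle on 64×64 and
32×32 crops; 500 replicate experiments (10 individuals, 9-point grid,
3 treatments) for slope unbiasedness and interval coverage; 1,000 simulated
null experiments (8 individuals, 5-point grid) for the size of the
likelihood-ratio test; and a 3-individual, 5-treatment rendered experiment
for simulate→measure→analyse closure under noiseless fast approach.
`scripts/acceptance.R` recomputes the same quantities from scratch under a
caller-supplied seed.

## Known limitations

* Only the trichromatic RNL form is provided; receivers with two or four
  chromatic classes are rejected by design.
* Camera spectral-sensitivity estimation, RAW decoding, ultraviolet
  channels and flat-field correction are out of scope; inputs must already
  be band-registered rasters.
* Absolute PDD values depend on filter shape, spectrum normalization and
  image bit-depth conventions; compare PDDs only within one configuration.
* The greyscale/colour split of responses (double-cone catch vs chromatic
  JND) is a fixed convention of `cmd_analyse()`; custom analyses can call
  `fit_time_by_treatment()` with any response column.
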