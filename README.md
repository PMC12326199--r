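# chromatch

Quantifying dynamic background matching through the eyes of a predator.

Many colour-changing animals — chameleons are the canonical case — are
claimed to tune their appearance to the background they sit on. Testing that
claim rigorously requires measuring an animal's colour, brightness and
patterning *as its predators would see them*, repeatedly over the minutes a
physiological colour change takes, and asking whether the match to the
background improves. `chromatch` is an R implementation of that full
analysis pipeline, aimed at sensory ecologists working with calibrated
multiband photographs of animals on standardized experimental backgrounds.

The pipeline has five stages, each usable on its own:

1. **Calibration** — linearize raw camera values and map them to reflectance
   with two photographed grey standards (8.6% and 95.8% reflectance by
   default), then summarize polygon regions of interest (ROIs).
2. **Vision** — convert per-band reflectances into photoreceptor quantum
   catches for a violet-sensitive avian trichromat plus the double cone that
   mediates avian achromatic vision.
3. **Discrimination** — compute chromatic distances between animal and
   background in the receptor-noise-limited (RNL) model. For catches
   `q`, log contrasts `Δf_i = ln(q_A,i / q_B,i)` and channel Weber fractions
   `e_i` (reference 0.05, scaled across channels as
   `e_i = w √(η_ref / η_i)`):

   ```
   ΔS = sqrt( [e₁²(Δf₃−Δf₂)² + e₂²(Δf₃−Δf₁)² + e₃²(Δf₁−Δf₂)²]
              / [(e₁e₂)² + (e₁e₃)² + (e₂e₃)²] )
   ```

   in just-noticeable-difference (JND) units; the achromatic distance is
   `ΔS_L = |ln(q_A,dbl / q_B,dbl)| / w_dbl`. Values below ~1 JND are
   indistinguishable to the receiver.
4. **Granularity** — decompose the double-cone luminance image into pattern
   "energy" (SD of a frequency-domain bandpass) over a geometric ladder of
   spatial scales (2 px, ×1.414, up to 724 px), yielding the dominant
   spatial scale and the pattern distribution difference (PDD) between
   animal and background spectra.
5. **Trends** — linear mixed-effects models
   `response ~ time × background + (1 | individual) [+ (1 | trial)]`
   with per-background time slopes (Satterthwaite df), pairwise slope
   contrasts under Benjamini–Hochberg correction, a likelihood-ratio test of
   the time-by-background interaction, and a one-way ANOVA testing whether
   animals match the pattern scale they were exposed to.

Because the original photographs of any given study live in external
archives, the package ships a first-class synthetic-experiment generator
(`experiment_config()`, `generate_records()`, `render_trial_images()`) that
renders image series with known ground truth — 13 background treatments
(4 hues, 3 greyscale levels, 6 patch mosaics), two repeated-photography time
grids, individual variation and measurement noise — so every stage can be
validated end to end.

## Worked example

How far is a resting animal from a yellow background, in avian JNDs?

```r
library(chromatch)

receptors <- receptor_set()   # VS trichromat + double cone, Weber 0.05
animal     <- c(sw = 0.15, mw = 0.40, lw = 0.35, dbl = 0.375)
background <- c(sw = 0.08, mw = 0.55, lw = 0.70, dbl = 0.625)
compare_rois(animal, background, receptors)
#> # A tibble: 1 × 3
#>   chromatic_jnd achromatic_jnd weber_used
#>           <dbl>          <dbl>      <dbl>
#> 1          18.3           10.2       0.05
```

18.3 JND: a flagrant chromatic mismatch (anything above ~1–3 JND is readily
distinguished), and 10.2 JND darker than the background.

Does a simulated population darken on a black background? Generate a
synthetic experiment, fit the luminance trend model, and read the slopes:

```r
cfg  <- experiment_config(n_individuals = 6,
                          treatments = c("yellow", "grey", "black"),
                          seed = 7)
recs <- generate_records(cfg)$records

fit <- fit_time_by_treatment(
  dplyr::filter(recs, treatment %in% c("grey", "black")),
  luminance, random_terms = "individual")
tidy(fit)
#> # A tibble: 2 × 8
#>   treatment     slope       se    df lower_cl  upper_cl t_ratio  p_value
#>   <chr>         <dbl>    <dbl> <dbl>    <dbl>     <dbl>   <dbl>    <dbl>
#> 1 black     -0.00499  0.000337  99.0 -0.00565 -0.00432   -14.8  8.26e-27
#> 2 grey      -0.000554 0.000337  99.0 -0.00122  0.000115   -1.64 1.04e- 1

pairwise_slope_contrasts(fit)
#> # A tibble: 1 × 7
#>   contrast          estimate       se    df t_ratio  p_value p_adjusted
#>   <chr>                <dbl>    <dbl> <dbl>   <dbl>    <dbl>      <dbl>
#> 1 black versus grey -0.00443 0.000477  99.0   -9.30 3.76e-15   3.76e-15
```

Double-cone catch falls by 0.005 per minute on black (animals darken), is
flat on the grey control, and the black-versus-grey slope difference is
strongly supported. `plot_trajectories(recs, luminance)` and
`autoplot(fit)` draw the trajectories and the slope intervals;
`autoplot()` on an `energy_spectrum()` draws pattern-energy spectra.

A file-based interface (`cmd_simulate()`, `cmd_measure()`, `cmd_analyse()`,
driven by a YAML config; thin CLI in `inst/cli/chromatch.R`) runs the same
pipeline over image directories.

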