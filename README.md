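# dfmap — Diagnostic Feature Mapping by Gabor-wavelet reverse correlation

`dfmap` implements a reverse-correlation pipeline for mapping which visual
features of a face drive accurate categorisation — here, the child-vs-adult
discrimination that matters to, for example, forensic image analysts. It is
aimed at visual psychophysicists who want to run, simulate, or re-analyse
Diagnostic Feature Mapping (DFM) experiments, where stimuli are built from
random subsets of Gabor wavelet features so that diagnosticity can be
estimated jointly over **position**, **spatial frequency (SF)** and
**orientation** in a single experiment.

## The method

1. **Gabor decomposition.** Each greyscale face image (250×250 px by
   default) is reduced to its 2200 best-fitting Gabor wavelets, drawn from
   a dictionary of 20 SF levels geometrically spaced from 2.4 to 87 cycles
   per image × 12 orientations (15°…180°) × every pixel position. The fit
   score is the normalised least-squares correlation of the image with the
   channel's quadrature pair (phase fitted analytically); amplitudes are
   equalised at reconstruction.

2. **Stimulus synthesis.** A trial's stimulus is the sum of a random subset
   of the 2200 features, linearly rescaled to span the full 0–255 range.
   Standard preprocessing (similarity-Procrustes landmark alignment,
   elliptical masking, luminance equalisation) is included.

3. **Adaptive sessions.** The number of features shown per trial is driven
   by a QUEST staircase (Weibull psychometric model in log10 feature count)
   targeting 75% accuracy over 2400 trials per participant; the converged
   feature-count threshold is the individual performance index.

4. **Reverse correlation.** The Feature Diagnosticity index weights each
   trial's sampled-feature indicator by the participant's z-scored
   accuracy and sums over trials:

   `FDi[p, i, f] = Σ_t  selected_t(f) · z_t`,

   giving a participants × images × features tensor. FDi is then
   reprojected to image positions (Gaussian-smoothed, sd 10 px), and band
   profiles over the 20 SF and 12 orientation levels are computed from the
   per-trial band sampling; child vs adult faces are compared with
   unpaired pooled-variance t-tests.

Because the original face photographs and human observers cannot be
redistributed, the package ships a first-class synthetic study: a face-like
image generator that injects category-diagnostic Gabor atoms at known
positions, SF bands and orientations, plus a simulated observer whose
decision rule uses exactly those features — so the whole pipeline's
recovery can be scored against ground truth.

## Worked example

A miniature study (64-px images, 6 SF × 4 orientation dictionary, 500
features, 4 participants × 600 trials; the defaults run the full 250-px,
2200-feature, 16 × 2400 study in a few minutes):

```r
library(dfmap)

cfg <- dfm_config(image_size = 64, n_sf = 6, sf_min = 2.4, sf_max = 20,
                  n_orientations = 4, orientation_step = 45,
                  n_features = 500)
signal <- tibble::tribble(
  ~category, ~fx,  ~fy,  ~sf_level, ~orientation, ~sign,
  "child",   0.50, 0.40, 3L,        90,           1,
  "child",   0.34, 0.44, 6L,        90,           1,
  "child",   0.66, 0.44, 6L,        90,           1,
  "adult",   0.50, 0.45, 5L,        180,          -1,
  "adult",   0.34, 0.32, 5L,        180,          -1,
  "adult",   0.66, 0.32, 5L,        180,          -1)

run <- run_pipeline(dfm_run_config(
  master_seed = 1, n_participants = 4, n_trials = 600,
  dictionary = cfg,
  face_spec = synthetic_face_spec(category_signal = signal)))
run
#> <dfm_run> 4 participants x 600 trials = 2400 trials; 12 images
#> <dfm_recovery>
#>   significant pixels: 21.7% (94.7% of them inside true signal regions)
#>   child SF bands 5.6, 20 cpi -> ranks 2, 1 of 6 (signs ok: TRUE)
#>   primary child orientation 90 deg -> rank 2 of 4 (signs ok: TRUE)
#>   FDi template correlation: 0.667
```

Reading this: 95% of the map pixels showing a significant child–adult
contrast lie inside the regions where the generator injected its signal
atoms; the two injected child SF bands (5.6 and 20 cpi) are the top
child-signed bands; and the participant- and image-averaged FDi vector
correlates 0.67 with the observer's true feature weights.

Each staircase session tracks the 75% target:

```r
run$sessions[[1]]
#> <dfm_session> 'p01': 600 trials, accuracy 0.793, threshold 165 features
run$sf_contrast          # per-band t statistics (positive = child evidence)
autoplot(run$position_contrast)   # pixelwise t map (positive = adult evidence)
autoplot(run$sf_contrast)         # band profile with significance stars
```

Lower-level entry points: `decompose_image()`, `render_stimulus()`,
`quest_init()/quest_update()/quest_recommend()`, `run_session()`,
`compute_fdi()`, `project_positions()`, `band_profile()`,
`contrast_maps()/contrast_bands()`, `recover_ground_truth()`. Fitted
objects have `tidy()`/`glance()` methods; results serialise to PNG, CSV
and JSON via the `write_*`/`read_*` helpers.

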