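---
title: "Diagnostic Feature Mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic Feature Mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dfmap)
```

This vignette is the package's account of the science behind its pipeline:
the models and procedures it implements, the parameters that matter and
why their defaults are what they are, what the synthetic data emulate (and
what they deliberately do not), and the numerical and design choices made
where the method leaves room.

## The problem and the estimator

Reverse correlation asks which parts of a stimulus drive a perceptual
decision: present randomly sampled stimulus content over many trials and
correlate what was shown with how the observer responded. Diagnostic
Feature Mapping is the variant in which the sampled content is a set of
Gabor wavelets fit to the source image, so that the recovered "diagnostic
features" are simultaneously localised in position, spatial frequency
(SF) and orientation — the three dimensions early visual cortex cares
about.

The core estimator is the Feature Diagnosticity index. With
`selected_t(f)` the indicator that feature `f` of the shown image was
sampled on trial `t`, and `z_t` the trial's correctness z-scored over all
of a participant's trials,

```
FDi[participant, image, f] = sum over trials t of that image of selected_t(f) * z_t
```

A feature whose presence systematically co-occurs with accurate responses
accumulates positive FDi. Three read-outs follow: FDi reprojected to the
feature centres and Gaussian-smoothed (positional maps), and per-trial
band-sampling correlated with correctness over the 20 SF and 12
orientation levels (band profiles). Each is contrasted between the child
and adult image groups with unpaired pooled-variance t-tests at
`alpha = 0.05`, uncorrected; with 6 images per category the tests have
10 degrees of freedom. The display conventions are: positional maps,
positive t = adult evidence; band profiles, positive t = child evidence.

## The Gabor dictionary and the fit score

A dictionary channel is one (SF, orientation) pair; the candidate set is
every pixel centre of every channel. Defaults follow the study
configuration: 20 SF levels geometrically spaced between 2.4 and 87
cycles per image (so consecutive levels have a constant ratio, and the
endpoints are exact), 12 orientations in 15° steps, 2200 retained
features for a 250 × 250 px image. The printed formula for the SF levels
in the source material is internally inconsistent with its own stated
endpoints; geometric spacing is the reading consistent with
"exponentially increasing" between the endpoints, and it reproduces the
significant band values reported there (level 5 ≈ 5.11 cpi, level
13 ≈ 23.2 cpi, level 17 ≈ 49.4 cpi).

Scoring: the image (mean removed — DC is not representable by Gabor
atoms) is correlated with each channel's even/odd quadrature pair by FFT
(zero-padded, kernels truncated at 4 envelope sds), the projections are
combined through the kernel Gram matrix, and the projection norm is
expressed per unit kernel energy. This is the least-squares correlation
with a unit-energy atom: an image patch that *is* a dictionary atom of
amplitude A scores A/√2 at its own channel and position, whatever its SF,
so ranks are comparable across channels instead of favouring large
envelopes. The best-fitting phase is the quadrature arctangent; phases
and amplitudes of the selected atoms are refit with 6-sd kernels, whose
truncation error is below 1e-6.

Two parameters deserve comment:

* **Envelope size** (`size_multiplier`, envelope sd in carrier
  wavelengths, default 1 ≈ half-octave bandwidth). The quadrature fit
  magnitude is phase-invariant, so its spatial autocorrelation decays
  only with envelope overlap, `exp(-d²/(4·sd²))`, and its cross-channel
  correlation decays with tuning bandwidth. At one-octave bandwidth
  (0.5 wavelengths) a strong image component "chains" across neighbouring
  SF levels at ~0.85 correlation per step, flooding the feature budget
  with near-duplicates of the few strongest components and starving other
  channels; at half-octave the chain dies within a couple of steps and
  selections keep a balanced channel composition. The narrower bandwidth
  is standard in Gabor-jet representations.

* **Selection separation** (`min_separation_fraction`, default 2
  wavelengths = 2 envelope sds). For the same reason, same-channel
  candidates closer than ~2 envelope sds are near-duplicates (≥ 0.4
  correlation); the greedy ranking enforces this minimum centre distance
  per channel, with deterministic tie-breaks (channel index, then
  row-major position). Whether the original analysis deduplicated
  overlapping atoms is unstated; some deduplication is necessary for the
  2200 features to cover the image at all.

Rank mode (the default) scores once and takes the best candidates;
pursuit mode subtracts each selected atom's exact local fit from a
residual before rescoring, which guarantees non-increasing residual
energy but costs one full rescore per atom — it is intended for small
configurations.

**Equal amplitudes.** Reconstruction and stimulus rendering sum the
selected atoms at amplitude 1 with their fitted phases; fitted amplitudes
are retained as metadata only. One consequence, verified in the tests: on
images with a graded amplitude spectrum, reconstruction fidelity rises
monotonically with the number of features, but on images dominated by a
few strong components (like the synthetic faces below) fidelity peaks
within the first tens of features, because weakly fitting atoms are
over-amplified. This is a property of the equal-amplitude rule itself.

## The staircase

The number of features per trial is controlled by a Bayesian adaptive
staircase (Watson–Pelli QUEST) on `log10(feature count)` — thresholds on
counts are ratio-scaled, and the staircase assumes translation invariance
on its intensity axis. The assumed psychometric function is a Weibull
with slope `beta = 3.5`, guess rate `gamma = 0.5` (two-alternative
forced choice), lapse `delta = 0.01`, reparameterised so that the
threshold parameter sits exactly at the target probability
(`target_p = 0.75`): `p(x; T) = gamma + (1 - gamma - delta) *
(1 - exp(-10^(beta (x - T + eps))))` with `eps` solving `p(T) = target_p`.
The prior over the log10 threshold is Gaussian (mean `log10(300)`, sd 1),
discretised at 0.01 log10 units on a grid symmetric about the prior mean
(so the initial posterior-mean recommendation is the prior mean, 300
features, rather than an artefact of grid truncation); each trial's
recommendation is the posterior-mean intensity, exponentiated, rounded
and clipped to `[1, 2200]`. These are conventional psychophysics-toolbox
settings; all are configurable, since the source material cites the
algorithm without stating them.

One behaviour worth knowing: 50%-accuracy feedback (chance for 2-AFC) at
a fixed intensity correctly drives the threshold estimate *upwards* — for
a guess rate of 0.5, chance performance is evidence that the intensity is
far below threshold, not near it.

## What the synthetic data emulate

`generate_faces()` stands in for an aligned, masked,
luminance-equalised face set — with ground truth. All exemplars share one
base structure: a soft-edged elliptical "face" with eye, eyebrow, nose
and mouth blobs, plus a fixed texture field (sd 6 grey levels, constant
across all images and exemplars) that plays the role of skin texture and
shading: it populates every channel with genuine structure so that the
2200 selections have a realistic, balanced band composition. Category
information is injected as Gabor atoms *from the analysis dictionary
itself* (integer positions, dictionary SF level and orientation, phase 0,
amplitude 60 grey levels), so the ground truth maps directly onto the
analysis's feature space without registration:

* child signal: low SF (level 5, ≈ 5.1 cpi) horizontal (90°) across the
  eye band, high SF (level 17, ≈ 49.4 cpi) horizontal at the eyes and
  mouth corners, and low-SF obliques (60°/150°) at the jaw;
* adult signal: mid SF (level 13, ≈ 23.2 cpi) vertical (180°) along the
  glabella–nasal line and at the eyebrows.

Amplitude 60 places the atoms' fit scores at the top of the ranking while
keeping every pixel inside 0–255 under the exemplar jitter below.
Same-channel atoms are placed at least one selection separation apart so
each is recovered as its own feature; `diagnostic_indicator()` matches
each injected atom to the nearest same-channel feature within half a
separation (unambiguous by construction) and is the key against which
recovery is scored.

**Exemplar variability** is luminance gain (sd 0.06 around 1) and offset
(sd 3 grey levels) jitter — the classic photographic nuisance that
luminance equalisation removes in a real pipeline. Crucially, gain and
offset change the images but not the *ranking* of fit scores, so the
diagnostic features of same-category exemplars occupy identical feature
indices; that exact index correspondence is what makes cross-image FDi
averages (and the template-recovery score) well defined. Additive white
pixel noise is available (`exemplar_noise_sd`) but defaults to 0: it
perturbs ranks by several indices per unit sd and thereby destroys the
correspondence — measured, not hypothesised. What the generator therefore
does **not** emulate: identity variation between exemplars of a category,
photographic noise, geometric variability (the landmark/alignment stage
is exercised by its own tests with explicitly jittered landmark sets),
and anything about real craniofacial structure. Passing the recovery
tests shows the estimator recovers known structure under its own
assumptions — not that real child and adult faces differ where the
synthetic signal was placed.

**The simulated observer** is linear in the sampled features, matching
the estimator's assumptions: evidence = Σ selected(f) · w(f) + Gaussian
internal noise (sd 1), respond "child" if evidence exceeds criterion 0,
with a 2% lapse rate; `w` is +1 on a child image's diagnostic features
and −1 on an adult image's. With the default design the observer's 75%
point sits near 360 features and QUEST holds late-session accuracy at
~75% (the cohort mean across 16 participants is 75.5–76.6% over the
final 1000 trials across master seeds). A `weibull_observer()` whose
accuracy depends only on the *number* of features (with a known 75%
point) serves the staircase-recovery checks, and `null_observer()`
(responses independent of sampling) serves type-I calibration.

## Band profiles: the predictor choice

The band profile correlates per-trial band sampling with correctness,
pooling each image's trials across participants. The predictor is the
**proportion** of the trial's presented features falling in the band, not
the raw count: under staircase control the total feature count varies
across trials and itself correlates with accuracy, so raw counts load
*every* populated band with that shared intensity effect, and the
child–adult contrast then ranks bands by composition differences rather
than by diagnosticity (measured on the default design: the injected
child SF bands ranked {1, 10} of 20 with counts, {1–3} with proportions).
The count predictor remains available (`predictor = "count"`). A residual
second-order confound is unavoidable in any within-trial decomposition:
sampling many features of one band leaves slightly fewer draws for the
diagnostic features (hypergeometric competition), which can give heavily
populated bands small category-consistent coefficients; at the default
composition this stays well below the injected bands' effects for the SF
axis and below the primary orientation band in the large majority of
seeds.

## Calibration checks and problem sizes

Pixelwise p-values of a smoothed map are spatially correlated, so a
binomial check of the 5% false-positive rate over raw pixels would be
invalid. Type-I calibration under the null observer is therefore checked
on (a) the SF bands, (b) the orientation bands, and (c) a pixel lattice
thinned to one sample per 4 smoothing sds (`contrast_typeI_fraction()`),
pooled over 10 seeded replicates, against a 3-binomial-sd band around
0.05.

Problem sizes used by the test-suite, chosen as this package's own
standard configurations: exact-arithmetic fixtures and brute-force
oracles run on 8–64 px dictionaries of 4–24 channels; property checks on
a 64-px, 6 SF × 4 orientation, 500-feature desk-scale study (500 because
the 64-px dictionary's capacity under the separation rule is ~575); the
end-to-end recovery and cohort bookkeeping checks run the full 250-px,
20 × 12-channel, 2200-feature dictionary with 16 participants × 2400
trials (38,400 trials), which completes in a few minutes.

## Known limitations

* The synthetic faces are cartoons with an engineered, index-aligned
  ground truth; none of the recovery results transfer claims to real
  faces.
* Equal-amplitude reconstruction fidelity is non-monotone on
  sparse-spectrum images (above).
* The band estimator retains the hypergeometric-competition confound;
  with few images per category (df = 10) individual weak bands — e.g. the
  single-atom oblique orientations of the default design — can fluctuate
  in sign from seed to seed.
* Significance is uncorrected across pixels and bands, mirroring the
  original analysis; a permutation-based correction is a natural
  extension but is not implemented.
* The preprocessing order implemented is align → mask → equalise; the
  original order, and the exact equalisation operation used there, are
  unstated. Histogram matching to the set-average histogram is the
  implementation here.
* Sessions are simulated in feature space; display timing, viewing
  geometry and human response processes are out of scope.
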