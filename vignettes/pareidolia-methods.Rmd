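---
title: "Models and methods behind pareidolia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pareidolia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pareidolia)
```

This vignette documents the models implemented in **pareidolia**, the
assumptions behind them, the parameter choices that matter, and the
places where the design was genuinely open and a choice had to be made.
It states no empirical result that the package's tests and acceptance
script do not themselves compute.

## The task being modelled

The package models a divided-visual-field yes/no detection experiment:
on each trial a briefly presented (180 ms) image appears left or right
of fixation, and the observer reports whether it contains a signal
object — a face or a flower — or only noise. Blocks are signal-type
pure (the observer knows what to look for), stimuli are unique within a
block, and the interesting dependent variables are the equal-variance
signal-detection measures *d′* (sensitivity) and *c* (response bias)
per signal category and hemifield, their relationship to schizotypy
trait scores, and correct-trial reaction times. Because stimuli are
built to sit near detection threshold, false alarms — "seeing" a signal
in pure noise — are frequent enough to measure and lateralise.

## Stimulus synthesis

### Pink-noise fields

Noise fields have an amplitude spectrum proportional to 1/f in radial
spatial frequency, the second-order statistic of natural scenes.
Synthesis is spectral: a white Gaussian field is transformed, its
spectrum normalised to unit amplitude (leaving uniform random phase
with exact conjugate symmetry), multiplied by a deterministic 1/f
envelope with the DC term zeroed, and inverse-transformed. The result
is recentred on the mean luminance (128 on the 8-bit scale) and scaled
to the target RMS contrast exactly. Because the amplitude envelope is
deterministic, the radially averaged log-amplitude spectrum of every
generated field fits a log–log slope very close to −1; the test suite
checks the fitted slope stays within [−1.1, −0.9].

### Signal images

Photographic face and orchid images cannot be redistributed, so the
package ships four procedurally drawn stand-ins (two schematic faces,
two schematic flowers), rasterised directly at the standardised signal
size: 150 px high, 110 px wide for faces, 120 px for flowers. They are
synthetic by construction and documented as such; they carry the
properties the pipeline actually depends on — bilateral symmetry,
dark configural strokes on a mid-grey ground, matched mean
luminance — not photographic realism. `prepare_signal_image()`
standardises any user-supplied grayscale image the same way: bilinear
resampling to the target height and an additive shift of the mean to
the cross-image average, so no image is detectable from overall
luminance alone.

### Mixing, filtering, contrast

A composite stimulus is built in a fixed order: the signal image is
embedded in a fresh noise field at one of eight lateralised positions
(four elevations per side of the vertical midline); a companion
noise-only field is scaled to the same RMS contrast; the two are
combined pixel-wise; both images are band-pass filtered; the final RMS
contrast is enforced; and the result is quantised to 8 bits. Design
choices within that chain:

* **Exact-count mixing.** "A proportion of pixels" could mean
  independent Bernoulli draws per pixel or an exact count; the package
  designates exactly `round(fraction × N)` positions by a seeded
  permutation. This makes the pixel count an invariant (70,400 noise
  pixels at 44% of a 400 × 400 grid) rather than a random variable,
  which is both testable and faithful to a generator that prespecifies
  proportions.
* **RMS contrast** is defined as population standard deviation over
  mean of linear luminance — the conventional definition for
  non-periodic stimuli. The target is 0.30, centred in the legal
  0.25–0.35 range, and is re-enforced *after* filtering because
  filtering changes contrast; generation fails loudly if any emitted
  image leaves the range.
* **Octave-band Gaussian filter.** The filter has unit gain at
  1.5 cycles/degree and gain 0.5 one half-octave to either side. A
  Gaussian profile in *linear* frequency cannot satisfy both
  half-height points (the upper and lower offsets differ by a factor
  of √2), so the gain is Gaussian in log₂ frequency — the standard
  construction for octave-bandwidth filters in spatial vision — which
  meets both constraints exactly. DC is excluded from the gain and the
  output is recentred on the input mean, so mean luminance passes
  through unchanged.
* **Spatial scale.** All spatial-frequency arithmetic uses the
  stimulus-intrinsic scale, image pixels per degree
  (400 px / 4.2° ≈ 95.2 px/deg), the only scale on which the printed
  quantities cohere: the grid subtends 4.2°, the 150-px signal 1.57°,
  and 1.5 cpd is 6.3 cycles per image. Monitor-resolution bookkeeping
  (screen pixels per degree at the stated viewing distance) is display
  plumbing the package does not model.
* **Quantisation** to integer grey levels in [0, 255] happens last;
  the clipped fraction is recorded per image and generation tolerates
  at most 1% clipped pixels (measured sets stay far below this).

A full default set — 2 categories × 2 identities × 4 noise levels × 16
images, each with a paired noise-only companion — is 512 images and
generates in under a minute. The companion serves both as the mixing
source and as the block's noise-only stimulus, which is what the
set-size arithmetic (256 noise-only images for 256 composites)
requires.

## Trial schedules

Blocks hold 256 trials. The equal-ratio design uses all 128 signal and
128 noise images of a category; the 25/75 design needs 64 signal and
192 noise trials, and two choices had to be made that the design
description leaves open:

* the 64 signal images are drawn balanced over
  identity × noise level × side (16 cells × 4 images), preserving the
  factorial balance of the full set;
* 192 unique noise images per block exceed the 128 paired companions,
  so the generator can emit extra unique noise-only images
  (`n_extra_noise`, `virtual_manifest(n_noise_per_category = 192)`);
  uniqueness within block is kept as a hard invariant.

Noise-only trials are assigned a presentation hemifield balanced
64/64 (or 96/96); signal trials inherit the hemifield of their embedded
location. Cohort counterbalancing fills the eight cells of block order
× response mapping × responding hand as evenly as possible (counts
differ by at most one subject). Eight practice trials can be prepended,
flagged, and are excluded from analysis; they reuse images from the
block pool, which is immaterial because they never enter any estimate.

## Simulated observers

### Equal-variance SDT observer

Evidence on a trial is drawn from N(−d′/2, 1) on noise trials and
N(+d′/2, 1) on signal trials, and the observer responds "present" when
evidence exceeds the criterion for that category × hemifield. The
symmetric ±d′/2 placement makes the d′/criterion estimators exactly
unbiased at the population level: plugging the model's analytic rates
HR = Φ(d′/2 − c), FAR = Φ(−d′/2 − c) back into the estimators returns
(d′, c) identically, and the test suite asserts this closure to 1e-9.

Two realism terms are layered on top:

* a **lapse rate** (default 0.02, bounded at 0.05): with that
  probability the response is a fair coin, slightly attenuating
  measured sensitivity the way inattention does in real data;
* a **lognormal reaction time** whose log-mean increases by
  `rt_slow · exp(−|evidence − criterion|)` — responses slow when the
  evidence lands near the criterion. This is a phenomenological
  stand-in, not a process model; only its correct-trial mean is
  consumed downstream, and no acceptance quantity depends on it.

### Drift-diffusion observer

The accumulator starts at `bias(hemifield) × a` between absorbing
boundaries 0 ("absent") and `a` ("present"), drifts at
`drift_scale × (1 − noise fraction)` on signal trials and 0 on noise
trials, with diffusion coefficient s = 0.1, and reaction time is the
first-passage time plus a non-decision constant. Hemifield bias enters
through the start point (a more liberal field starts closer to the
"present" boundary), mirroring the interpretation of visual false
alarms as evidence-accumulation errors; mapping signal strength as one
minus the noise fraction keeps drift monotone in the manipulated
variable. Defaults (drift scale 0.35, boundary 0.12, biases 0.46/0.50
for LVF/RVF, t₀ = 0.30 s) produce accuracy and RT in the empirically
sensible range for this task.

Numerically, the walk is Euler–Maruyama at dt = 1 ms with a
**Brownian-bridge correction**: a step that ends inside the corridor
may still have touched a boundary within the step, with probability
exp(−2 (b−x₀)(b−x₁)/(s² dt)) for endpoint distances to boundary b, and
the simulator absorbs those crossings. Without the correction the
discrete walk overshoots decision times and biases choice
probabilities by O(√dt); with it, the simulator matches the standard
closed-form absorption probability
p = (1 − e^(−2vz/s²))/(1 − e^(−2va/s²)) and unbiased-start mean
decision time (a/2v)·tanh(va/2s²) within Monte-Carlo error at 20,000
trials, which the acceptance suite verifies. Walks not absorbed within
5 s are forced to a fair guess and flagged; flagged trials are excluded
from RT means but kept for rates.

### Traits and trait–bias coupling

Each observer carries four O-LIFE subscale scores, sampled as binomial
sums over the subscale item counts (12, 11, 10, 10) with per-item
endorsement probabilities 0.29, 0.35, 0.25, 0.30 — means in the range
typical of undergraduate samples, and ranges respected by
construction. The coupling between a trait and a category's criterion
is built as `r·z(trait) + √(1−r²)·ε` with the trait standardised by its
*population* moments, so the population correlation equals the target
exactly; large-sample tests confirm the generator reproduces a target
of −0.559 to within ±0.02. The bias deviate is shared across
hemifields (bias is modelled as a subject-level disposition; hemifields
differ by fixed offsets), and face and flower sensitivities correlate
at 0.5 within subject — individual-differences structure chosen once as
realistic (shared task ability) rather than fitted to anything.

## Analysis pipeline

Rates are corrected log-linearly — HR = (hits + ½)/(n + 1) — in **every**
cell, not only cells with extreme counts: uniform application avoids
conditioning the correction on the data and keeps every rate strictly
inside (0, 1) so the quantile transform is always defined. The
estimators then follow the standard equal-variance definitions. Two
notes on symmetries: d′ is antisymmetric under exchanging HR and FAR,
and swapping response labels maps (HR, FAR) → (1−FAR, 1−HR), which
leaves d′ unchanged and *negates* c.

The repeated-measures ANOVA handles fully within-subject designs of up
to three two-level factors by testing each effect against its own
subject × effect interaction — for two-level factors this is exactly a
paired t test on per-subject contrast scores (F = t², an identity the
tests verify against `stats::aov` to 1e-8), sphericity holds by
design, and partial eta squared is F/(F + df₂). Degrees of freedom are
the design-correct (1, n−1). Calibration is checked empirically: under
a null generator with no effects, the rejection rate of each effect at
α = 0.05 stays within 0.05 ± 0.01 over 5,000 simulated cohorts. That
calibration run uses the rate-level simulation engine — binomial counts
drawn from each observer's analytic per-cell response probabilities —
which is distributionally identical to trial-by-trial simulation for
rate-based measures and makes thousands of replicates affordable.

Trait correlations are plain Pearson tests with the familywise alpha
split over the four subscales (0.05/4 = 0.0125), and the regression
module computes VIF_j = 1/(1 − R²_j) by regressing each covariate on
the others (verified against `car::vif`), with tolerance as its exact
reciprocal. Bayesian model comparison is deliberately not implemented;
the frequentist machinery carries the same structural claims.

## Scenarios and parameter recovery

Named scenarios pin the generator to published group-level values: the
equal-ratio baseline uses flower sensitivity 0.791 (SD 0.49), face
0.277 (SD 0.45), criterion 0.329 (SD 0.48) in the left field and 0.09
(SD 0.45) in the right, n = 26, with the Unusual Experiences coupling
at −0.559; the 25/75 baseline uses the corresponding published values
at n = 29 with the Cognitive Disorganisation/flower coupling at
+0.437. `run_scenario()` simulates replicate cohorts, pushes each
through the full estimator pipeline, and reports bias, RMSE and
95%-CI coverage per recovered parameter. At the default 200 replicates
the flower-block group d′ and the left-field group criterion are
recovered within a few hundredths of the injected truths; the small
systematic attenuation of d′ (≈ 0.03) is the expected joint effect of
the 2% lapse rate and the log-linear shrinkage at 64 trials per cell,
and disappears when lapses are switched off and trials per cell grow —
a property the tests check explicitly.

## Problem sizes and determinism

Default sizes were chosen so the whole validation surface runs
comfortably on a single CPU: the full 512-image stimulus set builds in
under a minute; recovery runs use 200 replicate cohorts
(trial-by-trial engine, ~25 s); ANOVA calibration uses 5,000 rate-level
cohorts (~1 min). Every stochastic function takes a `seed` argument,
evaluated inside `withr::with_seed()` so the caller's RNG stream is
never disturbed; nested work derives child seeds from the parent seed
and an order-sensitive label hash, so identical configuration plus
seed yields byte-identical stimulus sets, schedules, trial logs and
recovery reports.

## What the generator does and does not emulate

The synthetic cohorts reproduce the *statistical* structure the
analysis assumes: per-condition response probabilities under
equal-variance evidence (or diffusion first-passage), between-subject
parameter spread at published group values, and a linear trait–bias
coupling. They do not emulate several features of real data: sequential
dependencies (criterion drift, post-error slowing, expectation updates
across a block), learning or fatigue, heteroscedastic evidence
(unequal-variance ROCs), response-hand or key-mapping asymmetries,
stimulus-specific difficulty beyond the noise-level factor, or any
mechanistic account of why face blocks are answered more slowly.
Passing recovery tests therefore demonstrates that the estimator
pipeline is correct and calibrated for data generated under these
assumptions — it does not by itself validate the assumptions against
human data.

Likewise the shipped signal images are schematic stand-ins: pipelines
exercised on them are bit-reproducible and structurally faithful, but
absolute detectability (the mapping from noise-pixel proportion to d′)
will differ from photographic stimuli. Users reproducing a real
experiment should substitute their own prepared images via the
`signal_images` argument of `build_stimulus_set()`.
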