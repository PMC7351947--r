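---
title: "Simulating polarity effects in voltage-indicator imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating polarity effects in voltage-indicator imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gevisim)
```

`gevisim` asks a design question about genetically encoded voltage
indicators (GEVIs): given two sensors with identical response amplitude but
opposite polarity — one dim at rest that brightens on a spike, one bright at
rest that dims — how does spike detectability degrade as more neurons are
labeled in the same tissue? This vignette lays out the generative model, the
analysis pipeline, every tunable parameter that matters, and the design
decisions taken where the underlying methods literature leaves choices open.

## The generative model

### Spike trains and voltage traces

Spikes are a homogeneous Poisson process thinned by an absolute refractory
period (default 4 frames, 10 ms at the default 400 Hz). The rate is
dead-time corrected so the *thinned* process keeps the requested expected
count; without the correction a mean-100-spike recording runs ~1% short,
which a calibration test over hundreds of seeds would flag. The reference
recording is 40,000 frames (100 s) with a mean of 100 spikes — 1 Hz tonic
firing, typical of the tonically active sensory neurons used to benchmark
such indicators in vivo; the sweeps in the test-suite use a 4,000-frame,
10-spike version of the same conditions to keep runtimes in minutes (problem
sizes: 4,000 frames × up to 96 cells per movie × 400 movies per sweep).

The normalized voltage trace is 0 at rest with unit mean spike height. Each
spike contributes a stereotyped optical action potential: linear 2-frame
rise, exponential 3-frame decay (5 ms / 7.5 ms at 400 Hz — the optical
transient of a fast eFRET sensor, slower than the electrical spike).
Overlapping waveforms collapse by pointwise maximum, so bursts never exceed
unit amplitude. Subthreshold activity is an Ornstein–Uhlenbeck process,
SD 0.1 of spike height with a 125 ms correlation time — visible, slow, and
about the relative magnitude seen in good optical recordings.

### The indicator

Fluorescence spans `[F_min, F_max]`. `F_max` is held fixed — the maximum
brightness is set by the fluorophore, not the rhodopsin — and sensitivity is
defined as `s = ΔF/F_min = (F_max − F_min)/F_min`, so `F_min = F_max/(1+s)`.
Polarity decides the mapping: positive-going rests at `F_min` and reaches
`F_max` at spike height; negative-going is the mirror image. Two exact
consequences used as test oracles: the two polarities sum to
`F_min + F_max` pointwise, and a rest→spike step has
`ΔF/F₀ = +s` (positive) versus `−s/(1+s)` (negative) against each sensor's
own resting baseline. The voltage→fluorescence map is linear (rhodopsin
eFRET responses are fast and near-linear in the physiological range);
subthreshold excursions below rest are clipped at the range boundary
(whether to clip was an open choice; clipping was chosen and is flagged in
the configuration). An optional asymmetric single-pole kinetics filter
(`tau_on`/`tau_off`) exists but is off by default — the polarity comparison
does not need it, and the double-exponential fitting tools characterize
kinetics where they matter.

### Footprints, background, movies

Somata are unit-sum anisotropic Gaussian blobs (radius 2 px, mild random
elongation) placed uniformly with a volume-exclusion constraint (centers at
least one soma diameter apart — cell bodies do not interpenetrate).
Normalizing footprints to unit sum makes brightness purely a property of the
indicator model.

Each in-focus neuron brings 5 out-of-focus background neurons: its own
footprint inflated by an 8 px Gaussian blur in quadrature (for Gaussian
profiles this equals convolution with the blur kernel), displaced up to
12 px, with the target's spike train circularly shifted by a random offset
("temporal shuffling" preserves count and ISI structure while destroying
alignment). Large blur makes the background what it is in real recordings:
diffuse flux that raises the local photon load everywhere, rather than a
second population of compact resolvable sources.

Movies are the outer product of footprints with bleached fluorescence
traces, summed, plus a flat 2-count offset (unlabeled-tissue floor), with
per-pixel Gaussian noise of SD `noise_coeff ×` pixel signal added
frame-wise and negatives clipped. The single-exponential bleach curve
(default τ = 20,000 frames, ~18% loss over a 4,000-frame recording) is a
parametric stand-in for an empirically measured curve; the bleach-fit
routine accepts real traces if you have them. An additive constant-variance
noise model is available as a control: it removes the polarity asymmetry by
construction and underpins the polarity-null test.

**Noise calibration.** `noise_coeff` is the one parameter with no published
value and first-order influence. It was fixed at 0.1 by a bracketing
requirement: at 5× baseline sensitivity — the regime the polarity
comparison is about — both polarities' error-versus-density curves must run
from reliable detection (error ≈ 0.05 at one neuron per field) to failure
(error → 1 at sixteen) within the simulated density range, so that
matched-error interpolation is well posed on both curves. A consequence
worth stating: at baseline sensitivity (0.2) the same noise level makes
spikes undetectable at any density, which is itself part of the story —
sensitivity, not only polarity, gates dense imaging.

## The analysis pipeline

### Trace processing

Bleach correction fits `A·exp(−t/τ) + C` (Levenberg–Marquardt, multi-start
over log-spaced τ, linear solves for the amplitudes at each start) and
divides it out, anchored at the first frame. Constant traces take the
`τ = ∞` branch untouched; a non-convergent fit falls back to linear
detrending and says so. The additive offset `C` is included because real
recordings have non-bleaching background. ΔF/F₀ uses either a fixed
pre-stimulus window (`compute_dff`) or a centered moving-percentile baseline
(`moving_dff`): bottom 10th percentile of a 1 s window for positive-going
indicators, top 10th for negative-going, edges truncated. Centered windows
were chosen over causal ones (no online constraint exists here); the
percentile is evaluated on a stride of 1/20 window and interpolated — the
baseline varies on the window timescale, and an exactness test bounds the
approximation. Double-exponential kinetics fits use log-spaced multi-start
τ pairs, amplitudes solved linearly per start, the best few starts refined
by Levenberg–Marquardt, τ reported in ascending order; genuinely
single-exponential data simply load one component. F–V curves average
steady-state ΔF/F per clamp voltage and report the fitted slope sign.

### Wavelet event detection

The detector z-transforms ΔF/F₀, applies a maximal overlap discrete wavelet
transform (sym4, 6 levels), reconstructs the signal from detail levels 3–6
only (≈3–50 Hz at 400 Hz: optical action potentials concentrate energy
there; drift and most pixel noise do not), squares it, and thresholds the
power. Implementation choices:

- **MODWT in-package.** No wavelet package ships in this stack, so the
  transform follows the standard pyramid algorithm with per-level rescaled
  filters; sym4 filter constants are hard-coded. Correctness is certified
  by identities rather than reference software: the additive
  multiresolution analysis must reconstruct the input to float tolerance,
  the periodic transform must preserve energy, level-1 Haar must match its
  closed form, and details must localize a sinusoid into the right dyadic
  band. Boundaries are handled by reflection extension (documented and
  fixed; periodic is available), avoiding wrap-around artifacts on bleached
  traces.
- **Threshold.** The power threshold is `(k × 1.4826·MAD of the
  band-limited signal)²`, i.e. events must exceed `k` robust SDs in the
  spike band. Thresholding the MAD of the *power* itself was considered and
  rejected: for Gaussian noise it sits near 1.5σ and fires constantly. The
  default `k = 7` is set between two regimes that the test-suite pins down
  from both sides: clipped subthreshold fluctuations at the default 10%
  amplitude produce genuinely spike-like band-limited bumps a few robust
  SDs high (a noiseless movie must yield zero false events), while spikes
  at trace SNR 10 — the design operating point — must all clear the
  threshold (the tonic-spiking recovery test).
- **Events.** Candidate events are local maxima of supra-threshold power,
  pruned by non-maximum suppression at the refractory spacing (strongest
  first, earlier frame on ties), then refined to the nearest local maximum
  of the z-scored trace without crossing a neighbor. Only upward excursions
  count by default (`sign = "positive"`): the pipeline always presents
  spikes upward, and sign-agnostic power also fires on the ringing
  undershoot that follows a large transient; `sign = "both"` restores the
  purely power-based rule for traces of unknown orientation. A structural
  limit worth knowing: two spikes closer than ~10 frames (25 ms) are one
  bump in a ≤50 Hz band and cannot be resolved into two events.

### Trace extraction from movies

A documented spike-pursuit-style variant (the original's internals are not
reproduced here, and no comparison to it is claimed): start from the
footprint-weighted pixel mean; high-pass (1 s moving average) and detect
provisional spikes; regress each pixel on the band-limited reconstruction
and keep positive weights (sign-flipped for negative polarity, so "positive"
always means spike-carrying); recompute and iterate (≤3 or spike-set
convergence). Two additions proved necessary in crowded fields and mirror
the role of the original's localized patches and background model: the
regression is confined to the seed footprint's support (weight refinement
sharpens the cell's own footprint; it must not recruit correlated pixels
from elsewhere), and the mean fluctuation of the non-support pixels is
subtracted from the trace (out-of-focus background is spatially smooth, so
soma and surround see it almost equally). Against a ground-truth seed the
plain weighted mean is already a matched filter; refinement earns its keep
when the seed is an imperfect manual ROI, which is what the corresponding
test measures.

### Evaluation

`spike_iou` compares binary per-frame labels at the imaging rate without
binning: `IoU = |∩|/|∪|`, error `1 − IoU`; two empty trains score 1. An
optional tolerance performs greedy nearest-first one-to-one matching before
labeling (used diagnostically; the headline numbers use tolerance 0). The
sweep driver crosses density (in-focus neurons in a fixed 32 × 32 field,
background scaled proportionally) with sensitivity and polarity, derives
every replicate seed from `(base_seed, cell, replicate)`, records per-cell
failures as `NA` rows, and summarizes with per-cell means and bootstrap
CIs. `matched_density_ratio` interpolates error against log-density (error
curves are closer to log-linear; a cross-method test checks linear
interpolation agrees on smooth curves) at an error target defaulting to the
midpoint of the negative-going curve's achievable range; if the
positive-going curve never reaches the target inside the simulated range
the ratio is reported against the highest simulated density and flagged as
a lower bound. `fidelity_ratio` reports positive/negative fidelity at one
grid cell, with fidelity defined as `1 − error` by default; because
"detection fidelity" admits more than one reading, the mean event z-score
is implemented as an alternative (`measure = "mean_event_z"`).

## What the simulation does and does not show

The generator reproduces the statistical structure that drives the polarity
asymmetry — fixed `F_max`, signal-proportional noise, diffuse shuffled
background, bleaching — under a fully synthetic background, so the
comparison between polarities is exact by construction: with additive
constant-variance noise and no background the two polarities are
statistically indistinguishable (the polarity-null property test), and any
separation under proportional noise is attributable to the rest-brightness
difference. It does not model optics beyond Gaussian blur, camera specifics
(read noise, fixed-pattern), motion, or a real tissue background, and it
evaluates one seeded target per movie rather than joint demixing of
overlapping in-focus somata.

One analytical consequence deserves emphasis. With `F_max` fixed and noise
SD proportional to pixel signal, the two polarities' error curves differ
only through their resting brightness, so
`error_pos(n) = error_neg(n × F_max/F_min)` and the matched-error density
ratio is pinned at `F_max/F_min = 1 + s` — exactly 2 at 5× baseline
sensitivity — for *any* error target and noise scale. Larger fold
differences in tolerable density require an asymmetry beyond this recipe
(for instance a bright shared tissue background interacting with detection
nonlinearly, or comparing a high-sensitivity positive indicator against a
lower-sensitivity negative incumbent). The fidelity ratio at a fixed high
density is not capped this way: where the negative-going curve has
collapsed and the positive-going one still detects, the ratio grows without
bound, which is why it is reported at the top of the density grid.

## Defaults at a glance

| parameter | default | units | why |
|---|---|---|---|
| `frame_rate_hz` | 400 | Hz | reference imaging rate |
| `frames` | 40,000 (sweeps: 4,000) | frames | 100 s reference; 10 s sweep scale |
| `mean_spikes` | 100 (sweeps: 10) | count | 1 Hz tonic firing |
| `refractory_frames` | 4 | frames | 10 ms absolute refractory |
| `subthreshold_sd`, `tau` | 0.1, 50 | spike units, frames | visible slow subthreshold activity |
| `footprint_radius_px` | 2 | px | soma sigma in a 32×32 field |
| `n_background_per_neuron` | 5 | count | out-of-focus sources per target |
| `background_blur_px`, `displace` | 8, 12 | px | diffuse background flux |
| `F_max`, `offset` | 100, 2 | counts | brightness scale; tissue floor |
| `sensitivity` | 0.2 (5×: 1.0) | ΔF/F_min | baseline vs improved sensors |
| `bleach_tau_frames` | 20,000 | frames | ~18% loss per 4,000-frame movie |
| `noise_coeff` | 0.1 | unitless | bracketing calibration (above) |
| `threshold_k` | 7 | robust SD | between subthreshold and spike regimes |
| `min_separation_frames` | 4 | frames | matches the refractory period |
| `n_iter` | 3 | count | extractor refinement iterations |

Every stochastic step draws its seed from a Lehmer-hash stream over
`(base_seed, indices…)`, so recordings, sweeps and the command-line tools
are bit-reproducible from one integer.
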