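# gevisim

Simulation and spike-detection analysis of positive- versus negative-going
genetically encoded voltage indicators (GEVIs).

## The problem

eFRET voltage indicators report membrane potential through quenching of a
bright fluorophore by a rhodopsin chromophore. Classical eFRET GEVIs are
*negative-going*: bright at rest, dimming during an action potential. A
*positive-going* indicator is dim at rest and brightens when the neuron
spikes. Both polarities can have the same response amplitude, yet they are
not equivalent in tissue: with photon noise proportional to signal and
out-of-focus background, a sensor that rests dim contributes far less
background flux — and therefore less noise — per labeled neuron. `gevisim`
provides a ground-truthed simulation and analysis pipeline to quantify that
asymmetry as a function of labeling density and indicator sensitivity, for
researchers designing or evaluating voltage imaging experiments.

## The model

- **Voltage traces.** Poisson spike trains with a refractory period drive
  normalized traces (rest 0, mean spike height 1): stereotyped unit-peak
  action-potential waveforms (overlaps collapse by maximum) plus
  Ornstein–Uhlenbeck subthreshold fluctuations.
- **Indicator.** Fluorescence spans `[F_min, F_max]` with `F_max` held fixed
  (dye-limited maximum brightness) and `F_min = F_max / (1 + s)` where
  `s = ΔF/F_min` is the sensitivity. Positive-going: `f = F_min +
  v (F_max − F_min)`; negative-going: `f = F_max − v (F_max − F_min)`.
- **Movies.** Unit-sum Gaussian somata (plus 5 blurred, temporally shuffled
  out-of-focus background neurons per target) are outer-multiplied with the
  bleached (`exp(−t/τ)`) fluorescence traces, summed, and corrupted with
  per-pixel Gaussian noise of SD proportional to the pixel signal.
- **Detection.** Traces are recovered by iterative pixel-weight refinement
  (a documented spike-pursuit-style variant), bleach-corrected by an
  exponential fit, converted to ΔF/F₀ against a moving 1-s 10th-percentile
  baseline (bottom side for positive-going, top for negative-going), and
  spike-like events are found on the z-scored trace with a maximal overlap
  discrete wavelet transform (sym4, 6 levels, details 3–6 reconstructed,
  power thresholded).
- **Evaluation.** Inferred trains are scored against ground truth at the
  imaging rate without binning: `IoU = |∩| / |∪|` of binary per-frame spike
  labels, error = `1 − IoU`, swept over density × sensitivity × polarity
  grids.

Kinetics utilities (double-exponential step-response fits, F–V curves from
voltage-clamp steps) cover the standard trace analyses applied to such
sensors.

## Worked example

```r
library(gevisim)

cfg <- default_run_config(frames = 4000, mean_spikes = 10)
rec <- simulate_recording(cfg, seed = 42, n_neurons = 2, sensitivity = 1.0,
                          polarity = "positive")
rec
#> <sim_recording> 4000 frames of 32x32 px at 400 Hz
#>   2 in-focus neuron(s), 10 background neuron(s)
#>   bleach tau 20000 frames, proportional noise (coeff 0.1), offset 2

det <- detect_from_movie(rec)      # extract -> bleach-correct -> dF/F -> MODWT
det
#> <detection> 8 event(s) [movie], power threshold 8.91
#>   mean event z-score 12.8

spike_iou(rec$neurons[[1]]$voltage$spikes, det$spike_frames)
#> <evaluation> IoU 1.000 (error 0.000): 8 true, 8 inferred, 8 shared
```

All 8 ground-truth spikes of the target neuron are recovered at their exact
frames (IoU 1) despite a second labeled neuron, ten background neurons,
bleaching and pixel noise; the mean event z-score (~13) is the margin over
the detection threshold in band-limited robust-SD units.

The full comparison is one call:

```r
sw <- run_polarity_sweep(densities = c(1, 2, 4, 8, 16),
                         sensitivities = c(0.2, 1.0), n_reps = 20,
                         config = cfg, base_seed = 1)
summary(sw)                   # mean error per grid cell with bootstrap CIs
plot(sw, sensitivity = 1.0)   # error-vs-density curves per polarity
matched_density_ratio(sw)     # fold more density at matched error
fidelity_ratio(sw)            # fold higher fidelity at the top density
```

A thin command-line front end over the same functions is installed at
`inst/cli/gevisim.R` (`simulate`, `detect`, `sweep`, `report` subcommands;
movies as multi-frame float TIFF, spikes/traces as CSV, configs as YAML,
manifests as JSON).

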