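# clickpop

Tools for studying how temporally patterned click sequences are
transformed from a synchronous, click-locked **temporal code** in the
primary thalamorecipient auditory pallium into sequence-selective
**population vectors** ("spatial codes") in secondary auditory areas — and
for asking whether that transformation can support behavioral
discrimination.

The stimuli are acoustic Morse code: 3-s click trains built from 249-ms
blocks, each block a permutation of ten inter-click intervals
(11, 14, 16, 20, 23, 26, 29, 34, 36, 40 ms). Different stimuli differ
*only* in interval order. The package implements, as tested reusable
stages:

* **Stimulus construction** — repeating / non-repeating block sequences,
  time reversal, cyclic permutation (phase shift), twofold dilation,
  WAV rendering of 100-µs rectangular pulses.
* **Synthetic recordings** — ground-truth-labeled generators for
  click-locked primary units and interval-context-tuned secondary units
  (tuning over preceding-interval classes and ordered pairs, read through
  a fixed ~40-ms memory), plus raw extracellular traces with known spike
  identities and reset-go operant trial logs.
* **Spike sorting** — 500-Hz Butterworth high-pass, threshold detection
  with spline realignment to 250 kHz, PCA + Haar-wavelet features, EM
  Gaussian-mixture clustering, SNR / refractory QC, peak-to-peak spike
  width (250-µs narrow/broad boundary).
* **Response metrics** — 5-ms PSTHs, Kaiser-window FIR band-pass
  smoothing (5–110 Hz) with min–max normalization, three-criterion peak
  detection, inter-peak-interval histograms, click-triggered latencies,
  and primary/secondary classification by the maximum PSTH-to-stimulus
  correlation (threshold 0.5).
* **Discriminability** — population-vector trajectories (5-ms bins, 30-ms
  boxcar, odd/even trial split), nearest-trajectory Euclidean distances,
  ROC/AUC; first-500-ms restriction; timescale-dilation comparison; and
  the rectangular-window "smoothing unit" separability analysis.
* **Reverberant model** — the critically tuned linear network
  dv/dt = αMv − γv + input + noise with antisymmetric M (all eigenvalues
  imaginary, every oscillatory mode equally excitable), exact
  matrix-exponential integration, threshold-crossing tick rasters, and
  model discriminability through the same ROC stage.
* **Behavior** — reset-go trial-outcome classification (interruptions
  after the 200-ms grace, hits within the 7-s response window),
  d′ = z(H) − z(F) with 1/(2n) correction, per-day learning curves with
  the d′ > 1 criterion, catch-trial interruption ratios, port-access
  probability maps.

## Worked example

```r
library(clickpop)

stim <- list(seq1 = build_sequence(repeating = TRUE,  seed = 11, seq_id = "seq1"),
             seq2 = build_sequence(repeating = FALSE, seed = 22, seq_id = "seq2"))
ens <- make_ensemble(n_primary = 10, n_secondary = 10, seed = 1)
ds  <- simulate_ensemble(stim, ens, n_trials = 20, seed = 101)

cls <- classify_units(ds)            # similarity score vs the click train
table(cls$area_label, ds$units$area_truth)
#>             primary secondary
#>   primary         9         0
#>   secondary       1        10

discriminability_experiment(ds, "primary",   n_units = 10)$roc
#> <roc_curve> AUC = 0.1407 (623 thresholds)
discriminability_experiment(ds, "secondary", n_units = 10)$roc
#> <roc_curve> AUC = 0.8747 (1686 thresholds)

slow <- simulate_ensemble(lapply(stim, dilate, 2), ens, n_trials = 20, seed = 201)
discriminability_experiment(slow, "secondary", n_units = 10)$roc
#> <roc_curve> AUC = 0.4142 (1380 thresholds)

dprime(0.85, 0.20, 500, 500)
#> [1] 1.878055
```

Reading the numbers: 19 of 20 units are assigned their true area by the
0.5 similarity threshold. Secondary population trajectories separate the
two sequences (AUC 0.87 for this stimulus pair) while primary trajectories
do not — with the nearest-point decoder, indiscriminable conditions fall
*below* 0.5 because the minimum over many candidate points undercuts the
trial-noise floor, so the ordering is the meaningful comparison. Slowing
the stimulus twofold pushes most intervals beyond the generator's 40-ms
context memory and discriminability collapses (0.41). A bird with an 85%
hit rate and 20% false-alarm rate has d′ ≈ 1.9, above the d′ > 1 learning
criterion.

The numbered scripts under `analysis/` run the full study in order —
stimuli, synthetic ensemble, classification, population ROC,
window-separation analysis, reverberant model, operant behavior — each
writing its tables under `results/` and printing a short summary of what
it found. The methods vignette
(`vignettes/click-sequence-transformation.Rmd`) documents the models,
parameter choices and numerical conventions.

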