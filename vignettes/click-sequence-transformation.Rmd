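---
title: "From click timing to population codes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From click timing to population codes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clickpop)
```

# The scientific question

Songbird auditory pallium transforms temporally patterned sounds as they
ascend from the primary thalamorecipient zone (Field L2a) to secondary
zones (L2b, L3). Stimuli that differ *only* in the ordering of inter-click
intervals — acoustic Morse code with no informative spectral content above
100 Hz — evoke synchronous, click-locked responses in the primary zone but
sparse, context-selective responses in secondary zones. The population
vector of secondary units therefore traces stimulus-specific trajectories
through phase space: a temporal code is converted into a spatial one.
`clickpop` implements every stage needed to study this transformation with
fully synthetic, ground-truth-labeled data: stimulus construction, spike
and raw-trace generators, spike sorting, unit classification, trajectory
ROC analysis, a reverberant linear network, and reset-go operant analysis.

# Stimuli

A stimulus is built from ten inter-click intervals
(11, 14, 16, 20, 23, 26, 29, 34, 36, 40 ms; sum 249 ms). One *block* is a
permutation of the ten intervals with a click at the block start and one
after each interval; the boundary click is shared between consecutive
blocks, so a sequence of $n$ blocks carries $10n$ intervals and $10n + 1$
clicks. The canonical 3-s stimulus repeats its pattern 11 times (last click
at 2739 ms) and ends in a silent tail; general durations fit as many
complete blocks as possible, and `n_blocks` is explicit for anything else.
Repeating sequences reuse one permutation; non-repeating sequences draw
pairwise-distinct permutations. Transformations are `reverse_sequence()`
(end-to-end interval reversal), `cyclic_permute()` (rotation of the
repeating interval stream — a phase shift), and `dilate()` (uniform
interval scaling with truncation at the original 3 s, so the twofold-slowed
canonical set spans 22–80 ms). Binning is half-open, `[t, t + 5)` ms, with
edge clicks assigned to the later bin.

```{r stimulus}
s1 <- build_sequence(repeating = TRUE, seed = 11, seq_id = "seq1")
s1
range(sequence_intervals(dilate(s1, 2)))
```

# The synthetic ensemble

The generator encodes the response phenomenology the analyses assume, with
ground-truth area labels for validation.

**Primary units** fire one spike per click with probability 0.9 at a
latency of 8–12 ms (SD 1 ms), over a 1-Hz baseline — click-locked,
context-free responses. Their rate tracks click count, so twofold dilation
roughly halves it.

**Secondary units** respond to a click according to the *context* of
preceding intervals. Each unit carries a tuning surface over the ten
interval classes and (by default, `context_depth = 2`) over all 100
ordered pairs of preceding classes. The surface is sparse and reliable: a
random ~40% of contexts drive the unit with probability 0.95, the rest
with 0.03 (`tuning_contrast` interpolates toward uniform 0.5). Responses
are small bursts (3 spikes over ~12 ms) at 12–20 ms latency (SD 3 ms) over
a 3-Hz baseline. Two modeling choices deserve emphasis:

* *Why near-binary weights rather than graded ones?* The trial-to-trial
  variance of a Bernoulli response peaks at $p = 0.5$; mid-range weights
  maximize within-stimulus noise while halving between-context contrast.
  Sparse-reliable tuning matches both the described physiology
  (selective, reproducible secondary responses) and the signal-to-noise
  regime in which ten units discriminate sequences at 20 trials.
* *Why ordered pairs?* Every block contains all ten interval classes, so
  depth-1 tuning makes both stimuli visit nearly the same set of
  population states, differing only in order — and a nearest-point
  decoder is blind to order. Interval *bigrams* differ between
  permutations, so pair tuning gives each stimulus its own repertoire of
  co-activation patterns. This is the minimal context structure that
  makes population vectors sequence-selective.

Context is read through a fixed absolute memory of 40 ms
(`context_window`): when the preceding interval exceeds it, the unit falls
back to its mean tuning weight — responsive but unselective. This single
mechanism reproduces the dilation result: at twice the timescale most
intervals outlast the memory, selectivity collapses, and discriminability
is lost while spike rates fall less than primary rates do (the fallback
preserves response probability; the baseline is click-independent).
The generator makes no claim that the biological context depth is 2; depth
1 is available, and depth is a hypothesis knob, not a finding.

Spike times are deterministic given a seed; the refractory rule deletes
the later spike of any pair closer than 1 ms.

# Spike sorting

The raw-trace stage mirrors a standard extracellular chain: 3rd-order
Butterworth high-pass at 500 Hz (applied forward–backward — zero phase —
so later latency estimates are unbiased; the phase convention is ours),
detection at ±4 robust noise SDs (MAD-based; thresholds configurable since
no numeric value is canonical), cubic-spline upsampling to 250 kHz with
realignment to the negative peak, features from the first 3 principal
components plus 10 Haar-wavelet coefficients selected by a
normality-deviation (Lilliefors) score, EM-fitted Gaussian mixtures with
BIC model selection, and QC by SNR (peak-to-peak of the mean waveform over
twice the noise SD) and refractory violations (1-ms default). The Haar
transform is implemented in the package; mixtures come from `mclust`.
Templates in the trace simulator are difference-of-Gaussians biphasic
waveforms calibrated so the realized negative-to-positive peak width
matches the nominal value; 250 µs splits narrow from broad units. White
Gaussian noise is adequate for testing the sorter's contract; real traces
add 1/f background and drift the sorter does not model.

# PSTHs, peaks and classification

PSTHs use 5-ms half-open bins summed over trials. Smoothing follows the
fixed recipe: sample-and-hold upsampling to 1 kHz (the resampling step is
our choice; only the filter is canonical), a 2233-tap Kaiser-window FIR
band-pass at 5–110 Hz (≈5% passband ripple, 40 dB stopband) applied with
its group delay removed, then min–max normalization to [0, 1]; constant
PSTHs cannot be normalized and return a flagged zero vector. Peaks of the
normalized signal must exceed 0.3 in value and rise more than 0.05 (and
0.01) above the higher of their neighboring valleys; offending peaks are
merged iteratively, lowest first, with endpoints counting as valleys.
Inter-peak-interval histograms of primary ensembles then concentrate in
10–40 ms for the canonical stimulus and 20–80 ms for its twofold dilation.

A unit's *similarity score* is the maximum correlation coefficient between
its 5-ms PSTH and the binarized click vector over response lags 0–50 ms
(the lag range covers observed primary latencies; lag range and
correlation normalization are our reading of "maximum cross-correlation").
Zero-variance inputs score 0, and a score of exactly 0.5 classifies as
secondary. Scores above 0.5 label a unit primary; the threshold separates
the two generator populations with ≥95% accuracy across seeds.

# Discriminability of population trajectories

For each stimulus, the trial-averaged 5-ms PSTHs of the chosen units
(boxcar-smoothed over 30 ms, causal so mass is conserved) are stacked into
a time × unit matrix: the population trajectory. Trials are split into odd
and even halves. The *same-stimulus* distance at bin $t$ is the Euclidean
distance between the odd and even vectors at $t$ — the trial-noise floor.
The *cross-stimulus* distance is the distance from the odd vector at $t$
to the nearest point, over all time bins, of any other stimulus's
even-split trajectory ("nearest trajectory" as a path, which is what makes
primary populations indiscriminable: their trajectories trace the same
near-1-D manifold at different times). A time-matched variant
(`mode = "matched"`) is provided. Trajectories are clipped to the clicked
span (last click + smoothing window) by default: the silent tail carries
no sequence information, and both trajectories sit at baseline there, so
including it only pads both distributions with indistinguishable bins.

The ROC sweeps one threshold over both pooled distance sets
(TPR $= P(\text{cross} > \theta)$, FPR $= P(\text{same} > \theta)$); AUC
is computed by trapezoid and equals concordant-pair probability with ties
at ½. One subtlety of the nearest-point statistic: for truly
indiscriminable conditions the *minimum* over hundreds of candidate points
pulls cross distances below the matched-bin noise floor, so chance sits
*below* 0.5 (primary AUC ≈ 0.15 rather than 0.5). Orderings are therefore
the meaningful read-out, and all headline claims are comparative:
secondary > 0.9 > primary across seeds, the ordering persists in the first
500 ms, and twofold dilation collapses the secondary AUC.

# The rectangular-window ("smoothing unit") analysis

To ask how much integration time a purely feed-forward unit would need to
separate the training stimuli, each sequence's 1-ms click indicator is
smoothed with three boxcars of width $T$, $T/2$, $T/4$ (the two shorter
widths are our choice), giving a 3-D trace decimated to the 5-ms grid.
Small Gaussian replicates (SD 1% of the trace range, 20 replicates) stand
in for trial noise, and the same distance/ROC machinery runs at matched
time bins. Strict perfect separation (AUC = 1 on every replicate) turns
out to be unattainable in principle here: a boxcar of a click indicator is
a click *count* divided by the window, a lattice-valued signal, and two
sequences coincide exactly on a fraction of bins at any timescale. The
package therefore reports the strict rule alongside a relaxed criterion
(replicate-minimum AUC ≥ 0.95, i.e. ~95% of moments discriminable above
the noise floor) whose minimal passing $T$ lands at 40–140 ms depending on
the sequence pair — the order of magnitude at which click-rate vectors
become discriminative. Without the original training audio the exact
published window cannot be recomputed, and the criterion behind "perfect"
separation is our operationalization, not the authors'.

# The reverberant linear network

The model is the linear stochastic system
$\dot v = \alpha M v - \gamma v + b\,u(t) + \eta$, with $M$ a random
antisymmetric matrix ($M^\top = -M$, purely imaginary eigenvalues — a
rotation generator under which every oscillatory mode is equally
excitable, the "critical tuning"), $\gamma$ a uniform leak, $u(t)$ the
click impulse train coupled through a random unit vector $b$ (the input
term is our reading of "driven by click sequences"; the sign of zero-mean
$\eta$ is immaterial), and $\eta$ white noise. Defaults: $N = 50$,
eigenfrequencies up to 0.6 rad/ms (fastest period ≈ 10 ms),
$\gamma = 1/80$ ms$^{-1}$ so the effective memory is ~80 ms, dt = 0.1 ms.
No published parameter values exist for this illustration; only the
qualitative behavior is claimed.

Integration uses the exact matrix-exponential propagator of the linear
part per step, with input and noise added discretely. We chose this over
explicit Euler–Maruyama (available as `method = "euler"`) because the
rotational flow is then norm-preserving to machine precision and the pure
leak matches $e^{-\gamma t}$ exactly — explicit Euler inflates the norm by
$\tfrac12(\omega\,dt)^2$ per step, which over 3 s at functional
frequencies exceeds any sensible conservation tolerance. Threshold
crossings of the state ("ticks") play the role of spikes; feeding the tick
rasters of noise-replicate runs through the trajectory ROC shows the tuned
network discriminating the canonical pair (AUC > 0.9) while a memoryless
control ($\alpha = 0$, fast leak) does not.

# Behavior: the reset-go task

A trial log records, per trial, the reward class, catch tag and the
trial-port / water-port event times. Outcomes partition trials:
*interruption* (trial-port access ≥ 200 ms after stimulus start and before
its 3-s end), else *hit* / *miss* on rewarded trials (water-port access
within playback plus the 7-s response window) and *false alarm* /
*correct rejection* on non-rewarded ones; water access outside the window
on a rewarded trial counts as a false alarm. The hit/false-alarm event
definitions are our operationalization — the task defines the
contingencies, not the signal-detection bookkeeping. Sensitivity is
$d' = z(H) - z(F)$ with extreme rates corrected by the $1/(2n)$ rule, and
the learning criterion is $d' > 1$. Catch trials (reverse or cyclic
probes, canonically 10% of non-rewarded trials) are excluded from $d'$ and
analyzed through the interruption ratio: an agent that treats the reversed
pattern like the familiar one shows no ratio difference, one that fails to
recognize it stops interrupting on catch trials. The agent simulator draws
interruptions and water-port visits from per-day Bernoulli policies with
uniform latencies — enough structure to validate the analysis round-trip
(simulate → classify → recover the generating probabilities within
binomial error), with no claim of modeling real learning dynamics.

# Problem sizes, determinism and limitations

Headline simulations use the study's scale: 10 + 10 units, 2 stimuli, 20
trials, 3-s sequences; property checks sweep 20 seeds. Every generator
takes an explicit seed and restores the caller's RNG state; per-(unit,
stimulus) child seeds make whole datasets reproducible. What passing tests
show is that the *analyses* behave as claimed on data with the assumed
structure; they cannot show that real secondary neurons carry bigram
context, a 40-ms absolute memory, or uncorrelated noise — within-animal
noise correlations, non-Poisson backgrounds, electrode drift and
overlapping spikes are all outside the generator. The deposited spike
data, if available locally, can be run through the identical pipeline via
`import_spike_data()` on a `primary/` + `secondary/` folder layout.
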