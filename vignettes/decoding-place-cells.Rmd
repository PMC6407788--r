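---
title: "Decoding self-location from place-cell populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding self-location from place-cell populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hippocampal place cells fire selectively when an animal occupies a
restricted region of its environment. Given simultaneous spike trains from a
few tens of such units and a tracked position trace, the position of the
animal can be decoded from windowed spike counts; the achievable accuracy is
a lower bound on the positional information carried by the population.
`placedecode` implements three decoders over a shared feature pipeline:

1. a **flat-prior Poisson decoder** (a maximum-likelihood estimator over
   spatial bins),
2. a **Bayesian decoder with memory** — the same likelihood combined with a
   behavioural occupancy prior and a movement-continuity constraint, and
3. a **many-to-one LSTM sequence regressor** trained on sequences of spike
   count vectors.

All three are exercised by a synthetic session generator so that the whole
pipeline is testable without recorded data.

## Feature extraction

Spike counts are taken in sliding windows of length $T$ (canonically scanned
from 200 to 4000 ms) advanced by a 200 ms stride, so consecutive windows
overlap by $1 - \text{stride}/T$. Windows are half-open $[s, s+T)$: a spike
on the start boundary belongs to the window, one on the end boundary does
not, so non-overlapping windows partition spikes exactly. The window grid is
anchored at the start of the usable span (the intersection of the neural and
positional recordings); the anchoring convention is ours, nothing in the
method depends on it.

For the sequence regressor, each sample is the stack of `seq_len`
consecutive count vectors (canonically 100, spanning roughly 20 s of
activity) and the target is the position linearly interpolated at the centre
of the sample's last window. Samples that would need windows before the
session start are simply absent rather than padded; this makes the
cross-validation discard arithmetic exact.

The Bayesian decoders are often run with half-window overlap instead of the
fixed 200 ms stride; both conventions are supported (`stride_ms` in
`run_config()`) and results record which was used.

## The Poisson decoders

With ratemaps $\alpha_i(x)$ (unit $i$, spatial bin $x$), the likelihood of a
count vector $K = (k_1,\dots,k_N)$ in a window of length $T$ is

$$P(K \mid x) \;=\; \prod_{i=1}^{N}
  \frac{(T\,\alpha_i(x))^{k_i}}{k_i!}\, e^{-T\,\alpha_i(x)} .$$

The flat-prior decoder normalises this over visited bins and reads out the
argmax bin centre. The memory decoder multiplies the likelihood by the
occupancy prior $p(x)$ and, from the second window on, by an isotropic
Gaussian centred on the previously *decoded* position,

$$P(x_t \mid K_t, x_{t-1}) \;=\; C\, p(x)\, P(K_t \mid x)\,
  \mathcal{N}\!\left(\lVert x - x_{t-1}\rVert;\, \sigma_t\right),$$

with $\sigma_t$ equal to the mean displacement per step of the decoded path
over the previous 15 steps, multiplied by a scale factor (1 for open-field
decoding, 5 for the linearised track).

Numerical choices:

* All likelihood math is in the log domain with $\log k!$ via `lgamma`; a
  4000 ms window with a 60 Hz interneuron would overflow the direct product.
* Ratemaps are floored at `rate_floor_hz` (default 0.01 Hz) on visited bins
  so $k \log \alpha$ is always finite. The floor is a numerical necessity,
  not part of the model; it is configuration-exposed.
* Whether the continuity width should be derived from decoded or true
  displacements is ambiguous in the literature this follows; decoding at
  test time cannot see the truth, so the decoded path is the default (the
  implementation computes it from the decoded history only).
* With fewer than 15 previous steps all available ones are used; the first
  window uses the prior alone; and $\sigma_t$ is floored at `min_sigma_cm`
  (default 2 cm, one bin) so a stationary decoded history cannot collapse
  the constraint to a delta function.
* Ties in the argmax read-out break to the lowest bin index, making
  decoding fully deterministic.
* The occupancy prior defaults to training-data occupancy (`train_only`) to
  avoid test-set leakage; `full_trial` reproduces the classical
  whole-session prior on demand.

## Ratemaps

Spike and dwell maps are accumulated on 2 cm bins (square in 2D, arc-length
segments in 1D), each smoothed with a truncated Gaussian kernel
($\sigma = 1.5$ bins, radius $4\sigma$), and divided. Two details are our
own decisions where the classical recipe is silent:

* **Edge handling**: each source bin's kernel is renormalised over the
  visited bins it reaches, which conserves total spike and dwell mass
  exactly (verified against a brute-force convolution oracle in the tests).
* **Visited mask**: bins with zero raw (pre-smoothing) dwell are excluded
  from decoding; $\alpha_i(x)$ is undefined without occupancy there.

Occupancy attributes each tracking sample's forward inter-sample interval to
its bin; intervals longer than five times the median (tracking gaps, or the
splice across an excluded validation block) are capped so one sample cannot
absorb a gap as dwell. The Skaggs spatial information utility
($\sum_i p_i (\lambda_i/\bar\lambda)\log_2(\lambda_i/\bar\lambda)$ bits per
spike) comes from the classical place-field literature and is included as a
comparison score only.

## The sequence regressor

The many-to-one regressor is an input layer of size $N$, two LSTM layers
(512 units each in the reference configuration) and a linear read-out to the
coordinates, with the loss applied only to the final-timestep output. It is
trained for exactly 50 epochs with RMSprop at a constant learning rate of
0.001 and mini-batches of 64, minimising the mean over samples of the summed
squared coordinate error; no early stopping, and no validation data touch
the training loop. Since no deep-learning backend is available to this
package, the LSTM forward pass, backpropagation through time and RMSprop are
implemented directly in R matrix algebra; this keeps every arithmetic step
inspectable and bit-reproducible given the seeds, at the cost of speed.

Declared defaults where the recipe is silent: inputs are raw spike counts
and targets raw cm coordinates (no standardisation; a config flag could add
it, and the tests show learning succeeds without it); weights are
Glorot-uniform with the forget-gate bias at 1, seed-pinned.

A **scaled CPU profile** is first-class for testing: hidden 128, 2 layers,
20 epochs, 25-step sequences, a single cross-validation fold, and every
second training sample. The profile was chosen once for CPU budgets, not
tuned against any criterion: shrinking the sequence from 100 to 25 steps
still spans ~6 s of context with 1400 ms windows, and halving the training
set roughly halves compute while leaving thousands of samples. The
acceptance checks compare this profile against the predict-training-mean
baseline, which is capacity- and scale-independent.

Input-gradient sensitivity backpropagates each sample's own loss to its
input counts, giving the $D \times T \times N$ tensor of magnitudes
$|\partial L_s / \partial x_{s,t,n}|$; the per-sample (not batch-averaged)
loss convention is ours and is verified against central finite differences.

## Blocked cross-validation

Random train/validation splits leak badly here: overlapping windows make
neighbouring samples nearly identical. Folds are therefore contiguous
blocks of the recording (fold 1 is the first tenth, and so on; remainder
samples go to the last fold), and a validation sample is discarded whenever
its window span shares any window with any training sample — for samples
built from `seq_len` windows, exactly when the sample indices differ by
less than `seq_len`. The discard *predicate* is authoritative; the familiar
"99 samples per border" constant is just its value at `seq_len = 100`, and
the tests verify the predicate exhaustively.

The Bayesian decoders are deterministic and run once per fold, with
ratemaps and prior estimated from training-time data only; the effective
dependency length for their border discards is the number of windows
sharing raw spike data, $\lceil T/\text{stride}\rceil$. The stochastic
regressor is retrained `n_repeats` times with distinct seeds and the
reported aggregate is the average of per-realization errors, not the error
of averaged predictions.

Errors are Euclidean distances in continuous coordinates by default;
`compute_errors(mode = "bin2d")` provides the bin-centre-to-bin-centre
variant used by grid decoders, and reports state which was used. On the
Z-track, 2D camera positions are projected orthogonally onto the ideal
three-segment polyline (190 + 220 + 190 cm) and errors are absolute
arc-length differences on $[0, 600]$.

## The synthetic session generator

The generator states a world with the statistical structure the decoders
assume, with defaults mirroring a typical single-animal session: **40 place
cells + 3 interneuron-like units, 1200 s, 1 m × 1 m arena, 50 Hz
tracking**.

* **Behaviour**: an Ornstein–Uhlenbeck velocity process (relaxation 1 s,
  mean speed 15 cm/s) reflected at the walls, with stationary pauses
  (probability 0.05 per second, mean 1.5 s); on the Z-track, back-and-forth
  laps with reward dwells at corners and ends. Any smooth coverage process
  would do; this one is chosen for its simplicity and realistic speed
  statistics.
* **Tuning**: Gaussian place fields with centres uniform over the arena,
  widths $\sigma \sim U(6, 14)$ cm, peaks $U(5, 20)$ Hz, baselines
  $U(0.05, 0.5)$ Hz — typical dorsal CA1 values; interneuron-like units get
  a high, spatially flat rate ($U(30, 60)$ Hz, roughly four times a typical
  place-cell peak) with only weak modulation.
* **Spiking**: inhomogeneous Poisson by thinning. Because place-cell count
  variability exceeds Poisson, the rate is optionally multiplied per
  1-second block by a gamma variate with mean 1 (shape `overdispersion_k`,
  default 3), giving Fano factors above 1 at the 1 s scale.
* **Seeds**: one master seed; each component derives a child seed
  deterministically, so every output is a pure function of (config, seed).

What the generator does **not** model — and hence what a green test does not
establish: non-local activity during immobility (replay), theta phase
precession, directional tuning on the track, multi-field cells, tracking
artefacts beyond out-of-arena jitter, and electrode drift. Decoding
accuracies on this synthetic world are not comparable to accuracies on
recorded sessions; the benchmark checks only that each decoder recovers
position far better than chance in a world satisfying its assumptions.

One empirical property worth flagging: at the default 1200 s the mean
occupancy is only ~0.5 s per 2 cm bin, so the argmax of an estimated
ratemap fluctuates by one to a few bins around the true field centre even
for strong units; the test suite therefore checks the *median* peak-location
error across strong place units (within two bins) rather than demanding it
unit by unit, which sampling noise at this session length cannot guarantee.

## Sensitivity analyses

* **Knockout without retraining**: one unit's counts are zeroed in all
  validation samples, predictions recomputed, and the increase in mean
  error ranks the unit. The model never sees the perturbation at training
  time, so it cannot compensate.
* **Gradient sensitivity**: mean magnitudes of the input gradients,
  averaged across any of the tensor's dimensions — per unit, per sequence
  position, or per spatial bin of the sample's true location (the
  "sensitivity field"; the assignment of a sample to the bin of its true
  position is our choice).
* **Rate-normalised curve**: per unit, counts and gradient magnitudes are
  divided by their own 99th percentiles (the percentile, not the maximum,
  so one outlier count in a sparse unit does not set the scale; a few
  normalised values exceed 1 by construction), pooled, and averaged within
  normalised-rate bins. On the synthetic benchmark the curve falls at the
  top of the rate axis, i.e. the trained model is least sensitive to count
  perturbations near field centres where firing is maximal.

The two rankings (knockout and gradient) are compared with the
tie-corrected Spearman coefficient; on the benchmark they correlate
positively but far from perfectly — they probe different perturbations
(removal versus infinitesimal deviation).

## Known limitations

* Pure-R LSTM training is two to three orders of magnitude slower than a
  GPU implementation; the reference configuration (512 hidden units,
  100-step sequences, 10 × 10-fold CV) is API-complete but intended for
  workstation runs, not the test suite.
* The memory decoder is a filtering (forward-only) decoder; no smoother or
  particle-filter variants are provided.
* Reading proprietary acquisition formats, spike sorting and LFP handling
  are out of scope; inputs are plain delimited tables.
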