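---
title: "Waveform-to-waveform prediction of physiological signals"
author: "pulsecast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Waveform-to-waveform prediction of physiological signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Several clinically important pressure signals — intracranial pressure (ICP)
above all, but also continuous arterial blood pressure (ABP) — can only be
measured invasively. Both, however, are mechanically coupled to signals that
are easy to record: ABP drives ICP through the cerebrovascular bed, and the
photoplethysmogram (PPG) reflects the same pulse wave that creates the ABP
waveform. `pulsecast` implements an end-to-end method that learns the mapping
from an observable pulsatile waveform to a hard-to-measure one, predicting
the *full target waveform* (not just summary values such as systolic
pressure), sample by sample.

The mapping is difficult for three reasons that shape the whole design:
the relationship is nonlinear; the two signals are mutually delayed by a
variable, subject-dependent lag (phase mismatch); and the target depends on
the source across several cardiac cycles, with slow modulations
(respiration, vasomotion) superimposed.

## The model

### Composite 7-channel input

Rather than feeding the raw 1-D signal, the input is expanded into a
point-aligned `T x 7` feature matrix: the raw samples; four per-cycle
morphological features broadcast to every sample of their cycle — amplitude
(peak minus opening trough), pulse width, rise time and fall time, in
seconds; and the pointwise first and second derivatives. Cycles are
delimited trough-to-trough, so `width = rise + fall` holds exactly. Cycle
boundaries are detected with a scale-free rule: peaks are local maxima with
a minimum separation of `60 * fs / hr_high` samples and topographic
prominence of at least 0.25 times the interquartile range of the signal;
troughs are found the same way on the inverted signal, and the two landmark
sets are reconciled into a strict trough/peak interleaving (trough pairs
that bracket no peak — as happens around artifacts — are merged by dropping
the shallower trough).

The per-cycle channels give every sample direct access to rhythm and
morphology information that a network would otherwise need many layers to
infer; the derivative channels make slope and curvature explicit.

### CBAnet

The network composes three subnets and a readout, all length-preserving:

* **LFE** — two 1-D convolutions (kernel 3, stride 1, zero same-padding, no
  subsampling), 7 -> 32 -> 64 channels, each followed by ReLU. The
  three-point neighborhood smooths sample noise while keeping the local
  gradient structure of rising and falling edges, and the absence of
  pooling preserves phase.
* **TRN** — a stack (default two layers) of bidirectional LSTMs with
  unidirectional hidden size `h` (default 64); forward and backward states
  are concatenated to `2h` per step, modeling long-range, cross-cycle
  dependencies in both temporal directions.
* **GRA** — one block of multi-head scaled-dot-product self-attention over
  the whole window (default 4 heads, head width `2h / heads`), with no
  causal mask: any two time steps attend to each other directly, which
  performs a global soft realignment that absorbs variable lags. No
  positional encoding is added — the recurrent stage that precedes
  attention already provides order information.
* **readout** — the same affine map `2h -> 1` applied independently at each
  time step.

Training minimizes the mean squared error between predicted and reference
windows (the primary objective). A composite loss is also available that
adds three consistency terms: a first-difference (slope) term, a spectral
term (squared L2 distance between one-sided periodograms, `|DFT|^2 / T`),
and `1 - Pearson correlation`. Default weights are 0.1, 0.01 and 0.1;
all-zero weights recover plain MSE exactly. Note that the spectral term is
a sum over frequency bins and grows with window length — on z-scored
windows of a few hundred samples it dominates the total even at weight
0.01 — so the composite loss is opt-in and every default protocol trains
on plain MSE. Optimization uses
AdamW (default learning rate 1e-3, weight decay 1e-2 on weight matrices
only), batch size 32, 100 epochs at full scale.

Because no automatic-differentiation framework is involved, the package
implements forward and backward passes explicitly (the recurrent inner loop
in C++); the unit tests verify every analytic gradient against central
finite differences.

### Windows, normalization, fusion

Long records are sliced into windows of `T = 700` samples with stride
`S = 100` (configurable), giving `floor((L - T)/S) + 1` windows. All seven
input channels and the target are z-scored with parameters fitted on the
training partition only. At inference, overlapping window predictions are
fused by a weight-normalized average with a strictly positive Hann-shaped
taper per window (shifted half a sample so end weights never vanish):
weights are renormalized to sum to one at every covered sample, so a sample
covered by one window passes through unchanged and agreeing windows
reproduce their common value exactly. No padding is used; the uncovered
tail, if any, is reported and excluded from evaluation rather than
fabricated. Splits (train/test 8:2, optional trailing validation block) are
contiguous in time, and cross-validation folds are contiguous blocks,
because window-level random splits would leak overlapping samples between
partitions.

### Evaluation

Predictions are mapped back to physical units before any metric. The
package reports RMSE, MAE and R²; preprocessing-improvement deltas
(`dRMSE% = 100 (RMSE_s - RMSE_x) / RMSE_s`, likewise for MAE, and the
signed difference `dR² = R²_x - R²_s`); and Bland–Altman agreement: bias
`mean(pred - ref)`, SD of the differences (denominator `n - 1`, the
conventional choice for limits of agreement), and 95% limits
`bias ± 1.96 SD`.

## The denoising chain

Raw optical recordings need cleaning before cycle segmentation. The chain
has three steps, in order:

1. **Despiking.** Samples adjacent to a first difference exceeding
   `k = 6` times the MAD of all first differences are flagged (runs widened
   by 2 samples) and replaced by a natural cubic spline through their
   neighbors. The MAD rule is scale-free; a constant trace (MAD = 0) is
   passed through, and a trace with more than half its samples flagged is
   rejected as unusable.
2. **Baseline removal.** The drift estimate is the mean of a grayscale
   morphological opening and closing with a flat structuring element of
   1.5 s (about 1.5 cycles at rest) — averaging the two operators treats
   peaks and troughs symmetrically, so pulse amplitude is not biased.
3. **Bandpass.** A Butterworth bandpass, 0.5–10 Hz, order 4, applied
   forward and backward for zero phase (phase fidelity is a design goal
   throughout). Odd-reflection padding of `3 / f_low` seconds suppresses
   the start/end transients of the low corner.

All stages are length-preserving. Applied at their pipeline position they
are near-idempotent: despiking exactly so; the zero-phase filter to well
under 1% RMS for in-band content (pulse harmonics near the 10 Hz corner
move about 1% on a second pass); the morphological baseline estimate to a
few percent (envelope curvature within the structuring window moves on
reapplication). Out of position — e.g. filtering a signal that still
contains spikes — the operators are deliberately not idempotent, which is
why the chain order is fixed.

## The synthetic data generator

Because the published clinical datasets cannot ship with the package, every
claim is exercised on a seeded simulator whose ground truth is known. The
source signal is a train of asymmetric beat templates (raised-cosine rise
over a configurable fraction of the cycle, default 0.3; quasi-exponential
fall; optional dicrotic-like bump), placed at onsets with per-beat period
jitter (3% default) around a mean heart rate (70 bpm), amplitude-modulated
by respiration (0.25 Hz, 10% depth), plus slow sinusoidal drift, sparse
Poisson spike artifacts (0.05/s, about five times the signal range) and
white noise (SD 0.02). Defaults: 50 Hz, 60 s.

The paired target applies a known transfer to the *artifact-free
physiological component* (pulses + respiration + drift): delay 0.2 s,
first-order smoothing with time constant 0.1 s, gain 1.5, plus a mild
quadratic term (coefficient 0.2) and independent measurement noise. Spike
artifacts and channel noise deliberately do not propagate: they are
sensor-local, as in real paired recordings — an early version that passed
the raw recorded samples through the transfer made artifacts *predictable*,
which inverted the value of despiking and misrepresented the task.

What the simulator does **not** emulate: baroreflex and autoregulation
dynamics, beat-morphology changes under arrhythmia, sensor saturation, and
inter-subject variability. Passing the recovery benchmark therefore shows
that the implementation can learn a delayed, smoothed, mildly nonlinear
transfer under realistic quasi-periodicity and noise — not that it attains
any particular accuracy on clinical data.

## The reduced-scale recovery benchmark

`synthetic_benchmark()` runs the whole method at desk scale: one 60 s
record at 50 Hz, windows 200/50, hidden size 32, 30 epochs, batch 32; the
first 80% of the record trains the model (about 45 windows, so roughly 60
optimizer steps), the final 20% is held out. Because the optimization
budget is so short, the benchmark's default learning rate is 5e-3 rather
than the full-scale 1e-3; a pilot at seed 1 gave held-out R² 0.84 / 0.94 /
0.96 at 1e-3 / 3e-3 / 5e-3, all comfortably stable. Two baselines
contextualize the result: a persistence baseline (the source trace affinely
rescaled to the target's training mean/SD) and a raw-input ablation — the
network fed only the unprocessed single-channel source, mirroring the
raw-versus-preprocessed contrast of the full-scale experiments. In the
preprocessed arm the source is despiked before featurization (artifacts are
sensor-local and would corrupt per-cycle features); baseline wander is kept,
since the transfer acts on it too.

## Numerical choices and degenerate inputs

* Derivatives: central differences scaled by `fs` and `fs²` (exact for
  affine/quadratic signals), one-sided at the edges.
* Zero-variance channels in the normalizer get scale 1 with a warning, so
  normalization stays invertible.
* Zero-variance inputs to the correlation loss term set the term to 1
  (`rho := 0`) with a warning; R² is an error for a zero-variance
  reference.
* Softmax rows are max-stabilized; a single-step window yields the exact
  weight 1.
* Weight initialization: fan-in uniform for convolutions and linear maps,
  per-gate orthogonal recurrent matrices, forget-gate bias 1; all keyed to
  the run seed.
* Tie-breaks in peak selection are tallest-first under the
  minimum-separation constraint.

## Limitations

The implementation is CPU-only and intended for method study, not clinical
deployment. Mixed sampling rates are rejected rather than resampled. The
published full-scale results on clinical datasets depend on external data
and long GPU training and are out of scope here; the package reproduces the
method, its worked evaluation examples, and recovery on synthetic ground
truth.
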