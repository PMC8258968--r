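---
title: "Methods: validating a wearable IMU against optical motion capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating a wearable IMU against optical motion capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kidmotion)
```

## The measurement problem

A wrist-worn IMU reports tri-axial specific force in its own, arbitrarily
oriented device frame, together with an orientation quaternion from its
on-board sensor fusion. An optical motion-capture system reports the 3D
position of a retroreflective marker attached next to the IMU. To compare
the two — and to ask whether the wearable alone supports movement-type
decoding — both must be brought to a common representation: gravity-free
motion acceleration in a shared world frame (x mediolateral, y
anteroposterior, z vertical), time-aligned, segmented into movement cycles,
and expressed on a normalized timescale.

This vignette documents the model each stage implements, the tunable
parameters with their defaults, what the synthetic-data generator does and
does not emulate, and the design choices made where the procedure left
genuine freedom.

## Preprocessing model

**IMU route.** Per sample, `a_world = R(q) a_dev`, where `q` is the
Hamilton, scalar-first `(w, x, y, z)` unit quaternion encoding the
device-to-world rotation. Accelerometers measure specific force, so a
resting device reads `+g` on the world vertical after rotation; the
constant `(0, 0, +9.81)` m/s² is subtracted (`gravity.enabled` /
`gravity.value` in the pipeline config). Channels are then low-pass
filtered. Quaternions within `1e-3` of unit norm are renormalized;
anything further off is rejected as corrupt rather than silently fixed.

**Optical route.** Marker positions are filtered first and differentiated
second, because double differentiation amplifies noise by `(2*pi*f)^4` per
unit power and must see a band-limited signal. The central second
difference `a[i] = (p[i+1] - 2 p[i] + p[i-1]) fs^2` is exact for quadratic
motion and accurate to `O((2*pi*f/fs)^2)` (< 0.1 % at 1 Hz, 200 Hz) in the
passband; endpoints use one-sided formulas. Marker drop-outs up to 10
samples are linearly interpolated; longer gaps are an error rather than a
guess.

**Filter.** A 2nd-order Butterworth low-pass at 6 Hz, applied forward and
backward (`lowpass_filter`). The dual pass cancels the phase response —
event timing is preserved, which matters for cycle segmentation — and
squares the magnitude response, so the effective attenuation is
`1 / (1 + (f/6)^4)`. Edges are handled by odd-mirror padding (at least
`fs/cutoff` samples) plus steady-state initialization, so a constant series
passes through exactly. The cutoff and order are config keys
(`filter.cutoff_hz`, `filter.order`); 6 Hz retains all voluntary arm-motion
content at the movement tempos involved while suppressing differentiation
noise. The processing order (rotate, subtract gravity, then filter the IMU
channels) treats the rotation as sample-wise; with a constant or slowly
varying orientation, rotation and filtering commute to numerical precision,
which the orientation-invariance test verifies.

## Synchronization, segmentation, time normalization

The two streams start at different times (the wearable records before the
cameras roll). The lag is estimated on the acceleration magnitude `Am`:
the optical series is held fixed, the IMU series is shifted forward by
integer lags `0..max_lag` (default 2 s × fs), and the Pearson correlation
over the overlap is maximized; exact ties go to the smallest lag. Only
non-negative lags are searched because only the IMU stream's initial
samples are ever cut. The estimated lag is applied to all channels, and
both streams are trimmed to the common length.

One practical refinement: the *copies* of `Am` handed to the lag search are
conditioned — one second is trimmed from both ends of the reference and
from the start of the query, and both copies get an extra low-pass at half
the analysis cutoff. The abrupt rest-to-motion transition and the
end-of-stream filter transients otherwise sit inside the correlation
window and can drag the argmax by a sample, and for movements whose `Am`
modulation is weak relative to differentiation noise (the ellipse is the
worst case: its magnitude varies only between `b*omega^2` and `a*omega^2`)
the extra smoothing sharpens the integer-lag peak. The aligned output
streams themselves are untouched. With this conditioning, injected lags of
0–50 samples are recovered exactly in ≥ 95 % of default-noise replicates;
residual misses are ±1 sample, which the boundary clamp absorbs (a
one-sample misalignment shifts each 10 %-bin mean by 1/40th of a bin and
must not cost a whole cycle).

Cycles are delimited by the event markers stored during acquisition (the
simulator emits them at ground-truth boundaries), not detected from signal
periodicity — the platform records an explicit marker stream for exactly
this purpose. Cycle `k` spans the half-open interval
`[boundary_k, boundary_{k+1})`. Each cycle is summarized as 10 bins per
channel: contiguous, near-equal blocks of samples (remainder to the
earliest bins), each bin the mean of its block. Binning by means (rather
than point resampling at decile instants) follows from the agreement
analysis averaging "for each time-bin"; point resampling is the documented
alternative, not implemented. Note that because averaging does not commute
with the Euclidean norm, the binned `Am` channel is not the norm of the
binned components; `Am` is always binned from the raw-sample magnitude.

## Agreement statistics

Per movement type, `Am` is averaged across each participant's ten cycles
separately per time bin and device, and the participant × bin means are
stacked into an `n = 200` row, `k = 2` column table. The row structure
(participant × bin, one table per movement type) is a design choice: it
matches how the binned profiles are reported per movement type and gives
every ICC the same `n`. Alternatives (per-bin ICCs across participants)
are noted but not implemented.

From the two-way crossed decomposition (`SSR`, `SSC`, `SSE = SST − SSR −
SSC`, divided by `n−1`, `k−1`, `(n−1)(k−1)`):

* consistency `= (MSR − MSE) / MSR` — invariant to a constant offset
  between devices;
* absolute agreement `= (MSR − MSE) / (MSR + (MSC − MSE)/n)` — the column
  (device) variance penalizes systematic offsets.

Significance against ICC = 0 uses `F = MSR/MSE` with `(n−1, (n−1)(k−1))`
degrees of freedom; for absolute agreement under a non-zero null the
McGraw–Wong average-measure form with Satterthwaite degrees of freedom is
implemented (at null 0 it reduces to the same `F`). `MSE = 0` (e.g. the
textbook 4 × 2 table) is reported as a flagged degenerate case with
`F = Inf`, `p = 0` rather than an error. Bonferroni adjustment uses
`m = 8` — four movement types × two indices, the number of tests actually
reported. Negative ICCs are reported as computed, with a warning, never
clipped.

## Classification

Features are the three world-axis bin vectors concatenated in fixed order
(30 per cycle); `Am` is excluded as redundant. The classifier is a linear
SVM: L2-regularized hinge loss solved by dual coordinate descent (the
standard linear-SVM algorithm; implemented in C++ in this package because
no SVM library is part of its dependency footprint), with a bias term as an
augmented constant feature and one-vs-one voting for the four classes (ties
broken by summed decision values, then class order — deterministic).

The cross-validation is structured by design, not random: each of the 10
folds holds exactly one cycle per participant per movement type, so every
test fold is an 80-cycle miniature of the full design and every class and
participant is equally represented everywhere. Within each outer training
set, the remaining nine folds serve as inner validation folds for tuning
`C` over `10^-3..10^3` (7 log-spaced values; the linear kernel has no other
hyperparameter); features are z-scored with statistics fit on the training
rows only; the model is refit on the full training set and evaluated on the
held-out fold. Reported: per-fold accuracies, their mean, SEM (SD of the
10 fold accuracies / sqrt(10)), and the pooled row-normalized confusion
matrix.

Cross-classification tunes and fits entirely on one modality's table and
evaluates on the other modality's cycles fold-by-fold using the same
structured folds, so its SEM is comparable to the within-source analysis.
(Consequence: with the test table identical to the training table, the
result is the resubstitution accuracy.)

The permutation null shuffles movement-type labels globally across cycles
and recomputes the full nested-CV accuracy per permutation. The design
folds are kept fixed — they are defined by participant and cycle slot, and
a stratified re-draw on shuffled labels would be impossible anyway. By
default the hyperparameter search is repeated inside every permutation
(conservative); `retune = FALSE` with a fixed `C` is the documented fast
path. `p = (1 + #{null ≥ observed}) / (1 + n_perm)`: with 100 permutations
the smallest attainable p is 1/101 ≈ 0.0099, so conventions like
"p < 0.001" are not reachable at that permutation count and results are
reported against the attainable minimum.

## The synthetic world

The generator states the study design rather than offering dials: 20
participants × 4 movement types × 10 cycles at 200 Hz. Movements are
closed-form curves in the frontal (x–z) plane: horizontal
`x = 0.20 sin(2*pi*t/T)` (0.40 m peak-to-peak), vertical
`z = 0.25 sin(2*pi*t/T)` (0.50 m), ellipse `x = 0.1125 cos`, `z = 0.0755
sin` (the 22.5 / 15.1 cm template), and a 1:2 Lissajous figure-eight with
the same semi-axes — the standard analytic figure-eight, since only a
drawing defines the task shape. The tempo `T = 2` s is a package default,
not a measured value: the protocol paced movements only "approximately"
with a tone, and 2 s per cycle is a comfortable rate for school-aged
children on ~0.4 m excursions. For the same reason each cycle's duration
is jittered ±5 % uniformly.

Each participant gets a Haar-uniform random device orientation (constant
within a recording), a random IMU start lag of 0–80 samples realized as
rest-pose (gravity-only) padding, plus one trailing rest sample so the
final boundary marker lands on a stored row. The IMU stream is the
analytic world acceleration plus the gravity reaction, rotated into the
device frame by the inverse orientation, with white Gaussian noise of SD
0.05 m/s² (a mid-grade MEMS accelerometer after internal decimation); the
optical stream is the analytic position with white noise of SD 0.5 mm
(optical systems claim sub-millimeter precision). Everything is
reproducible from one seed.

Deliberately not emulated: biomechanical arm dynamics, soft-tissue
artifact, sensor-fusion drift or bias, magnetometer behavior, marker
occlusion gaps, nonstationary noise. A green test therefore establishes
that the *pipeline* is correct and that the statistics behave as designed
under the stated noise model — not that any physical device meets the
reported numbers. Accordingly the simulated ICCs (~0.999) and accuracies
(~1.0) sit at the optimistic end of the real study's ranges (0.981–0.999;
0.97–0.99): the acceptance criteria treat the real-data results as floors
the stated world must meet, which a harsher world would not.

## Numerical choices and degenerate inputs

* Quaternions: renormalized within `1e-3` of unit norm, rejected beyond;
  near-zero quaternions error.
* Filter: series shorter than the padding requirement (~`fs/cutoff`
  samples) error out instead of returning transient-dominated output.
* Lag search: zero-variance series and empty overlaps are errors; ties go
  to the smallest lag.
* Segmentation: boundaries must be strictly increasing; the final boundary
  may be one past the last sample (exclusive end); after alignment,
  boundaries are clamped into range rather than discarded.
* Binning: remainder samples go to the earliest bins; segments shorter
  than the bin count error.
* ICC: `MSR = 0` and non-positive agreement denominators are errors;
  `MSE = 0` is a flagged degenerate significance case.
* SVM: solver tolerance 0.01 on the projected-gradient spread, 200 epoch
  cap, per-model seeds — results are deterministic for a given seed.
* The permutation p-value can never be 0 by construction.

## Known limitations

* The structured fold scheme requires each participant × type stratum to
  divide evenly into the folds (10 cycles / 10 folds); unbalanced designs
  are rejected, not approximated.
* Sub-sample lag estimation is out of scope; synchronization is integer
  lag only.
* The agreement analysis implements the two average-measure ICCs above
  only — no single-measure variants, confidence intervals, or
  Bland–Altman analysis.
* Orientation is taken from the device quaternion as given; no sensor
  fusion is performed or corrected.
* The CSV dialects defined here are the package's canonical interchange;
  proprietary capture formats need external conversion.
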