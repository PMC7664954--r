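---
title: "Methods: zero-velocity updates and learned integration in zuptr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zero-velocity updates and learned integration in zuptr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zuptr)
```

## The problem and the model

A body-worn IMU delivers gravity-removed linear acceleration $a_t$ (m/s²)
and angular velocity $\omega_t$ (rad/s) at a fixed rate (120 Hz throughout).
Position follows from double integration,

$$v_t = v_{t-1} + a_t\,\Delta t, \qquad p_t = p_{t-1} + v_t\,\Delta t,$$

but any bias $\beta$ in $a$ grows into a position error
$\tfrac{1}{2}\beta t^2$; dead reckoning is unusable after seconds. Human
activity, however, alternates between movements and dwells. During a dwell
the velocity is exactly zero, which yields two corrections:

* **Zero-velocity update (ZUPT)**: while a frame is classified stopped,
  force $v = 0$ and freeze $p$.
* **Linear drift removal**: a moving segment entered from rest must also end
  at rest, so the residual end velocity $v_e$ is attributed to linearly
  accumulated drift and removed:
  $\text{drift rate} = (v_e - v_b)/(t_e - t_b)$,
  $v^{corr}(t_i) = v(t_i) - \text{drift rate}\cdot(t_i - t_b)$.
  The anchor $v_b$ is the zero velocity at the sample before the segment,
  so a constant in-segment accelerometer bias — which produces an exactly
  linear velocity ramp — is removed completely.

Everything else in the package is about deciding *when* the sensor is
stopped, and about replacing the fixed integrator with learned ones.

## Zero-velocity ground truth from a position reference

Given a reference track, a window of $N = 30$ samples (0.25 s) is labeled
moving when the movement inside it exceeds `thresh` = 1 cm — equivalently an
average velocity of 0.04 m/s — with the label placed at the window centre
(`floor(N/2)`; the even-$N$ centre is taken at index 15). Hysteresis
multiplies the threshold by $T = 3$ while the current state is stopped, so
3 cm of movement is needed to leave rest, suppressing chatter.

Choices the definition leaves open, decided here once:

* *Movement measure*: maximum Euclidean deviation from the window's first
  sample. This matches the average-velocity interpretation (1 cm per 0.25 s)
  and is robust to jitter; a path-length measure is available behind
  `measure = "path_length"`.
* *Boundary semantics*: movement exactly at the threshold keeps the stopped
  state (strict inequality); the initial state is stopped because trials
  start at rest at the origin.
* *Stride*: 1, so that every frame inside the labeling margin receives a
  label (the gated integrator needs dense labels); frames outside the margin
  inherit the nearest labeled value.
* *Calibration*: `fit_labeling_params()` maximises mean per-trial accuracy
  over a user grid; ties go to the smallest threshold, then the smallest
  hysteresis multiplier.

## Detectors

**SHOE** thresholds the variance-normalised windowed energy
$\frac{1}{N}\sum (\|a_n\|^2/\sigma_a^2 + \|\omega_n\|^2/\sigma_\omega^2) < \gamma$;
**ARED** uses the gyro term alone. Both place the window's decision at the
same centre frame as the labeler so that outputs align. $\sigma_a^2$ and
$\sigma_\omega^2$ are estimated as pooled per-axis variances over stationary
training frames when not supplied — the source of these constants is
otherwise unspecified. Thresholds are calibrated by maximising accuracy
pooled over all training frames on a log-spaced candidate grid between the
smallest and largest observed statistic; 400 grid points (~15% threshold
granularity) are needed because the normalised statistic spans many decades.
Ties go to the smallest threshold. The detector window size is nowhere
stated; 30 samples is used to match the labeling window.

**Learned window classifiers** (logistic regression, RBF-kernel SVM, random
forest) consume 11 time-domain statistics (mean, max, min, sum, sd, q25,
q75, median, variance, energy, maximum discrete difference — signed, the
literal reading; an absolute variant sits behind a flag) per channel, 66
features per window. Features with $|r| > 0.9$ against an already-kept
column are dropped (keep-first in column order, deterministic), and the
train-fitted drop list and standardisation are reapplied verbatim to
validation and test rows; the tree model skips standardisation.
Hyperparameters are chosen by subject-grouped 3-fold CV with a pluggable,
seeded random search (the original optimisation strategy is treated as a
replaceable component); search spaces are arguments, not code. Because
ridge-penalised logistic regression, an SVM and a random forest are not
available in the target environment, the SVM (kernelised Pegasos) and the
random forest (bagged CART, Gini splits, per-node feature subsets) are
implemented in-package; logistic regression is backed by glmnet.

**LSTM sequence classifiers** read raw six-channel windows standardised
with training-subject statistics: one LSTM layer of 30 units with 20%
recurrent dropout, or six layers of 80 units with a 20% dropout layer before
the head; both end in a one-unit sigmoid dense layer. Training uses Adam
(learning rate 5e-3, weight decay 1e-5), binary cross-entropy, batch 32,
gradient clipping (global norm 1; the clipping norm is unspecified
upstream), early stopping with patience 20, and a subject-wise 7:3
train/validation split. A binary median filter (default kernel 31 samples
≈ 0.26 s; the kernel is unspecified upstream) is available as
post-processing.

## The recurrent engine

No deep-learning runtime is available in the target environment, so the
package carries a small pure-R LSTM engine: multi-layer LSTM and dense
layers, inverted dropout and per-sequence recurrent dropout, analytic
backpropagation through time, Adam with L2 weight decay, and global-norm
gradient clipping. Correctness is pinned by finite-difference gradient
checks in the test suite (worst relative disagreement < 1e-5 across layer
types, activations and both heads of the stacked model). Validation loss is
also evaluated *before* the first update and the best-validation weights are
restored at the end, so a warm-started model can never be degraded by
training — without this, Adam's scale-free steps walk a near-optimal
initialisation away from the optimum even when the loss is already ~0.

## Warm-started displacement regressors

The integrative warm start builds a two-layer LSTM that *is* Euler double
integration before any training: cell activations are identities, gate
weights are tiny random values with large positive biases (so the sigmoid
gates saturate open), and the candidate weight on the integrated channel is
$\Delta t$, making unit 1 of each layer accumulate
$c_t = c_{t-1} + \Delta t\,x_t$. The dense head passes layer 2's
integrating unit through with weight 1.

Two numerical choices deviate from the obvious reading and matter:

* *Gate bias* +16 rather than +10. A gate at $\sigma(10) = 1 - 4.5\times
  10^{-5}$ decays the cell state by ≈1% over a 240-step series — visible
  against a $10^{-3}$ oracle-equivalence tolerance. $\sigma(16)$ leaves
  ≈$5\times10^{-5}$ accumulated deviation over 480 integration steps while
  still satisfying the ≥ 0.9999 saturation requirement.
* *Candidate-path perturbations* (candidate bias, recurrent candidate
  weights, head weights) are drawn from ±1e-9 rather than ±1e-6. They feed
  the integral directly, so a ±1e-6 draw accumulates into ~1e-4 m of output
  error on a 2-s series — up to 2% relative. ±1e-9 keeps symmetry breaking
  (all values distinct) and stays inside the "close to zero" envelope.

The pre-trained warm start instead *learns* integration: a one-layer LSTM +
linear head is trained (batch 1, MSE) to map single-axis acceleration to its
Euler-integrated velocity — drift-corrected velocity in the drift variant —
with all three axes pooled as independent samples; the trained pair is then
stacked twice (drift variant: drift-trained weights in layer 1, plain in
layer 2, since drift removal is specific to the acceleration→velocity step).
The no-init variant uses standard Glorot initialisation with 3, 6 or 9 input
channels (adding gyro and the double-integrated position estimate). All
regressors are trained per moving segment on displacement-since-segment-start
targets, batch 1 (variable lengths), subject-wise 7:3 split, patience 20.
The per-layer unit count of the regressors is nowhere stated; 30 is used,
consistent with the stacked model.

One stated expectation is *not* met and is recorded rather than tuned for:
a zero-input series fed to the pre-trained integrator produces a slow drift
(~0.1× the target scale over 150 steps), because training data contain only
moving segments and zero input is out of distribution. The test suite
asserts the bound that does hold (mean response ≪ target scale).

## Stacked joint model

A full-trial model: LSTM(30) + sigmoid dense gives a per-timestep
stopped-probability; that probability is concatenated onto the six input
channels; two further LSTM(30) layers, dropout 0.25 and a linear dense head
emit the 3D displacement since trial start. The loss is
$L = (1-\alpha)\,L_{BCE} + \alpha\,L_{MSE}$ with both terms means over
timesteps (MSE also over axes) and probabilities clipped to
$[10^{-7}, 1-10^{-7}]$; $\alpha = 1$ reduces exactly to MSE, $\alpha = 0$ to
BCE. The label channel is supervised with truth labels during training and
used as a raw probability in the concatenation. Inputs are standardised with
training-subject statistics (unspecified upstream; chosen for optimisation
stability and stated here).

## Error metrics

Per axis, RMSE and MAE of the position residuals; in 3D, the absolute
trajectory error $\mathrm{ATE} = \sqrt{\tfrac1N\sum\|\Delta p_i\|^2}$ and
the mean residual norm. Both tracks share the trial-start frame, so no
alignment is applied, and $\mathrm{ATE}^2 = \sum_{axes}\mathrm{RMSE}^2$
holds as an identity. $R^2$ is implemented as squared Pearson correlation —
the two textbook forms (variance ratio vs squared correlation) disagree in
general, and only the correlation form is bounded in $[0,1]$ with value 1
at perfect prediction; the variance ratio sits behind
`form = "variance_ratio"`. A sign-flipped estimate also scores 1 — a
documented caveat of that definition. Aggregation across trials reports
mean and *sample* standard deviation (n−1; single trial → sd 0 by
convention).

## The simulator: what it emulates and what it does not

`simulate_trajectory()` produces alternating dwells and movements starting
at rest at the origin. Each movement follows a minimum-jerk profile per
axis, $s(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5$ — the standard model of
human point-to-point sub-movements — giving exactly zero velocity and
acceleration at segment boundaries: precisely the structure ZUPT methods
assume, with peak acceleration $10\,d/(\sqrt3\,T^2)$ as an analytic check.
Defaults describe a plausible manual-activity trial at 120 Hz: 9 segments,
dwells and moves of 1–3 s, per-axis move distances 0.2–0.6 m.

`corrupt_to_imu()` derives the clean acceleration as the second central
finite difference of position times rate² (endpoints, inside dwells, zero)
and adds: white noise (default sd 0.05 m/s²), a bias random walk
(0.005 m/s²·√s), and a slow sinusoidal per-axis "gravity leak"
(0.05 m/s², period 60 s) standing in for low-frequency orientation error —
residual gravity is orientation-error-driven and therefore slow. A gyroscope
signal cannot be derived from a position-only trajectory, so it is an
Ornstein–Uhlenbeck process (correlation time 0.3 s) scaled per frame state:
1 rad/s while moving, 0.02 rad/s at rest. This preserves exactly the
statistical contrast SHOE/ARED rely on, and nothing more. Defaults are
plausible for consumer-grade MEMS after soft-tissue artefacts; they were
chosen once and are not fitted to any result.

Not emulated: multi-joint kinematics, activity taxonomy, magnetometer or
orientation dynamics, non-stationary noise. A green test on simulated data
therefore establishes algorithmic correctness (round trips, orderings,
separability under the stated noise), not field performance on any real
recording.

Per-trial seeds are a stable arithmetic hash of (master seed, subject,
placement, trial), so datasets are bit-reproducible and subject-disjoint
splits are well defined.

## Numerical and degenerate-input decisions

* Euler (rectangular) integration everywhere, matching the recurrent
  update's form; segment velocity resets to zero at each moving-segment
  start (the zero-velocity assumption implies a reset rather than carrying
  velocity across stopped spans).
* Length-1 segments pass through drift removal unchanged ($t_e = t_b$).
* Zero-variance feature columns: kept by the pruner (undefined correlation
  treated as 0), centred only by the standardiser (sd guarded to 1).
* Stationary-frame noise variances are floored at $10^{-12}$ so noise-free
  synthetic data cannot divide by zero.
* Classifier probability 0.5 maps to the moving class (strict `> 0.5` for
  stopped), mirroring the detectors' strict inequality.
* All training entry points take explicit seeds; dropout, shuffling,
  initialisation and search draw from them.

## Known limitations

* The pure-R engine is adequate for the tested scales (tens of units,
  thousands of timesteps) but far from GPU training throughput; the 6×80
  classifier and the stacked model are practical only in scaled-down runs
  here.
* The in-package SVM (Pegasos) and random forest are small, dependency-free
  implementations — correct but not tuned to the quality of mature
  libraries.
* $R^2$ as squared correlation rewards sign-flipped or affinely scaled
  estimates; read it together with RMSE/MAE.
* The simulator's error model is additive and stationary; real gravity leak
  correlates with re-orientation events, which no term here reproduces.
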