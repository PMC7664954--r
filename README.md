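# zuptr — zero-velocity update detection and inertial motion tracking

`zuptr` estimates the 3D translational motion of a body-worn IMU (tri-axial
accelerometer + tri-axial gyroscope, gravity already removed upstream) during
activities that alternate between stationary dwells and bounded movements —
the situation of a person screwing, lifting, or carrying in a workspace while
wearing sensors on the shoulders, upper arms or feet. It is aimed at
researchers in human-movement biomechanics and wearable-sensor analytics who
need position tracks from inertial data without an optical reference.

Plain double integration of measured acceleration,
`v_t = v_{t-1} + a_t·dt`, `p_t = p_{t-1} + v_t·dt`, diverges within seconds
because noise and residual gravity accumulate twice. The package implements
the standard remedy — zero-velocity updates (ZUPT) — and several learned
extensions, end to end:

1. **Zero-velocity labeling** from a reference position track: windowed
   displacement threshold (1 cm over 0.25 s ⇒ average velocity 0.04 m/s)
   with hysteresis (3× the threshold to leave the stopped state).
2. **Detectors**: fixed-threshold SHOE
   ( y_k = 1 iff (1/N)·Σ(‖a‖²/σ_a² + ‖ω‖²/σ_ω²) < γ ) and ARED
   ( (1/N)·Σ‖ω‖² < γ_ω ) with automatic threshold calibration; learned
   window classifiers (logistic regression, RBF-SVM, random forest over 11
   time-domain statistics × 6 channels with correlation pruning and
   subject-grouped 3-fold CV) and LSTM sequence classifiers (1×30 units with
   recurrent dropout; 6×80 units), plus binary median-filter post-processing.
3. **Gated dead reckoning**: velocity forced to zero and position frozen
   while stopped; per-segment double integration with linear drift removal
   (`drift_rate = (v_e − v_b)/(t_e − t_b)`,
   `v_corr(t_i) = v(t_i) − drift_rate·(t_i − t_b)`).
4. **LSTM displacement regressors** for moving segments: an *integrative*
   warm start whose untrained weights already perform Euler double
   integration (candidate weight = dt, saturated gates, identity cell
   activations), a *pre-trained* warm start (a one-layer LSTM first taught to
   integrate, stacked twice), and plain randomly initialised variants.
5. **Stacked joint model**: LSTM(30) → stopped-probability, concatenated
   back onto the input, → 2×LSTM(30) → dropout → 3D displacement, trained
   with the joint loss `L = (1−α)·BCE + α·MSE`.
6. **Metrics**: per-axis RMSE/MAE/R² and 3D ATE (`√(mean‖Δp‖²)`) / 3D MAE,
   aggregated as mean ± sd across trials.

A built-in simulator (minimum-jerk movements between dwells, plus an IMU
error model with white noise, bias random walk, sinusoidal gravity leak and
state-scaled gyro activity) generates multi-subject datasets so the whole
pipeline is testable without any external data.

## Worked example

```r
library(zuptr)

ds <- make_dataset(n_subjects = 4, placements = "RSHO", trials_per_subject = 1,
                   spec = trajectory_spec(n_segments = 7, seed = 1),
                   err = imu_error_spec(), master_seed = 42)
train <- ds[1:3]; test <- ds[[4]]          # subject-disjoint split

shoe <- calibrate_threshold("shoe", lapply(train, `[[`, "trial"),
                            lapply(train, `[[`, "labels"))
pred <- shoe_detect(test$trial, shoe)
compare_labels(pred, test$labels)
#> <classification_report> acc 0.9628  prec 1.0000  rec 0.9340  (TP 821 FP 0 TN 679 FN 58)

est <- gated_dead_reckoning(test$trial, pred, drift_correction = TRUE)
error_report(test$track, est$track)
#> <error_report> n=1587  ATE 0.0200 m  3D-MAE 0.0156 m
#>           x      y      z
#> RMSE 0.0165 0.0105 0.0042
#> MAE  0.0128 0.0072 0.0035
#> R2   0.9990 0.9991 0.9999

trajectory_errors(test$track, naive_dead_reckoning(test$trial)$track)$ate
#> [1] 2.82
```

Reading: the calibrated SHOE detector recovers the stopped/moving
segmentation of the held-out subject with 96% frame accuracy (precision 1:
it never calls a moving frame stopped here); gating the integrator on those
labels and removing the per-segment linear drift brings the 13-second
trial's absolute trajectory error from 2.82 m (naive double integration)
down to 2 cm.

Higher-level drivers reproduce whole comparison tables:
`run_detection_experiment()` (detector × accuracy, with/without median
filter) and `run_tracking_experiment()` (detector × regressor × metric,
mean ± sd over test trials).

## Command line

An executable wrapper is installed at
`system.file("exec", "zupt", package = "zuptr")`:

```sh
zupt simulate --out data --subjects 2 --seed 7     # CSV trials + YAML manifest
zupt label    --trial data/S01_RSHO.csv --out labels.csv
zupt calibrate --method shoe --trials data/S01_RSHO.csv \
              --labels data/S01_RSHO_labels.csv --out shoe.yaml
zupt detect   --method shoe --trial data/S02_RSHO.csv --params shoe.yaml --out det.csv
zupt track    --trial data/S02_RSHO.csv --labels det.csv --out track.csv
zupt evaluate --truth data/S02_RSHO.csv --estimate track.csv
```

Trial CSVs have header `t,ax,ay,az,gx,gy,gz[,px,py,pz]` (s, m/s², rad/s, m),
one file per subject × placement; identity is encoded in the file name
(`S01_RSHO.csv`) and recorded in the manifest.

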