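---
title: "Decoding methods and the synthetic multi-session study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding methods and the synthetic multi-session study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgagg)
```

## The problem

Regression-based myoelectric decoders map multi-channel EMG amplitude to
continuous joint kinematics (here 12 degrees of freedom, DOFs, normalized to
$[-1, 1]$). Because implanted-electrode recordings drift from day to day —
impedance changes, slight electrode migration, user state — a decoder
calibrated on one day degrades on later days, and the conventional remedy is
to recalibrate from scratch, discarding all earlier sessions. `emgagg`
implements the alternative paradigm of *dataset aggregation*: training on the
concatenation of the $K$ most recent calibration sessions, and measuring how
accuracy and robustness change with $K \in \{1, 5, 10\}$ for two decoder
families, a thresholded Kalman filter (MKF) and a convolutional regression
network (CNN).

Because suitable multi-session human recordings are not openly available, the
package ships a synthetic generator that produces multi-day studies with the
statistical structure the analysis needs, so the whole pipeline runs
end-to-end from code alone.

## Feature extraction

Raw EMG is sampled at 1 kHz per contact. Conditioning is strictly causal
(forward-only filtering), since the same pipeline must be realizable in
real-time control:

* sixth-order Butterworth high-pass at 15 Hz, second-order low-pass at
  375 Hz;
* second-order band-stop notches at 60, 120 and 180 Hz. The notch bandwidth
  is not dictated by the recording chain itself; we fix it at 2 Hz, wide
  enough to kill mains lines and narrow enough to spare the EMG band.

Differential channels are formed as all pairwise differences $x_i - x_j$
($i < j$, lexicographic, applied to the time-domain signal before
rectification), so $n$ contacts yield $n + \binom{n}{2}$ channels (528 for
32 contacts, 210 for 20). The feature is the mean absolute value (MAV) over
a *trailing* 300 ms window, evaluated at 30 Hz; a trailing rather than
centered window again reflects the real-time constraint. Early frames whose
window precedes the recording use the available samples only.

Users react to movement prompts with a visuomotor delay, so the prompted
kinematics lead the muscle response. `align_lag()` estimates one nonnegative
lag per session (up to 1 s) by maximizing the cross-correlation between the
channel-averaged, mean-centered features and the rectified-kinematics
average, then *delays* the kinematics by that many frames (head padded with
rest). On raw-EMG sessions the estimated lag absorbs the reaction lag plus
the group delay of the causal filters and the trailing MAV window — that is
the correct pairing for training, which is why the estimate on the full
chain sits a few frames above the injected reaction lag, while on
feature-level sessions it recovers the injected lag exactly.

## Channel selection

The Kalman path reduces the feature set to 48 channels by stepwise
Gram–Schmidt forward selection. All channels are mean-centered; at each step
every unselected channel is residualized against the span of the already
selected ones, and the candidate maximizing
$\sum_{d=1}^{12} \mathrm{cor}(r, y_d)^2$ — the forward
orthogonal-least-squares criterion generalized to the 12 kinematic targets —
is added, ties broken by lowest index. The criterion makes selection
invariant to positive channel rescaling and deterministic. A channel whose
residual norm falls below $10^{-10}$ of its original norm is numerically
inside the selected span and is dropped from consideration; if every
candidate is exhausted before 48 picks the function returns fewer indices
with a warning.

## The modified Kalman filter

The state is the 12-DOF position vector itself (no velocity augmentation —
one filter predicts all DOFs, and nothing in the design calls for derivative
states). Training is least squares on 100% of the (lag-aligned,
baseline-subtracted, channel-selected) data: $A$ maps each frame's
kinematics to the next, $H$ maps kinematics to features, and $W, Q$ are the
residual covariances (the maximum-likelihood estimates). Transition pairs
never straddle a session boundary in aggregated training data.

Decoding runs the standard predict/update recursion from a rest (zero)
initial state with a broad initial covariance $10 I$ — rest is the natural
prior and the burn-in is a few frames. The update is computed in information
form, which inverts only $12\times 12$ matrices regardless of the number of
observation channels; a $10^{-9}$ diagonal jitter keeps the predicted
covariance invertible when unused DOFs make $W$ rank-deficient. Each raw
estimate then passes a dead zone: values with $|x| \le 0.2$ are zeroed,
values beyond pass through unchanged (producing a small discontinuity at
$\pm 0.2$; we implement only the zeroing rule, with no post-threshold
rescaling), and the result is clamped to $[-1, 1]$.

## The convolutional regression network

The network input is an $N \times 10$ window: all $N$ feature channels at
the current and nine previous frames. One convolutional layer applies ten
$1 \times 5$ kernels across time only ($N \times 6 \times 10$ feature map),
followed by ReLU, two fully connected ReLU layers of $2N$ units, and a
linear 12-output regression head. Optimization is stochastic gradient
descent with momentum at learning rate $10^{-5}$; training data are a
random 60% of each movement's trials (the split is over trials, never
frames, so correlated frames of one trial cannot leak across the split) and
early stopping halts training once the validation loss has not improved for
20 consecutive checks, returning the best-checkpoint weights. Gradients are
computed analytically (the layer stack is small enough that hand-derived
backpropagation is simpler and faster here than an autodiff dependency) and
are verified against finite differences in the test suite.

Several knobs the architecture leaves open are fixed as follows:

* **Momentum 0.9, mini-batch 64** — the conventional SGDM defaults.
* **Validation every 25 mini-batches, patience in checks.** Aggregated
  datasets differ in size by an order of magnitude between $K=1$ and
  $K=10$; validating on a step schedule rather than per epoch keeps the
  early-stopping granularity, and the run time, independent of $K$.
* **Per-channel z-scoring** of the features with training-set statistics
  (stored in the model, applied at prediction). At learning rate $10^{-5}$,
  raw MAV scales train impractically slowly; `standardize = FALSE` restores
  the literal pipeline.
* **Window thinning.** Adjacent 10-frame windows at 30 Hz overlap by 90%,
  so training uses every third frame as a window anchor, capped at 6000
  training and 1000 validation windows (evenly thinned beyond the cap), and
  a hard cap of 600 SGD steps bounds each fit. At the study sizes used
  here the step cap, not patience, usually ends training; the
  accuracy-floor test relaxes the cap to 1200 steps. Inference always runs
  at every frame, with the first nine frames of a sequence edge-replicated.
* **No baseline subtraction** on the CNN path; rest-level information is
  something the network can use, and only the Kalman path calls for it.

## Metrics

For each trial (one active movement, annotated frame span):

* **Intended RMSE** — error on the active DOF(s) against the prompted
  trajectory; **unintended RMSE** — the cross-talk, each resting DOF's RMSE
  against its zero target, averaged across the resting DOFs of the 12-DOF
  trace (DOFs outside the protocol are identically zero on both sides and
  contribute zero).
* **Windowed RMSE** for target-holding trials: per-frame error is reduced
  by the tolerance half-width 0.15 before squaring, so a DOF anywhere
  within the window scores zero. The "within ±15%" tolerance is interpreted
  as an absolute 0.15 in normalized kinematic units: rest targets sit at 0,
  where a percent-of-target window would be undefined, and the on-screen
  feedback window has fixed size.
* **Time-in-target occupancy**: the percentage of frames with *every* DOF
  inside its window, and the longest consecutive such run in seconds.
* **Log mean absolute jerk** of the active DOF(s), from third-order central
  differences scaled by $f_s^3$; resting DOFs are excluded so that their
  near-zero jerk does not dilute the smoothness measure. An exactly
  constant trace returns $-\infty$ with a warning.
* **Robustness slopes**: ordinary least-squares slope of test RMSE versus
  days since training, per DOF, summarized by median and interquartile
  range.
* **Group comparisons**: Kruskal–Wallis across conditions, followed (when
  significant) by pairwise Wilcoxon rank-sum tests whose normal-approximate
  statistics are referred to the studentized-range distribution — an
  approximate, Tukey-style correction on ranks.

## The synthetic generator

Each session pairs prompted kinematics with synthetic EMG:

* **Kinematics.** Trapezoidal single-movement trials: linear rise over 3 s
  to the target amplitude, 1 s hold, 3 s return (7 s movements), repeated
  consecutively per movement, separated by 2 s rest. Target-holding trials
  use a 0.7 s ramp and hold for the rest of a 5 s trial, 2 s between trials.
* **EMG.** A subject is a nonnegative mixing matrix from 24 rectified
  drives (12 DOFs × flexion/extension) to contact envelopes, plus rest
  baselines, per-contact noise, and a 200 ms reaction lag (a typical
  visuomotor latency, and recoverable by `align_lag()`). Each contact's
  signal is its envelope times a unit-variance Gaussian carrier band-passed
  to 15–375 Hz — the recording band — plus white noise. No motor-unit
  physiology, electrode geometry, or force model is attempted.
* **Feature-level shortcut.** Because carriers are Gaussian, the expected
  MAV has the closed form $\sqrt{e^2 + s^2}\,\sqrt{2/\pi}$ per channel
  (envelope $e$, noise SD $s$; differential pairs add envelope powers), so
  sessions can be generated directly at the feature level with
  multiplicative scatter standing in for windowing noise. The shortcut is
  statistically matched at the envelope level — the tests verify it against
  the full chain within 10% — but does not reproduce the frame-to-frame
  correlation of overlapping MAV windows; the large studies use it for
  tractability, and the raw-EMG path remains the default elsewhere.
* **Drift.** Day-to-day change is a seeded random walk: small Givens
  rotations of the mixing matrix in random two-contact planes, a
  multiplicative per-contact log-gain walk, and an additive baseline walk.
  On top of the walk, each recorded session draws a *non-accumulating*
  log-gain fluctuation (`session_gain_sd`) representing day-of-recording
  state — impedance, electrode seating, user effort — that does not
  persist. This term matters structurally: under a pure random walk the
  most recent session is always the best single predictor of a test day,
  and recency-only calibration could never lose; transient day-specific
  variability is precisely what aggregation averages away.
* **Calibration of the drift knobs.** No quantitative drift magnitudes are
  available to match, only the qualitative picture of per-movement feature
  clusters separating across days in the first two principal components.
  We fixed the defaults (rotation 0.06 rad/day, gain walk 0.10/day,
  baseline walk 0.004/day, session fluctuation 0.25) so that the mean
  between-day centroid distance of a movement's cluster is comparable to
  its within-day spread (ratio ≈ 1) over a 40-day span — clusters visibly
  separated without becoming disjoint point masses. These values were set
  once, against that picture only.

## The offline study and its scale

`run_aggregation_study()` draws one synthetic subject per seed and runs the
full comparison. The shipped study conditions are: 11 contacts (66 MAV
channels, the reduced feature count that keeps the network tractable on a
desktop core), 8 movements (flexion and extension of four DOFs) × 6 trials
per session, 10 training sessions spaced 3 days apart, and test sessions 4
and 32 days after the last training day — training data spanning a month,
tests up to two months out. The acceptance suite runs 10 seeds and checks
only qualitative, pre-registered orderings: unintended RMSE nonincreasing
in $K$ for both decoders, a larger intended-RMSE gain for the CNN than the
MKF, and flatter CNN error-growth slopes at $K=10$ than $K=1$ (one-sided
sign test across seeds). `scripts/acceptance.R` reports the corresponding
improvement percentages and slopes at 6 seeds, plus a target-holding replay
and the feature-space drift summary.

## What passing tests do and do not show

The generator reproduces the structure the analysis assumes — amplitude-
coded features, reaction lag, rest baselines, between-day drift with a
transient session component — but not human motor variability within a
trial, co-contraction, fatigue trends within a session, electrode artifacts,
or any learning by the user across sessions (the simulated user is
stationary; the online human-learning confound is deliberately out of
scope). Passing the aggregation properties therefore shows that the
pipeline, decoders and metrics behave as designed under the assumed drift
structure; it is not evidence about any particular participant population.
Synthetic "participants" are seeds, and summaries are reported per seed as
well as pooled, mirroring the caveat that pooling across heterogeneous
subjects can mask individual differences.

## Known limitations

* The dead-zone threshold passes values through unrescaled, so decoded
  traces jump at $\pm 0.2$; smoothing that discontinuity is a documented
  variant in the literature that we do not implement.
* The Gram–Schmidt selection criterion (summed squared correlation) is the
  standard forward-OLS score; other published variants weight by error
  reduction. At $k = 48$ of 66–528 channels the retained set is insensitive
  to this choice in our tests, but the criterion is a package decision.
* With the default step cap the CNN is deliberately under-trained relative
  to convergence; comparisons across $K$ share the cap, so the orderings
  are meaningful, but absolute CNN RMSE values should not be read as the
  architecture's ceiling.
* With twelve sessions per subject, ten of which train the largest
  aggregate, each robustness slope is fitted through two test points and is
  correspondingly noisy: the flatter-slope-with-aggregation effect is
  visible in the median across subjects but not consistently within every
  subject, and the acceptance suite's per-seed sign test on slopes reflects
  that honestly. Studies that fit slopes over many test sessions per
  subject measure this far more stably.
* Aggregation sizes beyond 10 are configurable but unstudied here.
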