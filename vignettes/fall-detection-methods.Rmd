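---
title: "Methods: two-stage smartphone fall detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage smartphone fall detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(falldetect)
```

## The detection problem

A smartphone carried through daily life records tri-axial acceleration (in
g, gravity-inclusive) and angular velocity (rad/s) at a nominal 50 Hz, but
irregularly: other apps steal the sensor loop, so sample spacing jitters and
occasionally drops out entirely. Against this background the detector must
recognise the signature of a fall — a brief free-fall phase, a sharp impact,
and a post-impact rest — while ignoring gait, posture changes, stumbles that
recover, and the phone itself being dropped. Falls are rare (roughly one per
participant-month in high-risk populations), so the operating point that
matters is not windowed classification accuracy but deployment behaviour:
the fraction of true falls alerted and the number of days between false
alarms.

`falldetect` implements the full online pipeline: windowing and quality
gating, feature extraction, a two-stage classifier, streaming detection with
alerting and portal-style event records, deployment metrics, and a seeded
synthetic IMU generator that makes every stage testable without access to
recorded falls.

## Windows, quality gates, interpolation

The stream is segmented into 5-second tumbling (non-overlapping, half-open)
windows `[t0, t0 + 5000)` ms, starting from the first sample's timestamp
rounded down to the whole second. Non-overlapping segmentation is the
package's reading of the deployed system: it is consistent with a device
that assesses about 720 events per worn hour (648,000 over 90 days at
10 h/day), and overlap would inflate the event count.

A window is usable iff it contains at least 200 raw samples and no gap
between consecutive timestamps exceeds 200 ms. The gap rule is extended to
the window edges (first sample within 200 ms of `t0`, last within 200 ms of
the window end) so that the resampling step below never fabricates more
than 200 ms of signal at a boundary. Usable windows are linearly
interpolated per channel onto a fixed grid of 250 points at 20 ms spacing;
grid points outside the raw span take the nearest raw value. Linear
interpolation with constant edge extrapolation is the simplest choice that
adds no artificial dynamics; no filtering or smoothing is applied anywhere.
Failing windows are not silently dropped: they propagate through the
detector as processing failures so that bookkeeping (failures + classified
= total) always balances.

Time is integer milliseconds throughout. On ingest, rows with non-finite
values are dropped with a logged count and duplicate timestamps keep their
first occurrence — both deterministic rules.

## Features

Each valid window yields 40 features, 20 per sensor, computed on the
interpolated arrays. Eight scalar statistics — mean, median, sample standard
deviation, skewness, kurtosis, IQR, minimum, maximum — are taken on the
magnitude (per-sample Euclidean norm) series; the IQR, minimum and maximum
are additionally taken on its first-difference series ("derivative", per
20 ms step, not divided by the step); and maximum, minimum and IQR are
computed per axis. Conventions are pinned once for reproducibility:

* quantiles use linear interpolation between order statistics (R type 7);
* standard deviation uses the n−1 denominator;
* skewness is `m3 / m2^1.5` and kurtosis the non-excess `m4 / m2^2` with
  population central moments (a Gaussian window scores ≈ 3);
* a zero-variance series takes skew = kurt = 0, so resting windows produce
  finite features.

Scalar features operate on the magnitude rather than any single axis: the
phone's orientation in a pocket is arbitrary, and the magnitude is invariant
to it (the test suite asserts axis-permutation invariance and scale
equivariance). The per-axis extrema retain what orientation information
survives.

## The two-stage classifier

**Stage 1 — the 2 g screen.** A window passes iff the peak of its
interpolated acceleration magnitude strictly exceeds 2 g. The screen's job
is computational and statistical: the overwhelming majority of daily-living
windows never approach 2 g, while genuine fall impacts essentially always
do, so the expensive classifier only sees a thin, impact-rich slice of the
stream. The screen is evaluated on the interpolated series — the same
signal the classifier sees — with the raw-sample peak also recorded for
diagnostics. Both the 2 g and the alert boundaries are strict (`>`).

**Stage 2 — elastic-net logistic regression.** On screened windows the
40 features are standardised (zero-variance columns get std 1 and weight
exactly 0) and scored by a logistic model fit under the elastic-net
penalty:

$$\min_{w,b}\; \frac{1}{n}\sum_i \ell_i(w,b) \;+\;
  \lambda\left(\alpha \lVert w\rVert_1 + \tfrac{1-\alpha}{2}\lVert w\rVert_2^2\right),$$

with `ℓ` the negative Bernoulli log-likelihood and the intercept
unpenalised — the dominant convention for this penalty, so the deployment
hyperparameters α = 0.6, λ = 0.015 keep their meaning. The solver is
deterministic cyclic coordinate descent: each coordinate takes a
soft-thresholded step on the quadratic majorisation of the logistic loss
with the global curvature bound 1/4, which guarantees monotone descent of
the convex objective. Convergence is declared when a full cycle decreases
the objective by less than 1e−8 (at most 10,000 cycles); there are no
stochastic restarts. Tests verify the optimum against both a generic
quasi-Newton optimizer on the same objective and glmnet under the shared
convention. No class reweighting is applied, matching the deployed model's
training on a fall-heavy window population.

**Threshold calibration.** The alert cutoff is the 5th percentile (type-7
linear interpolation) of the posterior probabilities of the training fall
windows, so at least 95 % of training falls score at or above it — a
construction that targets 95 % training sensitivity directly rather than
optimising a surrogate. The shipped default threshold, 0.908, is the
deployed constant from the original training data, which is not public;
`calibrate_threshold()` recomputes the cutoff for any retrained model.
Model selection uses leave-one-participant-out cross-validation (whole
participants held out, preventing identity leakage) scored by AUROC
(Mann–Whitney, ties at ½), with grid-search ties broken toward larger λ
then larger α — the sparser model.

## The streaming engine

`stream_detect()` tumbles a recording, classifies every window, and emits
one time-ordered event record per window. Alerts (posterior strictly above
the threshold) invoke a user hook exactly once each — hook errors are
logged and isolated — and are enriched with contextual fields through a
provider contract: timestamp, location, movement speed over the preceding
five minutes, weather category, and most-likely activity with confidence.
Providers must be total; failures degrade to `unknown`, never to a missed
detection. The real weather/activity/GPS services are out of scope, so the
package ships a null provider and a fixed-value stub. Posteriors in
(0.5, threshold] mark *potential* events; the retention rule keeps exactly
the windows within a closed ±15 minutes of some posterior-above-0.5 event,
mirroring the transmit-saving policy of a deployed phone. Event logs are
JSON lines, one versioned record per window.

## Deployment metrics

Alerts are matched to ground-truth falls greedily and one-to-one, each
truth fall to its nearest unmatched alert within ±10 s (configurable; field
studies verify falls by interview, so no tolerance is canonical — 10 s is
two windows). Conservation identities (`tp + fn` = truth falls, `tp + fp` =
alerts) are asserted after every match. From the counts the package derives
sensitivity, specificity, precision, accuracy, F1, the daily false-alarm
rate and its more interpretable reciprocal, days per false alarm, plus the
processing-failure rate. Undefined ratios are reported as `NA`, never 0,
and excluded (with reported n) from per-participant averages. Accuracy uses
the total number of assessed windows as its denominator: in field
bookkeeping the participant-reported fall count need not equal the number
of classified windows, and this is the denominator that makes the
deployment study's own printed counts internally consistent. Full precision
is carried everywhere; rounding happens only in rendering.

## The synthetic generator

`gen_study()` emulates the data regime the detector is designed for:
per-participant continuous streams at nominal 50 Hz with Gaussian timestamp
jitter (SD 3 ms) and random dropout gaps (probability 0.001 per second,
250–1000 ms long — the only mechanism producing gaps over 200 ms), in which
falls, stumbles and phone drops are planted at uniformly random
non-overlapping times. Signal phenomenology:

* **ADL**: alternating rest and walking epochs; walking adds a 1.5–2.5 Hz
  sinusoidal gait component of 0.2–0.8 g over the 1 g baseline, with
  orientation drifting slowly; under these defaults well under 1 % of
  5-s windows exceed 2 g.
* **Fall**: 2 s of gait, 300–500 ms free-fall decaying toward 0.3 g, a
  ~100 ms half-sine impact peaking at 3–6 g, 500 ms damped oscillation,
  then ≥ 5 s rest at a new orientation, with a 3–8 rad/s gyroscope burst
  through the fall phase. The impact is the unique magnitude maximum of its
  ±2.5 s neighbourhood, so label-based impact localisation is exact.
* **Stumble**: a 1.8–3 g spike during gait with gait resuming — the
  near-fall confounder; **phone drop**: deep free-fall to ~0.05 g, a sharp
  spike that can exceed 2 g, then unnaturally complete stillness with
  almost no rotation; **sit–stand**: a smooth 0.5–1.5 g swing, below the
  screen.

The default study dimensions mirror the deployment regime (23 participants
× 90 days × 10 h/day, ~2 falls per participant); the 10 h/day worn time is
inferred from 648,000 five-second windows per 90-day participant. Tests and
the acceptance script run the same generator at smaller, explicitly stated
sizes — e.g. the end-to-end recovery test uses 8 participants × 30 minutes
with 5 falls, 8 stumbles and 5 drops each (train on 6, stream 2 held out),
and the calibration target uses 500 fall plus 500 confounder windows —
sizes chosen so the full suite exercises every pipeline stage in tens of
seconds while leaving every rate and threshold at its default.

What the generator does *not* emulate: biomechanically validated fall
dynamics, soft falls against furniture, phone-in-hand vs pocket placement
effects, vehicle vibration, or the long-tailed diversity of real
activities. Synthetic falls and confounders are therefore more separable
than real ones — the original deployment reached 73 % sensitivity at one
false alarm per 46 days, while the synthetic end-to-end test demands ≥ 90 %
sensitivity. Passing tests show the pipeline is implemented correctly and
that its division of labour (screen passes ≫ alerts) behaves as designed,
not that real-world performance would match.

## Numerical and design choices

* Percentiles: type-7 linear interpolation everywhere (features and
  calibration), R's default and the pinned convention.
* Window boundaries half-open; screen and alert thresholds strict;
  impact-search interval closed at ±2.5 s; retention interval closed at
  ±15 min; ties in impact search break to the earliest sample.
* The fall-window augmentation draws 10 start offsets uniformly from the
  4999 positions keeping the impact inside the window; invalid draws are
  kept but flagged, not resampled, so augmentation never biases toward
  clean signal.
* Solver: tolerance 1e−8 on the per-cycle objective decrease, 10,000-cycle
  cap, fixed cyclic order.
* Seeds: every stochastic entry point takes an explicit seed; R's
  Mersenne–Twister makes results platform-independent.

## Limitations

The λ convention of the original MATLAB fit may differ from the one here,
so 0.908 and λ = 0.015 are treated as given deployment constants rather
than re-derivable quantities; the deployed system's training corpus
(7874 fall / 578 non-fall windows from 17 lab participants) is not public,
so laboratory-level results (CV AUROC ≈ 0.995, the 83.9 % screen rejection
rate) are out of reach of this package's synthetic data and are not claimed.
Whether the deployed phone used overlapping windows is unknown; tumbling
windows are adopted as documented above.
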