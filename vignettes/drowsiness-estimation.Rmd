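---
title: "Fuzzy drowsiness estimation from facial-state streams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy drowsiness estimation from facial-state streams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drowsefis)
```

## The problem and the processing chain

Behavioural drowsiness monitoring watches a driver's face and turns what the
eyes and mouth do over time into a fatigue estimate. Single-threshold rules on
one indicator (for example, "alarm when PERCLOS exceeds 0.2") are brittle:
blinking frequency varies across people and moments, eye-state classification
misfires, and mouth openings happen for many reasons other than yawning. This
package implements a chain that addresses those failure modes by combining
three complementary indicators through an interpretable fuzzy rule system:

1. **Facial-state streams** (`state_stream`): one record per frame with eyelid
   gaps (left/right), mouth aspect ratio (`mar`), and/or binary eye/mouth
   states.
2. **Personalized calibration** (`calibrate`): open-eye and open-mouth
   references estimated from the driver's own first minute.
3. **Binarization** (`binarize_stream`): eyes closed when the gap falls below
   20% of the personal open reference; mouth open when `mar > 0.7`.
4. **Sliding-window indicators** (`sliding_indicators`): PERCLOS, ECD and AOT
   each second over a one-minute window.
5. **Mamdani fuzzy inference** (`infer`, `infer_series`): a 27-rule system
   maps the indicator triple to Low/Normal, Medium/Drowsy or High/Severe.
6. **Segment-level evaluation** (`segment_predictions`, `confusion`) against
   ground-truth labels.

A seeded simulator (`simulate_stream`) generates labelled blink/yawn streams
so the whole chain can be exercised and scored without a camera.

## Indicators

Let `frame[j]` be 1 when the eyes are closed in frame `j` and let a window
hold `n` frames. The three indicators emitted at each instant are

- **PERCLOS** — the fraction of closed frames,
  `PERCLOS = sum(frame[j]) / n`, in `[0, 1]`;
- **ECD** (eye closing duration) — the mean duration in seconds of the
  maximal eyes-closed runs in the window (`0` when there are none);
- **AOT** (average mouth opening time) — the mean duration of *yawns* in the
  window, where a yawn is a mouth-open run longer than 3 s and its duration is
  counted only past those first 3 s (`0` when no run qualifies).

PERCLOS and ECD are deliberately redundant: PERCLOS rises with both frequent
blinking and long closures, while ECD isolates closure *length*, making the
pair robust to blink-rate variation and to isolated misclassified frames. AOT
adds an independent mouth channel.

Conventions the implementation commits to, where a windowed definition needs
one:

- Windows are half-open on frame timestamps, `[t - W, t)`, with the first
  emission at `t = W` (no partial-window output). A frame is stamped at the
  start of the period it samples, so consecutive windows partition time
  exactly, and a full 60 s window at 30 fps always holds exactly 1800 frames.
- Runs straddling a window edge are clipped to their in-window portion; this
  keeps every window self-contained and makes `ECD <= W` provable.
- Durations default to run length times the nominal frame period, matching
  frame-count arithmetic at fixed fps; `duration_mode = "timestamps"` instead
  sums observed inter-frame intervals, for streams with dropped frames.
- ECD uses *all* closed intervals (no blink-duration floor); the rule base
  compensates, since short-blink regimes leave ECD in its Low term anyway.
- Frames carrying no measurement (no face detected) count as eyes-open /
  mouth-closed, biasing against false alarms rather than toward them.

## Personalized calibration

Eye apertures and mouth shapes differ enough between people that fixed gap
thresholds do not transfer. During the first `duration_s = 60` seconds the
stream's gap and `mar` values are collected (1800 per signal at 30 fps), each
signal is sorted descending, and the mean of the top `ceiling(0.05 * N)`
values — the frames with clearly open eyes/mouth — becomes that signal's open
reference. The estimator is an order statistic plus a mean, hence invariant
under permutation of the calibration frames, and scales linearly with the
signal (so a camera-distance change rescales references without changing any
subsequent classification).

Per-frame classification then applies:

- eye closed: `gap < 0.2 * reference`, per eye, with `eyes_closed` requiring
  **both** eyes by default. The AND combination suppresses single-eye landmark
  glitches and winks; `eye_combine = "any"` is available.
- mouth open: `mar > 0.7`, strict. The 0.7 constant is the one committed
  threshold; `mar_mode = "calibrated"` optionally replaces it with a ratio of
  the calibrated open-mouth reference for drivers whose resting `mar` sits
  unusually high or low.

The 20% rule is applied to the eyelid *gap* (the mean of the two vertical
lid landmark-pair distances). An area-based variant (polygon over all six eye
landmarks) would need different references; the ratio form is indifferent to
that choice of measure as long as calibration and classification use the same
one.

## The fuzzy inference system

Each indicator is a fuzzy variable with trapezoidal `Low`, `Medium`, `High`
terms. Published drowsiness thresholds disagree substantially (PERCLOS
thresholds from 0.15 to 0.4 appear across the behavioural-monitoring
literature, under varying window sizes and frame rates), which is precisely
why soft boundaries are used instead of one cut-off. The shipped defaults
place the term crossovers at:

| variable | universe | Low/Medium | Medium/High |
|---|---|---|---|
| PERCLOS | [0, 1] | 0.15 | 0.30 |
| ECD (s) | [0, 60] | 1 | 4 |
| AOT (s) | [0, 60] | 2 | 6 |

These bracket the literature range for PERCLOS and put the ECD Medium core
(1.5–3 s) above ordinary blinks but below incapacitating closures. They are
tunable defaults, not clinical ground truth: `read_fis_config()` /
`write_fis_config()` round-trip the whole configuration through a YAML file
so a deployment can move every breakpoint, and the same file format ships in
`inst/extdata/fis_default.yaml`.

Inference is Mamdani with minimum for the AND connective and implication,
maximum for aggregation, singleton output sets (0, 0.5, 1 on a normalized
drowsiness scale — only their order matters), and minimum-of-maximum
defuzzification: among output terms attaining the maximal aggregated degree,
the smallest singleton wins. The tie therefore breaks toward the *less*
drowsy label; this is the defined behaviour of min-of-max with singletons,
and the rule base's monotone completion makes genuine ties rare.

The 27-rule table encodes complementarity. Its anchored cells are: all
indicators Low maps to Low; both eye indicators Medium maps to Medium; a
single eye indicator High (others Low) maps to Medium; AOT High plus any
other indicator Medium maps to Medium; and AOT High *alone* maps to Low — a
driver talking or singing opens the mouth for long stretches, and a mouth
channel with no corroborating eye evidence must not raise the level. All
remaining cells take the smallest output consistent with monotonicity, with
High reserved for both eye indicators High, or one High plus the other Medium
with AOT High. Totality and monotonicity are validated whenever a rule base
is constructed or loaded; the monotone table gives the system a provable
property checked in the test suite: raising any one input never lowers the
output level (verified over a 20x20x20 grid).

Out-of-universe inputs are clamped to the universe bounds rather than
rejected — an indicator can only exceed its universe through configuration
edits, and clamping keeps the inference total. Inference over a series is
stateless per sample; an optional alarm debounce (`debounce_s`) is applied
only to event extraction, never to the level estimates.

## The simulator

`simulate_stream()` renders a segment plan (ordered `label`/`duration`
pairs) to per-frame binary states. Eye closures come from two independent
alternating on/off renewal processes — fast *blinks* and long *sustained
closures* — with exponential closure lengths; with rate `r` events/min and
mean duration `m` s the cycle is `60/r` s, so each process occupies an
expected fraction `r*m/60` of time, and the OR of the two gives the exact
expected PERCLOS `1 - (1 - f_blink)(1 - f_sustained)` returned by
`expected_perclos()`. Processes start in their equilibrium state, so the
expectation holds from the first frame, and a single seeded generator drives
all draws in a fixed order for reproducibility. Yawns are an independent
renewal process with shape-4 gamma durations: yawns are stereotyped events,
and exponential (memoryless) durations would make most simulated "yawns"
shorter than the 3 s qualification floor.

The default regime presets were fixed at design time so that each regime's
*expected* indicator triple lands inside the intended fuzzy terms of the
default configuration:

| regime | blinks | sustained closures | yawns | E[PERCLOS] | ~E[ECD] |
|---|---|---|---|---|---|
| Normal | 15/min x 0.2 s | — | — | 0.05 | 0.2 s |
| Drowsy | 6/min x 0.3 s | 4/min x 3.5 s | 0.5/min x 6 s | 0.26 | 1.6 s |
| Severe | 2/min x 0.3 s | 3/min x 18 s | 2/min x 12 s | 0.90 | 10 s |

Drowsy slows the blink rate while adding multi-second closures — the
physiologically typical pattern — which keeps ECD's denominator from being
swamped by blinks. Note the arithmetic constraint here: ECD averages *all*
closed intervals, so a regime with many fast blinks plus a few long closures
has a *low* mean closure duration; regimes meant to read as drowsy must shift
the interval mix, not merely add events.

The default 200-segment evaluation plan (`default_plan()`) lays the segments
out as contiguous blocks — 100 Normal, then 60 Drowsy, then 40 Severe
one-minute segments — emulating a session in which fatigue accumulates.
Because the estimator looks back over a full minute, its per-second output
necessarily lags a regime change by up to the window length; a blocked plan
confines that transient to the two block boundaries, which is also how
scripted validation sessions are realistically staged.

What the simulator does *not* emulate: landmark jitter and correlated
measurement noise, illumination changes, partial occlusion, head pose, and
any physiological coupling between eye and mouth events (the processes are
independent). Passing tests on simulated streams therefore demonstrates the
correctness of the *processing chain* — calibration arithmetic, window
bookkeeping, rule semantics, evaluation protocol — not field accuracy on real
drivers.

## Evaluation protocol

Ground truth is a per-second label track; `truth_segments()` splits its runs
into approximately one-minute segments, and `segment_predictions()` assigns
each segment the majority vote of the per-second levels inside its span,
with ties going to the more severe label (a late alarm is worse than an
early one). `confusion()` reports the 3x3 count matrix with per-class and
total accuracy. On the default seeded 200-segment session the chain
recognizes all 40 Severe segments and reaches 91–95% total accuracy
depending on the seed; the residual errors are Drowsy segments whose minute
happens to contain zero or one sustained closure and which therefore
genuinely present as Normal — the same direction of error one expects at a
regime boundary.

## Numerical and degenerate-input choices

- Strict inequalities where a threshold is stated strictly: `mar > 0.7`,
  yawn runs `> 3 s`; gap comparison `gap < 0.2 * ref`.
- `ECD = 0` and `AOT = 0` when no interval qualifies (the defining ratios are
  0/0 there, and "no events" must read as least drowsy).
- Top-k count in calibration is `ceiling(top_fraction * N)`; boundary ties are
  resolved by sort order, making the estimate deterministic.
- Window emission uses an epsilon of 1e-9 s on timestamp comparisons so that
  frames stamped exactly on the grid fall on the intended side.
- Empty streams, streams shorter than the calibration or analysis window,
  non-monotone timestamps, negative measurements, incomplete or non-monotone
  rule bases, and zero mouth width in the landmark geometry all raise typed
  errors naming the offending row/rule/asset.

## Problem sizes used in the checks

The shipped tests and the acceptance script size their simulations to run on
one CPU in a few minutes while keeping the statistics meaningful: 1000 random
windows for the indicator/oracle cross-check, a 30-minute stationary stream
for the PERCLOS expectation check (3-standard-error band from the two-state
Markov autocovariance), and one 200-minute, 360,000-frame session for the
end-to-end confusion matrix.

## Known limitations

- The `haar`/`hog` detection backends are interface stubs: they name the
  pretrained model assets they would consume but have no runtime binding
  here; the executable path into the landmark geometry is the `schematic`
  backend on synthetic frames, or any external frontend that writes the
  stream CSV/JSONL.
- Video containers are not decoded; frame sequences (matrices or PNG paths)
  are.
- No online re-calibration during a drive, no head-pose channel, and no
  hysteresis in the level estimate (only the alarm extractor debounces).
- The analytic PERCLOS standard error slightly understates the variance of
  the *windowed* mean on finite streams (overlapping windows edge-weight the
  data), so the 3-SE check is marginally anti-conservative.
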