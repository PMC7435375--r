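# drowsefis

Fuzzy drowsiness estimation from facial-state streams.

`drowsefis` implements the processing chain of a behavioural driver-drowsiness
monitor for anyone who has — or can produce — per-frame facial measurements:
eyelid opening distances and the mouth aspect ratio (`mar`), or pre-binarized
eye/mouth states. It is aimed at researchers and engineers prototyping
fatigue-monitoring pipelines who need the *estimation* layers (calibration,
indicators, inference, scoring) decoupled from any particular camera or
landmark stack.

## The method

Per-frame states are summarised each second over a one-minute sliding window
into three complementary indicators:

- **PERCLOS** `= (1/n) Σ frame[j]` — the fraction of the window's `n` frames
  with eyes closed (`frame[j] ∈ {0,1}`);
- **ECD** `= (1/p) Σ Duration[j]` — the mean duration of the `p` eyes-closed
  intervals in the window;
- **AOT** `= (1/N_y) Σ t_j` — the mean yawn duration, a yawn being a
  mouth-open run longer than 3 s, its duration `t_j` counted past those 3 s.

Eye/mouth states come from a one-minute personalized calibration: each
signal's *open reference* is the mean of its top 5% of values (1800 values
per signal at 30 fps); an eye counts as closed below 20% of its reference,
the mouth as open when `mar > 0.7`.

The indicator triple feeds a Mamdani fuzzy inference system — trapezoidal
`Low/Medium/High` terms per indicator, a complete monotone 27-rule table,
`min` for AND and implication, `max` for aggregation, singleton consequents,
minimum-of-maximum defuzzification — yielding one of three states each
second: **Low/Normal**, **Medium/Drowsy**, **High/Severe**. The rule design
makes the indicators corroborate each other; in particular a high AOT alone
(talking, singing) never raises the level.

A seeded simulator generates labelled blink/yawn streams (renewal-process
event model with known expected PERCLOS), and the evaluation module scores
per-second output against ground truth in one-minute segments by majority
vote, reporting a 3×3 confusion matrix.

See `vignettes/drowsiness-estimation.Rmd` for the full methods account and
design rationale.

## Worked example

Simulate a 10-minute session that degrades from alert to severe, run the
default pipeline, and score it:

```r
library(drowsefis)

sim <- simulate_stream(simulation_params(
  plan = data.frame(label = c("Normal", "Drowsy", "Severe"),
                    duration_s = c(300, 180, 120)),
  seed = 7))

res <- run_pipeline(sim)
res
#> <pipeline_result>
#>   binarized input: frontend and calibration skipped
#>   18000 frames in (0 without measurements), 541 per-second levels out
#>   levels: Low 313, Medium 122, High 106
#>   alarms: 2 event(s)

as.data.frame(res$indicators[res$indicators$t %in% c(300, 420, 540), ])
#>       t    perclos        ecd      aot n_frames p_intervals n_yawns
#> 241 300 0.05888889  0.1962963 0.000000     1800          18       0
#> 361 420 0.29055556  1.5848485 0.000000     1800          11       0
#> 481 540 0.88555556 13.2833333 6.677778     1800           4       3
```

At `t = 300` s (alert) about 6% of the last minute's frames are closed and
the mean closure lasts 0.2 s — ordinary blinking, label `Low`. At `t = 420`
(drowsy) PERCLOS has risen to 0.29 and closures average 1.6 s → `Medium`. At
`t = 540` (severe) the eyes are shut 89% of the time, closures average 13 s
and three yawns average 6.7 s past the 3 s floor → `High`. Scoring against
the ground truth in one-minute segments:

```r
confusion(segment_predictions(res$levels, truth_segments(sim$truth)))
#> <confusion_summary> 10 segments, total accuracy 90.0%
#>         predicted
#> truth    Normal Drowsy Severe
#>   Normal      5      0      0
#>   Drowsy      1      2      0
#>   Severe      0      0      2
#> per-class accuracy: Normal 100.0%, Drowsy 66.7%, Severe 100.0%

res$alarms
#>   t_start t_end  level
#> 1     364   380 Medium
#> 2     390   600   High
```

The one missed Drowsy segment is the first after the regime change: the
one-minute window still mostly contains alert frames — the expected
transition lag of a windowed estimator.

Continuous streams work the same way once calibrated:

```r
cont <- render_continuous(sim$stream)        # gap/mar signals, no binary states
res2 <- run_pipeline(cont, calibration_s = 60)
```

A thin command-line wrapper with `simulate`, `calibrate`, `binarize`,
`indicators`, `infer`, `run` and `evaluate` subcommands is installed at
`inst/cli/drowsefis.R`.

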