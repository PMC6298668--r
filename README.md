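# screendetect

Automatic recognition of screen-plays — the minimal cooperative play in
basketball — from multi-agent positional tracking data.

A *screen* is set when an attacker (the **screener**) plants himself on the
path of the defender guarding a teammate (the **user-defender**), freeing
that teammate (the **user**) to cut. Screens both on the ball
(pick-and-roll, hand-off) and away from it (down, flare, pin, back, flex,
cross) structure most half-court offense, but hand-labelling them from
video is slow and plays with the same label vary wildly in space and time.
`screendetect` is for sports scientists and analysts with per-frame player
and ball coordinates (e.g. 25 fps optical feeds) who want those events
found and typed automatically.

## Method

The pipeline has three stages:

1. **Segmentation.** For every (screener, user, user-defender) candidate
   triple, a frame is a *signal* when `d(screener, defender) < 1.2 m` and
   the defender is the closest player to the user. Runs shorter than 3
   frames are dropped; same-identity runs with gaps ≤ 13 frames are joined;
   each merged run becomes an *action*, a 27-frame window centred on the
   frame of minimum screener–defender distance, flagged on-/off-ball by who
   possesses the ball there.
2. **Features.** Each action maps to a 148-dimensional vector with named
   blocks: the conventional 30-dim pairwise-distance descriptor, a 45-dim
   expanded distance block (9 distances × {min, mean and rate of change
   over the former/latter 7 frames of the 13-frame window}), a 13-dim
   moving-distance block (path lengths), and a 60-dim geometric block
   (screen-area one-hot, ball distances, three-player angles).
3. **Classification.** A soft-margin Gaussian-kernel SVM detects screens
   (cost and kernel width tuned by stratified 10-fold cross-validation
   maximizing AUC); one-against-all or one-against-one reductions of the
   same machine type off-ball screens into down / flare / back / cross.
   Evaluation uses ROC/AUC, the recall–precision trade-off and the F score
   `F = 2RP/(R+P)`, reported as medians over 5 repeated random test splits.

Because real tracking feeds of this kind are proprietary, the package
includes a synthetic 5-on-5 half-court simulator (`simulate_session()`)
that plants screen motifs of all eight types, plus non-screen distractor
plays, with per-frame positional jitter — the whole pipeline runs and is
tested end to end on data it generates itself.

## Worked example

```r
library(screendetect)

cfg  <- scenario_config(n_plays = 120, seed = 11)   # 25 fps, 0.05 m jitter
sess <- simulate_session(cfg)
sess$seq
#> <tracking_sequence> 13428 frames @ 25 fps, 10 players (5 offense / 5 defense),
#>   ball present in 13428 frames

acts <- match_actions(segment_actions(sess$seq), sess$truth)
recovery_stats(acts, sess$truth)
#>            n_truth          n_actions          recovered      recovery_rate
#>            76.0000           168.0000            76.0000             1.0000
#> screen_action_rate
#>             0.4524

x <- build_feature_matrix(acts, sess$seq)
dim(x)
#> [1] 168 148

reports <- run_protocol(x, acts$label, onball = acts$onball,
                        plan = split_plan(seed = 5))
aggregate_reports(reports)
#>       auc   f_score    recall precision
#>         1         1         1         1
```

All 76 planted screens are recovered (recovery rate 1.0), 45% of the
candidate actions are true screens (the rest are incidental contacts and
planted distractors), and on held-out test thirds the detector separates
them essentially perfectly — the synthetic scenes are much cleaner than a
real game, where reported performance for this class of method is
substantially lower (AUC around 0.85–0.94).

A YAML-configured command-line front end over the same stages
(`simulate`, `segment`, `featurize`, `train-eval`) ships in
`inst/cli/screendetect.R`.

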