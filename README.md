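# splitscope

Analysis of trajectory-dependent ("splitter") and place coding in
hippocampal calcium-imaging data recorded during continuous spatial
alternation on a figure-8 maze.

During alternation, a mouse runs repeatedly through the same central
stem before turning left or right. Some CA1 neurons fire differently on
the stem depending on the upcoming turn — at the same physical location —
and these splitter cells are a window on how the hippocampus encodes
trajectory and task context on top of space. `splitscope` implements the
full statistical pipeline for one-photon (miniscope) calcium event data:

* **Behavior** — aligning position tracking to imaging frames, parsing
  figure-8 traversals into trials, scoring the alternation rule
  (correct ⇔ turn ≠ previous turn), and finding the task-acquisition
  session (third consecutive session ≥ 70 % correct).
* **Splitter classification** — occupancy-normalised left/right tuning
  curves in ~1 cm stem bins; per-bin significance from 1000 trial-label
  permutations (a bin is trajectory-dependent when the real |left −
  right| rate difference exceeds more than 95 % of shuffled differences);
  a splitter has ≥ 3 significant bins, stem events on ≥ 5 trials, and a
  confirmatory ANOVA showing the trial-type effect survives speed and
  lateral-position covariates. Metrics: discriminability
  Σ|L−R| / Σ(L+R), reliability (mean per-bin shuffle exceedance),
  1 − Spearman ρ of the two curves, and splitting extent (fraction of
  significant bins).
* **Place-cell classification** — spatial information (Skaggs-style
  mutual information between the binary event indicator and 4 cm
  position bins, in bits),

      I_pos(x_i) = Σ_{k∈{0,1}} P(k|x_i) log2( P(k|x_i) / P_k ),
      SI = Σ_i P(x_i) I_pos(x_i),

  tested against 1000 circular event-timestamp shuffles (place cell:
  ≥ 5 transients and SI above more than 95 % of shuffles); smoothed
  1 cm rate maps (Gaussian σ = 2.5 cm) and half-peak connected place
  fields, with field length = area / 5 cm corridor width.
* **Decoding** — linear-discriminant prediction of the upcoming turn
  from population stem activity, 1000 random 50/50 train/test splits of
  correct trials, accuracy in ~3.3 cm stem bins, with a label-shuffled
  chance pipeline.
* **Longitudinal analysis** — cross-session neuron registration by
  mutual-nearest ROI centroids with an orientation-change QC shuffle
  test; functional labels (splitter / stem place cell / arm place cell /
  stem non-PC / arm non-PC); per-class stay-active probabilities versus
  day lag (with event-rate matching); cross-session Spearman map
  correlations; one-sided signed-rank tests per lag, Holm–Bonferroni
  corrected over ≤ 15 lags.
* **Ontogeny** — first session each tracked neuron passes the splitter
  or place criteria, metrics aligned on ±10 days around onset, one-sided
  Kolmogorov–Smirnov onset comparisons, and a χ² goodness-of-fit test of
  the onset-day-difference histogram against a sign-symmetric null.
* **Synthetic data** — a seeded generator emulating the whole
  experiment (alternating trials with errors, jittered stem runs,
  Bernoulli transient onsets shaped by Gaussian place fields and
  trajectory modulation, multi-session turnover with class-dependent
  persistence, ROI jitter), with known ground truth so every stage is
  testable without any external recording.

It is aimed at systems-neuroscience analysts who have event rasters,
ROI tables and tracking data (all plain delimited text) and want the
classification statistics, population decoding and multi-day stability
analyses behind splitter-cell studies in a tested, reusable form.

## Worked example

Generate a synthetic session, parse behavior, and classify every neuron:

```r
library(splitscope)

cfg    <- synth_config(n_neurons = 60, n_trials = 40, seed = 42,
                       error_rate = 0.1)
ex     <- generate_experiment(cfg)
b      <- ex$sessions[[1]]
geom   <- synth_geometry(cfg)
trials <- parse_trials(b$behavior, geom)

session_performance(trials)
#> [1] 0.875

cls <- classify_session(b$raster, b$behavior, geom, trials = trials,
                        seed = 1)
summary(cls)
#> session_classification: 60 neurons (60 active)
#>
#> splitter  stem_pc   arm_pc stem_npc  arm_npc
#>       11        9       20       12        8
```

The session performance (87.5 % correct free trials) reflects the
generator's 10 % alternation-error rate. The label table is the
pipeline's verdict per neuron; against the generator's ground truth,
all 9 true splitters are recovered (two other stem-active neurons are
flagged alongside them) and place cells are recovered nearly perfectly.

A single splitter's stem tuning and metrics:

```r
tun <- stem_tuning_curves(b$raster, b$behavior, trials, neuron = 1,
                          geometry = geom)
tun
#> stem_tuning (neuron 1): 51 bins (51 valid), 18L/17R correct trials,
#>   peak rate L 13.75 / R 5.00 events/s; 23 stem-event trials
discriminability(tun)
#> [1] 0.571
```

The left-trial rate at the field peak is ~2.75× the right-trial rate,
and 57 % of the summed tuning-curve mass is left/right difference.

Population decoding of the upcoming turn, with its shuffled-label
chance level:

```r
lda_turn_decoder(b$raster, b$behavior, trials, geom, n_repeats = 200,
                 seed = 2)
#> decode_result: mean accuracy 0.716 over 15 stem bins (200 repeats);
#>   trial-vote accuracy 0.881
decoder_chance(b$raster, b$behavior, trials, geom, n_repeats = 200,
               seed = 2)
#> decode_result (label-shuffled chance): mean accuracy 0.503 over 15
#>   stem bins (200 repeats); trial-vote accuracy 0.507
```

Frame-level accuracy (0.72) sits well above the shuffled-label chance
(0.50); majority voting over a trial's stem frames reaches 0.88.

See `vignettes/splitter-analysis.Rmd` for the statistical model, the
generator's assumptions, and every tunable threshold.

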