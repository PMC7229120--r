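---
title: "Trajectory-dependent and place coding analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-dependent and place coding analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitscope)
```

`splitscope` analyses calcium-imaging recordings from mice performing
continuous spatial alternation on a figure-8 maze. This vignette is the
package's own account of the statistical machinery: the models and
their assumptions, every tunable parameter with its default and the
reason for it, what the synthetic-data generator does and does not
emulate, and the design choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The data model

The unit of input is a session: a binary `event_raster` (neurons ×
imaging frames, 20 Hz by default), a behavior trace (time, x, y in
maze-aligned cm), and an ROI table (centroid in µm, major-axis
orientation in degrees mod 180). A calcium *event* is the inferred
spiking epoch of one transient; the raster marks **every frame of the
transient's rising phase**, so one transient spans several consecutive
frames and transient counts are recovered from rising edges
(`count_events()`). All activity thresholds ("at least four events to be
active", "at least five transients for the place-cell test", "at least
five events while running for the stay-active base population") count
transients, not frames.

Frames are 0-based in the text file dialect and 1-based inside R; bin
intervals are half-open `[lo, hi)`; orientations live on the half-circle
(differences are `min(|Δ|, 180 − |Δ|)`).

## Trial parsing and behavior

The maze is described by `maze_geometry()`: a stem of length 64 cm at
x = 0, base below, choice above, entries and return arms at
x = ±(24..36) cm. A trial is one full base → stem → choice → entry →
return-arm → approach traversal; incomplete traversals (for example an
interrupted stem run) are dropped and counted, since their handling
during trial counting is not otherwise determined. The alternation rule
scores trial *t* correct iff its turn differs from trial *t − 1*'s; the
first free trial is correct by convention (reward is delivered
regardless of the first turn). Forced trials keep their slot in the
alternation sequence — the next trial's correctness is judged against
them — but are excluded from every downstream selection. Task
acquisition is the third consecutive session at or above 70 % correct.

Trajectory analyses run on the **central 80 % of the stem**
(`stem_restrict = c(0.1, 0.9)`). Trajectories diverge near the base and
the choice point, so including stem ends would let purely spatial
tuning masquerade as trajectory dependence. The window is a geometry
parameter rather than auto-detected: the divergence point is a property
of each apparatus, and a fixed default keeps analyses comparable.

## Splitter classification

For each neuron, per-trial event counts and occupancy times are
accumulated in ~1 cm stem bins over **correct free trials only**
(trajectory coding is defined relative to the executed, rewarded
trajectory). The tuning curve per trial type is pooled counts divided
by pooled occupancy seconds; with equal trial weighting this equals the
mean per-trial count over mean per-trial occupancy, so the two readings
of "mean event rate divided by time in bin" coincide. Zero-occupancy
bins are masked and excluded from bin counts, extent denominators and
metric sums.

Significance is by trial-label permutation: the statistic per bin is
|left − right| rate difference; each of 1000 shuffles permutes the turn
labels over the correct trials (preserving left/right counts — the
exchangeable quantity under the null is which trials carry which label)
and re-evaluates all bins, so the spatial correlation of the null is
preserved. Each neuron draws its own permutation set, reused across its
bins. `rel_per_bin` is the fraction of shuffles **strictly** exceeded
by the real difference; a bin is significant when `rel_per_bin >
1 − α` (α = 0.05). Two numerical points matter here:

* *Strictness.* With 1000 shuffles, requiring the real statistic to
  rank above more than 95 % of shuffles gives a per-bin level of
  50/1001 ≤ 0.05; the inclusive reading (≥ 950) would give 51/1001 >
  0.05. The strict rule is the one consistent with a 5 % level and with
  "reliability above 0.95".
* *Ties.* Sparse bins tie often, and the real and shuffled statistics
  travel different BLAS code paths; exceedance therefore uses a relative
  tolerance (`real − stat > 1e-9·(1 + real)`) so floating-point noise
  cannot break a tie toward significance. Ties count against
  significance, making the test conservative on sparse data (measured
  pooled null level ≈ 0.033 in the acceptance suite).

A splitter candidate needs ≥ 3 significant bins and stem events on ≥ 5
trials. Candidates then pass a confirmatory ANOVA: per correct trial ×
5 lengthwise stem bins, the mean event probability is modelled on trial
type, stem bin and their interaction (categorical) plus mean running
speed and mean lateral position (continuous); the candidate is
confirmed iff the trial-type main effect or the type × bin interaction
is significant at 0.05 in type-II tests (`car::Anova`). This guards
against "splitting" that merely reflects stereotyped kinematics —
e.g. hugging one stem wall after a particular turn. Constant covariates
(possible in degenerate synthetic data) are dropped with a warning
rather than producing a rank-deficient fit.

Per-neuron metrics: discriminability Σ|L−R| / Σ(L+R) over valid bins
(undefined and excluded from session means when both curves are zero);
reliability mean/peak of `rel_per_bin`; 1 − Spearman ρ of the
unsmoothed curves (undefined for zero-variance curves; deliberately
conservative for rate-scaling splitters, sensitive to field-shifting
ones); splitting extent = significant / valid bins. The per-bin
difference uses the absolute value: the source analysis specifies only
a "difference" with a one-tailed "exceeded" criterion, and the absolute
value makes each bin's test two-sided in sign while keeping that
criterion.

## Place-cell classification

Spatial information is the mutual information (base-2 logarithm, bits —
conventional for this statistic; configurable only by transforming the
output) between the binary per-frame event indicator and position
binned at 4 cm, over frames faster than 1 cm/s:

$$ I_{pos}(x_i) = \sum_{k \in \{0,1\}} P(k\mid x_i)\,
   \log_2 \frac{P(k\mid x_i)}{P_k}, \qquad
   \mathrm{SI} = \sum_i P(x_i)\, I_{pos}(x_i), $$

with 0·log(0/·) ≡ 0. SI ≥ 0 always, and SI = 0 exactly when the event
probability is bin-independent.

The null shuffles event timestamps relative to position. The default is
a **circular shift** of the whole activity train by a uniform random
offset: it preserves the event count and the train's internal structure
(burst spacing, transient durations), and for a stationary train the
family {real, shifts} is exchangeable, so the test is level-α. A full
random permutation of event frames over included frames is available
(`method = "permute"`) for users who want the harsher null that
destroys within-burst structure; whether the original analyses
preserved it is not determinable, so both are exposed. Classification
requires ≥ 5 transients and real SI strictly above more than 95 % of
shuffled SIs (ties against, same strictness argument as above).

Smoothed rate maps use 1 cm bins and a Gaussian kernel (σ = 2.5 cm)
applied to the occupancy-normalised rate map, with the kernel
re-normalised over in-range bins at every position so edges are
smoothed without leaking rate mass off the grid; unvisited bins are
masked NA afterwards and all map correlations use only bins visited in
both maps. Place fields are the 4-connected component of bins above
half the peak smoothed rate that contains the peak; field length is
field area divided by the 5 cm effective corridor width.

## Turn decoding

Observations are individual stem frames of correct trials: features are
the population's binary activity at that frame, the response is the
trial's upcoming turn. Each of 1000 repeats splits the correct trials
50/50 (stratified by direction, so no training set lacks a class),
trains a linear discriminant and predicts the held-out trials' frames;
accuracy is aggregated in ~3.3 cm stem bins and averaged over bins.
Because stem frames vastly outnumber trials, a pooled full covariance
is singular; the default discriminant therefore uses a shared
*diagonal* covariance (per-feature pooled variance, floored at 1e-6),
with `MASS::lda` available as the full-covariance option when the data
support it. Whether the original accuracy was per time point or per
trial is not stated; the per-frame accuracy is the default output and a
per-trial majority vote is always reported alongside. Chance is the
identical pipeline with turn labels permuted before every split; it is
reported next to the real accuracy, never subtracted.

## Longitudinal analysis

Registration matches ROI centroids across a session pair by mutual
nearest neighbours with a maximum distance (default 5 µm — the original
threshold lives in a separate methods codebase, so this is a
configurable package default chosen well below typical inter-ROI
spacing). Mutual matching is one-to-one by construction. Pair-level QC
compares the mean absolute orientation change of matched ROIs against
1000 identity shuffles; the pair passes when the real mean is smaller
than the null at p < 0.05. The original check was visual; a test makes
it automatable, and pairs failing it (or with < 10 matches) should be
excluded via the analysis' session-pair lists.

Functional labels partition each session's active neurons: splitter
(full criteria) takes precedence; place cells with no stem calcium
activity are arm place cells; stem-active place cells failing the
splitter criteria are stem place cells; remaining neurons split into
stem/arm non-place cells by stem activity. "Active" uses ≥ 4 transients
for session-level inclusion and ≥ 5 transients while running for the
stay-active base population — two distinct thresholds, each applied
where it belongs.

Stay-active probability per class and session pair is
`n_still_active / n_base`; classes with fewer than 4 base cells are
excluded as rows (not errors). Event-rate matching removes each class's
lowest-rate cells until its mean reaches the splitter mean (classes
already at or above it are untouched, as is the reference class). Lag
curves are compared by one-sided paired signed-rank tests per day lag
(sign test available — the source material names both), tested only at
lags with ≥ 5 pairs, Holm–Bonferroni corrected over the tested lags
(≤ 15). Day lag is the calendar-day difference; same-day session pairs
are excluded from lag analyses.

## Ontogeny

A neuron's splitter (or place) onset is the first registered session
passing the class criteria. Metrics are re-indexed by day relative to
the onset day within ±10 days; when two sessions share a day, the
earlier defines that day's metric and the later is excluded. Onset-day
distributions are compared by a one-sided two-sample KS test (default
alternative: splitter onsets stochastically later). The per-neuron
onset-day difference (splitter − place) is tested against symmetry
around zero by a χ² goodness of fit whose null is **label-swap
resampling**: under "no systematic order", each nonzero difference d is
equally likely to have been −d, so E(count at ±d) = (n_d + n_{−d})/2
with one degree of freedom per magnitude pair. The null for this test
is this package's choice (the original is unspecified) and is flagged
as such here. Within-session recruitment is each neuron's first event
(trial index and clock time), compared across classes by one-sided KS.

## The synthetic-data generator

`synth_config()` defines the study conditions; its defaults *are* the
conditions under which the package's statistical guarantees are tested.

| parameter | default | meaning / rationale |
|---|---|---|
| `frame_rate_hz` | 20 | miniscope frame rate |
| `stem_length_cm` | 64 | stem length; analyses use the central 80 % |
| `n_trials` | 44 | ≈ 40 correct trials at the default error rate |
| `error_rate` | 0.15 | alternation-error probability → ~85 % performance |
| `run_speed_cms` | 20 (± 4 jitter) | ballistic stem runs; ~1 frame per 1 cm bin |
| `lateral_sd_cm` | 1.5 | smooth AR(1) lateral drift inside the corridor — the covariate the confirmatory ANOVA needs |
| `base_event_rate_hz` | 1.5 | peak in-field transient-onset rate of field cells |
| `transient_duration_s` | 0.5 | frames marked per transient (rising-phase span) |
| `field_width_cm` | 10 | Gaussian field s.d. |
| `modulation_ratio` | 4 | preferred : non-preferred stem rate ratio of splitters |
| `npc_rate_scale` | 0.3 | non-place-cell rate as a fraction of the base rate |
| `persist_prob` | 0.95/0.85/0.75/0.65/0.65 | per-class session-to-session survival |
| `roi_jitter_um` | 2 | centroid jitter across sessions (≪ inter-ROI spacing) |
| `onset_delay_max` | 0 | latest splitter-onset delay, for ontogeny experiments |

Events are Bernoulli transient *onsets* per frame with probability
rate/frame-rate, where rate = base × Gaussian(field) × trajectory
modulation (splitters only, on the stem corridor, from their onset
session); each onset marks the raster active for
`transient_duration_s`. Modelling the transient's multi-frame rising
phase, rather than a single-frame impulse, is deliberate: it is what
upstream event extraction emits, and it is what gives individual 1 cm
bins enough per-trial activity frames for the permutation test to have
the power the pipeline is validated against. With the defaults above,
the acceptance suite measures splitter sensitivity ≈ 0.95 and the
per-bin null level ≈ 0.033; sensitivity degrades gracefully toward the
weaker corners of the regime (lower rates, modulation ratio near 3).
Splitter trajectory modulation is rate scaling in a fixed field by
default, with `field_shift_mode = TRUE` producing the field-shifting
phenotype instead.

Turnover is a Markov chain: all neurons are active in session 1, and an
active neuron stays active with its class's `persist_prob` (dropout is
absorbing), so the probability of being seen again after a lag of k
sessions decays geometrically — the shape the lag-curve analyses
expect. RNG streams are keyed by (seed, session, neuron), so adding
neurons or sessions never reshuffles existing ones.

What the generator does **not** emulate — and hence what passing tests
do and do not show about real data: no photobleaching or fluorescence
drift, no tracking dropouts or reflections, no anatomically realistic
ROI shapes (registration is tested on centroid/orientation statistics
only), no over-dispersed or bursty event trains beyond the transient
window, no behavioral covariation between speed and turn direction
beyond what AR(1) noise produces, and no remapping: a synthetic
neuron's field is stable across sessions. Passing the suite shows the
statistics are correct and well-calibrated under these idealised
conditions, not that real recordings meet them.

## Trace quality control

The calcium-trace QC fits a single exponential to the decaying portion
of the last recorded transient (nonlinear least squares seeded by a
log-linear fit); half-decay = ln 2 / rate. An apparent half-life above
7 s is treated as contamination by a neighbouring neuron's fluorescence
and the fit moves to the previous transient, iterating backwards;
neurons with no fittable transient are excluded as unfittable, and
neurons with half-decay > 2 s are excluded as potentially unhealthy.
`simulate_calcium_trace()` builds the idealised fixtures these fits are
tested on.

## Problem sizes in the test and acceptance suites

The suites generate everything at run time: the permutation-level check
pools three 80-neuron sessions (12 240 bins), the SI-specificity check
two 100-neuron sessions, the sensitivity check one 250-neuron session,
persistence recovery a 500-neuron three-session experiment, and the
pipeline-level phenotype checks 10-session experiments of 80–120
neurons at 36 trials/session. These sizes give the binomial margins the
assertions state while keeping each check to a few minutes on one core.

## Known limitations

* The permutation and SI tests assume trials (respectively the event
  train) are exchangeable under the null; slow within-session
  nonstationarities (drift, fatigue) violate this and are not modelled.
* The confirmatory ANOVA uses linear covariate adjustment; strongly
  nonlinear kinematic confounds would call for the generalised
  additive alternative, not provided here.
* The diagonal-covariance discriminant ignores noise correlations;
  on real data with strong shared variability the full-covariance
  option (with adequate trial counts) is preferable.
* Registration uses centroids and orientations only; intensity- or
  shape-overlap registration is out of scope.
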