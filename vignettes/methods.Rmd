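---
title: "Methods: effect-size time courses, population decoding, and behavioral preference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: effect-size time courses, population decoding, and behavioral preference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical procedures the package implements,
the assumptions behind its synthetic data generator, the defaults of every
tunable parameter, and the numerical and design choices made where more
than one reasonable convention exists. It states no empirical result that
the test suite does not itself compute.

## The analysis problem

The data are trial-structured extracellular recordings from a delayed
change-detection task. Three colored squares appear at fixed display
locations (top, middle, bottom); after a memory delay they reappear, and
the subject reports whether one color changed. On *pre-cue* trials a
spatial cue marks the only location where a change can occur; on *no-cue*
trials any location may change, and the subject is free to distribute or
focus attention. The scientific questions the pipeline addresses are:
(1) how much information single units and the population carry about the
cued location and about color identity, over time; (2) whether attention
(cue at a location) increases color information at that location; (3)
whether the population state identifies the attended location, including
on trials where attention is endogenous (no cue); and (4) what the
behavior alone says about which location was attended.

## Firing-rate binning

Rates are computed in sliding windows (default 200 ms bins advanced in
20 ms steps) aligned to a task event, as spike count divided by bin width.
Conventions:

- **Half-open intervals** `[t, t + width)`, anchored at the window start.
  The convention is arbitrary for continuous spike times but guarantees a
  spike on a boundary of two non-overlapping bins is counted exactly once.
- **Bin centers** are the reported timestamps. A 200 ms bin therefore
  smears evidence ±100 ms around its center: an effect can *appear* up to
  half a bin before the event that causes it. Plots and interpretations
  must account for this.
- Whenever consecutive bins enter one statistical test, only disjoint bins
  are used (`select_nonoverlapping`; every 10th bin at the defaults).

Inclusion rules: only completed trials are analyzed; units must average at
least 0.5 spikes/s during the 2 s inter-trial interval; every tested
condition must hold at least 20 completed trials, and analyses use exactly
the **first 20** completed trials of each condition, in chronological
session order (the only order the protocol defines), so conditions
contribute identically many observations regardless of performance
imbalances.

## Percent explained variance

Information is quantified as the one-way ANOVA effect size, interpreted as
percent explained variance (PEV):

$$\omega^2 = \frac{SSQ_e - df_e \, MS_{err}}{SSQ_{total} + MS_{err}},
\qquad
\omega_p^2 = \frac{df_e (F - 1)}{df_e (F - 1) + n}.$$

On one-way designs the two forms are algebraically identical (the test
suite verifies agreement to 1e-8 on 1000 random designs); the second form
is used when only `F`, `df` and `n` are available. Properties worth
keeping in mind:

- ω² is slightly negative in expectation under the null; **negative values
  are never clamped** before statistics. Clamping exists only in
  `display_log_transform`, which maps magnitudes below 1e-6 to 1e-6 for
  log-scale plotting and keeps the sign separately.
- A unit with zero within-group variance has ω² = 1; a constant unit has
  an undefined value, reported as `NA`.

Significance uses an empirical permutation null: trial labels are shuffled
(default 1000 times), the full unit × bin PEV recomputed per shuffle, and
a unit-bin flagged when the observed PEV exceeds 95% of shuffled values
(upper-tail criterion). The [2.5, 97.5] percentile band is also exposed —
it is what plots display; both conventions are deliberate and distinct.
Under a simulated null the 95% criterion flags 5% of unit-bins (verified
±1.5 percentage points over 2080 unit-bins by the validation suite).

Unit classification tests each unit for the location factor (3 levels) and
the color factor (2 levels: which of the session's two colors appeared at
the analyzed location) on non-overlapping bins. The Bonferroni family is
**all bins × both factors within a unit** — the correction scope is not
uniquely determined by the inclusion rule "corrected for multiple
comparisons", and this is the most conservative within-unit reading.

## Attentional shift (ΔPEV)

For color information at a location, three condition sets are compared on
the same non-overlapping grid, each subsampled to the first 20 trials per
color: cue at the location (*pre-cue*), no cue (*no-cue*), and cue
elsewhere (*cue-other*). Per unit and bin:

- gain = PEV(pre-cue) − PEV(no-cue),
- loss = PEV(pre-cue) − PEV(cue-other),
- overall = (gain + loss) / 2,

with the population summary reported as the absolute value of the
across-unit mean ("absolute average"); the formula behind the published
phrase is not stated anywhere, and (gain + loss)/2 is chosen so the
overall panel is exactly the average of the gain and loss panels.
Significance per bin is a one-sample Wilcoxon sign-rank across units
against zero, Bonferroni-corrected across tested bins. The Bayesian
signed-rank variant reported alongside it in the literature (computed in
external software) is out of scope; only the frequentist test is
implemented.

`color_shift_analysis(location = "all")` averages the per-location shift
matrices per unit. This is the form used for population-level inference:
a unit tuned to color at one location contributes its shift at that
location, diluted by the two untuned locations, rather than being dropped
entirely when a single location is analyzed. SEM and the sign-rank are
across units (the population pools all recorded units).

## Population decoding

Because units are recorded across sessions, decoding uses
pseudo-simultaneous trials: for each of 120 pseudo-trials (40 per cue
location), each unit contributes one of its own real trials of the
matching condition, drawn independently per unit (with replacement, since
the first-20 subsampling leaves 20 real trials per condition). Rates are
z-scored per bin using the mean and SD pooled over all units and
pseudo-trials in that bin ("populational" normalization; a per-unit
variant exists behind a flag because the phrase admits both readings).

The classifier is a linear multi-class max-margin model (SVM, one-vs-one
reduction — the multi-class scheme is not specified by the method
description; one-vs-one is the default of the standard implementations,
and is recorded in output metadata). Per resample a stratified 90% train /
10% test split is drawn (108/12 trials at the defaults), the model is fit
on one bin and tested on every bin, and the per-cell performance is the
fraction of the 12 held-out pseudo-trials classified correctly, averaged
over resamples. Where a narrative summary elsewhere describes an 80/20
split, the procedural description with exact counts (90%, 108, 36 per
condition) wins; `train_frac` is a configuration knob.

The null repeats the identical pipeline with labels permuted independently
per resample; it is centered on the theoretical chance level 1/3.
Significance:

- **Diagonal** (train = test bin): the inner 95% interval of the observed
  resample distribution must lie wholly above the null's inner 95%
  interval — a conservative criterion, at least p < 0.025.
- **Off-diagonal**: cells are flagged at the 5% level (observed mean above
  the null's 0.95 quantile), then only 4-connected clusters *exceeding* 5
  cells are kept. "Neighboring bins" is read as 4-connectivity in the
  train × test matrix, the conservative standard for cluster-based
  corrections on grids.

Cross-temporal symmetry is *not* assumed or asserted anywhere: asymmetric
generalization is a meaningful outcome.

Transfer classification fits on pre-cue pseudo-trials (location-significant
units only) and applies the model, bin by bin, to unlabeled no-cue
pseudo-trials, reporting per-bin classification fractions, a χ²
goodness-of-fit against the uniform expectation N/3 (N = number of no-cue
pseudo-trials, default 40; Bonferroni across bins), and the unweighted
mean fraction across bins ("average across the entire trial period" —
bin weighting is unspecified, and the unweighted mean is the neutral
choice). Whether the published procedure redraws the pseudo-assembly on
every resample or only the train/test split is not stated; this
implementation redraws only the split, so a single 40-trial assembly
carries composition noise of roughly ±0.05 per class — analyses that need
the chance level resolved more finely should pool assemblies or sessions,
as the validation suite does.

## Behavioral preference surrogate

Hit rate is hits/(hits+misses) per change location; correct-rejection rate
is CRs/(CRs+false alarms); undefined rates (zero denominators) are
reported as `NA`, never as 0. The attended-location surrogate divides each
session's completed trials into five equal consecutive blocks (sizes
differ by at most one trial), computes within-block no-cue hit rates per
change location, and labels locations "preferred"/"intermediate"/"least"
by descending rate. Ties — and locations with undefined rates, which rank
last — are resolved by display order (top before middle before bottom).
The session-level preferred location is the one most often
block-preferred, same tie rule; dataset-level fractions count
block-preferred locations over all blocks of all sessions. The analysis is
repeated for block counts s = 3…10 and the modal location's stability
across s is *reported*, not enforced. The omnibus test across locations is
Kruskal–Wallis on per-session rates, with Dunn-type pairwise post hocs on
the joint ranks (Bonferroni); the published analyses name no post hoc
procedure, and Dunn is the standard companion to Kruskal–Wallis.

The surrogate cannot resolve ties: a session in which two locations are
attended equally often has no well-defined majority, and the tie-break
then decides. It also lacks sensitivity to trial-by-trial switches —
both limitations are inherited from the design, not the implementation.

## The synthetic session generator

The generator exists so every analysis has a ground-truth target. It
emulates:

- the task timing (ITI 2.0 s; cue 200 ms + 500 ms delay, or 700 ms no-cue
  delay, so sample onset is locked 0.7 s after initiation in both trial
  types; sample 400 ms; delay 1100 ms; compare 400 ms);
- balanced, pseudorandomized conditions: per (trial type × cue location ×
  change/no-change) cell counts differ by ≤ 1; 50% of trials of each type
  contain a change (pre-cue changes only at the cued location); cue
  locations never repeat more than twice consecutively; colors are the
  session's two per-location palette colors, balanced within cells and
  reduced to indices {1, 2} since the analyses only ever contrast them;
- Poisson spiking: each unit is an epoch-wise homogeneous Poisson process,
  rate = baseline × spatial gain × color gain. No refractory period,
  latency jitter, adaptation, or rate drift — the analyses assume none of
  these, and the Fano factor of epoch counts is 1 by construction (tested);
- attention: exactly one attended location per trial (the cued location on
  pre-cue trials; the agent's choice on no-cue trials). The **spatial gain
  follows the attended location from sample onset onward**, and follows
  the physical cue only while the cue is visible (cue and post-cue epochs
  of pre-cue trials). This is a deliberate model choice: a classifier
  trained on pre-cue location can only transfer to no-cue trials if the
  spatial code reflects attention rather than retinal input, which is
  precisely the phenomenon the transfer analysis measures. The color-gain
  contrast is raised to the power `attn_gain` at the attended location
  (`attn_gain = 1` means no attentional modulation, the null used by the
  calibration tests);
- behavior: a change at the attended location is detected with
  `p_hit_attended` (default 0.95), elsewhere with `p_hit_unattended`
  (default 0.05), no-change trials are correctly rejected with `p_cr`
  (default 0.95); hits respond at the change location, misses and correct
  rejections at center, false alarms at the attended location. The
  response-location model for errors is an invention — the protocol only
  records that detected changes were virtually always pecked at the change
  location;
- sessions of 850 trials by default (the protocol's session length).
  Aborted (gaze-break) trials are not simulated: the analyses exclude them
  globally, so nothing downstream could observe them.

It does **not** emulate: graded or split attention, reaction times, reward
learning across sessions, eye/head movements, spike-sorting artifacts,
unit correlations beyond shared task drive, or oscillatory structure.
Passing tests therefore show the *pipeline* recovers known ground truth
under the analyses' own assumptions; they cannot certify behavior on data
violating those assumptions (e.g. strongly non-Poisson or correlated
populations).

Key defaults: baseline rates log-normal around 8 spikes/s (clamped at the
0.5 spikes/s inclusion floor), spatial gain 2, color gain 1.5,
`attn_gain` 2, class fractions 29% location-only / 4% color-only /
23% both / 44% untuned (the published composition). Seeding: one master
seed per session, with named substreams (trials, agent, spikes) so any
component reruns identically in isolation.

## Reproducibility and problem sizes

All randomness flows from explicit seeds; identical seeds give
byte-identical artifacts (checksums verified in the suite). The test and
validation suites run at desk scale, chosen to finish in minutes on one
core while leaving the statistical margins intact: sessions of 120–850
trials, populations of 16–160 units, 150–1000 permutations, 10–200
decoder resamples, and non-overlapping (200 ms step) grids for
decoder-heavy checks. Dataset-scale published quantities (e.g. peak
decoding percentages, unit-class percentages, behavioral medians) are
properties of the recorded dataset and are deliberately not reproduction
targets; the suite instead verifies the pathway properties that make those
numbers meaningful: permutation calibration, decoder chance recovery,
monotonic recovery of simulated attentional gain, strategy recovery from
transfer decoding, and surrogate-preference recovery.

Two consequences of desk scale are documented rather than hidden: small
random populations have imbalanced spatial tuning, which biases transfer
fractions for reasons unrelated to the agent (the strategy-recovery check
therefore uses a spatially balanced tuned population and pools sessions),
and small behavioral blocks can lack change trials at a location, making
that block's rate undefined and the block-preference fraction slightly
less than 1 even for a perfectly consistent agent.

## Known limitations

- The ANOVA is one-way throughout; factor interactions are not modeled.
- The permutation null shuffles whole-trial labels, which is exact for
  exchangeable trials but does not correct for slow within-session drift.
- The decoder is linear; nonlinear codes would be underestimated.
- χ² tests on transfer counts use the mean classification counts across
  resamples, not a hierarchical model of resample variability.
- The behavioral surrogate is blockwise-majoritarian: it cannot detect
  trial-by-trial attention switches and resolves exact ties by display
  order.
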