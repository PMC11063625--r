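---
title: "Methods: single-unit and population analysis of emotional memory spiking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-unit and population analysis of emotional memory spiking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emospike)
```

# Scope and data model

`emospike` analyzes microwire single-unit recordings from the human medial
temporal lobe (hippocampus, amygdala, entorhinal cortex) collected during
an emotional memory task: an incidental encoding session (120 scenes, 40
emotionally aversive and 80 neutral, 0.5 s presentation, 3.5 s
interstimulus interval, with no two emotional scenes adjacent) followed a
day later by a Remember/Know/New recognition session over the 120 old and
120 new scenes. All times are in seconds relative to stimulus onset;
analysis windows are half-open `[lo, hi)`, except the artifact-deletion
windows, which are closed. The default windows are baseline
`[-1.5, -0.2)` s and stimulus `[0.2, 1.5)` s.

Trials are labeled by subsequent memory: encoding trials become `eR`/`nR`
(emotional/neutral, later Remembered), `eF`/`nF` (later judged New, i.e.
forgotten) or `eK`/`nK` (later judged Know). Recognition trials become
RHit/KHit/Miss for old items and CR/FA for new items, again prefixed by
emotion. Know and false-alarm trials are rare in this task; they are kept
in the data but flagged `excluded_primary`, so the primary analyses skip
them while supplementary K-inclusive analyses remain possible.

# Unit quality control

Artifact spikes time-locked to the stimulus transitions are deleted in
closed 3 ms windows around onset (t = 0) and offset (t = 0.5 s); the
endpoint convention had to be fixed somewhere and a closed interval is the
conservative choice for artifact deletion. Deletion is idempotent.

A unit enters analysis iff (i) fewer than 3% of its interspike intervals
are under 3 ms, (ii) its mean firing rate exceeds 0.25 Hz, and (iii) it
fired on at least 50 encoding or 100 recognition trials. Two quantities in
these rules needed a definition the task description does not supply:

* ISIs are computed on spike times concatenated in trial order, with
  intervals that span a trial boundary discarded — the 3.5 s inter-trial
  gap dwarfs the millisecond ISI scale, so cross-trial intervals carry no
  information about sorting quality.
* Mean rate is total spikes divided by (number of trials × peri-stimulus
  window length), i.e. the rate over the recorded span.

# Event responsiveness

Per unit and trial type, the test statistic is the mean stimulus-window
spike count minus the mean baseline-window count. The null is generated by
swapping the baseline/stimulus labels independently within each trial — a
paired sign-flip of the per-trial count differences — which is the
exchangeability that actually holds under "no stimulus response"; an
unpaired pooled shuffle is available behind `pooled = TRUE` for
sensitivity analysis. The test is two-sided because both firing-rate
increases and decreases occur. Monte Carlo p-values use the add-one rule
`p = (1 + #{|T_perm| >= |T_obs|}) / (n_perm + 1)`, so p is never 0 and is
floored at `1/(n_perm + 1)`; exact enumeration of all `2^n` sign
assignments is available for small trial counts. All-zero counts return
p = 1 by convention.

# Selectivity census

Each unit's stimulus-window counts are analyzed with a between-trial
two-way factorial ANOVA — emotion (2) × memory (R/F at encoding;
RHit/Miss/CR at recognition), trials as replicates, type II sums of
squares (the design is unbalanced by construction: 40 emotional vs 80
neutral). Main effects are discarded whenever the interaction is
significant, so units are labeled `X` before `E`/`M`; a unit with both
main effects and no interaction is labeled `EM` and counts toward both
the E and M censuses. Units with a condition cell under 2 trials are
unanalyzable and are excluded from both the observed and null counts
symmetrically.

The census compares the observed number of selective units against a null
distribution built by shuffling, independently per unit and iteration,
the assignment of trials to conditions while preserving the per-cell
trial counts, and re-running the entire selection. Because the shuffle
preserves the condition multiset, it is implemented as a permutation of
the response vector against a fixed design matrix, which allows all
`B = 10000` re-fits to be solved with precomputed cross-product inverses
(the implementation is verified against `car::Anova` in the test suite).
The census p is `#{null >= observed} / B`, floored at `1/B` when no null
count reaches the observed count; it is conservative (super-uniform)
under the null by construction. Per-iteration permutation substreams are
keyed by unit position, so the null ensemble is invariant to unit
relabeling and reproducible from one master seed.

Pairwise recognition comparisons (all 6 pairs of RHit, KHit, Miss, CR)
use the identical census machinery with a two-level one-way ANOVA
(equivalent to a t-test) per unit; the conventional printed Bonferroni
threshold 0.0086 is the default, with `0.05/6 = 0.00833` available via
the `bonferroni` argument (the two differ in the third decimal; the
printed value is kept as the reference default and the discrepancy is
noted here). Stratified reruns by region or patient use the same
machinery per stratum; strata below a minimum unit count are flagged
underpowered rather than dropped.

# abs(z) population model

For each trial, `x` is the trial's mean stimulus-window firing rate
(Gaussian-smoothed by default; raw counts give the same significance
pattern on planted-effect cohorts, which the suite checks); `mu` and
`sigma` are the mean and SD of the per-trial baseline-window rates over
all trials, and `z = (x - mu)/sigma`. The per-trial reading of `x` is
required for a trial-level model; the alternative (a single across-trial
mean) would collapse each unit to one number. Units whose mean z is
negative have every z multiplied by −1, so suppressed units contribute
positive modulation. Units with zero baseline SD are excluded with a
logged reason, never zero-filled.

The population model is
`abs_z ~ 1 + Emotion * Memory + (1 | Patient / Neuron)`, fitted by REML
with `lme4`; random intercepts only, exactly the stated structure. Fixed
terms are tested with omnibus Wald chi-square tests (type II,
`car::Anova`), appropriate when an interaction is present. Pairwise
memory contrasts within each emotion level come from estimated marginal
means (`emmeans`, asymptotic Z ratios) with Benjamini–Hochberg adjustment
within the model's contrast family (the family is per fitted model, i.e.
per phase; encoding and recognition are fitted and corrected
separately).

# Demixed PCA

The trial-averaged tensor `X[unit, emotion, memory, time]` (smoothed
PSTHs: Gaussian kernel sigma = 50 ms, 10 ms bins, default time axis −0.5
to 2.5 s; raw Hz, with z-scoring left to the caller since the reference
analyses do not state normalized inputs) is centered per unit and split
by sequential condition averaging into condition-independent (time),
emotion, memory and interaction marginalizations. The decomposition is
additive and exact, and the parts are mutually orthogonal, so their sums
of squares partition the total variance.

Per marginalization, decoder/encoder pairs minimize
`||X_phi - F D X||^2` with a ridge penalty, solved as reduced-rank ridge
regression via `A = X_phi X' (X X' + lambda_eff I)^{-1}` and an SVD of
`A X`. Numerical choices:

* `lambda_eff = lambda * ||X||_F^2`, making `lambda` scale-free;
  `lambda = 0` is the unregularized limit and, with a single full
  marginalization, reproduces plain PCA exactly (checked against an SVD
  oracle to 1e-8).
* At `lambda = 0` the Gram matrix may be singular on noiseless synthetic
  tensors; a Moore–Penrose pseudo-inverse (eigenvalue threshold 1e-10
  relative) keeps the limit well defined.
* `lambda = "cv"` selects lambda on a log grid by 10-fold
  held-one-trial-out reconstruction error, with folds drawn from the
  master seed.
* 20 components are computed and the first 15 reported in the variance
  accounting; components are pooled across marginalizations and ranked by
  individually explained variance. Per-component variances can
  double-count shared variance across marginalizations, so the
  Eckart–Young comparison against PCA uses the joint reconstruction
  variance internally.

Unbalanced trial counts are handled by per-cell averaging, with per-cell
counts entering the noise estimate; no pseudo-trial resampling is used
for the fit. The signal-variance ceiling uses the 1/n law: the noise in
an n-trial average is the across-trial variance over n, summed over
cells and bins, and the signal fraction is `1 - noise/total`, clipped to
`[0, 1]`.

Decoding significance treats each condition component's decoder axis as a
1-D linear readout. Each Monte Carlo iteration holds out one single trial
per (unit, condition) as a pseudo-trial population response and
classifies it per time bin to the nearest training-class mean along the
axis, with ties broken toward the first class label; emotion components
decode the emotion label, memory components the memory label, interaction
components the full condition tuple. The null reassigns each unit's
trials to conditions uniformly while preserving per-condition counts
(`n_shuffles` times), repeating the cross-validation at one tenth the
iterations per shuffle — the extra Monte Carlo noise widens the null and
makes the test slightly conservative, which the null-calibration test
bounds at under 7% significant bins. A bin is significant where the real
accuracy exceeds the 97.5% shuffle quantile; 95% and 100% quantile curves
are also returned. Leave-one-region-out reruns the fit and decoding on
the complement of each region and reports variance and
significant-window deltas.

dPCA is fitted on the pooled pseudo-population across patients (units are
never simultaneously recorded across patients, but the pooled-population
reading is the standard one for this analysis and is the only one with
enough units per fit).

# Synthetic cohorts

The generator emulates the recorded data's structure and is itself
first-class, tested code. Defaults define the study conditions:

* 5 patients × 52 units over three regions (~260 units, the scale of the
  258/284 analyzable units per phase); 120 encoding and 240 recognition
  trials per patient with the real session's emotion counts, timing and
  non-adjacency constraint (enforced constructively by placing emotional
  items into distinct gaps between neutral items, which also yields the
  `n_e <= n_n + 1` feasibility bound).
* Behavioral outcome probabilities per emotion: P(R|old) = 0.55/0.50
  (emotional/neutral), P(K|old) = 0.10, P(FA|new) = 0.10 — a clearly
  above-chance recognizer with few Know responses and false alarms,
  matching the task's reported low K/FA counts; exact per-patient rates
  are not published, so these are fixed once as plausible values.
* Spike trains are inhomogeneous Poisson, sampled by thinning:
  `lambda(t) = baseline * (1 + bump(t) * G)` with a Gaussian bump
  (latency 0.3 s, width 0.2 s — the reference figures show but do not
  parameterize response shapes) and condition gain
  `G = event + emotion*1[e] + memory*1[R] + interaction*1[e&R]`, clipped
  at 0. Gains are multiples of the baseline rate. Refractoriness is
  enforced by dead-time deletion (default 2 ms), which is adequate for
  the quality metrics and keeps the short-ISI fraction near zero by
  construction.
* Baseline rates are log-normal with median 2 Hz and sdlog 0.8, so a few
  units straddle the 0.25 Hz inclusion boundary and exercise the QC
  paths. Planted effect classes default to ~10% emotion, ~7% memory, ~6%
  interaction and 30% event-only units, mirroring the reported selective
  fractions; emotion/memory gains take random sign (real selectivity
  includes suppression).

What the generator does **not** emulate: bursting and serial dependence
within spike trains beyond dead time, rate drift across the session,
waveform shapes (beyond a parametric template for the width metric),
inter-unit correlations, and any structured relation between region and
effect class. Passing tests therefore demonstrate correctness and
calibration of the estimators under Poisson-like variability, not that
real MTL data meet those assumptions.

# Problem sizes and runtime choices

The packaged tests calibrate on cohorts of 5 patients × 40 units with
full trial counts, 20 replicate cohorts for census uniformity and power,
B = 500 census iterations, and reduced decoding Monte Carlo
(`n_iter = n_shuffles = 100`); these sizes give stable binomial/KS bounds
while keeping the suite fast. Full-scale defaults (B = 10000,
`n_iter = n_shuffles = 1000`) remain the function defaults and are what
`run_full_analysis()` uses.

# Known limitations

* The per-unit "repeated measures" ANOVA is a between-trial factorial
  ANOVA on counts — trials are the replicates within one neuron; no
  within-trial repeated factor exists in this design.
* Whether the reference permutation test was paired or pooled is not
  documented; the paired reading is the default here and the pooled
  variant is exposed for sensitivity.
* Count data are modeled with Gaussian ANOVA/LMM machinery (as in the
  reference analyses), not count likelihoods; census calibration is
  guaranteed by the permutation construction rather than by
  distributional assumptions.
* The deposited per-unit data structure may store units pre- or
  post-inclusion filtering; the CSV adapter makes no assumption and
  always re-applies the filters.
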