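# emospike

Single-unit and population analysis of human medial-temporal-lobe (MTL)
spiking during an emotional memory task.

Microwire recordings in epilepsy patients yield a few hundred putative
single neurons from hippocampus, amygdala and entorhinal cortex while the
patient encodes emotionally aversive and neutral scenes and, a day later,
makes Remember/Know/New recognition judgments. The scientific questions
this package addresses: which neurons respond to stimuli at all, which
are selective for emotion, subsequent memory (remembered vs forgotten),
or their interaction, whether the *number* of selective neurons exceeds
chance, how firing-rate modulation varies with condition at the
population level, and whether emotion and memory are demixed and
decodable from the population. It is written for electrophysiologists
and computational neuroscientists who want these analyses as tested,
reusable building blocks rather than one-off scripts.

## What it implements

- **Quality control** — artifact spikes deleted in closed ±3 ms windows
  at stimulus onset/offset; inclusion rules: %ISI < 3 ms below 3%, mean
  rate > 0.25 Hz, spikes on ≥ 50 (encoding) / 100 (recognition) trials.
- **Event responsiveness** — per unit and trial type, a paired
  permutation test of baseline `[-1.5, -0.2)` s versus stimulus
  `[0.2, 1.5)` s spike counts: statistic `T = mean(n_stim) − mean(n_base)`,
  null by within-trial label swaps, two-sided
  `p = (1 + #{|T_perm| ≥ |T_obs|}) / (n_perm + 1)`.
- **Selectivity census** — per-neuron 2×2 (encoding) / 2×3 (recognition)
  factorial ANOVA on stimulus-window counts with interaction precedence
  (X discards E/M), then a bootstrap census: the observed count of
  selective neurons is compared with counts from B = 10 000
  shuffled-label re-selections; `p = #{null ≥ observed}/B`, floored at
  `1/B`. Pairwise RHit/KHit/Miss/CR censuses and region/patient-stratified
  reruns included.
- **abs(z) mixed model** — per-trial z of stimulus-window rate against
  baseline moments, sign-corrected to abs(z), modeled as
  `abs_z ~ 1 + Emotion * Memory + (1 | Patient/Neuron)` (lme4 REML),
  omnibus Wald χ² per term (car), BH-adjusted pairwise contrasts
  (emmeans).
- **Demixed PCA** — from-scratch marginalization of the
  unit × emotion × memory × time tensor into time / emotion / memory /
  interaction parts (additive, orthogonal, exact), ridge-regularized
  reduced-rank decoder/encoder estimation per marginalization
  (`min ‖X_φ − F D X‖² + λ‖·‖²`), explained-variance accounting,
  signal-variance ceiling, cross-validated decoding significance against
  shuffled-label nulls (97.5% quantile), PCA baseline and
  leave-one-region-out reruns.
- **Synthetic cohorts** — inhomogeneous-Poisson spike trains
  (`λ(t) = baseline·(1 + bump(t)·G)`, thinning, dead-time refractoriness)
  on task designs with the real session structure, with planted effect
  classes and ground truth, for calibration and power analysis.

## Worked example

```r
library(emospike)

cfg <- cohort_config(n_patients = 3, units_per_patient = 20,
                     prop_emotion = 0.25, gain = 2.5)
cohort <- simulate_cohort(cfg, seed = 42, phases = "encoding")
units  <- cohort_units(cohort, "encoding")
trials <- lapply(cohort$trials, `[[`, "encoding")

qc <- quality_filter(lapply(units, remove_artifact_spikes), "encoding")
census <- census_bootstrap(qc$units, trials, "encoding", effect = "E",
                           B = 2000, seed = 42)
census

mm <- fit_mixed_model(build_ztable(qc$units, trials), "encoding")
mm$anova

tensor <- build_population_tensor(qc$units, trials, "encoding")
model  <- fit_dpca(tensor, n_components = 10)
round(explained_variance(model, tensor)$marginalization_pct, 1)
estimate_signal_variance(tensor)
```

Output:

```
<census_result> effect E: observed 16 / 60 units, p = 0.0005 (B = 2000)

            term    chisq df           p
1        emotion 10.01567  1 0.001552139
2         memory 15.17977  1 0.000097745
3 emotion:memory  2.99366  1 0.083591040

       time     emotion      memory interaction
       60.5        16.7        14.1         8.7

signal-variance ceiling: 0.68
```

Reading it: 16 of 60 units show an emotion main effect — far more than
any of the 2000 shuffled-label re-selections produced, hence the census
p of 0.0005 (the floor at this B would be 1/2000). This cohort plants
emotion effects in 25% of units and, per the generator defaults, memory
effects in 7%, and the mixed model detects both main effects on abs(z)
while the (unplanted) interaction stays at trend level. The dPCA variance
split assigns 60.5% of population variance to condition-independent
temporal dynamics and 16.7% to emotion; the signal-variance estimate says
68% of the trial-averaged variance is explainable structure rather than
sampling noise.

`run_full_analysis()` chains every stage (QC → responsiveness → census →
mixed model → dPCA) into a reproducible JSON report;
`inst/scripts/run_pipeline.R` wraps simulation and the full pipeline for
shell use.

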