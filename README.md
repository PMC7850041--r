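# memsig

Spectral and behavioural biomarkers of successful memory encoding in
intracranial EEG (iEEG), built around the **subsequent memory effect
(SME)**: the contrast between brain activity recorded while studying items
that are later recalled versus later forgotten in delayed free recall.

The package is aimed at cognitive electrophysiologists who want a tested,
fully reproducible implementation of the standard free-recall iEEG analysis
stack, plus a synthetic data generator with *known, injectable effect
sizes* so that every stage can be validated end to end without access to
clinical recordings.

## What it computes

**Recall dynamics.** Serial-position curves; the temporal clustering score
(each recall transition's |serial-position lag| is percentile-ranked
against the lags of all not-yet-recalled items — 1.0 means every
transition goes to the nearest available neighbour, 0.5 is chance); the
adjusted ratio of clustering, ARC = (R − E(R)) / (maxR − E(R)) with
E(R) = Σᵢ nᵢ(nᵢ−1)/N and maxR = N − k, for semantic clustering on
categorized lists (1 = maximal, 0 = chance); and likelihood-ratio χ² tests
for group and group × task effects from linear mixed models with random
subject intercepts.

**Spectral power SME.** After 60 Hz notch filtering (4th-order Butterworth,
zero-phase) and optional bipolar re-referencing, signals are convolved with
complex Morlet wavelets (wave number 5; 20 frequencies log-spaced on
3–170 Hz), log-transformed, z-scored within session and averaged over
0.4–1.1 s after item onset. A Welch t-statistic per electrode × frequency
contrasts recalled vs not-recalled items (positive t = more power during
successful encoding), averaged into 4 regions × 2 bands (theta 4–8 Hz,
high-frequency activity 45–170 Hz) and compared between groups with
Benjamini–Hochberg-corrected Welch tests.

**Theta phase-locking networks.** For every electrode pair, the
phase-locking value PLV = |⟨e^{iΔφ}⟩| of 4–8 Hz phase differences is
computed per item class; the connectivity SME (recalled − not-recalled
PLV, averaged over the five theta frequencies) is standardised against a
null built from 500 item-label shuffles, giving a permutation Z per pair,
aggregated to region-of-interest pair edges and group tests.

**Recall classifier.** A per-subject L2-penalized logistic regression
(inverse-regularization C = 2.4 × 10⁻⁴, minority class weighted in inverse
proportion to its frequency) on mean log power at 8 frequencies
(3–180 Hz) per electrode over 0–1.366 s, evaluated by
leave-one-session-out (or leave-one-list-out) cross-validated ROC AUC with
a 1000-shuffle permutation p-value.

**Cohort matching.** A logistic propensity model of case membership on
demographic/coverage covariates, greedy 3:1 nearest-propensity matching
without replacement with exact matching on handedness, and standardized
mean-difference balance diagnostics.

**Synthetic generator.** Recall sequences from a sequential softmax sampler
(temporal kernel × category bonus) with primacy/recency-shaped recall
probabilities, and multichannel 1/f epochs with label-dependent band-limited
power shifts and pair-shared theta components — every effect size is a
generator parameter that downstream stages must recover.

## Worked example

```r
library(memsig)

cfg   <- sim_config(n_lists = 12, n_channels = 8)
truth <- effect_truth(theta_power_delta = -0.5, hfa_power_delta = 1.0)
ds    <- simulate_subject(cfg, truth, rng_seed = 42)

temporal_clustering_score(ds$events)
#>   subject temporal_score n_transitions
#> 1 s01              0.629            35

feats <- encoding_power_features(ds$epochs, ds$events)
sme   <- power_sme(feats, ds$events$recalled)
band_region_sme(sme, ds$electrodes)
#>   region   band  mean_t n_channels n_freqs
#> 1 frontal  theta  -3.56          2       3
#> 2 frontal  hfa    26.1           2       6
#> 3 MTL      theta  -3.19          2       3
#> 4 MTL      hfa    25.1           2       6
#> 5 LTC      theta  -2.67          2       3
#> 6 LTC      hfa    24.4           2       6
#> 7 parietal theta  -3.84          2       3
#> 8 parietal hfa    26.3           2       6
```

The subject's recall order is temporally organised (0.63 against a chance
level of 0.5), and the injected effects are recovered with the expected
signs: theta-band power decreases (negative mean t) and high-frequency
power increases (positive mean t) during successful encoding in every
region. With no synchrony injected, the theta network is flat:

```r
net <- connectivity_sme_z(ds$epochs, ds$electrodes, ds$events$recalled,
                          n_perm = 500, rng_seed = 1)
glance(net)
#>   n_pairs n_perm  mean_z n_significant
#> 1      28    500 -0.0237             0
```

and the classifier separates recalled from forgotten items perfectly at
these (deliberately large) effect sizes:

```r
x  <- build_feature_matrix(ds$epochs, ds$events, ds$electrodes)
cross_validated_auc(x, ds$events$recalled, ds$events$session, ds$events$list)
#> <classifier_result> leave-one-list-out: AUC = 1.000 over 12 folds (C = 0.00024)
```

Every result type has `tidy()`, `glance()` and `autoplot()` methods, and
`run_pipeline(run_config(...), out_dir = "...")` drives all stages and
writes JSON artifacts plus a markdown report.

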