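---
title: "Models and methods behind memsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind memsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(memsig)
```

memsig analyses delayed free recall with simultaneous intracranial EEG:
subjects study 12-item lists (up to 26 per session, the first being an
unscored practice list), perform an arithmetic distractor, then recall
freely. The package contrasts encoding-period physiology between items
later recalled and later forgotten (the subsequent memory effect, SME),
and ships a synthetic generator so that every estimator can be checked
against known ground truth. This vignette explains the models, the
defaults and the numerical choices, and states what the synthetic checks
do and do not establish.

## Behavioural statistics

**Serial-position curve.** Per subject and list position, the fraction of
presentations recalled. Primacy and recency are properties of the data,
not of the estimator.

**Temporal clustering.** For each recall transition, the absolute
serial-position lag to the item actually recalled next is ranked against
the lags to every item of that list not yet recalled. The percentile
convention — the fraction of the *other* available items strictly farther
plus half the fraction tied — is chosen so that a unique nearest-neighbour
transition scores exactly 1 and, by a symmetry argument (each unordered
pair of candidates contributes exactly one "farther" event or two half
"tied" events), a uniformly random recall order has expectation exactly
0.5 per transition. Transitions with no alternative candidate are skipped
as undefined rather than scored. Across-list transitions are never scored,
and only correct first recalls enter (repetitions and intrusions are out
of scope of the generator and of the score). The implementation is tested
for exact agreement with a brute-force enumeration on all lists of up to
6 items.

**Semantic clustering (ARC).** For a categorized list with $N$ recalls of
which $n_i$ fall in category $i$ ($k$ categories recalled), with $R$
observed same-category adjacent recall pairs,

$$\mathrm{ARC} = \frac{R - E(R)}{\max R - E(R)}, \qquad
E(R) = \sum_i \frac{n_i(n_i-1)}{N}, \qquad \max R = N - k.$$

$E(R)$ is the exact expectation of $R$ under a uniformly random
permutation of the recalls ($(N-1)$ adjacencies, each same-category with
probability $\sum_i n_i(n_i-1)/(N(N-1))$), which is what makes the chance
level 0; this is the classical definition of the statistic. Lists with
$\max R = E(R)$ (fewer than two recalls, or all recalls from a single
category) carry no information and are excluded from the subject mean.

**Group contrasts on recall.** A linear (Gaussian) mixed model on the
per-item 0/1 outcome — fixed effects for group, task variant and serial
position, random intercept per subject — fitted by maximum likelihood so
that likelihood-ratio $\chi^2$ tests (1 df) for the group main effect and
the group-by-task interaction are valid. A linear rather than logistic
link keeps the LR tests on the same scale as the package's reporting and
is robust at the recall rates involved; per-subject clustering scores are
compared with Welch's unequal-variance t-test.

## Spectral power SME

Preprocessing drops channels flagged as epileptogenic or inter-ictally
spiking, optionally forms bipolar neighbour differences when the montage
is monopolar, and removes 60 Hz line noise with a 4th-order Butterworth
band-stop. The stopband is set to 58–62 Hz and the filter is applied
forward–backward (zero-phase), so the notch cannot shift oscillatory
phase — a requirement for the downstream phase-locking analysis.

Time–frequency decomposition uses complex Morlet wavelets with wave
number 5 (envelope SD $\sigma_t = 5/(2\pi f)$), implemented as
frequency-domain multiplication with a one-sided Gaussian of SD $f/5$
centred on each target frequency. Epochs carry a 1 s buffer on each side;
at the lowest analysis frequency (3 Hz) the wavelet's $3\sigma_t$ reach is
0.80 s, so wrap-around and edge transients stay inside the buffer, which
is trimmed before any statistic is formed. The generator synthesises the
buffer as genuine stationary signal, so no padding heuristic (mirroring,
zero-padding) is needed anywhere.

Power features are $\log$ power averaged over 0.4–1.1 s after item onset
at 20 log-spaced frequencies on 3–170 Hz, z-scored across items within
each session separately per channel and frequency (so each feature has
mean 0, SD 1 over a session's items; a constant-power cell would yield
0/0 and is mapped to 0 with a warning). Items from multiple sessions are
pooled after within-session z-scoring, maximising item counts while
removing session-level gain differences. The SME is a Welch t per channel
and frequency, recalled minus not-recalled; cells average channels within
each of the four regions (frontal, MTL, lateral temporal, parietal) and
grid frequencies inside theta (4–8 Hz; the Methods-style 4 Hz lower edge
is used throughout) and high-frequency activity (45–170 Hz), both closed
intervals; grid frequencies outside both bands contribute to no cell.
Group contrasts over the 8 cells use Welch tests with Benjamini–Hochberg
correction applied jointly across all 8 (not per band).

## Theta connectivity

For every usable channel pair, phase differences at 4, 5, 6, 7, 8 Hz are
averaged over the 0.4–1.1 s window *circularly* (the resultant direction
of the unit phasors of the instantaneous differences), giving one angle
per item and frequency; the arithmetic mean of angles would be ill-defined
near the ±π wrap. The phase-locking value is the resultant length of
those per-item angles within each class. The connectivity SME (recalled −
not-recalled PLV) is averaged across the five frequencies *before*
standardisation, and the permutation null shuffles the item labels 500
times — one shared shuffle sequence for all pairs, preserving class sizes
exactly and the dependence structure across pairs — yielding
$Z = (\mathrm{obs} - \bar{\mathrm{null}})/\mathrm{SD}(\mathrm{null})$ per
pair. A null SD of exactly zero (constant SME across shuffles) yields a
missing Z with a warning rather than an infinite score. ROI-pair edges
average the Z of spanning channel pairs; |Z| > 1.96 is only a *display*
threshold for exported networks, never an analysis gate. Group inference
uses each subject's mean ROI edge weight: one-sample t against zero per
group and a Welch two-sample t between groups.

## Recall classifier

Features are mean log power over 0–1.366 s at 8 log-spaced frequencies on
3–180 Hz per channel, z-scored within session per feature (the package
exposes `z_score = FALSE` for raw log power; standardised features are
the default so the shared penalty acts on comparable scales). The model
minimises

$$\tfrac{1}{2}\lVert w\rVert^2 + C \sum_i s_i \log(1 + e^{-\tilde y_i (x_i w + b)}),$$

with unpenalized intercept, $C = 2.4\times10^{-4}$ interpreted as the
*inverse*-regularization parameter (smaller = stronger penalty, the
convention of the implementation lineage this constant comes from), and
observation weights $s_i = n/(2 n_{\mathrm{class}(i)})$ so the minority
class counts in inverse proportion to its frequency. The fit is a Newton
iteration on this exact objective (converged when the objective change is
below $10^{-10}$ relative and the gradient below $10^{-6}$), which is
deterministic; tests verify it against direct numerical minimisation of
the same objective and against `glm()` in the weak-penalty limit.

Evaluation is leave-one-session-out for multi-session subjects and
leave-one-list-out otherwise; out-of-fold predicted probabilities are
pooled and the ROC is a threshold sweep over the unique scores with
trapezoidal AUC (provably equal to the Mann–Whitney normalisation, which
a test asserts to $10^{-10}$). Significance permutes the labels, re-runs
the full cross-validation, and reports
$p = (1 + \#\{\mathrm{AUC}_{\mathrm{null}} \ge \mathrm{AUC}\})/(n_{\mathrm{perm}}+1)$.
Folds whose training data contain one class are skipped with a warning
rather than fitted degenerately.

## Cohort matching

Case membership is modelled by a logistic GLM on age, sex, handedness,
prior resection, years of education, age at seizure onset, and per-region
electrode-coverage and seizure-onset-zone indicators; fitted probabilities
are the propensity scores (numerical separation is flagged, constant
covariates are dropped with a message). Matching is greedy nearest
neighbour without replacement: cases in descending propensity order each
take their `match_ratio` (default 3) closest controls by |Δ propensity| on
the probability scale (a logit-scale distance is available), restricted to
controls with *identical handedness* (a hemispheric-dominance proxy), with
distance ties broken by subject id so the algorithm is deterministic.
Without-replacement is deliberate: a reported matched-control group of
distinct subjects implies uniqueness, so the package enforces it rather
than matching with replacement. Balance diagnostics report standardized
mean differences (pooled-SD denominator, categorical covariates expanded
to level indicators) and two-sample tests, case vs all controls and case
vs matched controls.

## The synthetic generator

The generator is the package's test bed and defines the study conditions
under which every calibration and recovery claim is made.

*Behaviour.* Recall flags are independent Bernoulli draws with a
serial-position-shaped probability (default: base ≈ 0.35 with
exponential primacy and recency components — plausible for delayed free
recall; per-list recall rates of the real task are free parameters, not
calibrated to any cohort). Recall order comes from a sequential softmax
over not-yet-recalled items with weights
$\exp(-|\mathrm{lag}|\,\tau)\times\exp(\sigma\,[\text{same category}])$
(the first recall uses $\exp(-(\mathrm{pos}-1)\tau)$ so the $\tau\to\infty$
limit reproduces study order). This is the simplest generative model that
spans chance (strengths 0) to perfect clustering; the literature defines
only the resulting scores, not a generative process. Categorized lists
place 3 categories × 4 exemplars as six successive same-category pairs
with adjacent pairs from distinct categories.

*Signals.* Epochs are synthesised in the frequency domain: white Gaussian
noise shaped to $1/f$ power (exponent 1.0, flattened below 1 Hz), default
500 samples/s so Nyquist clears the 180 Hz top analysis frequency.
`theta_power_delta` and `hfa_power_delta` multiply the within-band
synthesis amplitude by $e^{\delta/2}$ on recalled items, i.e. they are
log-power shifts in natural-log units; their magnitude in z-scored feature
units depends on the across-item SD of the window-averaged log power
(close to the nominal value at theta frequencies, larger at high
frequencies where window averaging shrinks the SD). For each designated
sync pair, a shared narrowband theta component replaces a fraction
$\rho$ of both channels' theta power ($\rho$ = `sync_base`, default 0.1,
on not-recalled items, plus `sync_plv_delta` on recalled items); the
induced PLV difference is approximately, not exactly, `sync_plv_delta`,
and recovery tests therefore assert rank separation of the injected pair,
not the exact PLV value.

*Cohort.* Covariates are drawn from fixed, realistic marginals and the
case label from a logistic model with user-supplied coefficients on
standardized covariates, retained as ground truth for recovery checks.

What the generator does **not** emulate: epileptiform artifacts and
inter-ictal spikes, word-pool semantics (categories are symbolic
integers), eye/muscle artifact, non-stationarity within sessions, and
real electrode geometry (regions are labels, not locations). Passing the
package's recovery suites therefore shows the *estimators* are correct
and calibrated under clean, stationary 1/f conditions — it does not show
robustness to clinical-recording pathologies, which must be handled by
the exclusion flags upstream.

## Numerical and design notes

- All randomness flows through explicit integer seeds; a pipeline run
  derives per-stage streams from one root seed, and identical
  configurations reproduce bit-identical artifacts (the configuration
  hash and seed are stamped into every output).
- Degenerate inputs fail loudly: single-item sessions (z-score
  undefined), single-class folds, empty classes, windows outside the
  buffered epoch, sampling rates below twice the analysis band.
- The epochs container is a flat float64 binary array with a JSON
  sidecar (axis order item × channel × sample) — no clinical EEG formats
  are consumed, so no EDF dependency is taken.
- Test and calibration problem sizes were chosen as the smallest designs
  whose Monte-Carlo error is comfortably inside each assertion's band:
  4000 lists for the behavioural chance levels, 20 subjects × 300 items
  for classifier chance, five independent 210-pair null networks (1050
  pairs) for permutation-Z calibration, 50 seeds for the SME
  sign-recovery rate.

## Known limitations

- The mixed model is linear on a binary outcome; with very extreme recall
  rates a logistic GLMM would be preferable.
- The permutation Z is treated as standard normal for the display
  threshold; with 500 shuffles the estimated null mean/SD add slight
  heavy-tailedness that the calibration test bounds but does not remove.
- Greedy matching is not optimal matching; with scarce
  handedness-compatible controls it can strand late (low-propensity)
  cases, which the package reports rather than repairs.
- The classifier's chance level under leave-one-list-out shows the usual
  slight per-subject CV dispersion from fold-wise class imbalance; it is
  unbiased in the mean, which is what the chance-level check asserts.
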