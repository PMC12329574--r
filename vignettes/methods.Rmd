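---
title: "Methods: vocoding, simulation, classification, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vocoding, simulation, classification, and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocattn)
```

This vignette is the package's own account of its methods: the models and
procedures it implements, the parameters that matter and why their
defaults are what they are, what the synthetic-data generators do and do
not emulate, and the numerical and design choices made where the design
was genuinely open.

## The noise vocoder

Noise vocoding degrades speech the way a cochlear-implant processor
presents it: spectral fine structure is discarded and only the slow
amplitude envelope of each frequency band is retained, carried by noise.
Intelligibility rises with the number of bands, which is why 8-band
speech serves as the *easy* and 4-band speech as the *hard* condition of
the dual-task design.

Band edges are placed on the Greenwood frequency–position map
$f = A\,(10^{a x} - k)$, equally spaced in cochlear position $x$, so each
channel covers a comparable extent of the basilar membrane. The constants
are `scale_hz` $A = 165.4$ Hz, `exponent` $a = 2.1$, and `offset`
$k = 1$. The integer offset matters: the frequently quoted $k = 0.88$
human-map variant shifts the interior edges by several percent (about
297 Hz instead of 311 Hz for the second edge of the 4-band, 50–5000 Hz
filterbank), while $k = 1$ reproduces the classical edge tables used for
vocoded sentence stimuli to within 1 Hz. The map round-trips
($x \circ f = \mathrm{id}$) to $10^{-9}$ relative error across 20 Hz –
20 kHz, and the 8-band edge set nests the 4-band set exactly because
positions at multiples of $1/4$ are also multiples of $1/8$.

The processing chain per band is: zero-phase 4th-order Butterworth
band-pass → half-wave rectification → zero-phase 2nd-order Butterworth
low-pass at 300 Hz (the envelope) → multiply a seeded white-noise stream
→ re-filter with the same band-pass → sum across bands. Published
descriptions of this stimulus class rarely state filter orders or phase
behavior, so those were open design choices; forward–backward
(zero-phase) filtering was chosen so the analysis and resynthesis filters
align in time and the same filter object can be reused on the modulated
carrier. Envelope low-pass ripple can push individual samples slightly
negative, so the envelope is clamped at zero as a final step. Each band's
carrier uses seed `noise_seed + band − 1`, making `vocode()`
deterministic given its parameters; the seed and edges are attached to
the output.

Two conventions required a decision:

* **Level normalization.** "70 dB" in stimulus-preparation protocols
  refers to an SPL calibration that has no meaning in a file on disk, so
  `rms_normalize()` targets a linear full-scale RMS instead, with
  `dbfs_to_amp()` for dB-full-scale conversion; the default target is
  −20 dBFS. Equating the RMS of 4- and 8-band outputs is what matters for
  the design, and that property is tested exactly.
* **Edge rounding.** Edges are computed at full precision and rounded
  only for display; the printed value 3307 Hz corresponds to a computed
  3306.96 Hz, so tests accept ±1 Hz.

The envelope-extraction tests use two independent oracles: the
steady-state envelope of a pure tone of amplitude $A$ must equal the
rectified-sine mean $A/\pi$ times the filter's unit DC gain, and the
envelope of a 4 Hz amplitude-modulated tone must correlate > 0.95 with
the analytic modulator. For the single-band vocoder identity check the
carrier noise contributes envelope fluctuation of its own above the
syllable rate, which caps the envelope correlation near 0.87 when both
envelopes are smoothed at the full 300 Hz cutoff; the test therefore
feeds a syllable-rate (3 Hz) modulated noise and compares envelopes
smoothed at 30 Hz — both via `extract_envelope()` — where the correlation
exceeds 0.99.

## The synthetic study

No raw subject data ships with the package; every downstream stage is
exercised on synthetic inputs whose ground truth is planted and known.
The generators reproduce the study design exactly where it is stated:

* 25 subjects, 4 conditions (speech easy/hard × visual easy/hard), 6 main
  runs of 8 blocks × 6 trials (288 trials per subject, 72 per condition);
  each condition fills 2 blocks per run and block order is
  pseudo-randomized with no condition occupying more than two consecutive
  blocks.
* Target–distractor angular discrepancy (TD) is drawn uniformly from
  (48°, 60°] for the easy and (6°, 18°] for the hard visual task; half of
  the visual trials in each block are targets (TD stored as 0 with a
  target flag, keeping the trial table flat-file friendly).
* The sentence pool holds 336 + 270 = 606 uniquely keyed pseudo-sentence
  records in two corpus tags, supports without-replacement draws, and
  builds the post-scan recognition fixture of 96 heard sentences (24 per
  condition) plus 32 new ones.

Behavioral responses are Bernoulli draws from a logistic model with
speech-difficulty, visual-difficulty, and interaction terms, a TD slope,
a TD × visual-difficulty slope, and Gaussian per-subject intercepts. The
default intercepts are back-solved (`coef_from_means()`) from the
observed condition accuracies of dual-task gist report
(0.857/0.870/0.533/0.568 for speech; 0.849/0.655/0.820/0.669 for visual),
and the default subject-intercept SD of 0.8 logits produces across-subject
accuracy SDs near 0.1, in the range such studies report. Note that with
random intercepts the population accuracy means are mildly attenuated
toward 0.5 relative to the targets (logit-normal averaging, about 0.01 at
these settings); the back-solved targeting is exact for the fixed-effects
means, i.e. at `subject_sd = 0`. The
`td_visual` slope exists so that the hard-visual TD response curve — at or
below chance for the smallest discrepancies, crossing 0.5 near 11°,
reliable rejection at the top of the range — can be emulated; its default
is 0.

The parcel-level generator emulates, at parcel resolution, the per-subject
per-condition *t*-maps that feed the classifier: 100 rows (25 subjects ×
4 conditions) × `n_parcels` columns. Each value is a stable per-subject,
per-parcel offset (SD `subject_sd` = 0.5) plus a planted condition mean
plus Gaussian noise (SD `noise_sd` = 1). Twelve of 100 parcels are
informative by default: four *general* parcels respond to both
difficulties, four *speech* parcels to speech difficulty, four *visual*
parcels to visual difficulty, with a signed cross-modal suppression of
−0.5 × `effect_size` applied to each modality-specific set when the other
task is hard — mirroring the resource trade-off in which regions
responsive to one modality's difficulty show suppressed responses to the
other's. The default `effect_size` of 2.0 noise SDs per difficulty step
makes the planted structure clearly recoverable at this sample size; 100
parcels is the smallest practical parcellation resolution and keeps
desk-scale runtimes.

What the generator deliberately does **not** emulate: voxel-level
hemodynamics, scanner noise spectra, spatial correlation between parcels,
inter-regional covariance, or any registration/preprocessing artifacts.
Passing tests therefore demonstrate that the pipeline's logic is correct
and calibrated — not that real fMRI data would yield comparable
accuracies. Real parcel matrices enter through `parcel_reduce()` /
`assemble_matrix()`, which average labeled voxels of same-grid statistic
volumes; atlas resampling is intentionally not performed (the caller must
supply a same-grid atlas) to avoid hidden interpolation choices, and an
atlas parcel with no voxels is a hard error rather than a silent zero.

## Classification, selection, and interpretation

The classifier is gradient-boosted trees (xgboost), *called* as a backend
rather than re-implemented: any function honoring the five tuned
hyperparameters plus a seed satisfies the contract. The full grid crosses
`colsample_bytree` {0.1, 0.3, 0.5, 0.7}, `gamma` {0–7}, `learning_rate`
{0.01, 0.04, 0.07, 0.1, 0.13}, `max_depth` {1–6}, and `n_estimators`
{50–300 by 50} — 5760 configurations — evaluated on *identical* stratified
5-fold splits (folds are a per-search constant; re-randomizing per
configuration would confound the comparison). Ties in mean validation
accuracy break to the earlier grid row, making the search fully
deterministic given data, grid, and seed. There is no held-out test set at
this sample size (100 maps), so validation accuracies are optimistically
biased; the reports carry that caveat, and the binomial calibration below
is the guard against over-interpreting them.

Feature importance is the mean absolute Shapley attribution over samples
and classes (per-class attributions are aggregated by mean; sum vs mean
only rescales and does not reorder). Iterative selection trains on the
top-1, top-2, … ranked features with the fixed best configuration and
folds; "improvement" means strictly exceeding the running maximum (a
plateau counts as stalling), and after 5 consecutive non-improvements the
feature count at the latest running maximum is chosen. Iteration *i* uses
exactly *i* features; because peak-iteration-versus-feature-count
conventions differ between reports of this procedure, `peak_offset = 1`
optionally retains one feature beyond the peak. A second grid search then
refines hyperparameters on the chosen columns; with all features selected
this reduces exactly to the baseline search, which is tested.

Pairwise interpretation fits binary models on the four design contrasts
(harder condition = positive class, 50 rows each) using the same selected
columns, and summarizes each included feature's direction of effect: the
sign of the Pearson correlation between a feature's values and its
per-sample attributions toward the positive class — positive =
*elevated* response predicts the harder condition, negative =
*alleviated*. Published summaries of this kind are usually read off
density plots; the correlation sign is the reproducible formalization.
Inclusion requires mean |attribution| > 0 exactly, with no magnitude
cutoff; constant features are excluded with a notice.

## Binomial inference

The null model for a cross-validated accuracy score is
$X \sim \mathrm{Binomial}(n, p)$ with $n$ evaluated maps and $p$ = 1/#classes.
`tail_p(s, n, p)` sums the exact mass from $s+1$ to $n$ in log space (no
normal approximation), and agrees with the independent incomplete-beta
evaluation to $10^{-12}$. The chance-level score is the smallest $s$
whose tail falls below $\alpha$: 32/100 for the 4-class problem at
$\alpha = 0.05$ (tail $p = 0.045$).

A subtlety deserves naming. When an accuracy is the best over $K = 5760$
searched configurations, the conservative null is the maximum of $K$
binomial scores, $1 - (1 - \mathrm{tail})^K$ — yet quoted per-score
probabilities in this literature (0.045 at 32/100; 0.0164 at 32/50)
correspond to the *single*-binomial tail. The package therefore reports
both, clearly labeled, defaulting to the single-binomial tail for
comparability. For the binary contrasts, neither the $\alpha = 0.05$
threshold (31/50) nor the Bonferroni-corrected one (33/50) equals the
sometimes-quoted 32/50; both conventions are computed and reported rather
than guessing which was intended. The Monte-Carlo cross-check of the
max-corrected tail runs at $K = 50$ (where the probability is
informative); at $K = 5760$ the closed form is instead checked against
the independent `pbinom`$^K$ route, since $10^5$ draws of a max-of-5760
would need ~$6 \times 10^8$ variates to confirm a probability
indistinguishable from 1.

## Behavioral analytics

Recognition sensitivity is $d' = z(\mathrm{hit}) - z(\mathrm{FA})$ with
the $1/(2N)$ rule for boundary rates (a hit rate of 1 over $N$ old items
becomes $1 - 1/(2N)$), chosen over the log-linear correction for its
transparency; which correction (if any) a given study used is rarely
stated. TD response curves are fitted by fixed-effects maximum-likelihood
logistic regression (`correct ~ TD × speech difficulty × visual
difficulty`) on nontarget trials. This deliberately replaces the crossed
random-effects GLMM such data receive in full analyses: random-effect
structure selection is not reproducible without raw subject data, and the
fixed-effects fit is sufficient for parameter recovery on synthetic
trials, which is what the package tests. Complete separation is detected
and flagged, with a lightly ridge-penalized refit as fallback.
Brain–behavior association is the Pearson correlation with its exact
t-transform p-value plus the simple regression line.

## Problem sizes, tolerances, and reproducibility

The test and simulation scales are the package's own choices: recovery
and direction properties run 20 replicates at the full study scale (25
subjects, 100 parcels, planted effect 2.0) over an 8-configuration
subgrid drawn from the tested value lists, since re-running all 5760
configurations per replicate adds nothing to a recovery check; the
type-I-error study runs 1000 zero-effect replicates at a reduced scale
(10 subjects = 40 maps, 50 parcels, threshold recomputed for $n = 40$).
Statistical assertions use 3-SE bands for generator round-trips, exact
tolerances ($10^{-9}$, $10^{-12}$) for analytic identities, and the
thresholds stated above for recovery (≥ 80% of planted parcels), direction
(≥ 90% of replicates), and type-I control (≤ 7%).

Every stochastic call takes an explicit seed; `run_all()` derives
per-stage seeds from the global one by fixed offsets and writes a
manifest (package and backend versions, stage seeds, file hashes)
sufficient to re-run bit-identically on the same backend version.

## Known limitations

* Synthetic parcels are independent given the subject offset; real parcel
  covariance will reduce effective dimensionality and can change how many
  redundant features selection retains.
* With strong planted effects, validation accuracy saturates before all
  informative parcels enter the model, so the patience rule correctly
  stops early; recall of redundant informative features is then
  structurally limited (precision remains high).
* The boosting backend's exact results depend on the installed xgboost
  version; the manifest records it.
* The vocoder is offline and mono; sine-carrier vocoding, real-time
  streaming, and SPL-calibrated loudness are out of scope.
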