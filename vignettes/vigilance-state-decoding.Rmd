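---
title: "Methods: temporal-generalization decoding across vigilance states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal-generalization decoding across vigilance states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the generative model, the analysis procedure, the
numerical choices behind each stage, and the package's deliberate
limitations. Code chunks are illustrative and not evaluated when the
vignette is built; the same computations are exercised, with assertions,
by the test suite.

## 1. The analysis in one paragraph

For each subject and vigilance state (WAKE, N1, N2, N3, REM), epoched EEG
with two trial conditions is band-pass filtered, cropped to a decoding
window, decimated, and balanced across conditions. A linear classifier is
fit at every time point on the spatial pattern across channels and
evaluated at every other time point, producing a train-time × test-time
accuracy matrix (temporal generalization matrix, TGM) — within a state by
two-fold stratified cross-validation, across states by direct transfer.
Matched label-permutation runs give per-subject null TGMs. At the group
level, each cell is tested with a two-sided Mann–Whitney U comparing
observed against null accuracies across subjects, with Benjamini–Hochberg
FDR control over the matrix. Classifier weights are converted to
forward-model activation patterns in µV so the recovered topography can be
compared to ground truth.

## 2. Generative model

One epoch of subject $s$, state $g$, condition $c \in \{0,1\}$ is

$$
X_{i}(ch, t) \;=\; A\, j_s\, \mathrm{topo}(ch)\, \mathrm{env}(t)\,
\mathbf{1}[c = c^\*,\, g \in G]
\;+\; \mathrm{pink}(ch, t) \;+\; \mathrm{osc}_g(t) \;+\; \mathrm{white}(ch, t),
$$

in microvolts throughout.

* **Layout.** `channel_layout(n)` places `n` electrodes on the unit disc by
  a sunflower (golden-angle) spiral — an even, deterministic coverage that
  stands in for a real montage at any channel count.
* **Topography.** A Gaussian spatial profile
  $\exp(-d^2 / 2\sigma^2)$ around a configurable center (default
  fronto-central, $(0, 0.45)$, spread $0.4$), normalized to a maximum of 1
  so the effect amplitude is interpretable as the peak-channel amplitude.
* **Envelope.** Zero before stimulus onset; a raised-cosine rise to the
  center of the peak window (default 250–400 ms); a fall back to zero at
  the reversal time (default 0.6 s); then a negative half-sine undershoot
  (default 0.7 of the peak) to the end of the epoch. The maximum absolute
  value is 1. This gives the two properties the analysis is designed to
  detect: a localized early peak and a later polarity reversal of the same
  topography.
* **Condition asymmetry.** The effect is added to *one* condition
  (`target_condition`), mimicking a deviant/standard design. Section 5.4
  discusses a measurable consequence for below-chance generalization.
* **States.** The effect is planted only in the states listed in
  `shared_states` (default N2 and N3). Cross-state generalization therefore
  has an exact ground truth: true between states sharing the effect, absent
  otherwise.
* **Noise.** Three independent components per channel: $1/f^{\alpha}$
  "pink" noise (default exponent 1, SD 5 µV), synthesized by shaping white
  Gaussian spectra in the frequency domain; a state-specific sinusoid with
  random phase per trial (WAKE 10 Hz/4 µV alpha, N1 7 Hz/3 µV theta, N2
  13 Hz/3 µV spindle band, N3 1.5 Hz/15 µV slow waves, REM 6 Hz/2 µV
  theta); and white noise (SD 2 µV). The oscillation makes states
  spectrally distinguishable and makes N3 the hardest test bed, as in real
  sleep EEG.
* **Subject variability.** Per subject, the amplitude is multiplied by a
  log-normal gain (`amp_sdlog`, default 0.3) and the topography center
  jittered by a Gaussian (`center_sd`, default 0.05). Both are drawn from a
  sub-stream keyed on (seed, subject, contrast) only, so a subject's
  effect is *identical across states* — the substantive claim that
  cross-state decoding is meant to detect.
* **Determinism.** Every epoch set is a pure function of
  (config seed, subject, state, contrast). Seeds for sub-streams are
  derived by exact integer arithmetic below $2^{31}$; the caller's RNG
  state is saved and restored around every draw.

Defaults: 16 subjects, 173 channels, 250 Hz, 5 s epochs (−2…3 s), 120
epochs per condition (40 in N1, where real recordings are short), VOICE
effect 5 µV in N2+N3 and NAME effect 2.5 µV in WAKE+N3.

### What the generator does and does not emulate

It reproduces the features the pipeline is sensitive to: 1/f background,
state-specific rhythms, µV scales, a spatially smooth effect with a
realistic time course, subject-level gain variability, and unbalanced
condition counts. It deliberately omits volume-conduction mixing of
multiple correlated sources (channels' *noise* is independent; only the
planted effect is spatially correlated), non-stationarity within an epoch,
artifacts (ocular, muscular, electrode drift), and trial-to-trial latency
jitter. Consequences: spatial covariance of the noise is nearly diagonal,
so the Ledoit–Wolf shrinkage estimate is close to its scaled-identity
target, and decoding accuracies are somewhat higher than typical empirical
values at matched amplitude.

## 3. Preprocessing

`preprocess()` chains four steps; each logs itself on the epoch object so
later stages can check what has already been applied.

* **Band-pass (1–20 Hz).** A zero-phase even-order FIR filter. The design
  is a windowed-sinc (Hamming) low/band-pass with transition width
  $\max(0.25 f_\mathrm{edge}, 2\,\mathrm{Hz})$ and the order capped at a
  third of the epoch length. Application is by FFT convolution with exact
  integer group-delay compensation — linear-phase FIR makes "zero-phase"
  a matter of shifting by half the filter order, without forward-backward
  filtering. This is vectorized over all trials × channels at once.
* **Crop (−0.2…1.0 s).** The *closed* interval, with a half-sample
  tolerance on the endpoints: at 250 Hz this keeps exactly 301 samples.
* **Decimate (×4).** Sample picking (every 4th sample starting at the
  first), yielding 76 samples at 62.5 Hz from the cropped window. Aliasing
  protection comes from the 1–20 Hz band-pass already applied (Nyquist
  after decimation is 31.25 Hz); `decimate_epochs` warns if no prior
  low-pass is on the log.
* **Balance (100/condition).** Seeded subsampling of each condition to
  $\min(n_\mathrm{target}, n_\mathrm{available})$ — so a state with only
  40 + 55 epochs yields 40 + 40, the "use all available" branch. Picked
  indices are sorted, preserving trial order.

At decode time, `condition_trials()` applies a 25 Hz low-pass (when still
meaningful given the sampling rate) and **per-trial standardization**: each
trial is centered and scaled by the standard deviation over all of its
channels × time points (population convention, $n$ in the denominator).
Per-trial scope makes the decoder robust to trial-level gain fluctuations;
the exact scales are stored so patterns can be mapped back to µV
(Section 5.3). Zero-variance trials are given scale 1 and flagged rather
than dropped.

## 4. Decoding

* **Classifier.** L2-penalized logistic regression at each time point,
  minimizing $\sum_i \log(1 + e^{-z_i(w^\top x_i + b)}) + \|w\|^2 / (2C)$
  with $C = 1$ and an unpenalized intercept. The solver is a dozen-line
  Newton–Raphson with step halving, converged when the gradient norm falls
  below $10^{-9}$; it is validated against a brute-force BFGS minimization
  of the same objective to $10^{-6}$. The objective is strictly convex
  (the penalty removes separability issues), so the optimum is unique —
  this solver is the computational core of the package and is written, and
  tested, by hand for that reason.
* **Temporal generalization.** All time points are scored in one matrix
  product; decision values $\ge 0$ (ties included) map to class 1.
* **Within state.** Two-fold stratified cross-validation: the TGM is the
  average of the two fold TGMs. Folds are seeded; trials must be balanced
  first.
* **Across states.** The decoder is fit on *all* balanced train-state
  epochs (no cross-validation — train and test data are disjoint by
  construction) and applied to the full test-state set. This maximizes
  training data where it is legitimate to do so.
* **Permutation null.** The same computation with labels permuted once per
  subject (seeded). One permutation per subject is cheap and gives the
  group test an empirical null *sample* rather than assuming 0.5
  (Section 6).

## 5. Forward model

### 5.1 The transform

Classifier weights are backward-model parameters; a channel can get a
large weight purely for *suppressing* noise. The activation pattern
$a = \Sigma w / (w^\top \Sigma w)$ (with $\Sigma$ the spatial covariance
of the training data at that time point) is the corresponding
forward-model topography. The test suite includes an explicit suppressor
scenario: a pure-noise channel that dominates the weights but is correctly
near zero in the pattern.

### 5.2 Covariance estimation

$\Sigma$ is estimated by Ledoit–Wolf shrinkage toward a scaled identity —
the standard analytic compromise that is well conditioned at any
trials-to-channels ratio, with the shrinkage intensity estimated from the
data. The implementation is validated for positive definiteness when
channels outnumber trials and for convergence to the ML covariance (with
vanishing shrinkage) in the large-sample, non-spherical case. Note that
with spherical truth, shrinkage legitimately stays large — the target is
then correct — which is why the consistency test uses an anisotropic
covariance.

### 5.3 Calibration back to microvolts

With the normalization above, $a$ gives the pattern's *shape*; its scale
is set by requiring that the forward model reproduce the classifier's
class separation: the pattern is scaled by the difference in mean decision
value between the classes, then multiplied channel-wise by the average
per-trial standardization scale. For a linear-Gaussian (LDA-consistent)
generator this recovers the planted class difference in µV.

Two biases are inherent and documented rather than hidden. First, per-trial
*mean removal* subtracts the envelope's time-mean from the effect (≈10 %
for the default undershoot), which scale-only unstandardization cannot
restore. Second, at high SNR the per-trial *scale* itself becomes
class-dependent (effect trials have larger variance), compressing the
recovered amplitude. At moderate SNR (effect amplitude comparable to the
noise SD) recovery is within ~15 %, and this is the tolerance the test
suite asserts; exact µV recovery under per-trial standardization is not a
claim this package makes.

### 5.4 Below-chance generalization is bounded

Training on the pre-reversal lobe and testing on the post-reversal lobe
flips the sign of the effect relative to the decision boundary, driving
accuracy *below* chance — the signature of a polarity-reversed
reactivation. Because the effect is planted on one condition only, the
boundary sits between 0 (non-target class) and $+A$ (target class); a
polarity flip moves the target class across the boundary but leaves the
non-target class mostly correct. Below-chance transfer therefore saturates
around 0.40–0.47 rather than mirroring the above-chance accuracy, and the
tests assert exactly that bounded dip.

A related saturation effect: at high amplitude the within-state TGM is
near ceiling over both lobes, so the location of the *maximum* accuracy
can tie between the early peak and the undershoot. Latency assertions in
the tests therefore locate the maximum within the positive lobe
($t \le 0.55$ s), which is the scientifically meaningful latency.

## 6. Group statistics

* **Per-cell test.** Two-sided Mann–Whitney U of the $n$ observed versus
  the $n$ permutation-null subject accuracies — a second *sample* rather
  than a fixed chance value, so any optimistic bias of the pipeline would
  inflate the null sample too and cancel. The exact distribution is used
  whenever both samples have ≤ 20 values and no ties; the normal
  approximation otherwise. A one-sample Wilcoxon signed-rank alternative
  against 0.5 (`mass_univariate_vs_chance`) is provided for when nulls are
  unavailable; it is lower-powered at small $n$ (its one-sample p-value
  floor is $2/2^n$).
* **FDR family.** BH at $q = 0.01$ over the cells of *one*
  (train state, test state) matrix. Each matrix answers its own scientific
  question ("does training on state A generalize to state B?"), so the
  family is the matrix, not the whole grid.
* **Granularity arithmetic.** The exact two-sided Mann–Whitney p-value
  with $n$ subjects per sample cannot fall below $2/\binom{2n}{n}$
  (e.g. $n=6$: 0.0022; $n=8$: $1.6\times10^{-4}$; $n=10$:
  $1.1\times10^{-5}$). BH over $m$ cells rejects only if some $k$ cells
  have $p_{(k)} \le kq/m$. These two facts jointly determine which cohort
  sizes can show significance over which grid sizes — e.g. over a 76 × 76
  matrix at $q=0.01$, 6 subjects can never reject, 8 subjects need ~90
  jointly saturated cells, 10 subjects only ~7. The cohort sizes in the
  examples and tests are chosen from this arithmetic, not tuned.

## 7. Problem sizes

The package's own choices for its shipped computations, sized so the whole
suite runs comfortably on one core:

* Unit tests run at 62.5 Hz decode resolution with 6–12 channels and
  30–150 epochs per condition; group-level mask-location tests use 10
  subjects (see the granularity arithmetic above).
* The end-to-end chance-level check uses 16 subjects × 3 states with the
  full 250 Hz preprocessing chain at 8 channels.
* False-discovery behaviour is estimated from 500 seeded global-null
  repetitions at reduced scale (6–8 subjects, small grids); with exact
  Mann–Whitney p-value floors above the per-cell BH threshold at that
  scale, the observed any-rejection proportion is expected to be ~0, and
  the assertion is the one that matters scientifically: it must not exceed
  $q$ (plus Monte-Carlo error).
* `scripts/acceptance.R` re-derives the two headline numbers (null-pipeline
  grand-mean accuracy; global-null any-rejection proportion) from scratch
  at the sizes documented in the script.

## 8. Limitations

* Synthetic data only: no readers for vendor EEG formats are included. The
  epoch bundle format (`write_epochs`/`read_epochs`: a JSON sidecar plus a
  plain-CSV array) is a portable interchange representation, not a
  neuroimaging standard.
* Single planted source per contrast; no correlated noise topographies, so
  covariance-based pattern recovery is easier than on real data.
* Two conditions, linear decoders, accuracy as the only metric (balanced
  designs make accuracy and AUC nearly equivalent here).
* The permutation null uses one permutation per subject; cells are tested
  marginally (no cluster-level inference).
* µV pattern recovery is approximate under per-trial standardization
  (Section 5.3).
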