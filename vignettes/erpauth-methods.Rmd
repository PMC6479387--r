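---
title: "Methods: ERP-based identity authentication from oddball EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ERP-based identity authentication from oddball EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpauth)
```

# The problem and the model

`erpauth` implements biometric identity authentication from event-related
potentials (ERPs). A subject watching/hearing a stream of stimuli in an
oddball schedule — per block, 3 *target* sources (their own face and name)
among 12 *non-target* sources — produces a positive stimulus-locked
deflection to the rare targets. The response is idiosyncratic enough to act
as a credential: at registration the system learns what the subject's
target response looks like; at login it asks whether the incoming responses
to the enrolled target sources still look like that. An impostor facing
someone else's target sources shows no systematic target/non-target
difference, which is the physiological premise the whole scheme rests on.

The pipeline is: epoch rejection → (optional ICA) → ensemble averaging →
point-biserial channel/interval selection → statistical features →
correlation-based subset search → bagging ensemble classification →
vote-fraction authentication decision.

# Synthetic sessions

Real oddball recordings of this kind are not publicly deposited, so the
package ships a generator (`simulate_session()`) that reproduces the
*statistical structure* the pipeline assumes, on the 14-channel / 128 Hz
consumer montage:

* **ERP**: a Gaussian bump per channel, default peak 5 µV, latency 300 ms,
  FWHM 150 ms, carried by the eight fronto-parieto-occipital channels
  (F3, F4, FC5, FC6, P7, P8, O1, O2). The shape is a modelling choice: only
  the existence and rough time course (a few hundred ms post-stimulus) of
  the positive target deflection is established, and the default latency
  and width keep the bump inside the 195–703 ms windows typical of this
  paradigm. Rarity scaling uses `amplitude_gain(p) = sqrt(0.2/p)` — any
  strictly decreasing map encodes "rarer targets, larger deflections"; the
  square-root form is gentle and equals 1 at the paradigm's own target
  probability 3/15 = 0.2, so the nominal amplitude is the amplitude under
  the default schedule.
* **Artifacts** (`artifact_model()`): Gaussian background noise (default SD
  10 µV, a realistic single-trial scalp EEG level), a 50 Hz powerline
  sinusoid (2 µV), blink transients — 200 ms half-sines of 120 µV on
  AF3/AF4 with per-epoch probability 0.05 — EMG bursts as 20–60 Hz
  band-limited noise on temporal channels, and an ECG-like periodic
  biphasic spike train (1.1 Hz, 1.5 µV) common to all channels. The artifact
  *classes* are the ones named for this device context; their generative
  forms (half-sine, band-limited burst, spike train) are package choices.
* **Impostors** produce no class-dependent ERP: either nothing at all
  (`impostor_mode = "null"`) or their own deflection attached to stimuli
  independently of the target/non-target schedule (`"misaligned"`).

What the generator does **not** emulate: volume-conducted forward-model
topographies, non-stationary background rhythms (alpha bursts),
habituation/fatigue drift across blocks, or continuous recordings between
epochs. Tests passing on this generator therefore demonstrate the
pipeline's *correctness and statistical behaviour under its own
assumptions*, not field performance on real scalp data.

# Preprocessing

* **Peak-to-peak rejection** (`peak_to_peak_reject()`): an epoch is kept iff
  max−min on *every* reference channel (AF3/AF4, the blink-sensitive
  frontals) stays ≤ 75 µV. The "segment" is the whole epoch — no
  sub-segmentation is defined for epoched data — and requiring all
  references below threshold is the conservative reading. Peak-to-peak is
  immune to slow baseline drift, unlike a plain amplitude threshold.
* **Ensemble averaging** (`ensemble_average()`): consecutive groups of
  n = 8 same-class epochs are averaged; a trailing incomplete group is
  dropped so every averaged trial has equal n (and hence equal noise
  variance). Averaging leaves the deterministic evoked response untouched
  and divides noise variance by n: SNR power gain n, amplitude gain
  √n ≈ 2.8 at n = 8 (`snr_gain()`).
* **ICA** (`ica_decompose()`): fixed-point negentropy maximisation with the
  log-cosh contrast, symmetric decorrelation, tolerance 1e-5, max 500
  iterations, on whitened data. Non-convergence is a warning, never
  silent. Pipeline order is rejection → ICA → averaging: rejection first so
  blinks cannot dominate the decomposition, averaging last so its noise
  model holds. `preprocess_session()` leaves ICA **off by default**:
  automatic component rejection needs reference artifact time courses
  (components correlating |r| > 0.7 with a supplied template are removed,
  `match_artifact_components()`), and ensemble averaging already cancels
  zero-mean structured artifacts. Turn it on when strong ECG/EMG
  contamination must be removed before averaging.

# Channel and interval selection

The discriminability of channel c at sample t is the point-biserial
correlation

$$ r(t) = \sqrt{\frac{n_1 n_2}{n_1+n_2}}\;\frac{m_1(t)-m_2(t)}{S(t)}, $$

where \(m_1, m_2\) are the class means over trials and \(S(t)\) is the
root **total** sum of squared deviations of the pooled trial values from
their pooled mean. With this normalisation r is exactly the Pearson
correlation between the pooled values and 0/1 class labels, hence bounded
in [−1, 1]; reading S as a per-n standard deviation would not bound r, so
the total-sum reading is adopted (the oracle-equivalence test pins this
down to 1e-12). Cells with zero pooled variance are set to 0 and counted.

Channels are ranked by the mean over time of r(t)² (descending, ties broken
by device channel order) and the top k = 8 kept. Within a channel, each
sample's r is superposed-and-averaged with its 5 subsequent samples
(window truncated at the trial end, no padding); a sample qualifies when
this smoothed value strictly exceeds the mean of the **raw** r over the
trial, and maximal qualifying runs of ≥ 25 samples (195 ms at 128 Hz,
ms values truncated to integers: ⌊25·1000/128⌋ = 195) become the channel's
intervals. Comparing the smoothed value against the raw-mean is one of two
defensible readings of the rule; it is the implemented default and the
alternative only shifts run boundaries by a few samples. Channels with no
qualifying interval are dropped from the profile (`drop_empty = TRUE`) so
that feature extraction always has at least one interval per retained
channel.

# Features and subset search

Per (trial, channel), the channel's intervals are concatenated and seven
statistics computed: sample SD (n−1), adjusted Fisher–Pearson skewness
(0 for zero variance), Shannon entropy in bits of a 10-bin equal-width
histogram over [min, max] (0·log 0 := 0; a constant segment has entropy 0),
max, min, mean, median. The entropy estimator and the n−1/adjusted
conventions are package choices — "entropy" and "standard deviation" admit
several estimators and these are the common defaults.

Normalization is per-feature min–max to [0, 1], because its purpose here is
bounding feature magnitude so no feature dominates by scale; training
parameters are stored and reapplied verbatim to test/login data (values
beyond the training range may leave [0, 1]; constant features map to 0 and
are flagged).

Subset selection is best-first search over the subset lattice (single-
feature add/remove moves, backtracking through an open list, stop after 5
consecutive non-improving expansions) under the CFS merit

$$ \mathrm{merit}(S) = \frac{k\,\bar r_{cf}}{\sqrt{k + k(k-1)\,\bar r_{ff}}} $$

with \(\bar r_{cf}\) the mean |point-biserial| of members against the
label and \(\bar r_{ff}\) the mean pairwise |Pearson| among members
(absolute correlations, the standard CFS convention). On data where SD and
median carry the class signal the search recovers {f1, f7} — the
two-feature subset conventionally called Fs2, against Fs1 = all seven.

# Classifiers

All three base learners are written from their defining equations:

* **Gaussian naive Bayes**: class priors from frequencies, per-class
  per-feature Gaussian likelihoods with sample moments, variances floored
  at 1e-9 to survive degenerate features, posteriors normalised in log
  space.
* **Logistic regression**: batch gradient ascent on the *mean*
  log-likelihood from β = 0, learning rate 0.1, 2000 iterations (the mean,
  rather than sum, keeps the step size meaningful across sample sizes).
  Non-finite gradients abort with a message.
* **BP neural network**: one sigmoid hidden layer, two output units
  (target, non-target), online back-propagation, weights uniform(−0.5, 0.5)
  seeded, learning rate 0.3, stop at training MSE ≤ 0.01 or `max_epochs`
  (default 10 000), termination reason recorded. The default hidden size
  ⌊(inputs+2)/2⌋ reproduces the canonical 7-4-2 and 2-2-2 architectures.
  "Training error" is read as the mean squared output error, the usual
  convention when the error's scale is otherwise unspecified.

**Bagging** (`fit_bagging()`): each base learner trains on its own
uniform-with-replacement bootstrap replicate of the training rows;
prediction is the majority of class votes with exact ties broken by a
seeded uniform draw. The default composition is 3 BPNN + 2 LR — an odd
count keeps votes mostly tie-free, and naive Bayes is left out of the
default strong learner (it remains available via `nb_spec()` for
comparisons). Class encoding is target = positive = 1 throughout.

The registration default caps BPNN training at 500 epochs: registration
feature sets are nearly separable, so the 0.01 target is reached long
before, and the cap bounds worst-case fitting time on degenerate inputs.

# Evaluation

Confusion counts follow the four standard definitions; Tpr = TP/(TP+FN),
Fpr = FP/(FP+TN), Acc = (TP+TN)/n. ROC curves sweep the sorted distinct
scores (ties grouped, one operating point per distinct value) and AUC is
trapezoidal — algebraically the Mann–Whitney statistic with half credit for
ties. Ensemble scores for ROC purposes are the fraction of target votes;
NB uses its target posterior, LR its P(y=1), BPNN its target output unit.
Cross-validation is stratified 10-fold with a seeded shuffle (unstratified
folds can lose a class entirely at small n) and reports pooled confusion
counts; per-fold rows are retained in the report.

# Registration, login, benchmark

Registration runs the full pipeline and freezes everything into the
template: selection profile, feature subset, normalization parameters,
stored target features and the trained ensemble. Login applies the stored
parameters only — nothing is re-fitted — which the tests assert by
serializing the template before and after a login and comparing bytes.

In the auth pipeline, epochs are averaged within (class, source-tag)
groups rather than pooled classes, so each averaged trial descends from
one stimulus source and decisions can report per-tag counts. The matching
rule is invented of necessity (no metric is canonical here): each
target-source trial is classified target when at least half of its
per-channel feature rows vote target, and access is granted when the
fraction of target-classified trials reaches the threshold (default 0.5).
This composes naturally with the trial-level classifier, is monotone in
the threshold, and yields the expected high-legal / low-illegal structure.

`benchmark_login()` simulates a population with per-subject ERP
individuality (log-normal per-channel amplitude scatter, SD 0.15; Gaussian
latency jitter, SD 15 ms), registers every subject, and runs genuine and
impostor login attempts (impostor drawn uniformly from the other
subjects). Under a noise-free, well-separated configuration the benchmark
must reach legal rate 1.0 and illegal rate 0.0, and replacing the decision
model with a fair coin drives both rates to 0.5 — both are asserted in the
test suite. Real-data headline rates are *not* targets of this package:
they depend on recordings that are not available.

# Numerical and size choices

* Sample coordinates are 0-based, intervals half-open [start, end); ms
  values are truncated (floored) for display.
* The point-biserial is undefined (error) when all pooled values are
  identical; inside the r-map such cells become 0 and are counted.
* ICA requires more samples than channels and full column rank of the
  requested component space; rank deficiency is an error, non-convergence
  a warning.
* Test and acceptance runs use deliberately compact problem sizes — e.g.
  registration sessions of 16–24 blocks (240–360 epochs), 100-seed channel
  recovery at 20+20 trials, 50-seed subset recovery at 200×7, 20-seed
  bagging comparisons at 200 training rows — chosen so the full suite
  exercises every stage at meaningful statistical power while remaining
  quick on one CPU.

# Known limitations

* The generator's ERP is deterministic within subject up to amplitude and
  latency perturbations between subjects; trial-to-trial latency jitter
  (which smears real averaged ERPs) is not modelled.
* ICA cleaning inside `preprocess_session()` decomposes concatenated
  epochs, which assumes stationary mixing across the session.
* The from-equations classifiers are reference implementations tuned for
  clarity and reproducibility, not speed; very large feature sets would
  want vectorised or compiled training loops.
* With `group_size = 8`, classes keep their 1:4 target:non-target imbalance
  after averaging; the classifiers see that imbalance, as the paradigm
  dictates.
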