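# erpauth

Identity authentication from event-related potentials (ERPs) in oddball
EEG. A subject watching and hearing a stream of stimuli — per block, 3
*target* sources (their own face image and name) among 12 *non-target*
sources — produces a positive stimulus-locked deflection to the rare
targets. `erpauth` turns that response into a biometric credential: it
learns a subject's target response at registration and, at login, decides
whether incoming responses to the enrolled target sources still match.
An impostor facing someone else's target sources shows no systematic
target/non-target difference, which is what the decision exploits.

The package is aimed at researchers prototyping ERP biometrics on
14-channel / 128 Hz consumer EEG (AF3, F7, F3, FC5, T7, P7, O1, O2, P8,
T8, FC6, F4, F8, AF4) and ships a synthetic oddball-session generator, so
every stage is testable without recordings.

## The method

1. **Epoch rejection** — epochs whose peak-to-peak amplitude on the
   blink-sensitive frontals AF3/AF4 exceeds 75 µV are discarded.
2. **Ensemble averaging** — groups of n = 8 same-class epochs are averaged
   (`x̄(t) = (1/n) Σ xᵢ(t)`), leaving the evoked response untouched while
   multiplying the SNR by n (amplitude gain √n ≈ 2.8). Fixed-point ICA
   (log-cosh contrast, symmetric decorrelation) is available for removing
   structured EMG/ECG components.
3. **Channel / interval selection** — the point-biserial discriminability
   `r(t) = √(n₁n₂/(n₁+n₂)) · (m₁(t) − m₂(t)) / S(t)` (equal to the Pearson
   correlation of potentials with 0/1 class labels) is computed per channel
   and sample; channels rank by mean r(t)², and smoothed runs of r above
   its mean lasting ≥ 25 samples (195 ms) become the feature windows.
4. **Features** — per (trial, channel, window): SD, skewness, entropy,
   max, min, mean, median; min–max normalized; the optimal subset found by
   best-first search under the CFS merit `k·r̄_cf / √(k + k(k−1)·r̄_ff)`.
5. **Classification** — from-equations Gaussian naive Bayes, logistic
   regression (batch gradient ascent) and a back-propagation neural network
   (7-4-2 / 2-2-2, training MSE target 0.01), combined as a bagging
   ensemble (default 3 BPNN + 2 LR), each base learner on its own
   bootstrap replicate, majority vote with seeded random tie-break.
6. **Authentication** — a login is granted when the fraction of
   target-source trials classified as target reaches the threshold
   (default 0.5). Tpr/Fpr/Acc, ROC/AUC (trapezoidal ≡ Mann–Whitney) and
   stratified 10-fold CV are provided for evaluation.

## Worked example

```r
library(erpauth)

session <- simulate_session(erp = erp_model(amplitude = 8),
                            art = artifact_model(background_sd = 5),
                            repetitions = 24, seed = 11)
template <- register(session, seed = 3)
template
#> Auth template for S1 - 8 channels, features { f6 }, 264 training rows, training Acc 1.000

template$profile
#> Selection profile: 8 channels
#>   O1   148-406 ms
#>   O2   148-437 ms
#>   FC5  156-406 ms
#>   F3   156-421 ms
#>   F4   125-429 ms
#>   P7   140-429 ms
#>   P8   148-414 ms
#>   FC6  156-414 ms

valid <- simulate_session(erp = erp_model(amplitude = 8),
                          art = artifact_model(background_sd = 5),
                          repetitions = 8, seed = 12)
login(valid, template)
#> Login S1 -> template S1: GRANTED (1.00 of 3 target-source trials; threshold 0.50)

impostor <- simulate_session(erp = erp_model(amplitude = 8),
                             art = artifact_model(background_sd = 5),
                             repetitions = 8, role = "impostor", seed = 13)
login(impostor, template)
#> Login S1 -> template S1: DENIED (0.00 of 3 target-source trials; threshold 0.50)
```

The registered template retains the eight ERP-bearing channels with
windows inside the expected 125–440 ms post-stimulus range, reaches
perfect training accuracy on this well-separated configuration, grants the
genuine login (all 3 target-source trials classified target) and denies
the impostor (none classified target).

A thin command-line front end over the same functions lives at
`inst/cli/erpauth.R` (`simulate`, `register`, `login`, `benchmark`
subcommands; `login` exits 0 on grant, 1 on deny), exchanging sessions as
plain-text epoch bundles (`write_session()` / `read_session()`).

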