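#' ERP response model for the oddball paradigm
#'
#' Describes the stimulus-locked positive deflection evoked by a target
#' stimulus: a smooth unimodal (Gaussian) bump per channel, centred at
#' `latency_ms` with full width at half maximum `width_ms`. The peak amplitude
#' is `amplitude * amplitude_gain(target_probability)`: the rarer the target,
#' the larger the response. The default gain `sqrt(0.2 / p)` is strictly
#' decreasing in p and equals 1 at the paradigm's target probability
#' 3/15 = 0.2, so `amplitude` is the peak in microvolts under the default
#' schedule.
#'
#' @param amplitude Peak amplitude(s) in microvolts; recycled over `channels`.
#' @param channels Channels carrying the deflection (others stay flat).
#' @param latency_ms Peak latency in ms after stimulus onset.
#' @param width_ms Full width at half maximum in ms.
#' @param target_probability Probability of a target stimulus per presentation,
#'   in (0, 1).
#' @param amplitude_gain Strictly decreasing function of the target
#'   probability, scaling the amplitude.
#' @return Object of class `"erp_model"`.
#' @examples
#' erp_model(amplitude = 5)
#' @export
erp_model <- function(amplitude = 5,
                      channels = c("F3", "F4", "FC5", "FC6",
                                   "P7", "P8", "O1", "O2"),
                      latency_ms = 300,
                      width_ms = 150,
                      target_probability = 0.2,
                      amplitude_gain = function(p) sqrt(0.2 / p)) {
  channels <- as.character(channels)
  amplitude <- rep_len(as.numeric(amplitude), length(channels))
  if (any(!is.finite(amplitude)) || any(amplitude < 0))
    stop("amplitudes must be finite and non-negative")
  if (target_probability <= 0 || target_probability >= 1)
    stop("target_probability must lie in (0, 1)")
  if (latency_ms <= 0 || width_ms <= 0)
    stop("latency_ms and width_ms must be positive")
  probs <- c(0.05, 0.2, 0.5, 0.9)
  g <- vapply(probs, amplitude_gain, numeric(1))
  if (any(diff(g) >= 0))
    stop("amplitude_gain must be strictly decreasing in the target probability")
  structure(list(amplitude = stats::setNames(amplitude, channels),
                 channels = channels,
                 latency_ms = as.numeric(latency_ms),
                 width_ms = as.numeric(width_ms),
                 target_probability = as.numeric(target_probability),
                 amplitude_gain = amplitude_gain),
            class = "erp_model")
}

#' @export
print.erp_model <- function(x, ...) {
  cat("ERP model: peak", format(max(x$amplitude)), "uV x gain(p =",
      format(x$target_probability), ") =",
      format(max(x$amplitude) * x$amplitude_gain(x$target_probability)),
      "uV\n  latency", x$latency_ms, "ms, FWHM", x$width_ms, "ms, on",
      paste(x$channels, collapse = " "), "\n")
  invisible(x)
}

#' Artifact and noise model for synthetic epochs
#'
#' Gaussian background noise on every channel, a powerline sinusoid, ocular
#' blink transients on frontal channels (200-ms half-sine), band-limited EMG
#' bursts on temporal/frontal-lateral channels, and an ECG-like periodic spike
#' train common to all channels.
#'
#' @param background_sd Background noise SD, microvolts.
#' @param powerline_freq,powerline_amp Mains frequency (Hz) and amplitude (uV).
#' @param blink_rate Per-epoch blink probability in `[0, 1]`.
#' @param blink_amp Blink peak amplitude (uV).
#' @param blink_channels Channels receiving blinks.
#' @param emg_rate Per-epoch EMG burst probability in `[0, 1]`.
#' @param emg_amp EMG burst SD (uV).
#' @param ecg_rate_hz,ecg_amp ECG spike rate (Hz) and amplitude (uV).
#' @return Object of class `"artifact_model"`.
#' @examples
#' artifact_model(background_sd = 0)  # noise-free
#' @export
artifact_model <- function(background_sd = 10,
                           powerline_freq = 50, powerline_amp = 2,
                           blink_rate = 0.05, blink_amp = 120,
                           blink_channels = c("AF3", "AF4"),
                           emg_rate = 0.05, emg_amp = 8,
                           ecg_rate_hz = 1.1, ecg_amp = 1.5) {
  amps <- c(background_sd, powerline_amp, blink_amp, emg_amp, ecg_amp)
  if (any(!is.finite(amps)) || any(amps < 0))
    stop("amplitudes and background_sd must be finite and non-negative")
  if (blink_rate < 0 || blink_rate > 1 || emg_rate < 0 || emg_rate > 1)
    stop("blink_rate and emg_rate must lie in [0, 1]")
  if (powerline_freq < 0 || ecg_rate_hz < 0)
    stop("frequencies must be non-negative")
  structure(list(background_sd = background_sd,
                 powerline_freq = powerline_freq,
                 powerline_amp = powerline_amp,
                 blink_rate = blink_rate, blink_amp = blink_amp,
                 blink_channels = as.character(blink_channels),
                 emg_rate = emg_rate, emg_amp = emg_amp,
                 ecg_rate_hz = ecg_rate_hz, ecg_amp = ecg_amp),
            class = "artifact_model")
}

#' Deterministic ERP template for one channel
#'
#' Evaluates the Gaussian deflection of an [erp_model()] on one channel of a
#' device, at the device's sample grid (sample s corresponds to
#' `s * 1000 / sampling_rate` ms, 0-based). Values below 1e-4 of the peak are
#' clamped to zero so the bump has finite support; channels outside the
#' model's channel set give an all-zero vector.
#'
#' @param erp An [erp_model()].
#' @param channel Channel label.
#' @param device A [device_spec()].
#' @return Numeric vector of length `device$epoch_length` (microvolts).
#' @examples
#' w <- erp_waveform(erp_model(), "P7", device_spec())
#' which.max(w)  # ~ round(300 * 128 / 1000)
#' @export
erp_waveform <- function(erp, channel, device = device_spec()) {
  stopifnot(inherits(erp, "erp_model"), inherits(device, "device_spec"))
  if (!channel %in% device$channel_labels)
    stop("unknown channel: ", channel)
  n <- device$epoch_length
  if (!channel %in% erp$channels) return(numeric(n))
  fs <- device$sampling_rate
  if (erp$latency_ms + erp$width_ms > (n - 1) * 1000 / fs)
    stop("latency + width does not fit inside the epoch")
  peak <- erp$amplitude[[channel]] *
    erp$amplitude_gain(erp$target_probability)
  if (peak == 0) return(numeric(n))
  t_ms <- (seq_len(n) - 1) * 1000 / fs
  sigma <- erp$width_ms / (2 * sqrt(2 * log(2)))  # FWHM -> sd
  w <- peak * exp(-0.5 * ((t_ms - erp$latency_ms) / sigma)^2)
  w[w < 1e-4 * peak] <- 0
  w
}

# Full channels x samples ERP template for a device (zero rows off the ERP
# channel set).
erp_template <- function(erp, device) {
  n <- device$epoch_length
  out <- matrix(0, length(device$channel_labels), n,
                dimnames = list(device$channel_labels, NULL))
  for (ch in intersect(erp$channels, device$channel_labels))
    out[ch, ] <- erp_waveform(erp, ch, device)
  out
}

# 200-ms half-sine blink transient starting at `onset` (0-based sample).
blink_transient <- function(n_samples, onset, amp, fs, width_ms = 200) {
  len <- max(2L, round(width_ms * fs / 1000))
  s <- sin(pi * seq(0, 1, length.out = len))
  w <- amp * s / max(s)       # peak exactly at amp regardless of the grid
  out <- numeric(n_samples)
  idx <- onset + seq_len(len)            # 1-based indices onset+1 ...
  keep <- idx <= n_samples
  out[idx[keep]] <- w[keep]
  out
}

# Band-limited (20-60 Hz) EMG burst of `len` samples, sd `amp`.
emg_burst <- function(len, amp, fs) {
  ny <- fs / 2
  hi <- min(60, ny * 0.95)
  bf <- signal::butter(4, c(20 / ny, hi / ny), type = "pass")
  x <- as.numeric(signal::filtfilt(bf, stats::rnorm(len + 64)))
  x <- x[33:(32 + len)]
  s <- stats::sd(x)
  if (s > 0) x <- x * amp / s
  x
}

# Periodic biphasic spike train (ECG-like), `rate_hz` beats/s, given phase.
ecg_train <- function(n_samples, rate_hz, amp, fs, phase = 0) {
  out <- numeric(n_samples)
  if (rate_hz <= 0 || amp <= 0) return(out)
  period <- fs / rate_hz
  spike <- amp * c(0.25, -0.5, 1, -0.5, 0.25)
  starts <- seq(1 + phase, n_samples, by = period)
  for (s in round(starts)) {
    idx <- s + seq_along(spike) - 1L
    keep <- idx >= 1 & idx <= n_samples
    out[idx[keep]] <- out[idx[keep]] + spike[keep]
  }
  out
}

#' Simulate an oddball-paradigm EEG session
#'
#' Generates `repetitions` stimulus blocks; each block presents the subject's
#' 3 target sources and 12 non-target sources once each, in random order
#' (target probability 3/15 = 0.2). Every epoch is background noise plus the
#' configured artifacts; for a `"valid"` subject the target-stimulus epochs
#' additionally carry the ERP deflection. An `"impostor"` produces no
#' class-dependent difference whatsoever: either no ERP at all
#' (`impostor_mode = "null"`, the default) or their own ERP attached to
#' stimuli independently of the target/non-target class
#' (`impostor_mode = "misaligned"`).
#'
#' @param device A [device_spec()].
#' @param erp An [erp_model()].
#' @param art An [artifact_model()].
#' @param repetitions Number of 15-stimulus blocks (>= 1).
#' @param role `"valid"` or `"impostor"`.
#' @param seed Integer seed; identical seeds give bit-identical sessions.
#' @param subject_id Subject identifier stored on every epoch.
#' @param impostor_mode How an impostor responds (see above).
#' @return Object of class `"erp_session"`: a list with `epochs` (each epoch a
#'   list with `data` channels x samples, `stimulus_class`, `subject_id`,
#'   `source_tag`, `epoch_index`), `device`, `paradigm`, `role`, `subject_id`,
#'   `seed`.
#' @examples
#' s <- simulate_session(repetitions = 2, seed = 1)
#' table(vapply(s$epochs, `[[`, "", "stimulus_class"))
#' @export
simulate_session <- function(device = device_spec(),
                             erp = erp_model(),
                             art = artifact_model(),
                             repetitions = 10,
                             role = c("valid", "impostor"),
                             seed = NULL,
                             subject_id = "S1",
                             impostor_mode = c("null", "misaligned")) {
  role <- match.arg(role)
  impostor_mode <- match.arg(impostor_mode)
  stopifnot(inherits(device, "device_spec"), inherits(erp, "erp_model"),
            inherits(art, "artifact_model"))
  if (!is.numeric(repetitions) || repetitions < 1)
    stop("repetitions must be a positive count")
  repetitions <- as.integer(repetitions)
  n_ch <- length(device$channel_labels)
  n_s <- device$epoch_length
  fs <- device$sampling_rate
  template <- erp_template(erp, device)
  tvec <- (seq_len(n_s) - 1) / fs

  with_seed(seed, {
    epochs <- vector("list", repetitions * 15L)
    idx <- 0L
    for (b in seq_len(repetitions)) {
      tags <- c(paste0("T", 1:3), sprintf("N%02d", 1:12))
      classes <- c(rep("target", 3), rep("nontarget", 12))
      ord <- sample.int(15L)
      # misaligned impostor ERP: 3 stimuli per block, drawn independently of
      # the class schedule
      mis <- if (role == "impostor" && impostor_mode == "misaligned")
        sample.int(15L, 3L) else integer(0)
      for (j in seq_len(15L)) {
        k <- ord[j]
        x <- matrix(stats::rnorm(n_ch * n_s, sd = art$background_sd),
                    n_ch, n_s,
                    dimnames = list(device$channel_labels, NULL))
        if (art$powerline_amp > 0 && art$powerline_freq > 0) {
          ph <- stats::runif(1, 0, 2 * pi)
          pl <- art$powerline_amp * sin(2 * pi * art$powerline_freq * tvec + ph)
          x <- sweep(x, 2, pl, `+`)
        }
        if (art$ecg_amp > 0 && art$ecg_rate_hz > 0) {
          ecg <- ecg_train(n_s, art$ecg_rate_hz, art$ecg_amp, fs,
                           phase = stats::runif(1, 0, fs / art$ecg_rate_hz))
          x <- sweep(x, 2, ecg, `+`)
        }
        if (art$blink_amp > 0 && stats::runif(1) < art$blink_rate) {
          onset <- sample.int(max(1L, n_s - round(0.2 * fs)), 1L) - 1L
          bl <- blink_transient(n_s, onset, art$blink_amp, fs)
          bch <- intersect(art$blink_channels, device$channel_labels)
          x[bch, ] <- sweep(x[bch, , drop = FALSE], 2, bl, `+`)
        }
        if (art$emg_amp > 0 && stats::runif(1) < art$emg_rate) {
          len <- min(n_s, round(0.25 * fs))
          onset <- sample.int(n_s - len + 1L, 1L)
          ch <- sample(c("T7", "T8", "F7", "F8"), 1L)
          x[ch, onset:(onset + len - 1L)] <-
            x[ch, onset:(onset + len - 1L)] + emg_burst(len, art$emg_amp, fs)
        }
        has_erp <- (role == "valid" && classes[k] == "target") ||
          (role == "impostor" && j %in% mis)
        if (has_erp) x <- x + template
        idx <- idx + 1L
        epochs[[idx]] <- list(data = x,
                              stimulus_class = classes[k],
                              subject_id = subject_id,
                              source_tag = tags[k],
                              epoch_index = idx)
      }
    }
    structure(list(epochs = epochs,
                   device = device,
                   paradigm = list(n_target_sources = 3L,
                                   n_nontarget_sources = 12L,
                                   repetitions = repetitions),
                   role = role,
                   subject_id = subject_id,
                   seed = seed),
              class = "erp_session")
  })
}

#' @export
print.erp_session <- function(x, ...) {
  cl <- vapply(x$epochs, `[[`, "", "stimulus_class")
  cat("Oddball EEG session:", x$subject_id, sprintf("(%s)", x$role), "-",
      length(x$epochs), "epochs in", x$paradigm$repetitions, "blocks (",
      sum(cl == "target"), "target /", sum(cl == "nontarget"),
      "non-target )\n")
  print(x$device)
  invisible(x)
}

#' Stimulus classes of a session's epochs
#' @param session An [simulate_session()] result.
#' @return Character vector, one of `"target"`/`"nontarget"` per epoch.
#' @export
session_classes <- function(session) {
  vapply(session$epochs, `[[`, "", "stimulus_class")
}

#' Add an ocular blink transient to an epoch
#'
#' Adds a slow, high-amplitude 200-ms half-sine deflection (the shape of an
#' eye blink as seen by frontal electrodes) to the named channels, so the
#' epoch can exercise the peak-to-peak rejection rule. `amp = 0` leaves the
#' epoch unchanged.
#'
#' @param epoch An epoch (list with a channels x samples `data` matrix).
#' @param amp Peak amplitude in microvolts (>= 0).
#' @param channels Channels to contaminate; must exist in the epoch.
#' @param onset 0-based onset sample within the epoch.
#' @param sampling_rate Hz, used to size the 200-ms transient.
#' @return The modified epoch.
#' @export
inject_blink <- function(epoch, amp = 120, channels = c("AF3", "AF4"),
                         onset = 0L, sampling_rate = 128) {
  stopifnot(is.matrix(epoch$data))
  if (amp < 0) stop("amp must be non-negative")
  if (amp == 0) return(epoch)
  if (!all(channels %in% rownames(epoch$data)))
    stop("unknown channel(s): ",
         paste(setdiff(channels, rownames(epoch$data)), collapse = ", "))
  n <- ncol(epoch$data)
  if (onset < 0 || onset >= n) stop("onset outside epoch")
  bl <- blink_transient(n, onset, amp, sampling_rate)
  epoch$data[channels, ] <-
    sweep(epoch$data[channels, , drop = FALSE], 2, bl, `+`)
  epoch
}
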