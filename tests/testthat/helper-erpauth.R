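# Shared fixtures, all generated in code.

# Artifact model with everything silenced except (optionally) background noise.
quiet_artifacts <- function(background_sd = 0) {
  artifact_model(background_sd = background_sd, powerline_amp = 0,
                 blink_rate = 0, blink_amp = 0, emg_rate = 0, emg_amp = 0,
                 ecg_rate_hz = 0, ecg_amp = 0)
}

# A bare trial/epoch-like object as the selection and feature modules expect.
make_trial <- function(data, class = "target", tag = NULL) {
  out <- list(data = data, stimulus_class = class)
  if (!is.null(tag)) out$source_tag <- tag
  out
}

# Full-montage channels x samples ERP template matrix.
template_matrix <- function(erp = erp_model(), device = device_spec()) {
  t(sapply(device$channel_labels, erp_waveform, erp = erp, device = device))
}

# n1 target + n2 non-target trials: template + iid noise on targets.
noisy_trials <- function(n1, n2, template, sd = 1) {
  labels <- rownames(template)
  mk <- function(cl) {
    x <- matrix(stats::rnorm(length(template), sd = sd), nrow(template),
                ncol(template), dimnames = list(labels, NULL))
    if (cl == "target") x <- x + template
    make_trial(x, cl)
  }
  c(lapply(seq_len(n1), function(i) mk("target")),
    lapply(seq_len(n2), function(i) mk("nontarget")))
}

# Single-interval selection profile over the given channels.
flat_profile <- function(channels, start = 20, end = 70,
                         sampling_rate = 128, T = 128) {
  iv <- data.frame(start = start, end = end,
                   start_ms = as.integer(floor(start * 1000 / sampling_rate)),
                   end_ms = as.integer(floor(end * 1000 / sampling_rate)))
  structure(list(channels = channels,
                 intervals = stats::setNames(
                   replicate(length(channels), iv, simplify = FALSE),
                   channels),
                 sampling_rate = sampling_rate, T = T),
            class = "selection_profile")
}

# Two-class Gaussian feature data with a shift on the named columns.
gaussian_features <- function(n, p = 7, shift_cols = character(0),
                              shift = 1.2) {
  y <- rep(c("target", "nontarget"), length.out = n)
  x <- sapply(seq_len(p), function(j) stats::rnorm(n))
  colnames(x) <- paste0("f", seq_len(p))
  for (cl in shift_cols) x[, cl] <- x[, cl] + shift * (y == "target")
  list(x = x, y = y)
}

# Fair-coin label vector helper for confusion fixtures.
lab <- function(...) c(...)
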