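#' Electrode labels of the 14-channel consumer headset
#'
#' Canonical channel order of the Emotiv EPOC+ montage used throughout the
#' package: frontal (AF3, F7, F3, FC5), temporal (T7), parietal/occipital
#' (P7, O1, O2, P8), temporal (T8) and frontal (FC6, F4, F8, AF4).
#'
#' @format Character vector of length 14.
#' @export
EMOTIV_CHANNELS <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1", "O2",
                     "P8", "T8", "FC6", "F4", "F8", "AF4")

#' Describe the recording device
#'
#' A device spec fixes the channel montage, the sampling rate and the epoch
#' length (number of post-stimulus samples per epoch). Defaults match the
#' 14-channel headset sampled at 128 Hz with 1-s epochs.
#'
#' @param channel_labels Ordered channel names; must be a permutation of
#'   [EMOTIV_CHANNELS].
#' @param sampling_rate Sampling frequency in Hz.
#' @param epoch_length Samples per epoch (>= 32).
#' @return An object of class `"device_spec"`.
#' @examples
#' device_spec()
#' @export
device_spec <- function(channel_labels = EMOTIV_CHANNELS,
                        sampling_rate = 128,
                        epoch_length = 128) {
  channel_labels <- as.character(channel_labels)
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (!setequal(channel_labels, EMOTIV_CHANNELS))
    stop("channel labels must be the 14 Emotiv EPOC+ electrode names")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("sampling_rate must be a positive number")
  if (!is.numeric(epoch_length) || length(epoch_length) != 1L ||
      epoch_length < 32)
    stop("epoch_length must be at least 32 samples")
  structure(list(channel_labels = channel_labels,
                 sampling_rate = as.numeric(sampling_rate),
                 epoch_length = as.integer(epoch_length)),
            class = "device_spec")
}

#' @export
print.device_spec <- function(x, ...) {
  cat("EEG device spec:", length(x$channel_labels), "channels,",
      x$sampling_rate, "Hz,", x$epoch_length, "samples/epoch\n")
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}
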