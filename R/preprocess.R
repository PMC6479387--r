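#' Reject blink-contaminated epochs by peak-to-peak amplitude
#'
#' An epoch is kept iff on *every* reference channel the peak-to-peak
#' amplitude (max minus min over the whole epoch) does not exceed the
#' threshold. Peak-to-peak detection is robust to slow baseline drift, unlike
#' a plain peak-amplitude rule. Default references are the blink-sensitive
#' frontal channels AF3/AF4 and the conventional 75 uV threshold.
#'
#' @param session An [simulate_session()] session.
#' @param ref_channels Reference channels used for detection.
#' @param threshold Rejection threshold in microvolts.
#' @return List with `session` (kept epochs, original `epoch_index` values
#'   preserved) and `report`, a `"rejection_report"` holding `kept`,
#'   `rejected` (epoch indices), the per-epoch per-reference `ptp` matrix and
#'   the `threshold`.
#' @examples
#' s <- simulate_session(repetitions = 2, seed = 1)
#' peak_to_peak_reject(s)$report
#' @export
peak_to_peak_reject <- function(session, ref_channels = c("AF3", "AF4"),
                                threshold = 75) {
  stopifnot(inherits(session, "erp_session"))
  if (length(session$epochs) == 0L) stop("empty session")
  labels <- session$device$channel_labels
  if (!all(ref_channels %in% labels))
    stop("unknown reference channel(s): ",
         paste(setdiff(ref_channels, labels), collapse = ", "))
  ptp <- t(vapply(session$epochs, function(e) {
    apply(e$data[ref_channels, , drop = FALSE], 1,
          function(x) max(x) - min(x))
  }, numeric(length(ref_channels))))
  colnames(ptp) <- ref_channels
  idx <- vapply(session$epochs, `[[`, 0L, "epoch_index")
  rownames(ptp) <- idx
  keep <- apply(ptp <= threshold, 1, all)
  out <- session
  out$epochs <- session$epochs[keep]
  report <- structure(list(kept = idx[keep], rejected = idx[!keep],
                           ptp = ptp, threshold = threshold),
                      class = "rejection_report")
  list(session = out, report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat("Peak-to-peak rejection @", x$threshold, "uV on",
      paste(colnames(x$ptp), collapse = "/"), ":",
      length(x$kept), "kept,", length(x$rejected), "rejected\n")
  invisible(x)
}

#' Ensemble-average same-class epochs
#'
#' Partitions the epochs, in their given order, into consecutive groups of
#' `group_size` (a trailing incomplete group is dropped) and returns the
#' pointwise mean of each group. Averaging n epochs leaves the deterministic
#' evoked response unchanged while shrinking zero-mean noise SD by sqrt(n);
#' see [snr_gain()].
#'
#' @param epochs List of epochs (or averaged trials) of a single stimulus
#'   class, each with a `data` matrix of identical shape.
#' @param group_size Number of epochs per average (n of the SNR relation).
#' @return List of `"erp_trial"` objects: `data` (mean matrix), `n_averaged`,
#'   `members` (epoch indices averaged), `stimulus_class`.
#' @export
ensemble_average <- function(epochs, group_size = 8) {
  if (group_size < 1) stop("group_size must be >= 1")
  group_size <- as.integer(group_size)
  n <- length(epochs)
  if (n < group_size) stop("fewer epochs than one averaging group")
  cls <- unique(vapply(epochs, `[[`, "", "stimulus_class"))
  if (length(cls) != 1L) stop("epochs must share one stimulus class")
  dims <- vapply(epochs, function(e) dim(e$data), integer(2))
  if (any(dims != dims[, 1])) stop("epochs must share one shape")
  n_groups <- n %/% group_size
  lapply(seq_len(n_groups), function(g) {
    members <- ((g - 1L) * group_size + 1L):(g * group_size)
    acc <- Reduce(`+`, lapply(epochs[members], `[[`, "data")) / group_size
    structure(list(data = acc, n_averaged = group_size,
                   members = vapply(epochs[members], function(e)
                     as.integer(e$epoch_index %||% NA_integer_), 1L),
                   stimulus_class = cls),
              class = "erp_trial")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal-to-noise gain of n-fold ensemble averaging
#'
#' Averaging n epochs divides the noise variance by n: the SNR power gain is
#' n and the amplitude (SD) gain is sqrt(n) - e.g. 2.8 for the customary
#' n = 8.
#'
#' @param n Number of averaged epochs (>= 1).
#' @return Named numeric `c(power_gain = n, amplitude_gain = sqrt(n))`.
#' @examples
#' round(snr_gain(8)["amplitude_gain"], 1)  # 2.8
#' @export
snr_gain <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  c(power_gain = as.numeric(n), amplitude_gain = sqrt(n))
}

#' Run the full epoch-domain preprocessing pipeline
#'
#' Order: peak-to-peak rejection, then (optionally) ICA cleaning of the
#' concatenated surviving epochs, then per-class ensemble averaging.
#' Rejection comes first so blinks cannot dominate the ICA decomposition;
#' averaging comes last so its noise model (mean of n independent epochs)
#' holds. ICA is off by default: automatic component rejection needs
#' caller-supplied artifact templates (time courses whose absolute
#' correlation with a component marks it for removal) and ensemble averaging
#' already cancels zero-mean structured artifacts.
#'
#' @param session An [simulate_session()] session.
#' @param ref_channels,threshold Passed to [peak_to_peak_reject()].
#' @param group_size Averaging group size.
#' @param by_tag Average within (class, source tag) groups instead of pooled
#'   classes; used by the authentication layer so decisions can be reported
#'   per source tag.
#' @param ica Run ICA cleaning between rejection and averaging.
#' @param ica_templates Optional list of artifact template time courses (each
#'   of length epochs x samples after rejection); components correlating with
#'   any template beyond `ica_cor` are removed.
#' @param ica_reject Manual component indices to remove (in addition).
#' @param ica_cor Absolute-correlation threshold for automatic rejection.
#' @param seed Seed for the ICA initialisation.
#' @return List with `trials` (list of `"erp_trial"`), `report` (rejection
#'   report) and `ica` (the decomposition and removed components, or NULL).
#' @export
preprocess_session <- function(session, ref_channels = c("AF3", "AF4"),
                               threshold = 75, group_size = 8,
                               by_tag = FALSE,
                               ica = FALSE, ica_templates = NULL,
                               ica_reject = integer(0), ica_cor = 0.7,
                               seed = NULL) {
  pr <- peak_to_peak_reject(session, ref_channels, threshold)
  kept <- pr$session$epochs
  if (length(kept) == 0L) stop("all epochs rejected")
  ica_info <- NULL
  if (isTRUE(ica)) {
    n_s <- ncol(kept[[1]]$data)
    x <- do.call(cbind, lapply(kept, `[[`, "data"))
    dec <- ica_decompose(x, seed = seed)
    reject <- as.integer(ica_reject)
    if (!is.null(ica_templates))
      reject <- union(reject,
                      match_artifact_components(dec, ica_templates, ica_cor))
    if (length(reject)) {
      clean <- ica_clean(dec, reject)
      for (i in seq_along(kept))
        kept[[i]]$data <- clean[, ((i - 1L) * n_s + 1L):(i * n_s),
                                drop = FALSE]
    }
    ica_info <- list(decomposition = dec, rejected_components = reject)
  }
  cls <- vapply(kept, `[[`, "", "stimulus_class")
  groups <- if (by_tag)
    split(kept, paste(cls, vapply(kept, `[[`, "", "source_tag")))
  else split(kept, cls)
  groups <- Filter(function(g) length(g) >= group_size, groups)
  if (length(groups) == 0L) stop("no class group reaches one full average")
  trials <- unlist(lapply(groups, function(g) {
    trs <- ensemble_average(g, group_size = group_size)
    if (by_tag)
      trs <- lapply(trs, function(tr) {
        tr$source_tag <- g[[1]]$source_tag
        tr
      })
    trs
  }), recursive = FALSE)
  names(trials) <- NULL
  list(trials = trials, report = pr$report, ica = ica_info)
}
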