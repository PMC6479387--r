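#' Point-biserial correlation between two groups of values
#'
#' The discriminability statistic used for channel and interval screening:
#' `r = sqrt(n1 n2 / (n1 + n2)) * (m1 - m2) / S`, with `m1`, `m2` the group
#' means and `S` the root *total* sum of squared deviations of the pooled
#' values from the pooled mean. With this normalisation r is exactly the
#' Pearson correlation between the pooled values and 0/1 class labels, hence
#' bounded in `[-1, 1]`.
#'
#' @param target_values Numeric vector (class 1), length >= 2.
#' @param nontarget_values Numeric vector (class 0), length >= 2.
#' @return The correlation r.
#' @examples
#' point_biserial(c(1, 3), c(0, 2))  # 0.4472
#' @export
point_biserial <- function(target_values, nontarget_values) {
  n1 <- length(target_values); n2 <- length(nontarget_values)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per class")
  pooled <- c(target_values, nontarget_values)
  S <- sqrt(sum((pooled - mean(pooled))^2))
  if (S == 0)
    stop("point-biserial undefined: all pooled values are identical")
  sqrt(n1 * n2 / (n1 + n2)) *
    (mean(target_values) - mean(nontarget_values)) / S
}

#' Channel x time discriminability map
#'
#' Computes the point-biserial statistic at every (channel, sample) cell over
#' a set of labelled trials: how well the potential at that cell separates
#' target from non-target trials. Cells where the pooled variance is zero are
#' set to 0 and counted in `n_undefined`.
#'
#' @param trials List of trials (e.g. [ensemble_average()] output), each with
#'   a channels x samples `data` matrix and a `stimulus_class`.
#' @return Object of class `"discriminability_profile"`: `r_map` (channels x
#'   samples), `n1`, `n2`, `T`, `channel_msq` (per-channel mean of r(t)^2),
#'   `n_undefined`, `channel_labels`.
#' @export
discriminability_profile <- function(trials) {
  cls <- vapply(trials, `[[`, "", "stimulus_class")
  n1 <- sum(cls == "target"); n2 <- sum(cls == "nontarget")
  if (n1 < 2 || n2 < 2)
    stop("need at least 2 trials of each class (got ", n1, " target, ",
         n2, " non-target)")
  d <- dim(trials[[1]]$data)
  mats <- lapply(trials, `[[`, "data")
  if (any(vapply(mats, function(m) any(dim(m) != d), logical(1))))
    stop("trials must share one shape")
  sum_t <- Reduce(`+`, mats[cls == "target"])
  sum_n <- Reduce(`+`, mats[cls == "nontarget"])
  sum_sq <- Reduce(`+`, lapply(mats, function(m) m * m))
  n <- n1 + n2
  m1 <- sum_t / n1
  m2 <- sum_n / n2
  pm <- (sum_t + sum_n) / n
  ss <- sum_sq - n * pm * pm
  ss[ss < 0] <- 0                     # numerical guard
  r <- sqrt(n1 * n2 / n) * (m1 - m2) / sqrt(ss)
  undef <- !is.finite(r)
  r[undef] <- 0
  dimnames(r) <- dimnames(mats[[1]])
  structure(list(r_map = r, n1 = n1, n2 = n2, T = d[2],
                 channel_msq = rowMeans(r^2),
                 n_undefined = sum(undef),
                 channel_labels = rownames(mats[[1]])),
            class = "discriminability_profile")
}

#' @export
print.discriminability_profile <- function(x, ...) {
  cat("Discriminability profile:", nrow(x$r_map), "channels x", x$T,
      "samples (n1 =", x$n1, ", n2 =", x$n2, ")\n")
  msq <- sort(x$channel_msq, decreasing = TRUE)
  cat("  top channels by mean-square r(t):",
      paste(sprintf("%s=%.3f", names(msq)[seq_len(min(4, length(msq)))],
                    msq[seq_len(min(4, length(msq)))]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Rank channels by mean-square discriminability
#'
#' Channels are sorted by the mean over time of r(t)^2, descending, and the
#' top k are returned. Ties are broken by the canonical device channel order
#' (the row order of the r map).
#'
#' @param profile A [discriminability_profile()].
#' @param k Number of channels to retain.
#' @return Character vector of k channel labels, best first.
#' @export
rank_channels <- function(profile, k = 8) {
  stopifnot(inherits(profile, "discriminability_profile"))
  msq <- profile$channel_msq
  if (k < 1) stop("k must be >= 1")
  if (k > length(msq)) stop("k exceeds the channel count")
  ord <- order(-msq)                  # stable: ties keep device order
  names(msq)[ord][seq_len(k)]
}

#' Extract discriminative time intervals from one channel's r(t)
#'
#' Each sample's r value is superposed-and-averaged with its subsequent
#' `smooth_ahead` samples (window truncated at the trial end); a sample
#' qualifies when this smoothed value strictly exceeds the mean of the raw
#' r(t) over the whole trial. Maximal runs of qualifying samples lasting at
#' least `min_run` samples (25 samples = 195 ms at 128 Hz) are returned.
#'
#' @param r_row Numeric vector, r(t) for one channel.
#' @param smooth_ahead Number of subsequent samples in the smoothing window.
#' @param min_run Minimum run length in samples.
#' @param sampling_rate Hz, for the ms conversion (ms values are truncated to
#'   integers, matching 25 samples -> floor(25 * 1000/128) = 195 ms).
#' @return data.frame with 0-based half-open sample intervals (`start`,
#'   `end`) and their ms equivalents (`start_ms`, `end_ms`); zero rows when
#'   no run qualifies.
#' @export
select_intervals <- function(r_row, smooth_ahead = 5, min_run = 25,
                             sampling_rate = 128) {
  T <- length(r_row)
  if (T == 0) stop("empty input")
  if (T < min_run)
    return(data.frame(start = integer(0), end = integer(0),
                      start_ms = integer(0), end_ms = integer(0)))
  smoothed <- vapply(seq_len(T), function(t)
    mean(r_row[t:min(T, t + smooth_ahead)]), numeric(1))
  qual <- smoothed > mean(r_row)
  runs <- rle(qual)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- runs$values & runs$lengths >= min_run
  start0 <- starts[ok] - 1L           # 0-based
  end0 <- ends[ok]                    # half-open
  data.frame(start = start0, end = end0,
             start_ms = as.integer(floor(start0 * 1000 / sampling_rate)),
             end_ms = as.integer(floor(end0 * 1000 / sampling_rate)))
}

#' Build a channel/interval selection profile
#'
#' Ranks channels on a discriminability profile and extracts each retained
#' channel's discriminative time intervals. Channels whose r(t) yields no
#' qualifying interval are dropped (with `drop_empty = TRUE`, the default),
#' so every retained channel contributes at least one interval to feature
#' extraction.
#'
#' @param trials Labelled trials, as for [discriminability_profile()].
#' @param k Number of channels to retain before interval screening.
#' @param smooth_ahead,min_run See [select_intervals()].
#' @param sampling_rate Hz.
#' @param drop_empty Drop channels without qualifying intervals.
#' @return Object of class `"selection_profile"`: `channels` (ordered labels)
#'   and `intervals` (named list of interval data frames), plus
#'   `sampling_rate` and `T`.
#' @export
select_profile <- function(trials, k = 8, smooth_ahead = 5, min_run = 25,
                           sampling_rate = 128, drop_empty = TRUE) {
  prof <- discriminability_profile(trials)
  chans <- rank_channels(prof, k)
  ints <- lapply(chans, function(ch)
    select_intervals(prof$r_map[ch, ], smooth_ahead, min_run, sampling_rate))
  names(ints) <- chans
  if (drop_empty) {
    keep <- vapply(ints, nrow, 0L) > 0L
    chans <- chans[keep]
    ints <- ints[keep]
  }
  structure(list(channels = chans, intervals = ints,
                 sampling_rate = sampling_rate, T = prof$T),
            class = "selection_profile")
}

#' @export
print.selection_profile <- function(x, ...) {
  cat("Selection profile:", length(x$channels), "channels\n")
  for (ch in x$channels) {
    iv <- x$intervals[[ch]]
    cat(sprintf("  %-4s %s\n", ch,
                paste(sprintf("%d-%d ms", iv$start_ms, iv$end_ms),
                      collapse = ", ")))
  }
  invisible(x)
}
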