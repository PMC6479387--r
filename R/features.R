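FEATURE_IDS <- c("f1", "f2", "f3", "f4", "f5", "f6", "f7")

#' Seven statistical features of an amplitude segment
#'
#' f1 sample standard deviation (n-1 denominator), f2 adjusted
#' Fisher-Pearson skewness (0 for zero-variance input), f3 Shannon entropy in
#' bits of a 10-bin equal-width histogram over `[min, max]`, f4 maximum,
#' f5 minimum, f6 mean, f7 median. Dispersion (f1, f3), range (f4, f5),
#' central tendency (f6, f7) and asymmetry (f2) together summarise the
#' amplitude distribution of a trial segment.
#'
#' @param segment Numeric vector of potentials, length >= 3.
#' @return Named numeric vector `f1`..`f7`.
#' @examples
#' extract_features(1:5)  # sd 1.5811, entropy 2.3219 bits, skewness 0
#' @export
extract_features <- function(segment) {
  n <- length(segment)
  if (n < 3) stop("segment must hold at least 3 samples")
  if (any(!is.finite(segment))) stop("segment must be finite")
  m <- mean(segment)
  f1 <- stats::sd(segment)
  m2 <- mean((segment - m)^2)
  f2 <- if (m2 <= 0) 0 else
    sqrt(n * (n - 1)) / (n - 2) * mean((segment - m)^3) / m2^1.5
  f3 <- segment_entropy(segment)
  c(f1 = f1, f2 = f2, f3 = f3, f4 = max(segment), f5 = min(segment),
    f6 = m, f7 = stats::median(segment))
}

# Shannon entropy (bits) of a 10-bin equal-width histogram; 0 log 0 := 0,
# and a constant segment (single occupied bin) has entropy 0.
segment_entropy <- function(segment, bins = 10) {
  lo <- min(segment); hi <- max(segment)
  if (hi == lo) return(0)
  breaks <- seq(lo, hi, length.out = bins + 1)
  counts <- tabulate(findInterval(segment, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), bins)
  p <- counts / length(segment)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Build a labelled feature matrix from trials and a selection profile
#'
#' One row per (trial, retained channel): the channel's selected intervals
#' are concatenated and the statistical features computed on the combined
#' segment. With 54 target trials and 8 channels this yields the canonical
#' 432 target feature vectors (7 columns for the full set Fs1, 2 for
#' Fs2 = {f1, f7}).
#'
#' @param trials List of labelled trials (`data` + `stimulus_class`).
#' @param profile A [select_profile()] result.
#' @param subset Feature ids to keep (character subset of f1..f7, a
#'   `"feature_subset"`, or NULL for all seven).
#' @return Object of class `"feature_matrix"`: `x` (numeric matrix), `labels`
#'   (factor nontarget/target), `provenance` (trial, channel per row), `norm`
#'   (normalization parameters, NULL until [normalize_features()]).
#' @export
build_feature_matrix <- function(trials, profile, subset = NULL) {
  stopifnot(inherits(profile, "selection_profile"))
  subset <- resolve_subset(subset)
  if (!length(trials)) stop("no trials")
  rows <- list(); labs <- character(0); prov_t <- integer(0)
  prov_c <- character(0)
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (is.null(rownames(tr$data)))
      stop("trial data must carry channel rownames")
    for (ch in profile$channels) {
      if (!ch %in% rownames(tr$data))
        stop("profile channel ", ch, " missing from trial data")
      iv <- profile$intervals[[ch]]
      if (nrow(iv) == 0L) stop("channel ", ch, " has no intervals")
      if (max(iv$end) > ncol(tr$data))
        stop("profile intervals exceed the trial length")
      seg <- unlist(lapply(seq_len(nrow(iv)), function(j)
        tr$data[ch, (iv$start[j] + 1L):iv$end[j]]), use.names = FALSE)
      rows[[length(rows) + 1L]] <- extract_features(seg)
      labs <- c(labs, tr$stimulus_class)
      prov_t <- c(prov_t, i); prov_c <- c(prov_c, ch)
    }
  }
  x <- do.call(rbind, rows)[, subset, drop = FALSE]
  structure(list(x = x,
                 labels = factor(labs, levels = c("nontarget", "target")),
                 provenance = data.frame(trial = prov_t, channel = prov_c),
                 norm = NULL),
            class = "feature_matrix")
}

resolve_subset <- function(subset) {
  if (is.null(subset)) return(FEATURE_IDS)
  if (inherits(subset, "feature_subset")) subset <- subset$features
  if (identical(subset, "fs1")) return(FEATURE_IDS)
  if (identical(subset, "fs2")) return(c("f1", "f7"))
  subset <- as.character(subset)
  if (!length(subset) || !all(subset %in% FEATURE_IDS))
    stop("subset must be drawn from ", paste(FEATURE_IDS, collapse = ", "))
  subset
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$x), "rows x", ncol(x$x), "features (",
      sum(x$labels == "target"), "target /",
      sum(x$labels == "nontarget"), "non-target );",
      if (is.null(x$norm)) "unnormalized" else "min-max normalized", "\n")
  invisible(x)
}

#' Min-max normalize a feature matrix
#'
#' Scales every feature to `[0, 1]` over the *training* data and stores the
#' per-feature min/max so that test data can be mapped with the same
#' parameters (values outside the training range may fall outside `[0, 1]`;
#' no clipping). A constant feature maps to 0 and is flagged. Normalizing a
#' matrix that already carries parameters is a no-op; passing `params`
#' applies stored training parameters to new data.
#'
#' @param fm A [build_feature_matrix()] result.
#' @param params Optional stored parameter list from a training matrix.
#' @return The feature matrix with scaled `x` and `norm` parameters.
#' @export
normalize_features <- function(fm, params = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$x) == 0L) stop("empty feature matrix")
  if (is.null(params)) {
    if (!is.null(fm$norm)) return(fm)      # already normalized: idempotent
    if (nrow(fm$x) < 2) stop("need at least 2 rows to fit normalization")
    params <- list(min = apply(fm$x, 2, min),
                   max = apply(fm$x, 2, max))
    params$constant <- params$max - params$min == 0
  }
  rng <- params$max - params$min
  x <- sweep(fm$x, 2, params$min)
  x <- sweep(x, 2, ifelse(params$constant, 1, rng), `/`)
  x[, params$constant] <- 0
  fm$x <- x
  fm$norm <- params
  fm
}

#' Correlation-based (CFS) merit of a feature subset
#'
#' `merit = k * rcf / sqrt(k + k (k - 1) * rff)` where `rcf` is the mean
#' absolute point-biserial correlation between each member feature and the
#' class label, `rff` the mean absolute pairwise Pearson correlation among
#' members, and `k` the subset size: high class correlation is rewarded,
#' redundancy among features penalised.
#'
#' @param subset Character vector of feature ids (columns of `x`).
#' @param x Numeric feature matrix (or a `"feature_matrix"`).
#' @param labels Class labels (target/nontarget or logical/0-1).
#' @return The merit (>= 0).
#' @export
cfs_merit <- function(subset, x, labels = NULL) {
  if (inherits(x, "feature_matrix")) {
    labels <- x$labels
    x <- x$x
  }
  subset <- as.character(subset)
  if (!length(subset)) stop("subset must be non-empty")
  if (!all(subset %in% colnames(x)))
    stop("unknown feature(s): ",
         paste(setdiff(subset, colnames(x)), collapse = ", "))
  pos <- as_positive(labels)
  k <- length(subset)
  rcf <- vapply(subset, function(f)
    abs(point_biserial(x[pos, f], x[!pos, f])), numeric(1))
  if (any(!is.finite(rcf))) stop("zero-variance feature in subset")
  rcf <- mean(rcf)
  rff <- if (k == 1) 0 else {
    cm <- abs(stats::cor(x[, subset, drop = FALSE]))
    if (any(!is.finite(cm))) stop("zero-variance feature in subset")
    mean(cm[upper.tri(cm)])
  }
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == 1)
  as.character(labels) == "target"
}

#' Best-first search for the optimal feature subset
#'
#' Greedy hill-climbing with backtracking over the subset lattice: starting
#' from the empty set, the open list holds evaluated subsets ordered by CFS
#' merit; the best open subset is expanded by single-feature additions and
#' removals. The search stops after `stale_limit` consecutive expansions
#' that fail to improve the best merit seen, and returns the highest-merit
#' subset visited.
#'
#' @param x Numeric feature matrix (or a `"feature_matrix"`).
#' @param labels Class labels (ignored when `x` is a feature matrix).
#' @param stale_limit Consecutive non-improving expansions tolerated.
#' @return Object of class `"feature_subset"`: `features` (ids) and `merit`.
#' @export
best_first_select <- function(x, labels = NULL, stale_limit = 5) {
  if (inherits(x, "feature_matrix")) {
    labels <- x$labels
    x <- x$x
  }
  feats <- colnames(x)
  if (length(feats) < 2) stop("need at least 2 features to search")
  usable <- vapply(feats, function(f) stats::sd(x[, f]) > 0, logical(1))
  if (!any(usable)) stop("all features have zero variance")
  feats <- feats[usable]
  merit_of <- function(ss) tryCatch(cfs_merit(ss, x, labels),
                                    error = function(e) -Inf)
  key <- function(ss) paste0("k:", paste(sort(ss), collapse = "|"))
  visited <- new.env(hash = TRUE)
  open_keys <- character(0); open_sets <- list(); open_merit <- numeric(0)
  push <- function(ss, m) {
    open_keys <<- c(open_keys, key(ss))
    open_sets[[length(open_sets) + 1L]] <<- ss
    open_merit <<- c(open_merit, m)
  }
  assign(key(character(0)), TRUE, envir = visited)
  push(character(0), -Inf)
  best <- NULL; best_merit <- -Inf; stale <- 0L
  while (length(open_sets) > 0L && stale < stale_limit) {
    i <- which.max(open_merit)
    node <- open_sets[[i]]
    open_sets[[i]] <- NULL
    open_merit <- open_merit[-i]
    open_keys <- open_keys[-i]
    improved <- FALSE
    neighbors <- c(lapply(setdiff(feats, node), function(f) c(node, f)),
                   if (length(node) > 1)
                     lapply(seq_along(node), function(j) node[-j]))
    for (nb in neighbors) {
      if (!length(nb)) next
      kk <- key(nb)
      if (exists(kk, envir = visited, inherits = FALSE)) next
      assign(kk, TRUE, envir = visited)
      m <- merit_of(nb)
      push(nb, m)
      if (m > best_merit) {
        best_merit <- m
        best <- nb
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  if (is.null(best)) stop("no evaluable subset found")
  structure(list(features = sort(best), merit = best_merit),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat("Feature subset {", paste(x$features, collapse = ", "),
      "}  merit =", format(x$merit, digits = 4), "\n")
  invisible(x)
}
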