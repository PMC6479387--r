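#' Binary confusion counts
#'
#' TP: targets predicted target; FN: targets predicted non-target; FP:
#' non-targets predicted target; TN: non-targets predicted non-target.
#'
#' @param labels True classes.
#' @param predictions Predicted classes, same length.
#' @return Object of class `"confusion_counts"`: named integer vector
#'   `TP`, `FN`, `FP`, `TN`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusion <- function(labels, predictions) {
  y <- as_label_factor(labels)
  p <- as_label_factor(predictions)
  if (length(y) != length(p)) stop("labels/predictions length mismatch")
  out <- c(TP = sum(y == "target" & p == "target"),
           FN = sum(y == "target" & p == "nontarget"),
           FP = sum(y == "nontarget" & p == "target"),
           TN = sum(y == "nontarget" & p == "nontarget"))
  structure(as.integer(out), names = names(out), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FN=%d FP=%d TN=%d (n=%d)\n",
              x["TP"], x["FN"], x["FP"], x["TN"], sum(x)))
  invisible(x)
}

#' True-positive rate, false-positive rate and accuracy
#'
#' `Tpr = TP / (TP + FN)`, `Fpr = FP / (FP + TN)`,
#' `Acc = (TP + TN) / (TP + FN + FP + TN)`.
#'
#' @param counts A [confusion()] result (or named vector with TP/FN/FP/TN).
#' @return Named numeric `c(Tpr, Fpr, Acc)`.
#' @examples
#' classification_metrics(confusion(c(1,1,1,1,0,0,0,0,0,0),
#'                                  c(1,1,1,0,1,0,0,0,0,0)))
#' @export
classification_metrics <- function(counts) {
  cc <- counts[c("TP", "FN", "FP", "TN")]
  if (any(is.na(cc))) stop("counts must name TP, FN, FP and TN")
  if (cc["TP"] + cc["FN"] == 0)
    stop("Tpr undefined: no target samples")
  if (cc["FP"] + cc["TN"] == 0)
    stop("Fpr undefined: no non-target samples")
  c(Tpr = unname(cc["TP"] / (cc["TP"] + cc["FN"])),
    Fpr = unname(cc["FP"] / (cc["FP"] + cc["TN"])),
    Acc = unname((cc["TP"] + cc["TN"]) / sum(cc)))
}

#' ROC curve by threshold sweep
#'
#' Samples are swept in score order; each distinct score value yields one
#' operating point (ties grouped), giving a curve from (0, 0) to (1, 1) that
#' is monotone in both coordinates. Higher scores mean more target-like.
#'
#' @param scores Numeric classifier scores.
#' @param labels True classes (both classes required).
#' @return data.frame with `threshold`, `fpr`, `tpr`; first row is the
#'   all-negative point (threshold Inf).
#' @export
roc_curve <- function(scores, labels) {
  y <- as_label_factor(labels)
  if (length(scores) != length(y)) stop("scores/labels length mismatch")
  P <- sum(y == "target"); N <- sum(y == "nontarget")
  if (P == 0 || N == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; pos <- y[ord] == "target"
  cum_tp <- cumsum(pos); cum_fp <- cumsum(!pos)
  last <- !duplicated(s, fromLast = TRUE)   # one point per distinct score
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, cum_fp[last] / N),
             tpr = c(0, cum_tp[last] / P))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of a [roc_curve()]; equal to the normalised
#' Mann-Whitney statistic with half credit for score ties. A convenience
#' form `auc(scores, labels)` builds the curve first.
#'
#' @param x A `roc_curve()` data frame, or a numeric score vector.
#' @param labels Class labels when `x` is a score vector.
#' @return The AUC in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))  # 1
#' @export
auc <- function(x, labels = NULL) {
  if (is.numeric(x) && !is.null(labels)) x <- roc_curve(x, labels)
  stopifnot(is.data.frame(x), all(c("fpr", "tpr") %in% names(x)))
  sum(diff(x$fpr) * (utils::head(x$tpr, -1) + utils::tail(x$tpr, -1)) / 2)
}

#' Stratified k-fold cross-validation of a classifier spec
#'
#' Rows are shuffled within class under the seed and dealt into k folds, so
#' every fold holds both classes. Each fold is held out once; the spec is
#' fitted on the remaining folds and evaluated on the held-out rows. Fold
#' confusion counts are pooled for the headline metrics; scores are pooled
#' for the ROC/AUC.
#'
#' @param x Numeric feature matrix or `"feature_matrix"`.
#' @param labels Class labels.
#' @param spec A `"classifier_spec"` (see [classifier_specs]).
#' @param k Number of folds.
#' @param seed Master seed (fold shuffle, learner seeds, tie-breaks).
#' @return Object of class `"eval_report"`: pooled `confusion`, `metrics`
#'   (Tpr/Fpr/Acc), `auc`, `roc`, per-fold data frame `folds`, `k`, `model`.
#' @export
cross_validate <- function(x, labels = NULL, spec = bagging_spec(), k = 10,
                           seed = NULL) {
  d <- as_feature_xy(x, labels)
  n <- nrow(d$x)
  if (k > n) stop("k exceeds the number of rows")
  if (min(table(d$y)) < k)
    stop("need at least k rows of each class for stratified folds")
  with_seed(seed, {
    fold <- integer(n)
    for (cl in levels(d$y)) {
      idx <- sample(which(d$y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    seeds <- child_seeds(2L * k)
    folds <- vector("list", k)
    scores <- numeric(n); preds <- character(n)
    for (f in seq_len(k)) {
      test <- fold == f
      model <- spec$fit(d$x[!test, , drop = FALSE], d$y[!test],
                        seed = seeds[2L * f - 1L])
      pr <- if (inherits(model, "bagging_ensemble"))
        predict(model, d$x[test, , drop = FALSE], type = "class",
                tie_seed = seeds[2L * f])
      else predict(model, d$x[test, , drop = FALSE], type = "class")
      sc <- predict(model, d$x[test, , drop = FALSE], type = "prob")
      if (is.matrix(sc)) sc <- sc[, "target"]
      preds[test] <- as.character(pr)
      scores[test] <- sc
      cc <- confusion(d$y[test], pr)
      folds[[f]] <- data.frame(fold = f, TP = cc["TP"], FN = cc["FN"],
                               FP = cc["FP"], TN = cc["TN"],
                               Acc = unname((cc["TP"] + cc["TN"]) / sum(cc)),
                               row.names = NULL)
    }
    pooled <- confusion(d$y, preds)
    roc <- roc_curve(scores, d$y)
    structure(list(confusion = pooled,
                   metrics = classification_metrics(pooled),
                   auc = auc(roc), roc = roc,
                   folds = do.call(rbind, folds),
                   k = k, model = spec$label),
              class = "eval_report")
  })
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%d-fold CV of %s: Acc %.3f, Tpr %.3f, Fpr %.3f, AUC %.3f\n",
              x$k, x$model, x$metrics["Acc"], x$metrics["Tpr"],
              x$metrics["Fpr"], x$auc))
  print(x$confusion)
  invisible(x)
}
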