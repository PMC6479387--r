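#' Classifier specifications
#'
#' Lightweight descriptions of how to fit a base learner, used by
#' [fit_bagging()] compositions and [cross_validate()]. Each spec carries a
#' label, the constructor name and parameters (so fitted pipelines can be
#' serialized and rebuilt), and a `fit(x, labels, seed)` closure returning a
#' model that answers `predict(model, newdata, type = "class"/"prob")`.
#'
#' `coin_spec()` is a null-model control: it ignores the features and
#' predicts target with probability `p` from the current RNG stream.
#'
#' @param learning_rate,iterations Gradient-ascent settings ([fit_logistic()]).
#' @param hidden,target_error,max_epochs Network settings ([fit_bpnn()]).
#' @param p Probability a coin classifier answers target.
#' @return Object of class `"classifier_spec"`.
#' @name classifier_specs
NULL

new_spec <- function(label, builder, params, fit) {
  structure(list(label = label, builder = builder, params = params,
                 fit = fit),
            class = "classifier_spec")
}

#' @rdname classifier_specs
#' @export
nb_spec <- function() {
  new_spec("naive Bayes", "nb_spec", list(),
           function(x, labels = NULL, seed = NULL) fit_gaussian_nb(x, labels))
}

#' @rdname classifier_specs
#' @export
lr_spec <- function(learning_rate = 0.1, iterations = 2000) {
  new_spec("logistic regression", "lr_spec",
           list(learning_rate = learning_rate, iterations = iterations),
           function(x, labels = NULL, seed = NULL)
             fit_logistic(x, labels, learning_rate, iterations))
}

#' @rdname classifier_specs
#' @export
bpnn_spec <- function(hidden = NULL, target_error = 0.01,
                      max_epochs = 10000, learning_rate = 0.3) {
  new_spec("BP neural network", "bpnn_spec",
           list(hidden = hidden, target_error = target_error,
                max_epochs = max_epochs, learning_rate = learning_rate),
           function(x, labels = NULL, seed = NULL)
             fit_bpnn(x, labels, hidden = hidden,
                      target_error = target_error, max_epochs = max_epochs,
                      learning_rate = learning_rate, seed = seed))
}

#' @rdname classifier_specs
#' @param composition List of base-learner specs (see [fit_bagging()]).
#' @param ... Arguments forwarded to the member spec constructors.
#' @export
bagging_spec <- function(composition = NULL, ...) {
  params <- list(...)
  new_spec("bagging ensemble", "bagging_spec",
           c(list(composition = composition), params),
           function(x, labels = NULL, seed = NULL)
             fit_bagging(x, labels,
                         composition = composition %||%
                           default_composition(...),
                         seed = seed))
}

#' @rdname classifier_specs
#' @export
coin_spec <- function(p = 0.5) {
  new_spec("coin flip", "coin_spec", list(p = p),
           function(x, labels = NULL, seed = NULL)
             structure(list(p = p), class = "coin_classifier"))
}

#' @export
predict.coin_classifier <- function(object, newdata,
                                    type = c("class", "prob"), ...) {
  type <- match.arg(type)
  n <- if (is.null(dim(newdata))) 1L else nrow(newdata)
  p <- stats::runif(n)
  if (type == "prob") return(p)
  factor(ifelse(p < object$p, "target", "nontarget"), levels = CLASS_LEVELS)
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("Classifier spec:", x$label, "\n")
  invisible(x)
}

#' Default bagging composition: 3 BP networks + 2 logistic regressions
#'
#' The odd count keeps majority votes mostly tie-free; naive Bayes is left
#' out of the default strong learner but available via [nb_spec()].
#'
#' @param ... Arguments passed to [bpnn_spec()] / split by name prefix:
#'   `bpnn = list(...)` and `lr = list(...)` override member settings.
#' @param bpnn,lr Optional argument lists for the member constructors.
#' @return List of five `"classifier_spec"` objects.
#' @export
default_composition <- function(bpnn = list(), lr = list(), ...) {
  c(replicate(3, do.call(bpnn_spec, bpnn), simplify = FALSE),
    replicate(2, do.call(lr_spec, lr), simplify = FALSE))
}

#' Bootstrap replicate of a sample set
#'
#' Draws rows uniformly with replacement until the replicate reaches the
#' size of the input (the self-sampling that gives every bagging base
#' learner its own training set).
#'
#' @param x Matrix or data frame of rows.
#' @param seed Optional seed.
#' @return Object like `x` with the sampled rows; the drawn row indices are
#'   attached as attribute `"indices"`.
#' @export
bootstrap_sample <- function(x, seed = NULL) {
  n <- nrow(x)
  if (is.null(n) || n < 1) stop("need at least one row")
  idx <- with_seed(seed, sample.int(n, n, replace = TRUE))
  out <- x[idx, , drop = FALSE]
  attr(out, "indices") <- idx
  out
}

#' Bagging ensemble with majority voting
#'
#' Trains every base learner of the composition on its own bootstrap
#' replicate of the training set and predicts by majority vote over the base
#' learners' class predictions; an exact tie is resolved by a seeded uniform
#' draw.
#'
#' @param x Numeric feature matrix or `"feature_matrix"`.
#' @param labels Class labels.
#' @param composition List of `"classifier_spec"`s (default 3 BPNN + 2 LR).
#' @param seed Master seed for bootstrap draws and learner seeds.
#' @return Object of class `"bagging_ensemble"` with `learners`, `specs`,
#'   `seeds` and `composition` (labels).
#' @export
fit_bagging <- function(x, labels = NULL, composition = default_composition(),
                        seed = NULL) {
  d <- as_feature_xy(x, labels)
  if (!length(composition)) stop("composition must be non-empty")
  with_seed(seed, {
    seeds <- child_seeds(2L * length(composition))
    learners <- vector("list", length(composition))
    for (i in seq_along(composition)) {
      boot <- bootstrap_sample(d$x, seed = seeds[2L * i - 1L])
      yb <- d$y[attr(boot, "indices")]
      learners[[i]] <- tryCatch(
        composition[[i]]$fit(boot, yb, seed = seeds[2L * i]),
        error = function(e)
          stop("base learner ", i, " (", composition[[i]]$label,
               ") failed: ", conditionMessage(e)))
    }
    structure(list(learners = learners, specs = composition, seeds = seeds,
                   composition = vapply(composition, `[[`, "", "label")),
              class = "bagging_ensemble")
  })
}

#' @rdname fit_bagging
#' @param object A fitted `"bagging_ensemble"`.
#' @param newdata Matrix or single row.
#' @param type `"class"` (majority vote), `"prob"` (fraction of target
#'   votes, the ensemble's ROC score) or `"votes"` (learner x row matrix).
#' @param tie_seed Seed for the random tie-break.
#' @param ... Unused.
#' @export
predict.bagging_ensemble <- function(object, newdata,
                                     type = c("class", "prob", "votes"),
                                     tie_seed = NULL, ...) {
  type <- match.arg(type)
  votes <- vapply(object$learners, function(m)
    as.character(predict(m, newdata, type = "class")),
    character(max(1L, if (is.null(dim(newdata))) 1L else nrow(newdata))))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  frac <- rowMeans(votes == "target")
  if (type == "votes") return(t(votes))
  if (type == "prob") return(frac)
  with_seed(tie_seed, {
    cls <- ifelse(frac > 0.5, "target",
                  ifelse(frac < 0.5, "nontarget", NA))
    ties <- is.na(cls)
    if (any(ties))
      cls[ties] <- ifelse(stats::runif(sum(ties)) < 0.5,
                          "target", "nontarget")
    factor(cls, levels = CLASS_LEVELS)
  })
}

#' @export
print.bagging_ensemble <- function(x, ...) {
  cat("Bagging ensemble of", length(x$learners), "base learners:",
      paste(x$composition, collapse = " + "), "\n")
  invisible(x)
}
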