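CLASS_LEVELS <- c("nontarget", "target")

as_label_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- ifelse(labels, "target", "nontarget")
  if (is.numeric(labels)) labels <- ifelse(labels == 1, "target", "nontarget")
  if (!all(labels %in% CLASS_LEVELS))
    stop("labels must be 'target'/'nontarget' (or 1/0, TRUE/FALSE)")
  factor(labels, levels = CLASS_LEVELS)
}

as_feature_xy <- function(x, labels) {
  if (inherits(x, "feature_matrix")) {
    labels <- x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  list(x = x, y = as_label_factor(labels))
}

#' Gaussian naive Bayes classifier
#'
#' Posterior `P(c|d) proportional to P(c) * prod_i p(d_i|c)` under the
#' attribute-conditional-independence assumption, each `p(d_i|c)` a
#' univariate Gaussian with the class-conditional sample mean and variance
#' of feature i. Variances are floored at 1e-9 to survive degenerate
#' features; posteriors are normalised by the evidence factor so they sum
#' to 1 (computed in log space).
#'
#' @param x Numeric feature matrix or a `"feature_matrix"`.
#' @param labels Class labels (ignored when `x` is a feature matrix).
#' @return Object of class `"gnb_model"` with `priors`, `means`, `vars`.
#' @export
fit_gaussian_nb <- function(x, labels = NULL) {
  d <- as_feature_xy(x, labels)
  if (nlevels(droplevels(d$y)) < 2) stop("training data holds a single class")
  priors <- prop.table(table(d$y))
  means <- do.call(rbind, lapply(CLASS_LEVELS, function(cl)
    colMeans(d$x[d$y == cl, , drop = FALSE])))
  vars <- do.call(rbind, lapply(CLASS_LEVELS, function(cl)
    apply(d$x[d$y == cl, , drop = FALSE], 2, stats::var)))
  rownames(means) <- rownames(vars) <- CLASS_LEVELS
  vars <- pmax(vars, 1e-9)
  structure(list(priors = as.numeric(priors[CLASS_LEVELS]),
                 means = means, vars = vars,
                 classes = CLASS_LEVELS, features = colnames(d$x)),
            class = "gnb_model")
}

#' @rdname fit_gaussian_nb
#' @param object A fitted `"gnb_model"`.
#' @param newdata Matrix (rows = samples) or single row.
#' @param type `"class"` for labels, `"prob"` for the posterior matrix.
#' @param ... Unused.
#' @export
predict.gnb_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  nd <- row_matrix(newdata, object$features)
  logpost <- vapply(seq_along(object$classes), function(ci) {
    ll <- matrix(0, nrow(nd), ncol(nd))
    for (i in seq_len(ncol(nd)))
      ll[, i] <- stats::dnorm(nd[, i], object$means[ci, i],
                              sqrt(object$vars[ci, i]), log = TRUE)
    log(object$priors[ci]) + rowSums(ll)
  }, numeric(nrow(nd)))
  if (nrow(nd) == 1L) logpost <- matrix(logpost, nrow = 1L)
  mx <- apply(logpost, 1, max)
  post <- exp(logpost - mx)
  post <- post / rowSums(post)
  colnames(post) <- object$classes
  if (type == "prob") return(post)
  factor(object$classes[max.col(post, ties.method = "first")],
         levels = CLASS_LEVELS)
}

#' @export
print.gnb_model <- function(x, ...) {
  cat("Gaussian naive Bayes:", length(x$features), "features, priors",
      paste(sprintf("%s=%.3f", x$classes, x$priors), collapse = ", "), "\n")
  invisible(x)
}

row_matrix <- function(newdata, features) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L,
                                               dimnames = list(NULL, features))
  nd <- as.matrix(newdata)
  if (!is.null(colnames(nd)) && all(features %in% colnames(nd)))
    nd <- nd[, features, drop = FALSE]
  if (ncol(nd) != length(features)) stop("feature count mismatch")
  nd
}

# Mean log-likelihood of a logistic model and its analytic gradient; the
# training loop ascends this objective.
lr_loglik <- function(beta, x1, y01) {
  eta <- drop(x1 %*% beta)
  mean(y01 * eta - log1p(exp(eta)))
}
lr_grad <- function(beta, x1, y01) {
  p <- stats::plogis(drop(x1 %*% beta))
  drop(crossprod(x1, y01 - p)) / nrow(x1)
}

#' Logistic regression by batch gradient ascent
#'
#' Models `logit P(y = 1 | w) = b0 + sum_i b_i w_i` with y = 1 for the
#' target class, and maximises the mean log-likelihood by batch gradient
#' ascent from a zero initial coefficient vector.
#'
#' @param x Numeric feature matrix or `"feature_matrix"`.
#' @param labels Class labels.
#' @param learning_rate Step size of the ascent.
#' @param iterations Number of gradient steps.
#' @return Object of class `"logistic_model"` with `coefficients`
#'   (intercept first) and the training hyperparameters.
#' @export
fit_logistic <- function(x, labels = NULL, learning_rate = 0.1,
                         iterations = 2000) {
  d <- as_feature_xy(x, labels)
  if (nlevels(droplevels(d$y)) < 2) stop("training data holds a single class")
  x1 <- cbind(`(Intercept)` = 1, d$x)
  y01 <- as.numeric(d$y == "target")
  beta <- numeric(ncol(x1))
  for (i in seq_len(iterations)) {
    g <- lr_grad(beta, x1, y01)
    if (any(!is.finite(g)))
      stop("non-finite gradient: reduce learning_rate")
    beta <- beta + learning_rate * g
  }
  if (any(!is.finite(beta))) stop("non-finite coefficients after training")
  structure(list(coefficients = stats::setNames(beta, colnames(x1)),
                 learning_rate = learning_rate, iterations = iterations,
                 features = colnames(d$x)),
            class = "logistic_model")
}

#' @rdname fit_logistic
#' @param object A fitted `"logistic_model"`.
#' @param newdata Matrix or single row.
#' @param type `"prob"` for P(target), `"class"` for labels.
#' @param ... Unused.
#' @export
predict.logistic_model <- function(object, newdata,
                                   type = c("prob", "class"), ...) {
  type <- match.arg(type)
  nd <- row_matrix(newdata, object$features)
  p <- stats::plogis(drop(cbind(1, nd) %*% object$coefficients))
  if (type == "prob") return(p)
  factor(ifelse(p >= 0.5, "target", "nontarget"), levels = CLASS_LEVELS)
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("Logistic regression (gradient ascent, lr =", x$learning_rate,
      ",", x$iterations, "iterations)\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.logistic_model <- function(object, ...) object$coefficients
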