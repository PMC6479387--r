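sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass for a whole matrix (rows = samples); returns hidden and
# output activations.
bpnn_forward <- function(net, x) {
  h <- sigmoid(x %*% t(net$W1) + matrix(net$b1, nrow(x), length(net$b1),
                                        byrow = TRUE))
  o <- sigmoid(h %*% t(net$W2) + matrix(net$b2, nrow(x), length(net$b2),
                                        byrow = TRUE))
  list(hidden = h, output = o)
}

# Gradient of the per-sample squared error E = 0.5 * sum((o - y)^2) with
# respect to every weight and bias; used by the online update and by the
# finite-difference oracle in the tests.
bpnn_grad <- function(net, x_row, y_row) {
  h <- sigmoid(drop(net$W1 %*% x_row + net$b1))
  o <- sigmoid(drop(net$W2 %*% h + net$b2))
  delta_o <- (o - y_row) * o * (1 - o)
  delta_h <- drop(t(net$W2) %*% delta_o) * h * (1 - h)
  list(W2 = tcrossprod(delta_o, h), b2 = delta_o,
       W1 = tcrossprod(delta_h, x_row), b1 = delta_h,
       output = o)
}

#' Back-propagation neural network (one hidden layer)
#'
#' A fully connected input-hidden-output network with logistic sigmoid
#' activations and two output units (target, non-target), trained by online
#' back-propagation of the squared output error: samples are presented in
#' order; each presentation adjusts weights and thresholds by the
#' error-gradient step. Training stops when the mean squared output error
#' over the training set drops to `target_error` (the conventional 0.01) or
#' at `max_epochs` - the termination reason is recorded. Weights start
#' uniform(-0.5, 0.5) under `seed`, so fits are reproducible. The canonical
#' architectures are 7-4-2 for the full feature set and 2-2-2 for the
#' {sd, median} subset; by default the hidden layer holds
#' `floor((inputs + 2) / 2)` neurons, reproducing both.
#'
#' @param x Numeric feature matrix or `"feature_matrix"`.
#' @param labels Class labels (one-hot encoded internally over the two
#'   output units).
#' @param hidden Hidden-layer size (default as above).
#' @param target_error Mean-squared-error stopping threshold.
#' @param max_epochs Maximum training epochs.
#' @param learning_rate Online learning rate.
#' @param seed Seed for the weight initialisation.
#' @return Object of class `"bp_network"` with weights `W1`, `b1`, `W2`,
#'   `b2`, `sizes`, final `mse`, `epochs` and `termination`
#'   (`"converged"`/`"max_epochs"`).
#' @export
fit_bpnn <- function(x, labels = NULL, hidden = NULL, target_error = 0.01,
                     max_epochs = 10000, learning_rate = 0.3, seed = NULL) {
  d <- as_feature_xy(x, labels)
  if (nlevels(droplevels(d$y)) < 2) stop("training data holds a single class")
  n_in <- ncol(d$x)
  if (is.null(hidden)) hidden <- max(2L, (n_in + 2L) %/% 2L)
  Y <- cbind(target = as.numeric(d$y == "target"),
             nontarget = as.numeric(d$y == "nontarget"))
  net <- with_seed(seed, list(
    W1 = matrix(stats::runif(hidden * n_in, -0.5, 0.5), hidden, n_in),
    b1 = stats::runif(hidden, -0.5, 0.5),
    W2 = matrix(stats::runif(2 * hidden, -0.5, 0.5), 2, hidden),
    b2 = stats::runif(2, -0.5, 0.5)))
  n <- nrow(d$x)
  mse <- Inf; epoch <- 0L; termination <- "max_epochs"
  for (epoch in seq_len(max_epochs)) {
    for (s in seq_len(n)) {
      g <- bpnn_grad(net, d$x[s, ], Y[s, ])
      net$W2 <- net$W2 - learning_rate * g$W2
      net$b2 <- net$b2 - learning_rate * g$b2
      net$W1 <- net$W1 - learning_rate * g$W1
      net$b1 <- net$b1 - learning_rate * g$b1
    }
    if (any(!vapply(net, function(w) all(is.finite(w)), logical(1))))
      stop("training diverged: non-finite weights")
    mse <- mean((bpnn_forward(net, d$x)$output - Y)^2)
    if (mse <= target_error) { termination <- "converged"; break }
  }
  structure(c(net, list(sizes = c(n_in, hidden, 2L), mse = mse,
                        epochs = epoch, termination = termination,
                        features = colnames(d$x))),
            class = "bp_network")
}

#' @rdname fit_bpnn
#' @param object A fitted `"bp_network"`.
#' @param newdata Matrix or single row.
#' @param type `"class"` for labels, `"prob"` for the target-unit output,
#'   `"output"` for both output units.
#' @param ... Unused.
#' @export
predict.bp_network <- function(object, newdata,
                               type = c("class", "prob", "output"), ...) {
  type <- match.arg(type)
  nd <- row_matrix(newdata, object$features)
  o <- bpnn_forward(object, nd)$output
  colnames(o) <- c("target", "nontarget")
  switch(type,
         output = o,
         prob = o[, "target"],
         class = factor(ifelse(o[, "target"] >= o[, "nontarget"],
                               "target", "nontarget"),
                        levels = CLASS_LEVELS))
}

#' @export
print.bp_network <- function(x, ...) {
  cat(sprintf("BP neural network %d-%d-%d: %s after %d epochs (MSE %.4g)\n",
              x$sizes[1], x$sizes[2], x$sizes[3], x$termination, x$epochs,
              x$mse))
  invisible(x)
}
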