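#' Fixed-point ICA decomposition of multichannel data
#'
#' Blind separation of a channels x samples matrix into statistically
#' independent component time courses: the observed signals are modelled as
#' an unknown mixing matrix applied to unknown independent sources, and the
#' unmixing matrix is estimated by fixed-point negentropy maximisation with
#' the log-cosh contrast and symmetric decorrelation, on whitened data.
#'
#' @param x Numeric matrix, channels x samples (samples > channels).
#' @param n_components Number of components (<= channels).
#' @param seed Seed for the random orthogonal initialisation.
#' @param max_iter Maximum fixed-point iterations.
#' @param tol Convergence tolerance on the unmixing update.
#' @return Object of class `"ica_decomposition"`: `unmixing` (components x
#'   channels, applied to centred data), `mixing` (channels x components),
#'   `S` (component time courses), `whitening` (components x channels),
#'   `means` (per-channel means), `sigma2` (per-channel noise variance
#'   estimate), `converged`, `iterations`.
#' @examples
#' src <- rbind(runif(500, -1, 1), ((1:500 %% 25) / 12.5) - 1)
#' mixed <- matrix(c(0.6, 0.4, -0.3, 0.8), 2) %*% src
#' d <- ica_decompose(mixed, seed = 1)
#' @export
ica_decompose <- function(x, n_components = nrow(x), seed = NULL,
                          max_iter = 500, tol = 1e-5) {
  stopifnot(is.matrix(x), is.numeric(x))
  n_ch <- nrow(x); n_s <- ncol(x)
  if (n_s <= n_ch) stop("need more samples than channels")
  if (n_components > n_ch) stop("n_components must be <= channels")
  means <- rowMeans(x)
  xc <- x - means
  cv <- tcrossprod(xc) / (n_s - 1)
  eg <- eigen(cv, symmetric = TRUE)
  if (any(eg$values[seq_len(n_components)] < 1e-12 * max(eg$values)))
    stop("rank-deficient data: cannot whiten ", n_components, " components")
  K <- diag(1 / sqrt(eg$values[seq_len(n_components)]),
            n_components, n_components) %*%
    t(eg$vectors[, seq_len(n_components), drop = FALSE])
  Z <- K %*% xc                      # whitened: cov(Z) = I

  sym_decorrelate <- function(W) {
    e <- eigen(tcrossprod(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), nrow(W)) %*%
      t(e$vectors) %*% W
  }
  W <- with_seed(seed,
                 matrix(stats::rnorm(n_components^2), n_components))
  W <- sym_decorrelate(W)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)                    # log-cosh contrast derivative
    W1 <- (G %*% t(Z)) / n_s - diag(rowMeans(1 - G^2)) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("ICA did not converge within ", max_iter, " iterations")
  unmixing <- W %*% K
  mixing <- eg$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(n_components)]), n_components) %*% t(W)
  structure(list(unmixing = unmixing, mixing = mixing,
                 S = unmixing %*% xc, whitening = K, means = means,
                 sigma2 = diag(cv), converged = converged, iterations = it),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat("ICA decomposition:", nrow(x$S), "components,", ncol(x$S), "samples;",
      if (x$converged) "converged" else "NOT converged", "in", x$iterations,
      "iterations\n")
  invisible(x)
}

#' Back-project an ICA decomposition with components removed
#'
#' Reconstructs the channel data from the component time courses with the
#' rejected components zeroed. An empty rejection list reconstructs the input
#' (up to the discarded subspace when `n_components < channels`); rejecting
#' every component returns the per-channel means.
#'
#' @param decomp An [ica_decompose()] result.
#' @param reject Integer component indices to remove.
#' @return Channels x samples matrix.
#' @export
ica_clean <- function(decomp, reject = integer(0)) {
  stopifnot(inherits(decomp, "ica_decomposition"))
  k <- nrow(decomp$S)
  reject <- as.integer(reject)
  if (length(reject) && (min(reject) < 1 || max(reject) > k))
    stop("component index out of range")
  keep <- setdiff(seq_len(k), reject)
  out <- decomp$mixing[, keep, drop = FALSE] %*%
    decomp$S[keep, , drop = FALSE] + decomp$means
  out
}

#' Find components matching artifact templates
#'
#' Marks every component whose absolute Pearson correlation with any template
#' time course exceeds the threshold - a batch-mode stand-in for the visual
#' component inspection of interactive toolboxes.
#'
#' @param decomp An [ica_decompose()] result.
#' @param templates List of numeric vectors, each of length `ncol(decomp$S)`.
#' @param threshold Absolute-correlation threshold.
#' @return Integer vector of component indices (possibly empty).
#' @export
match_artifact_components <- function(decomp, templates, threshold = 0.7) {
  stopifnot(inherits(decomp, "ica_decomposition"))
  if (!length(templates)) return(integer(0))
  hits <- vapply(seq_len(nrow(decomp$S)), function(i) {
    any(vapply(templates, function(tp) {
      if (length(tp) != ncol(decomp$S))
        stop("template length must equal the component length")
      if (stats::sd(tp) == 0 || stats::sd(decomp$S[i, ]) == 0) return(FALSE)
      abs(stats::cor(decomp$S[i, ], tp)) > threshold
    }, logical(1)))
  }, logical(1))
  which(hits)
}
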