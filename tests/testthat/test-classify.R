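test_that("naive Bayes moments, priors and posterior normalization are exact", {
  set.seed(1)
  d <- gaussian_features(60, p = 3, shift_cols = "f1")
  m <- fit_gaussian_nb(d$x, d$y)
  for (cl in c("nontarget", "target")) {
    sel <- d$y == cl
    expect_equal(m$means[cl, ], colMeans(d$x[sel, ]), tolerance = 1e-12)
    expect_equal(m$vars[cl, ], apply(d$x[sel, ], 2, var), tolerance = 1e-12)
  }
  expect_equal(sum(m$priors), 1)
  post <- predict(m, d$x, type = "prob")
  expect_equal(unname(rowSums(post)), rep(1, nrow(d$x)), tolerance = 1e-12)
  expect_error(fit_gaussian_nb(d$x, rep("target", 60)), "single class")
})

test_that("a symmetric two-Gaussian problem gives a 0.5/0.5 posterior at zero", {
  x <- matrix(c(rep(c(-1.5, -1, -0.5), 10), rep(c(0.5, 1, 1.5), 10)),
              ncol = 1, dimnames = list(NULL, "f1"))
  y <- rep(c("nontarget", "target"), each = 30)
  m <- fit_gaussian_nb(x, y)
  post <- predict(m, matrix(0, 1, 1, dimnames = list(NULL, "f1")),
                  type = "prob")
  expect_equal(unname(post[1, ]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("naive Bayes agrees with an independent reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(2)
  d <- gaussian_features(100, p = 4, shift_cols = c("f1", "f3"))
  m <- fit_gaussian_nb(d$x, d$y)
  ref <- e1071::naiveBayes(d$x, factor(d$y))
  post <- predict(m, d$x, type = "prob")
  ref_post <- predict(ref, d$x, type = "raw")
  expect_equal(post[, "target"], unname(ref_post[, "target"]),
               tolerance = 1e-6)
})

test_that("logistic regression: zero coefficients, gradient oracle, separable fit", {
  set.seed(3)
  d <- gaussian_features(40, p = 2, shift_cols = "f1", shift = 1)
  m0 <- fit_logistic(d$x, d$y, iterations = 0)
  expect_true(all(predict(m0, d$x) == 0.5))
  # analytic gradient vs central finite differences of the mean log-likelihood
  x1 <- cbind(1, d$x)
  y01 <- as.numeric(d$y == "target")
  beta <- rnorm(3, sd = 0.5)
  g <- erpauth:::lr_grad(beta, x1, y01)
  h <- 1e-5
  for (j in 1:3) {
    e <- numeric(3); e[j] <- h
    num <- (erpauth:::lr_loglik(beta + e, x1, y01) -
              erpauth:::lr_loglik(beta - e, x1, y01)) / (2 * h)
    expect_equal(unname(g[j]), num, tolerance = 1e-6)
  }
  # linearly separable toy set reaches perfect training accuracy
  xs <- cbind(f1 = c(rnorm(10, -3), rnorm(10, 3)), f2 = rnorm(20))
  ys <- rep(c("nontarget", "target"), each = 10)
  ms <- fit_logistic(xs, ys, iterations = 2000)
  expect_equal(mean(predict(ms, xs, type = "class") == ys), 1.0)
  # an overflowing step produces a reported, not silent, failure
  xo <- cbind(f1 = c(0, rnorm(19, sd = 1e170)))
  yo <- rep(c("target", "nontarget"), each = 10)
  expect_error(fit_logistic(xo, yo, learning_rate = 1e200, iterations = 10),
               "finite")
})

test_that("BP network outputs 0.5 at zero weights and its gradients match finite differences", {
  zero_net <- structure(list(W1 = matrix(0, 3, 2), b1 = numeric(3),
                             W2 = matrix(0, 2, 3), b2 = numeric(2),
                             sizes = c(2L, 3L, 2L),
                             features = c("f1", "f2")),
                        class = "bp_network")
  o <- predict(zero_net, c(f1 = 1.3, f2 = -2), type = "output")
  expect_equal(unname(o[1, ]), c(0.5, 0.5))
  set.seed(4)
  net <- structure(list(W1 = matrix(rnorm(6, sd = 0.5), 3, 2),
                        b1 = rnorm(3, sd = 0.5),
                        W2 = matrix(rnorm(6, sd = 0.5), 2, 3),
                        b2 = rnorm(2, sd = 0.5)), class = "bp_network")
  x <- rnorm(2); y <- c(1, 0)
  g <- erpauth:::bpnn_grad(net, x, y)
  E <- function(n) {
    o <- erpauth:::sigmoid(n$W2 %*% erpauth:::sigmoid(n$W1 %*% x + n$b1) +
                             n$b2)
    0.5 * sum((o - y)^2)
  }
  h <- 1e-5
  for (fld in c("W1", "b1", "W2", "b2")) {
    for (i in seq_along(net[[fld]])) {
      np <- net; np[[fld]][i] <- np[[fld]][i] + h
      nm <- net; nm[[fld]][i] <- nm[[fld]][i] - h
      num <- (E(np) - E(nm)) / (2 * h)
      expect_equal(g[[fld]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("a 2-2-2 network learns XOR within five seeded restarts", {
  x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4,
              dimnames = list(NULL, c("f1", "f2")))
  y <- c("nontarget", "target", "target", "nontarget")
  solved <- FALSE
  for (s in 1:5) {
    net <- fit_bpnn(x, y, hidden = 2, max_epochs = 10000, seed = s)
    if (net$mse <= 0.01) { solved <- TRUE; break }
  }
  expect_true(solved)
  expect_identical(net$termination, "converged")
  expect_equal(as.character(predict(net, x)), y)
})

test_that("BPNN fits are reproducible and report their termination", {
  set.seed(5)
  d <- gaussian_features(60, p = 2, shift_cols = "f1", shift = 3)
  a <- fit_bpnn(d$x, d$y, max_epochs = 30, seed = 9)
  b <- fit_bpnn(d$x, d$y, max_epochs = 30, seed = 9)
  expect_identical(a$W1, b$W1)
  expect_identical(a$W2, b$W2)
  expect_true(a$termination %in% c("converged", "max_epochs"))
  expect_identical(unname(a$sizes), c(2L, 2L, 2L))  # 2-2-2 for two features
  d7 <- gaussian_features(60, p = 7, shift_cols = "f1", shift = 3)
  n7 <- fit_bpnn(d7$x, d7$y, max_epochs = 5, seed = 1)
  expect_identical(unname(n7$sizes), c(7L, 4L, 2L))  # 7-4-2 for seven
})

test_that("bootstrap replicates resample rows with replacement, seeded", {
  set.seed(6)
  x <- matrix(rnorm(660 * 2), 660)
  b <- bootstrap_sample(x, seed = 3)
  expect_equal(nrow(b), 660L)
  expect_true(all(attr(b, "indices") %in% 1:660))
  expect_true(all(b[1, ] == x[attr(b, "indices")[1], ]))
  expect_identical(bootstrap_sample(x, seed = 3), b)
  expect_gt(length(unique(attr(b, "indices"))), 300)  # sampling w/ replacement
  expect_error(bootstrap_sample(x[0, , drop = FALSE]), "one row")
})

test_that("bagging votes by majority with a seeded random tie-break", {
  set.seed(7)
  d <- gaussian_features(40, p = 2, shift_cols = "f1", shift = 2)
  always_t <- coin_spec(1); always_n <- coin_spec(0)
  # 5 constant learners: the vote equals the constant
  ens_t <- fit_bagging(d$x, d$y, composition = replicate(5, always_t,
                                                         simplify = FALSE),
                       seed = 1)
  expect_true(all(predict(ens_t, d$x) == "target"))
  # 3 target / 2 non-target -> target
  ens32 <- fit_bagging(d$x, d$y,
                       composition = c(replicate(3, always_t, simplify = FALSE),
                                       replicate(2, always_n, simplify = FALSE)),
                       seed = 1)
  expect_true(all(predict(ens32, d$x) == "target"))
  expect_equal(unname(predict(ens32, d$x[1:2, ], type = "prob")),
               c(0.6, 0.6))
  # 1-1 tie resolved by a seeded draw, reproducibly
  tie <- fit_bagging(d$x, d$y, composition = list(always_t, always_n),
                     seed = 1)
  v1 <- predict(tie, d$x, tie_seed = 11)
  expect_identical(predict(tie, d$x, tie_seed = 11), v1)
  expect_true(any(v1 == "target") && any(v1 == "nontarget"))
  expect_error(fit_bagging(d$x, d$y, composition = list()), "non-empty")
})

test_that("ensemble fits propagate base-learner failures and reproduce under seeds", {
  set.seed(8)
  d <- gaussian_features(30, p = 2, shift_cols = "f1")
  bad <- erpauth:::new_spec("broken", "nb_spec", list(),
                            function(x, labels = NULL, seed = NULL)
                              stop("boom"))
  expect_error(fit_bagging(d$x, d$y, composition = list(bad)),
               "base learner 1")
  comp <- default_composition(bpnn = list(max_epochs = 10),
                              lr = list(iterations = 50))
  a <- fit_bagging(d$x, d$y, composition = comp, seed = 5)
  b <- fit_bagging(d$x, d$y, composition = comp, seed = 5)
  expect_identical(lapply(a$learners, unclass)[1:3],
                   lapply(b$learners, unclass)[1:3])
})

test_that("bagging is at least as accurate as its base learners on overlapping classes", {
  gen <- function(n, seed) {
    set.seed(seed)
    y <- rep(c("target", "nontarget"), each = n / 2)
    list(x = cbind(f1 = rnorm(n) + 2 * (y == "target"), f2 = rnorm(n)),
         y = y)
  }
  te <- gen(600, 999)
  comp <- default_composition(bpnn = list(max_epochs = 50),
                              lr = list(iterations = 500))
  bag <- base <- numeric(20)
  for (s in 1:20) {
    tr <- gen(200, s)
    ens <- fit_bagging(tr$x, tr$y, composition = comp, seed = s)
    bag[s] <- mean(predict(ens, te$x, tie_seed = s) == te$y)
    base[s] <- mean(vapply(ens$learners, function(m)
      mean(predict(m, te$x, type = "class") == te$y), numeric(1)))
  }
  expect_gte(mean(bag), mean(base))
})
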