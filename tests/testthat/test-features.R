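test_that("the seven statistical features match their estimators", {
  f <- extract_features(1:5)
  expect_equal(unname(f["f6"]), 3)           # mean
  expect_equal(unname(f["f7"]), 3)           # median
  expect_equal(unname(f["f4"]), 5)           # max
  expect_equal(unname(f["f5"]), 1)           # min
  expect_equal(unname(f["f2"]), 0)           # symmetric: zero skewness
  expect_equal(unname(f["f1"]), 1.5811, tolerance = 1e-4)
  # 5 values occupy 5 of 10 equal-width bins, one point each -> log2(5) bits
  expect_equal(unname(f["f3"]), 2.3219, tolerance = 1e-4)
  # median of an even-length segment is the mean of the middle two
  expect_equal(unname(extract_features(c(1, 2, 3, 10))["f7"]), 2.5)
  # constant segment: zero sd, zero skewness, zero entropy
  fc <- extract_features(rep(2, 10))
  expect_equal(unname(fc[c("f1", "f2", "f3")]), c(0, 0, 0))
  expect_error(extract_features(1:2), "at least 3")
})

test_that("feature ordering invariants hold on random segments", {
  set.seed(1)
  for (i in 1:200) {
    f <- extract_features(rnorm(sample(3:50, 1), sd = runif(1, 0.1, 20)))
    expect_lte(f[["f5"]], f[["f6"]]); expect_lte(f[["f6"]], f[["f4"]])
    expect_lte(f[["f5"]], f[["f7"]]); expect_lte(f[["f7"]], f[["f4"]])
    expect_gte(f[["f1"]], 0); expect_gte(f[["f3"]], 0)
  }
})

test_that("skewness follows the adjusted Fisher-Pearson oracle", {
  set.seed(2)
  x <- rexp(40)
  n <- length(x); m <- mean(x)
  g1 <- mean((x - m)^3) / mean((x - m)^2)^1.5
  expect_equal(unname(extract_features(x)["f2"]),
               sqrt(n * (n - 1)) / (n - 2) * g1, tolerance = 1e-12)
  expect_gt(extract_features(x)[["f2"]], 0)   # right-skewed
})

test_that("54 trials x 8 channels yield the canonical 432 feature rows", {
  set.seed(3)
  chans <- c("F3", "F4", "FC5", "FC6", "P7", "P8", "O1", "O2")
  prof <- flat_profile(chans, start = 25, end = 90)
  trials <- noisy_trials(54, 0, template_matrix(erp_model()), sd = 1)
  fm <- build_feature_matrix(trials, prof)
  expect_equal(dim(fm$x), c(432L, 7L))
  expect_true(all(fm$labels == "target"))
  fm2 <- build_feature_matrix(trials, prof, subset = "fs2")
  expect_equal(dim(fm2$x), c(432L, 2L))
  expect_identical(colnames(fm2$x), c("f1", "f7"))
  one <- build_feature_matrix(trials[1], flat_profile("P7"))
  expect_equal(nrow(one$x), 1L)
  expect_error(build_feature_matrix(trials, flat_profile("P7", end = 400)),
               "exceed")
})

test_that("multiple intervals per channel are concatenated before extraction", {
  prof <- flat_profile("P7", start = 0, end = 10)
  prof$intervals$P7 <- rbind(prof$intervals$P7,
                             data.frame(start = 20, end = 30,
                                        start_ms = 156, end_ms = 234))
  x <- matrix(0, 14, 128, dimnames = list(EMOTIV_CHANNELS, NULL))
  x["P7", ] <- seq_len(128)
  fm <- build_feature_matrix(list(make_trial(x)), prof)
  expect_equal(unname(fm$x[1, "f6"]), mean(c(1:10, 21:30)))
  expect_equal(unname(fm$x[1, "f4"]), 30)
})

test_that("min-max normalization scales to [0,1], reuses training parameters and is idempotent", {
  fm <- structure(list(x = cbind(f1 = c(0, 5, 10), f7 = c(1, 1, 1)),
                       labels = factor(c("target", "nontarget", "target"),
                                       levels = c("nontarget", "target")),
                       provenance = data.frame(trial = 1:3, channel = "P7"),
                       norm = NULL), class = "feature_matrix")
  nm <- normalize_features(fm)
  expect_equal(unname(nm$x[, "f1"]), c(0, 0.5, 1))
  expect_true(all(nm$x[, "f7"] == 0))          # constant column flagged to 0
  expect_true(nm$norm$constant[["f7"]])
  expect_identical(normalize_features(nm), nm) # idempotent once fitted
  # test data reuses TRAINING parameters; values beyond the max may exceed 1
  test_fm <- fm; test_fm$x <- cbind(f1 = c(20, -5), f7 = c(3, 3))
  tn <- normalize_features(test_fm, params = nm$norm)
  expect_equal(unname(tn$x[, "f1"]), c(2, -0.5))
})

test_that("CFS merit follows the correlation formula", {
  set.seed(4)
  d <- gaussian_features(80, p = 3, shift_cols = c("f1", "f2"), shift = 1)
  pos <- d$y == "target"
  rcf <- mean(abs(sapply(c("f1", "f2"), function(f)
    point_biserial(d$x[pos, f], d$x[!pos, f]))))
  rff <- abs(cor(d$x[, "f1"], d$x[, "f2"]))
  expect_equal(cfs_merit(c("f1", "f2"), d$x, d$y),
               2 * rcf / sqrt(2 + 2 * rff), tolerance = 1e-12)
  # k = 1 reduces to the absolute feature-class correlation
  expect_equal(cfs_merit("f1", d$x, d$y),
               abs(point_biserial(d$x[pos, "f1"], d$x[!pos, "f1"])),
               tolerance = 1e-12)
  xz <- cbind(d$x, fz = 0)
  expect_error(cfs_merit("fz", xz, d$y))
  expect_error(cfs_merit(character(0), d$x, d$y), "non-empty")
})

test_that("best-first search matches exhaustive enumeration for small feature sets", {
  for (s in 1:50) {
    set.seed(s)
    p <- sample(5:7, 1)
    eff <- rnorm(p, 0, 0.8) * rbinom(p, 1, 0.5)
    y <- rep(c("target", "nontarget"), each = 30)
    x <- sapply(seq_len(p), function(j) rnorm(60) + eff[j] * (y == "target"))
    colnames(x) <- paste0("f", seq_len(p))
    bf <- best_first_select(x, y)
    exhaustive <- -Inf
    for (k in seq_len(p)) {
      cm <- utils::combn(p, k)
      for (i in seq_len(ncol(cm))) {
        m <- tryCatch(cfs_merit(colnames(x)[cm[, i]], x, y),
                      error = function(e) -Inf)
        exhaustive <- max(exhaustive, m)
      }
    }
    expect_equal(bf$merit, exhaustive, tolerance = 1e-12)
  }
})

test_that("a lone informative feature is found and search space stays bounded", {
  set.seed(6)
  d <- gaussian_features(200, p = 5, shift_cols = "f3", shift = 2)
  ss <- best_first_select(d$x, d$y)
  expect_true("f3" %in% ss$features)
  expect_error(best_first_select(matrix(0, 10, 3,
                                        dimnames = list(NULL, paste0("f", 1:3))),
                                 rep(c("target", "nontarget"), 5)),
               "zero variance")
})

test_that("sd and median are recovered when they carry the class signal", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(s)
    d <- gaussian_features(200, p = 7, shift_cols = c("f1", "f7"),
                           shift = 1.2)
    ss <- best_first_select(d$x, d$y)
    if (all(c("f1", "f7") %in% ss$features)) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})
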