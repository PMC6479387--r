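# Small, fast simulation settings shared by the auth tests.
strong_erp <- erp_model(amplitude = 8)
quick_cfg <- auth_config(model = bagging_spec(
  bpnn = list(max_epochs = 200), lr = list(iterations = 500)))

test_that("registration on separable data stores a perfectly fitted template", {
  s <- simulate_session(erp = strong_erp, art = quiet_artifacts(0),
                        repetitions = 16, seed = 1)
  tpl <- register(s, quick_cfg, seed = 2)
  expect_s3_class(tpl, "auth_template")
  expect_equal(tpl$training$accuracy, 1.0)
  expect_true(all(tpl$subset %in% paste0("f", 1:7)))
  expect_gt(nrow(tpl$features), 0)           # stored target feature rows
  expect_false(is.null(tpl$norm))
})

test_that("registration fails loudly when a stimulus class is missing", {
  s <- simulate_session(erp = strong_erp, art = quiet_artifacts(1),
                        repetitions = 16, seed = 3)
  s$epochs <- Filter(function(e) e$stimulus_class == "nontarget", s$epochs)
  expect_error(register(s, quick_cfg), "registration.*no target epochs")
})

test_that("genuine logins are granted and impostor logins denied", {
  s <- simulate_session(erp = strong_erp, art = quiet_artifacts(5),
                        repetitions = 24, seed = 4)
  tpl <- register(s, quick_cfg, seed = 5)
  valid <- simulate_session(erp = strong_erp, art = quiet_artifacts(5),
                            repetitions = 8, seed = 6)
  dec_v <- login(valid, tpl)
  expect_true(dec_v$granted)
  expect_gte(dec_v$fraction, 0.5)
  imp <- simulate_session(erp = strong_erp, art = quiet_artifacts(5),
                          repetitions = 8, role = "impostor", seed = 7)
  dec_i <- login(imp, tpl)
  expect_false(dec_i$granted)
  # threshold 0 is a degenerate always-grant bound
  expect_true(login(imp, tpl, threshold = 0)$granted)
  # granting is monotone non-increasing in the threshold
  grants <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                   function(th) login(valid, tpl, threshold = th)$granted,
                   logical(1))
  expect_true(all(diff(as.integer(grants)) <= 0))
})

test_that("login applies stored parameters only and leaves the template untouched", {
  dir <- withr::local_tempdir()
  s <- simulate_session(erp = strong_erp, art = quiet_artifacts(3),
                        repetitions = 16, seed = 8)
  tpl <- register(s, quick_cfg, seed = 9)
  before <- file.path(dir, "before.json"); after <- file.path(dir, "after.json")
  write_template(tpl, before)
  valid <- simulate_session(erp = strong_erp, art = quiet_artifacts(3),
                            repetitions = 8, seed = 10)
  invisible(login(valid, tpl))
  write_template(tpl, after)
  expect_identical(readLines(before), readLines(after))
})

test_that("templates round-trip through JSON serialization", {
  dir <- withr::local_tempdir()
  s <- simulate_session(erp = strong_erp, art = quiet_artifacts(3),
                        repetitions = 16, seed = 11)
  tpl <- register(s, quick_cfg, seed = 12)
  path <- file.path(dir, "tpl.json")
  write_template(tpl, path)
  tpl2 <- read_template(path)
  expect_identical(tpl2$subject_id, tpl$subject_id)
  expect_identical(tpl2$subset, tpl$subset)
  expect_identical(tpl2$profile$channels, tpl$profile$channels)
  expect_equal(tpl2$features, tpl$features, tolerance = 1e-12)
  expect_equal(tpl2$norm$min, tpl$norm$min, tolerance = 1e-12)
  # the restored model makes identical decisions
  valid <- simulate_session(erp = strong_erp, art = quiet_artifacts(3),
                            repetitions = 8, seed = 13)
  d1 <- login(valid, tpl); d2 <- login(valid, tpl2)
  expect_identical(d1$granted, d2$granted)
  expect_equal(d1$fraction, d2$fraction, tolerance = 1e-12)
})

test_that("device mismatch between login session and template is refused", {
  s <- simulate_session(erp = strong_erp, art = quiet_artifacts(2),
                        repetitions = 16, seed = 14)
  tpl <- register(s, quick_cfg, seed = 15)
  other <- simulate_session(device = device_spec(epoch_length = 64),
                            erp = erp_model(amplitude = 8, latency_ms = 200,
                                            width_ms = 100),
                            art = quiet_artifacts(2),
                            repetitions = 8, seed = 16)
  expect_error(login(other, tpl), "device")
})

test_that("the zero-noise benchmark separates legal from illegal logins perfectly", {
  b <- benchmark_login(n_subjects = 3, trials_per_subject = 3,
                       config = quick_cfg, erp = strong_erp,
                       art = quiet_artifacts(0),
                       reg_repetitions = 16, login_repetitions = 8,
                       amp_sd = 0.1, latency_sd = 5, seed = 7)
  expect_equal(b$legal_rate, 1.0)
  expect_equal(b$illegal_rate, 0.0)
  expect_equal(b$n_legal, 9L)
  expect_true(all(b$attempts$fraction >= 0 & b$attempts$fraction <= 1))
})

test_that("benchmarks are deterministic under the master seed", {
  a <- benchmark_login(n_subjects = 2, trials_per_subject = 2,
                       config = quick_cfg, erp = strong_erp,
                       art = quiet_artifacts(2),
                       reg_repetitions = 16, login_repetitions = 8, seed = 5)
  b <- benchmark_login(n_subjects = 2, trials_per_subject = 2,
                       config = quick_cfg, erp = strong_erp,
                       art = quiet_artifacts(2),
                       reg_repetitions = 16, login_repetitions = 8, seed = 5)
  expect_identical(a$attempts, b$attempts)
  expect_error(benchmark_login(n_subjects = 1), "2 subjects")
})

test_that("a coin-flip decision model drives both success rates to chance", {
  cfg <- auth_config(model = coin_spec(), k_channels = 7, subset = "fs1")
  b <- benchmark_login(n_subjects = 4, trials_per_subject = 10,
                       config = cfg, erp = strong_erp,
                       art = quiet_artifacts(5),
                       reg_repetitions = 16, login_repetitions = 8,
                       seed = 21)
  sd3 <- 3 * sqrt(0.25 / b$n_legal)
  expect_lt(abs(b$legal_rate - 0.5), sd3)
  expect_lt(abs(b$illegal_rate - 0.5), sd3)
})
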