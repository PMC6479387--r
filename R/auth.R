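#' Configuration of the registration/login pipeline
#'
#' Bundles the preprocessing, selection, feature and classifier settings the
#' pipeline applies at registration; login reuses the stored settings.
#'
#' @param ptp_threshold Peak-to-peak rejection threshold (uV).
#' @param ref_channels Rejection reference channels.
#' @param group_size Ensemble-averaging group size.
#' @param ica Run ICA cleaning during preprocessing.
#' @param k_channels Channels retained by the selection stage.
#' @param smooth_ahead,min_run Interval-rule parameters ([select_intervals()]).
#' @param subset `"auto"` (best-first CFS search), `"fs1"` (all seven
#'   features), `"fs2"` ({f1, f7}) or an explicit feature-id vector.
#' @param model A `"classifier_spec"` for the decision model. The default
#'   bagging composition caps BPNN training at 500 epochs: registration
#'   feature sets are nearly separable, so the 0.01 error target is reached
#'   long before that.
#' @param threshold Granting threshold on the fraction of target-source
#'   trials classified target.
#' @return Object of class `"auth_config"`.
#' @export
auth_config <- function(ptp_threshold = 75, ref_channels = c("AF3", "AF4"),
                        group_size = 8, ica = FALSE, k_channels = 8,
                        smooth_ahead = 5, min_run = 25,
                        subset = "auto",
                        model = bagging_spec(bpnn = list(max_epochs = 500)),
                        threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  structure(list(ptp_threshold = ptp_threshold,
                 ref_channels = ref_channels, group_size = group_size,
                 ica = ica, k_channels = k_channels,
                 smooth_ahead = smooth_ahead, min_run = min_run,
                 subset = subset, model = model, threshold = threshold),
            class = "auth_config")
}

auth_preprocess <- function(session, config, stage) {
  tryCatch(
    preprocess_session(session,
                       ref_channels = config$ref_channels,
                       threshold = config$ptp_threshold,
                       group_size = config$group_size,
                       by_tag = TRUE, ica = config$ica),
    error = function(e) stop(stage, " preprocessing failed: ",
                             conditionMessage(e)))
}

#' Register a subject from an oddball session
#'
#' Runs the full training pipeline on the subject's session: peak-to-peak
#' rejection and per-(class, source tag) ensemble averaging, point-biserial
#' channel/interval selection, feature extraction, subset selection,
#' min-max normalization and classifier training. The resulting template
#' stores everything login needs - nothing is re-fitted on login data.
#'
#' @param session A `"valid"`-role [simulate_session()] session (or real
#'   epochs in the same structure) containing both stimulus classes.
#' @param config An [auth_config()].
#' @param seed Master seed for subset search order and classifier training.
#' @return Object of class `"auth_template"`: `subject_id`, `device` summary,
#'   `profile`, `subset`, `norm`, `features` (stored normalized target
#'   rows), `model`, `training` (accuracy and counts), `config`, `seed`.
#' @export
register <- function(session, config = auth_config(), seed = 1) {
  stopifnot(inherits(session, "erp_session"), inherits(config, "auth_config"))
  cls <- session_classes(session)
  if (!any(cls == "target"))
    stop("registration failed: session has no target epochs")
  if (!any(cls == "nontarget"))
    stop("registration failed: session has no non-target epochs")
  pp <- auth_preprocess(session, config, "registration")
  profile <- tryCatch(
    select_profile(pp$trials, k = config$k_channels,
                   smooth_ahead = config$smooth_ahead,
                   min_run = config$min_run,
                   sampling_rate = session$device$sampling_rate),
    error = function(e) stop("registration selection failed: ",
                             conditionMessage(e)))
  if (length(profile$channels) == 0L)
    stop("registration selection failed: no discriminative channel/interval")
  fm <- build_feature_matrix(pp$trials, profile)
  with_seed(seed, {
    subset <- switch(
      if (is.character(config$subset) && length(config$subset) == 1L)
        config$subset else "explicit",
      auto = best_first_select(fm)$features,
      fs1 = FEATURE_IDS,
      fs2 = c("f1", "f7"),
      resolve_subset(config$subset))
    fm$x <- fm$x[, subset, drop = FALSE]
    fm <- normalize_features(fm)
    model_seed <- child_seeds(1L)
    model <- tryCatch(config$model$fit(fm$x, fm$labels, seed = model_seed),
                      error = function(e)
                        stop("registration training failed: ",
                             conditionMessage(e)))
    train_pred <- predict(model, fm$x, type = "class")
    structure(list(subject_id = session$subject_id,
                   device = list(
                     channel_labels = session$device$channel_labels,
                     sampling_rate = session$device$sampling_rate,
                     epoch_length = session$device$epoch_length),
                   profile = profile, subset = subset, norm = fm$norm,
                   features = fm$x[fm$labels == "target", , drop = FALSE],
                   model = model,
                   training = list(
                     accuracy = mean(train_pred == fm$labels),
                     n_rows = nrow(fm$x),
                     n_trials = length(pp$trials),
                     kept_epochs = length(pp$report$kept)),
                   config = config, seed = seed),
              class = "auth_template")
  })
}

#' @export
print.auth_template <- function(x, ...) {
  cat("Auth template for", x$subject_id, "-", length(x$profile$channels),
      "channels, features {", paste(x$subset, collapse = ", "), "},",
      x$training$n_rows, "training rows, training Acc",
      sprintf("%.3f", x$training$accuracy), "\n")
  invisible(x)
}

#' Authenticate a login session against a stored template
#'
#' Applies the template's selection profile, feature subset and stored
#' normalization parameters to the login session (no re-fitting), classifies
#' every averaged trial with the template's model, and grants access iff the
#' fraction of *target-source* trials classified target reaches the
#' threshold. A trial counts as target when at least half of its per-channel
#' feature rows vote target.
#'
#' @param session The login session (same device spec as the template).
#' @param template An [register()] template.
#' @param threshold Granting threshold; defaults to the template's config.
#' @return Object of class `"auth_decision"`: `granted`, `fraction`,
#'   `threshold`, `n_trials`, `tag_counts` (target-classified trials per
#'   source tag), `subject_id`, `template_subject`.
#' @export
login <- function(session, template, threshold = NULL) {
  stopifnot(inherits(session, "erp_session"),
            inherits(template, "auth_template"))
  dv <- session$device
  if (!identical(dv$channel_labels, template$device$channel_labels) ||
      dv$sampling_rate != template$device$sampling_rate ||
      dv$epoch_length != template$device$epoch_length)
    stop("login device does not match the template's device spec")
  if (length(session$epochs) == 0L) stop("empty login session")
  threshold <- threshold %||% template$config$threshold
  pp <- auth_preprocess(session, template$config, "login")
  trials <- Filter(function(tr) tr$stimulus_class == "target", pp$trials)
  if (length(trials) == 0L)
    stop("login session yields no target-source trials")
  fm <- build_feature_matrix(trials, template$profile)
  fm$x <- fm$x[, template$subset, drop = FALSE]
  fm <- normalize_features(fm, params = template$norm)
  votes <- predict(template$model, fm$x, type = "class")
  per_trial <- vapply(seq_along(trials), function(i)
    mean(votes[fm$provenance$trial == i] == "target"), numeric(1))
  trial_target <- per_trial >= 0.5
  # averaged by (class, source tag): every trial carries one source tag
  tag_of <- vapply(trials, function(tr) tr$source_tag %||% "target", "")
  fraction <- mean(trial_target)
  structure(list(granted = fraction >= threshold,
                 fraction = unname(fraction), threshold = threshold,
                 n_trials = length(trials),
                 tag_counts = table(tag_of[trial_target]),
                 subject_id = session$subject_id,
                 template_subject = template$subject_id),
            class = "auth_decision")
}

#' @export
print.auth_decision <- function(x, ...) {
  cat(sprintf("Login %s -> template %s: %s (%.2f of %d target-source trials; threshold %.2f)\n",
              x$subject_id, x$template_subject,
              if (x$granted) "GRANTED" else "DENIED",
              x$fraction, x$n_trials, x$threshold))
  invisible(x)
}

#' Benchmark legal and illegal login success rates
#'
#' Simulates a population of subjects (each with an individually perturbed
#' ERP: per-channel amplitude scatter and latency jitter around the base
#' model), registers each one, then runs `trials_per_subject` genuine logins
#' and `trials_per_subject` impostor logins per subject; the impostor is
#' drawn uniformly from the other subjects and - per the oddball premise -
#' shows no class-dependent ERP to the template owner's sources.
#'
#' @param n_subjects Number of simulated subjects (>= 2).
#' @param trials_per_subject Login attempts of each kind per subject.
#' @param config An [auth_config()].
#' @param device,erp,art Base simulation models ([device_spec()],
#'   [erp_model()], [artifact_model()]).
#' @param reg_repetitions,login_repetitions Stimulus blocks per registration
#'   and per login session.
#' @param amp_sd,latency_sd Between-subject log-amplitude SD and latency SD
#'   (ms) of the ERP perturbation.
#' @param impostor_mode Passed to [simulate_session()].
#' @param seed Master seed; the whole benchmark is reproducible under it.
#' @return Object of class `"login_benchmark"`: `legal_rate`,
#'   `illegal_rate`, counts, and a per-attempt data frame `attempts`.
#' @export
benchmark_login <- function(n_subjects = 5, trials_per_subject = 10,
                            config = auth_config(),
                            device = device_spec(), erp = erp_model(),
                            art = artifact_model(),
                            reg_repetitions = 24, login_repetitions = 8,
                            amp_sd = 0.15, latency_sd = 15,
                            impostor_mode = "null",
                            seed = 1) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  with_seed(seed, {
    subj_seeds <- child_seeds(n_subjects)
    erps <- lapply(seq_len(n_subjects), function(s) with_seed(
      subj_seeds[s], {
        amp <- erp$amplitude * exp(stats::rnorm(length(erp$amplitude),
                                                0, amp_sd))
        lat <- max(50, erp$latency_ms + stats::rnorm(1, 0, latency_sd))
        erp_model(amplitude = amp, channels = erp$channels,
                  latency_ms = lat, width_ms = erp$width_ms,
                  target_probability = erp$target_probability,
                  amplitude_gain = erp$amplitude_gain)
      }))
    templates <- vector("list", n_subjects)
    run_seeds <- matrix(child_seeds(n_subjects * (2 * trials_per_subject + 2)),
                        nrow = n_subjects)
    for (s in seq_len(n_subjects)) {
      reg <- simulate_session(device, erps[[s]], art,
                              repetitions = reg_repetitions, role = "valid",
                              seed = run_seeds[s, 1],
                              subject_id = paste0("S", s))
      templates[[s]] <- register(reg, config, seed = run_seeds[s, 2])
    }
    rows <- list()
    for (s in seq_len(n_subjects)) {
      for (tme in seq_len(trials_per_subject)) {
        sd1 <- run_seeds[s, 2 + tme]
        valid <- simulate_session(device, erps[[s]], art,
                                  repetitions = login_repetitions,
                                  role = "valid", seed = sd1,
                                  subject_id = paste0("S", s))
        dec_v <- login(valid, templates[[s]])
        sd2 <- run_seeds[s, 2 + trials_per_subject + tme]
        other <- with_seed(sd2, sample(setdiff(seq_len(n_subjects), s), 1))
        imp <- simulate_session(device, erps[[other]], art,
                                repetitions = login_repetitions,
                                role = "impostor",
                                impostor_mode = impostor_mode, seed = sd2,
                                subject_id = paste0("S", other))
        dec_i <- login(imp, templates[[s]])
        rows[[length(rows) + 1L]] <-
          data.frame(template = s, attempt = tme,
                     kind = c("legal", "illegal"),
                     login_subject = c(s, other),
                     granted = c(dec_v$granted, dec_i$granted),
                     fraction = c(dec_v$fraction, dec_i$fraction))
      }
    }
    attempts <- do.call(rbind, rows)
    legal <- attempts$kind == "legal"
    structure(list(legal_rate = mean(attempts$granted[legal]),
                   illegal_rate = mean(attempts$granted[!legal]),
                   n_legal = sum(legal), n_illegal = sum(!legal),
                   attempts = attempts, n_subjects = n_subjects,
                   seed = seed),
              class = "login_benchmark")
  })
}

#' @export
print.login_benchmark <- function(x, ...) {
  cat(sprintf("Login benchmark (%d subjects): legal %.1f%% (%d/%d), illegal %.1f%% (%d/%d)\n",
              x$n_subjects, 100 * x$legal_rate,
              sum(x$attempts$granted[x$attempts$kind == "legal"]), x$n_legal,
              100 * x$illegal_rate,
              sum(x$attempts$granted[x$attempts$kind == "illegal"]),
              x$n_illegal))
  invisible(x)
}
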