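# JSON serialization of fitted models and templates. Matrices are stored as
# {".matrix", dim, dimnames, data}; classifier specs as their constructor
# name + parameters, so reading rebuilds the fit closures.

plain <- function(x) {
  if (is.matrix(x))
    return(list(.matrix = TRUE, dim = dim(x), dimnames = dimnames(x),
                data = as.vector(x)))
  if (is.factor(x)) return(as.character(x))
  if (is.data.frame(x)) return(list(.df = TRUE, cols = lapply(x, plain)))
  if (is.list(x)) return(lapply(x, plain))
  x
}

unplain <- function(x) {
  if (is.list(x) && isTRUE(x$.matrix)) {
    m <- matrix(unlist(x$data), x$dim[[1]], x$dim[[2]])
    if (!is.null(x$dimnames))
      dimnames(m) <- lapply(x$dimnames, function(d)
        if (is.null(d) || !length(d)) NULL else unlist(d))
    return(m)
  }
  if (is.list(x) && isTRUE(x$.df))
    return(as.data.frame(lapply(x$cols, function(cl) unlist(unplain(cl))),
                         stringsAsFactors = FALSE))
  if (is.list(x)) return(lapply(x, unplain))
  x
}

model_to_list <- function(model) {
  cls <- class(model)[1]
  body <- switch(cls,
    gnb_model = model[c("priors", "means", "vars", "classes", "features")],
    logistic_model = model[c("coefficients", "learning_rate", "iterations",
                             "features")],
    bp_network = model[c("W1", "b1", "W2", "b2", "sizes", "mse", "epochs",
                         "termination", "features")],
    coin_classifier = model["p"],
    bagging_ensemble = list(
      learners = lapply(model$learners, model_to_list),
      specs = lapply(model$specs, spec_to_list),
      seeds = model$seeds, composition = model$composition),
    stop("cannot serialize model of class ", cls))
  c(list(.class = cls), plain(body))
}

model_from_list <- function(lst) {
  cls <- lst$.class
  body <- unplain(lst[setdiff(names(lst), ".class")])
  if (cls == "bagging_ensemble") {
    body$learners <- lapply(lst$learners, model_from_list)
    body$specs <- lapply(lst$specs, spec_from_list)
    body$seeds <- unlist(body$seeds)
    body$composition <- unlist(body$composition)
  }
  if (cls == "gnb_model") {
    body$priors <- unlist(body$priors)
    body$classes <- unlist(body$classes)
  }
  if (cls == "logistic_model")
    body$coefficients <- unlist(body$coefficients)
  if (cls == "bp_network") {
    body$b1 <- unlist(body$b1); body$b2 <- unlist(body$b2)
    body$sizes <- unlist(body$sizes)
  }
  if (!is.null(body$features)) body$features <- unlist(body$features)
  structure(body, class = cls)
}

spec_to_list <- function(spec) {
  list(builder = spec$builder,
       params = plain(spec$params[!vapply(spec$params, is.null,
                                          logical(1))]))
}

spec_from_list <- function(lst) {
  params <- unplain(lst$params)
  if (identical(lst$builder, "bagging_spec") &&
      !is.null(params$composition))
    params$composition <- lapply(params$composition, spec_from_list)
  do.call(get(lst$builder, envir = asNamespace("erpauth")),
          lapply(params, function(p) if (is.list(p)) p else unlist(p)))
}

#' Serialize / restore an authentication template
#'
#' Templates round-trip losslessly through a structured JSON file (numeric
#' arrays at full precision), so a template database is simply a directory
#' of these files keyed by subject id.
#'
#' @param template An [register()] template.
#' @param path JSON file path.
#' @return `write_template` returns `path` invisibly; `read_template` the
#'   restored `"auth_template"`.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "auth_template"))
  cfg <- template$config
  lst <- list(
    subject_id = template$subject_id,
    device = template$device,
    profile = plain(unclass(template$profile)),
    subset = template$subset,
    norm = plain(template$norm),
    features = plain(template$features),
    model = model_to_list(template$model),
    training = template$training,
    config = c(plain(unclass(cfg)[setdiff(names(unclass(cfg)), "model")]),
               list(model = spec_to_list(cfg$model))),
    seed = template$seed)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  lst <- jsonlite::read_json(path)
  profile <- unplain(lst$profile)
  profile$channels <- unlist(profile$channels)
  class(profile) <- "selection_profile"
  subset <- unlist(lst$subset)
  norm <- unplain(lst$norm)
  norm <- list(min = stats::setNames(unlist(norm$min), subset),
               max = stats::setNames(unlist(norm$max), subset),
               constant = stats::setNames(unlist(norm$constant), subset))
  cfg_raw <- unplain(lst$config)
  cfg <- auth_config(
    ptp_threshold = cfg_raw$ptp_threshold,
    ref_channels = unlist(cfg_raw$ref_channels),
    group_size = cfg_raw$group_size, ica = isTRUE(cfg_raw$ica),
    k_channels = cfg_raw$k_channels, smooth_ahead = cfg_raw$smooth_ahead,
    min_run = cfg_raw$min_run, subset = unlist(cfg_raw$subset),
    model = spec_from_list(lst$config$model),
    threshold = cfg_raw$threshold)
  structure(list(subject_id = lst$subject_id,
                 device = list(
                   channel_labels = unlist(lst$device$channel_labels),
                   sampling_rate = lst$device$sampling_rate,
                   epoch_length = lst$device$epoch_length),
                 profile = profile,
                 subset = subset,
                 norm = norm,
                 features = unplain(lst$features),
                 model = model_from_list(lst$model),
                 training = unplain(lst$training),
                 config = cfg, seed = lst$seed),
            class = "auth_template")
}
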