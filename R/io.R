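#' Write / read an epoch bundle
#'
#' The on-disk exchange format for sessions: a `metadata.txt` key-value
#' file (subject_id, role, sampling_rate, epoch_length, seed, comma-joined
#' channel labels), an `events.tsv` table (epoch_index, stimulus_class,
#' source_tag) and one tab-delimited numeric file per epoch
#' (`epoch_0001.tsv`, rows = channels in label order, columns = samples).
#'
#' @param session An [simulate_session()] session.
#' @param dir Bundle directory (created if missing).
#' @return `write_session` returns `dir` invisibly; `read_session` returns
#'   the reconstructed `"erp_session"`.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "erp_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(subject_id = session$subject_id,
            role = session$role,
            sampling_rate = session$device$sampling_rate,
            epoch_length = session$device$epoch_length,
            channels = paste(session$device$channel_labels, collapse = ","),
            repetitions = session$paradigm$repetitions,
            seed = if (is.null(session$seed)) "NA" else session$seed)
  writeLines(paste(names(meta), meta, sep = "\t"),
             file.path(dir, "metadata.txt"))
  events <- data.frame(
    epoch_index = vapply(session$epochs, `[[`, 0L, "epoch_index"),
    stimulus_class = session_classes(session),
    source_tag = vapply(session$epochs, `[[`, "", "source_tag"))
  utils::write.table(events, file.path(dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (i in seq_along(session$epochs))
    utils::write.table(session$epochs[[i]]$data,
                       file.path(dir, sprintf("epoch_%04d.tsv", i)),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta_lines <- readLines(file.path(dir, "metadata.txt"))
  kv <- strsplit(meta_lines, "\t", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  labels <- strsplit(meta[["channels"]], ",", fixed = TRUE)[[1]]
  device <- device_spec(labels, as.numeric(meta[["sampling_rate"]]),
                        as.integer(meta[["epoch_length"]]))
  events <- utils::read.table(file.path(dir, "events.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  epochs <- lapply(seq_len(nrow(events)), function(i) {
    x <- as.matrix(utils::read.table(
      file.path(dir, sprintf("epoch_%04d.tsv", i)), sep = "\t"))
    dimnames(x) <- list(labels, NULL)
    list(data = x,
         stimulus_class = events$stimulus_class[i],
         subject_id = meta[["subject_id"]],
         source_tag = events$source_tag[i],
         epoch_index = events$epoch_index[i])
  })
  seed <- suppressWarnings(as.integer(meta[["seed"]]))
  structure(list(epochs = epochs, device = device,
                 paradigm = list(n_target_sources = 3L,
                                 n_nontarget_sources = 12L,
                                 repetitions = as.integer(
                                   meta[["repetitions"]])),
                 role = meta[["role"]],
                 subject_id = meta[["subject_id"]],
                 seed = if (is.na(seed)) NULL else seed),
            class = "erp_session")
}

#' Write / read a selection profile table
#'
#' Tab-delimited table with one row per (channel, interval):
#' channel, start_ms, end_ms, start, end (sample coordinates 0-based,
#' half-open).
#'
#' @param profile A [select_profile()] result.
#' @param path Output file.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "selection_profile"))
  rows <- do.call(rbind, lapply(profile$channels, function(ch)
    cbind(channel = ch, profile$intervals[[ch]])))
  utils::write.table(rows[, c("channel", "start_ms", "end_ms",
                              "start", "end")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param sampling_rate,T Device context not stored in the table.
#' @export
read_profile <- function(path, sampling_rate = 128, T = 128) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  channels <- unique(tab$channel)
  ints <- lapply(channels, function(ch)
    tab[tab$channel == ch, c("start", "end", "start_ms", "end_ms")])
  names(ints) <- channels
  structure(list(channels = channels,
                 intervals = lapply(ints, function(d) {
                   rownames(d) <- NULL
                   d
                 }),
                 sampling_rate = sampling_rate, T = T),
            class = "selection_profile")
}

#' Write a feature matrix as a delimited table
#'
#' Header = feature ids plus `label`, `trial`, `channel` columns.
#'
#' @param fm A [build_feature_matrix()] result.
#' @param path Output file.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  tab <- data.frame(fm$x, label = as.character(fm$labels),
                    trial = fm$provenance$trial,
                    channel = fm$provenance$channel,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  feat <- setdiff(names(tab), c("label", "trial", "channel"))
  structure(list(x = as.matrix(tab[, feat, drop = FALSE]),
                 labels = factor(tab$label,
                                 levels = c("nontarget", "target")),
                 provenance = data.frame(trial = tab$trial,
                                         channel = tab$channel),
                 norm = NULL),
            class = "feature_matrix")
}
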