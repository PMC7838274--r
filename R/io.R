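#' Read a table of recording traces from CSV/TSV
#'
#' Accepts long format (`recording_id` optional, `cell_id`, `t_s`, `value`)
#' or wide format (`t_s` plus one column per cell). Validates finite values,
#' strictly increasing uniform time (relative tolerance 1e-6), and no
#' duplicate (cell, time) pairs; each violation raises a distinct named
#' error condition (`fibsir_nan_value`, `fibsir_nonmonotone_time`,
#' `fibsir_nonuniform_time`, `fibsir_duplicate_sample`,
#' `fibsir_ragged_traces`). Rows may arrive in any order; they are sorted
#' by time per cell.
#'
#' @param path CSV (or TSV; delimiter sniffed from the header line) file.
#' @param modality `"calcium"` or `"current"`.
#' @return A named list of [trace()] objects.
#' @export
read_traces <- function(path, modality = c("calcium", "current")) {
  modality <- match.arg(modality)
  hdr <- readLines(path, n = 50)
  hdr <- hdr[!startsWith(hdr, "#")][1]
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (all(c("cell_id", "t_s", "value") %in% names(df))) {
    long <- df[, c("cell_id", "t_s", "value")]
  } else if ("t_s" %in% names(df)) {
    cells <- setdiff(names(df), c("t_s", "recording_id"))
    long <- do.call(rbind, lapply(cells, function(cl) {
      data.frame(cell_id = cl, t_s = df$t_s, value = df[[cl]],
                 stringsAsFactors = FALSE)
    }))
  } else {
    stop_fibsir("expected long (cell_id, t_s, value) or wide (t_s, <cells>) layout",
                "fibsir_bad_layout")
  }
  if (anyNA(long$value) || any(!is.finite(long$value))) {
    i <- which(!is.finite(long$value))[1]
    stop_fibsir(sprintf("non-finite value at row %d (cell %s, t = %s)",
                        i, long$cell_id[i], format(long$t_s[i])),
                "fibsir_nan_value")
  }
  split_cells <- split(long, long$cell_id)
  lens <- vapply(split_cells, nrow, integer(1))
  if (length(unique(lens)) > 1L)
    stop_fibsir("cells have unequal sample counts (ragged table)",
                "fibsir_ragged_traces")
  traces <- lapply(names(split_cells), function(id) {
    d <- split_cells[[id]]
    d <- d[order(d$t_s), , drop = FALSE]
    if (anyDuplicated(d$t_s))
      stop_fibsir(sprintf("duplicate time sample for cell %s", id),
                  "fibsir_duplicate_sample")
    dt <- diff(d$t_s)
    if (any(dt <= 0))
      stop_fibsir(sprintf("non-monotone time for cell %s", id),
                  "fibsir_nonmonotone_time")
    if (diff(range(dt)) > 1e-6 * max(dt))
      stop_fibsir(sprintf("non-uniform sampling for cell %s", id),
                  "fibsir_nonuniform_time")
    trace(d$value, t = d$t_s, cell_id = id, modality = modality)
  })
  stats::setNames(traces, names(split_cells))
}

#' Write traces to a long-format CSV
#'
#' Columns `recording_id`, `cell_id`, `t_s`, `value`; a `# config_hash:`
#' header comment embeds the resolved configuration hash when a config is
#' supplied, making artifact files traceable to their run.
#'
#' @param traces A list of [trace()] objects.
#' @param path Output file.
#' @param recording_id Recording label.
#' @param config Optional [run_config()] recorded as a hash header.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, recording_id = "rec1", config = NULL) {
  long <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(recording_id = recording_id, cell_id = tr$cell_id,
               t_s = tr$t, value = tr$y, stringsAsFactors = FALSE)
  }))
  write_csv_artifact(long, path, config)
}

write_csv_artifact <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(sprintf("# config_hash: %s", config_hash(config)), con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 9))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a detected-event table to CSV
#'
#' Stable column order, 9 significant digits for floating-point columns,
#' logical flags serialized into a semicolon-joined `flags` token column
#' (e.g. `boundary_truncated;unmatched`).
#'
#' @param events Event data frame.
#' @param path Output file.
#' @param config Optional [run_config()] recorded as a hash header.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, config = NULL) {
  ev <- events
  flag_cols <- intersect(c("boundary_truncated", "matched"), names(ev))
  flags <- vapply(seq_len(nrow(ev)), function(i) {
    tok <- character(0)
    if ("boundary_truncated" %in% flag_cols && isTRUE(ev$boundary_truncated[i]))
      tok <- c(tok, "boundary_truncated")
    if ("matched" %in% flag_cols && isFALSE(ev$matched[i]))
      tok <- c(tok, "unmatched")
    paste(tok, collapse = ";")
  }, character(1))
  if (!nrow(ev)) flags <- character(0)
  ev <- ev[, setdiff(names(ev), flag_cols), drop = FALSE]
  ev$flags <- flags
  first <- intersect(c("cell_id", "t_start", "t_peak", "t_end", "amplitude",
                       "auc", "duration", "peak_offset", "rise_time"),
                     names(ev))
  ev <- ev[, c(first, setdiff(names(ev), first)), drop = FALSE]
  write_csv_artifact(ev, path, config)
}

#' Read an event table written by [write_events()]
#' @param path CSV file.
#' @return Event data frame with flags expanded back into logical columns.
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("flags" %in% names(ev)) {
    fl <- as.character(ev$flags)
    fl[is.na(fl)] <- ""
    ev$boundary_truncated <- grepl("boundary_truncated", fl)
    if (any(grepl("unmatched", fl)) || "amplitude_pA" %in% names(ev))
      ev$matched <- !grepl("unmatched", fl)
    ev$flags <- NULL
  }
  ev
}

#' Resolved run configuration
#'
#' Every tunable of the pipeline with its default, validated against the
#' known key set (unknown keys are rejected), round-trippable through YAML.
#'
#' @param ... Overrides of the defaults.
#' @return A `"run_config"` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    calcium_window_s = 5,
    current_window_s = 0.05,
    epsilon = NA_real_,            # NA: epsilon_multiple x robust noise
    epsilon_multiple_calcium = 2,
    epsilon_multiple_current = 7,
    rdp_method = "vertical",
    cutoff_fraction = 0.10,
    silent_threshold_au = 5,
    histogram_bins = 10,
    filter_cutoff_hz = 200,
    filter_order = 2,   # per pass; filtfilt gives 4 poles zero-phase
    match_tolerance_ms = 5,
    k_range = 2:6,
    standardize_features = TRUE,
    wave_bin_s = 2,
    wave_min_fraction = 0.5,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop_fibsir(paste("unknown config keys:", paste(unknown, collapse = ", ")),
                "fibsir_unknown_config_key")
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_config` returns the validated `"run_config"`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$epsilon <- if (is.null(vals$epsilon)) NA_real_ else as.numeric(vals$epsilon)
  do.call(run_config, vals)
}

#' Short stable hash of a resolved configuration
#'
#' FNV-1a over the canonical YAML serialization; embedded in artifact-file
#' headers so every output is traceable to the configuration that made it.
#'
#' @param config A [run_config()].
#' @return 8-hex-digit character hash.
#' @export
config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483648), as.integer(b))
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

#' Run the calcium analysis pipeline on co-recorded traces
#'
#' Chains FIBSI detection, per-cell summaries with and without the
#' amplitude cutoff, silent classification (on the no-cutoff summaries),
#' the Pearson/Fisher-Z adjacency of the processed recordings, and
#' synchronous-wave detection. With `output_dir` set, writes the event,
#' summary, adjacency, mean-r and wave CSV artifacts (all carrying the
#' config hash).
#'
#' @param traces Named list of calcium [trace()] objects from one culture.
#' @param config A [run_config()].
#' @param output_dir Optional directory for CSV artifacts.
#' @return List: `fits`, `events`, `events_cutoff`, `summaries` (with
#'   `is_silent`), `summaries_cutoff`, `adjacency`, `waves`, `config`.
#' @export
run_calcium_pipeline <- function(traces, config = run_config(),
                                 output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  eps <- if (is.na(config$epsilon)) NULL else config$epsilon
  fits <- lapply(traces, function(tr)
    fibsi(tr, window_s = config$calcium_window_s, epsilon = eps,
          epsilon_multiple = config$epsilon_multiple_calcium,
          rdp_method = config$rdp_method))
  events <- do.call(rbind, c(lapply(fits, function(f) f$events),
                             list(empty_events())))
  rownames(events) <- NULL
  dur <- duration_of(traces[[1]])
  ids <- vapply(traces, function(tr) tr$cell_id, character(1))
  summaries <- classify_silent(
    summarize_cells(events, dur, cell_ids = ids),
    threshold_au = config$silent_threshold_au)
  events_cutoff <- apply_amplitude_cutoff(events, config$cutoff_fraction)
  summaries_cutoff <- summarize_cells(events_cutoff, dur, cell_ids = ids)
  adjacency <- if (length(fits) >= 2L)
    build_adjacency(lapply(fits, residuals)) else NULL
  waves <- detect_sync_waves(events, n_cells = length(traces),
                             bin_s = config$wave_bin_s,
                             min_fraction = config$wave_min_fraction,
                             t_range = c(traces[[1]]$t[1], dur))
  out <- list(fits = fits, events = events, events_cutoff = events_cutoff,
              summaries = summaries, summaries_cutoff = summaries_cutoff,
              adjacency = adjacency, waves = waves, config = config)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_events(events, file.path(output_dir, "events.csv"), config)
    write_csv_artifact(summaries, file.path(output_dir, "cell_summaries.csv"),
                       config)
    if (!is.null(adjacency)) {
      adj_df <- data.frame(cell_id = adjacency$cell_ids,
                           as.data.frame(adjacency$r))
      write_csv_artifact(adj_df, file.path(output_dir, "adjacency.csv"),
                         config)
      write_csv_artifact(
        data.frame(cell_id = adjacency$cell_ids,
                   mean_r = adjacency$mean_r_per_cell),
        file.path(output_dir, "mean_pearson_r.csv"), config)
    }
    write_csv_artifact(waves, file.path(output_dir, "waves.csv"), config)
  }
  out
}

#' Run the sEPSC analysis pipeline on one current recording
#'
#' Chains zero-phase low-pass filtering, FIBSI detection on the filtered
#' trace, raw-trace amplitude matching, feature extraction, silhouette-based
#' k-medoids clustering and semantic cluster labeling.
#'
#' @param raw A current [trace()].
#' @param config A [run_config()].
#' @param output_dir Optional directory for CSV/JSON artifacts.
#' @return List: `fit` (events carry cluster assignments and labels),
#'   `model` (labeled `"cluster_model"`), `features`, `config`.
#' @export
run_epsc_pipeline <- function(raw, config = run_config(), output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  filtered <- lowpass_filter(raw, cutoff_hz = config$filter_cutoff_hz,
                             order = config$filter_order)
  eps <- if (is.na(config$epsilon)) NULL else config$epsilon
  fit <- detect_epscs(filtered, window_s = config$current_window_s,
                      epsilon = eps,
                      epsilon_multiple = config$epsilon_multiple_current)
  fit <- match_filtered_to_raw(fit, raw,
                               tolerance_ms = config$match_tolerance_ms)
  feats <- epsc_features(fit$events)
  model <- label_clusters(
    select_k_silhouette(feats, k_range = config$k_range,
                        standardize = config$standardize_features))
  ev <- fit$events
  ev$cluster <- NA_integer_
  ev$cluster_label <- NA_character_
  rows <- attr(feats, "event_rows")
  ev$cluster[rows] <- model$assignments
  ev$cluster_label[rows] <- model$labels[model$assignments]
  fit$events <- ev
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_events(ev, file.path(output_dir, "epsc_events.csv"), config)
  }
  list(fit = fit, model = model, features = feats, config = config)
}
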