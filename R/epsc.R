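#' Zero-phase low-pass filter for current traces
#'
#' Butterworth low-pass applied forward and backward (`signal::filtfilt`),
#' so filtered peaks are not time-shifted and the DC gain is exactly 1.
#' The default order-2 design gives 4 poles overall after the two passes;
#' steeper per-pass orders ring on fast synaptic events and are best
#' avoided for detection. Default cutoff 200 Hz, suitable for sEPSC
#' detection at 2 kHz.
#'
#' @param trace A current [trace()].
#' @param cutoff_hz Cutoff frequency; must be below Nyquist.
#' @param order Per-pass filter order, default 2 (4 poles effective).
#' @return A filtered [trace()].
#' @export
lowpass_filter <- function(trace, cutoff_hz = 200, order = 2) {
  stopifnot(inherits(trace, "trace"))
  fs <- 1 / trace$sample_interval_s
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop_fibsir("`cutoff_hz` must lie in (0, Nyquist)", "fibsir_bad_cutoff")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  ## odd-symmetric reflection padding suppresses the start/end transients
  ## that an unpadded forward-backward pass produces
  y <- trace$y
  n <- length(y)
  pad <- min(n - 1L, max(3L * round(fs / cutoff_hz), 9L))
  yp <- c(2 * y[1] - y[(pad + 1L):2], y, 2 * y[n] - y[(n - 1L):(n - pad)])
  yf <- signal::filtfilt(bf, yp)[(pad + 1L):(pad + n)]
  trace(yf, t = trace$t, sample_interval_s = trace$sample_interval_s,
        cell_id = trace$cell_id, modality = trace$modality)
}

#' Detect spontaneous EPSCs in a (filtered) current trace
#'
#' Runs [fibsi()] with the voltage-clamp settings: 50 ms running-median
#' window, reference traced through peaks above the median, polarity -1
#' (inward events as negative deflections). Interevent intervals are
#' computed peak-to-peak in ms, and charge transfer Q is the residual area
#' converted to pA*ms.
#'
#' @param filtered A current [trace()], typically from [lowpass_filter()].
#' @param window_s Running-median window (s), default 0.05.
#' @param epsilon Detection tolerance (pA) or `NULL` for the robust default.
#' @param epsilon_multiple Robust-noise multiple when `epsilon` is `NULL`
#'   (default 7 for current traces).
#' @return A `"fibsi"` fit whose `events` gain `amplitude_pA`,
#'   `charge_transfer_pAms` and `iei_ms` columns.
#' @export
detect_epscs <- function(filtered, window_s = 0.05, epsilon = NULL,
                         epsilon_multiple = 7) {
  stopifnot(inherits(filtered, "trace"))
  if (filtered$modality != "current")
    stop_fibsir("sEPSC detection expects a current trace", "fibsir_bad_modality")
  fit <- fibsi(filtered, window_s = window_s, side = "above", polarity = -1,
               epsilon = epsilon, epsilon_multiple = epsilon_multiple)
  ev <- fit$events
  if (nrow(ev)) {
    ev$amplitude_pA <- ev$amplitude
    ev$charge_transfer_pAms <- ev$auc * 1000
    ev$iei_ms <- c(NA_real_, diff(ev$t_peak) * 1000)
    ev$matched <- NA
  }
  fit$events <- ev
  fit
}

#' Match filtered-trace detections back to the raw recording
#'
#' Low-pass filtering attenuates fast peaks; amplitudes are therefore
#' re-measured on the unfiltered recording. For each detected event, in time
#' order, the extreme raw residual (raw trace minus the detection's
#' reference line, sign-corrected) within `tolerance_ms` of the filtered
#' peak is located; matching is one-to-one and greedy, so when two filtered
#' events compete for the same raw extremum the earlier event wins and the
#' later one is flagged unmatched (its filtered amplitude is retained).
#'
#' @param fit A `"fibsi"` fit from [detect_epscs()] on the filtered trace.
#' @param raw The unfiltered current [trace()] on the same time base.
#' @param tolerance_ms Peak-matching tolerance (ms), default 5.
#' @return The fit with event columns `amplitude_pA` (raw where matched),
#'   `raw_peak_s` and `matched` updated.
#' @export
match_filtered_to_raw <- function(fit, raw, tolerance_ms = 5) {
  stopifnot(inherits(fit, "fibsi"), inherits(raw, "trace"))
  ev <- fit$events
  if (!nrow(ev)) return(fit)
  if (length(raw$t) != length(fit$trace$t) ||
      max(abs(raw$t - fit$trace$t)) > 1e-9)
    stop_fibsir("raw and filtered traces must share one time base",
                "fibsir_bad_timebase")
  resid_raw <- fit$polarity * (raw$y - eval_reference(fit$reference, raw$t))
  tol_s <- tolerance_ms / 1000
  taken <- integer(0)
  ev$matched <- FALSE
  ev$raw_peak_s <- NA_real_
  for (i in seq_len(nrow(ev))) {
    sel <- which(raw$t >= ev$t_peak[i] - tol_s & raw$t <= ev$t_peak[i] + tol_s)
    sel <- setdiff(sel, taken)
    if (!length(sel)) next
    j <- sel[which.max(resid_raw[sel])]
    if (resid_raw[j] <= 0) next         # no raw deflection in the window
    ## claim the local extremum run around j so later events cannot reuse it
    lo <- j; hi <- j
    while (lo > 1L && resid_raw[lo - 1L] > 0) lo <- lo - 1L
    while (hi < length(resid_raw) && resid_raw[hi + 1L] > 0) hi <- hi + 1L
    taken <- c(taken, lo:hi)
    ev$matched[i] <- TRUE
    ev$raw_peak_s[i] <- raw$t[j]
    ev$amplitude_pA[i] <- resid_raw[j]
  }
  fit$events <- ev
  fit
}

#' k-medoids (PAM) clustering of sEPSC features
#'
#' Partitioning around medoids under manhattan (L1) distance on the feature
#' rows `[iei_ms, amplitude_pA, charge_transfer_pAms]`. By default each
#' feature column is first scaled by its mean absolute deviation (the same
#' rule `cluster::pam` uses), because the raw columns live on very different
#' scales (tens of pA against thousands of ms) and an unscaled L1 distance
#' is dominated by the interevent-interval axis; set `standardize = FALSE`
#' for raw-scale clustering. The first event of a cell (undefined IEI) is
#' excluded by [epsc_features()]. Implemented via `cluster::pam`
#' (BUILD + SWAP), which is deterministic for a fixed input order.
#' `k == n` is the trivial model: every event its own medoid, objective 0.
#'
#' @param features Numeric matrix/data frame of per-event feature rows.
#' @param k Number of clusters, `2 <= k <= n`.
#' @param standardize Scale each column by its mean absolute deviation
#'   before clustering (default `TRUE`); zero-spread columns are left
#'   unscaled.
#' @return Object of class `"cluster_model"`: `k`, `medoid_ids` (row
#'   indices), `assignments`, `avg_silhouette`, `silhouette_widths`,
#'   `objective` (sum of distances to medoids in the clustering space),
#'   `medoids` (feature rows in raw units).
#' @export
pam_cluster <- function(features, k, standardize = TRUE) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (k > n) stop_fibsir("k cannot exceed the number of events",
                         "fibsir_bad_k")
  if (k < 1) stop_fibsir("k must be >= 1", "fibsir_bad_k")
  if (k == n) {
    return(structure(list(k = k, medoid_ids = seq_len(n),
                          assignments = seq_len(n),
                          avg_silhouette = NA_real_,
                          silhouette_widths = rep(NA_real_, n),
                          objective = 0, medoids = x, labels = NULL),
                     class = "cluster_model"))
  }
  xs <- if (standardize) scale_mad(x) else x
  fit <- cluster::pam(xs, k, metric = "manhattan", stand = FALSE,
                      keep.diss = FALSE, keep.data = FALSE)
  sw <- if (k >= 2L) fit$silinfo$widths else NULL
  widths <- rep(NA_real_, n)
  if (!is.null(sw)) widths[as.integer(rownames(sw))] <- sw[, "sil_width"]
  structure(list(k = k, medoid_ids = as.integer(fit$id.med),
                 assignments = as.integer(fit$clustering),
                 avg_silhouette = if (k >= 2L) fit$silinfo$avg.width else NA_real_,
                 silhouette_widths = widths,
                 objective = objective_l1(xs, as.integer(fit$id.med),
                                          as.integer(fit$clustering)),
                 medoids = x[fit$id.med, , drop = FALSE], labels = NULL),
            class = "cluster_model")
}

## scale columns by mean absolute deviation from the column mean
## (cluster::pam's standardization rule); zero-spread columns untouched
scale_mad <- function(x) {
  for (j in seq_len(ncol(x))) {
    s <- mean(abs(x[, j] - mean(x[, j])))
    if (s > 0) x[, j] <- x[, j] / s
  }
  x
}

objective_l1 <- function(x, medoid_ids, assignments) {
  sum(vapply(seq_len(nrow(x)), function(i) {
    sum(abs(x[i, ] - x[medoid_ids[assignments[i]], ]))
  }, numeric(1)))
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, avg silhouette = %.3f, L1 objective = %.4g\n",
              x$k, x$avg_silhouette, x$objective))
  if (!is.null(x$labels)) {
    tab <- table(factor(x$labels[x$assignments], levels = x$labels))
    cat("  clusters:",
        paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract the clustering feature rows from detected sEPSCs
#'
#' @param events Event data frame from [detect_epscs()] (after matching).
#' @return Matrix with columns `iei_ms`, `amplitude_pA`,
#'   `charge_transfer_pAms`; the first event (undefined IEI) is dropped.
#'   Attribute `event_rows` maps feature rows back to event rows.
#' @export
epsc_features <- function(events) {
  keep <- which(!is.na(events$iei_ms))
  x <- as.matrix(events[keep, c("iei_ms", "amplitude_pA",
                                "charge_transfer_pAms")])
  rownames(x) <- NULL
  attr(x, "event_rows") <- keep
  x
}

#' Select the number of sEPSC clusters by average silhouette width
#'
#' Fits [pam_cluster()] for each `k` in `k_range` (restricted to `k < n`)
#' and returns the model with the largest average silhouette width, with
#' the full k-to-silhouette profile attached.
#'
#' @param features Feature matrix (see [epsc_features()]).
#' @param k_range Candidate cluster counts, default `2:6`.
#' @param standardize Passed to [pam_cluster()].
#' @return The selected `"cluster_model"` with a `silhouette_profile`
#'   data frame (`k`, `avg_silhouette`) attached.
#' @export
select_k_silhouette <- function(features, k_range = 2:6,
                                standardize = TRUE) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 3L)
    stop_fibsir("need at least 3 events to select k", "fibsir_too_few_events")
  if (all(apply(x, 2, function(col) stats::var(col) == 0)))
    stop_fibsir("all feature rows identical; clustering is degenerate",
                "fibsir_degenerate_features")
  ks <- k_range[k_range >= 2 & k_range < n]
  if (!length(ks))
    stop_fibsir("no feasible k in k_range", "fibsir_bad_k")
  fits <- lapply(ks, function(k) pam_cluster(x, k, standardize))
  sil <- vapply(fits, function(f) f$avg_silhouette, numeric(1))
  best <- fits[[which.max(sil)]]
  best$silhouette_profile <- data.frame(k = ks, avg_silhouette = sil)
  best
}

#' Name sEPSC clusters by medoid amplitude and interevent interval
#'
#' The cluster with the largest medoid amplitude is `"large"` — demoted to
#' `"medium"` when `k >= 4` and its medoid amplitude is under twice the
#' smallest medoid amplitude. The remaining clusters are `"small"`, ordered
#' by medoid IEI: a single one is `"small"`; two are `"small;short"` /
#' `"small;long"`; three or more interpolate `"small;mid"` grades.
#'
#' @param model A `"cluster_model"` whose features carried `amplitude_pA`
#'   and `iei_ms` columns.
#' @return The model with a `labels` character vector (one per cluster).
#' @export
label_clusters <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  med <- model$medoids
  amp <- med[, "amplitude_pA"]
  iei <- med[, "iei_ms"]
  k <- model$k
  labels <- character(k)
  big <- which.max(amp)
  labels[big] <- if (k >= 4 && max(amp) < 2 * min(amp)) "medium" else "large"
  rest <- setdiff(seq_len(k), big)
  if (length(rest) == 1L) {
    labels[rest] <- "small"
  } else if (length(rest)) {
    ord <- rest[order(iei[rest])]
    grade <- if (length(ord) == 2L) c("small;short", "small;long")
             else c("small;short",
                    if (length(ord) == 3L) "small;mid"
                    else sprintf("small;mid%d", seq_len(length(ord) - 2L)),
                    "small;long")
    labels[ord] <- grade
  }
  model$labels <- labels
  model
}
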