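#' Running median of a trace
#'
#' Sliding (time-windowed) median used as the slow baseline estimate. Element
#' `i` is the median of all samples whose time lies within `window_s / 2` of
#' `t[i]`; the window is truncated (shrinks) at the recording edges.
#'
#' Typical windows: ~5 s (5-25 s) for calcium fluorescence sampled around
#' 1 frame/s; 50 ms for voltage-clamp current sampled at 2 kHz.
#'
#' @param trace A [trace()] object.
#' @param window_s Full window width in seconds; must be at least one
#'   sampling interval.
#' @return Numeric vector, same length as the trace.
#' @examples
#' tr <- trace(c(1, 9, 1, 9, 1), sample_interval_s = 1)
#' running_median(tr, window_s = 3)  # 5 1 9 1 5
#' @export
running_median <- function(trace, window_s) {
  stopifnot(inherits(trace, "trace"))
  dt <- trace$sample_interval_s
  if (!is.finite(window_s) || window_s < dt)
    stop_fibsir("`window_s` must cover at least one sampling interval",
                "fibsir_bad_window")
  y <- trace$y
  n <- length(y)
  h <- floor(window_s / 2 / dt + 1e-9)   # half-width in samples
  if (h == 0L) return(y)
  k <- 2L * as.integer(h) + 1L
  if (k >= n) {
    out <- vapply(seq_len(n), function(i) {
      stats::median(y[max(1L, i - h):min(n, i + h)])
    }, numeric(1))
    return(out)
  }
  out <- stats::runmed(y, k, endrule = "keep")
  idx <- c(seq_len(h), seq.int(n - h + 1L, n))
  out[idx] <- vapply(idx, function(i) {
    stats::median(y[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
  as.numeric(out)
}

#' Trace the reference polyline through peaks on one side of the running median
#'
#' The reference line of the FIBSI procedure: local extrema of the signal on
#' the stated side of its running median (troughs for `side = "below"`, as
#' used for calcium; peaks for `side = "above"`, as used for inward synaptic
#' currents) are connected by linear interpolation. Both endpoints are clamped
#' to `min(y, median)` (resp. `max`) so the polyline spans the recording.
#'
#' @param trace A [trace()] object.
#' @param median_y Running median from [running_median()] on the same trace.
#' @param side `"below"` or `"above"`.
#' @return Object of class `"fibsi_reference"`: list with `knot_times`,
#'   `knot_values`, `side`. Evaluate anywhere with [eval_reference()].
#' @export
build_reference <- function(trace, median_y, side = c("below", "above")) {
  side <- match.arg(side)
  stopifnot(inherits(trace, "trace"))
  y <- trace$y
  t <- trace$t
  n <- length(y)
  if (length(median_y) != n)
    stop_fibsir("median vector length must match the trace",
                "fibsir_bad_reference")
  sgn <- if (side == "below") 1 else -1
  w <- sgn * y            # work on a flipped copy so we always seek minima
  m <- sgn * median_y

  ## interior local minima of w, plateaus contributing their first sample:
  ## a maximal run of equal values is a (weak) local minimum when both
  ## neighbours are higher (or absent), and it must touch the stated side of
  ## the median
  r <- rle(w)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(starts)
  knots <- integer(0)
  if (nr > 1L) {
    v <- r$values
    left_up <- c(TRUE, v[-nr] > v[-1L])
    right_up <- c(v[-1L] > v[-nr], TRUE)
    sideok <- v <= m[starts]
    long <- which(r$lengths > 1L & !sideok)
    for (q in long) sideok[q] <- any(v[q] <= m[starts[q]:ends[q]])
    knots <- starts[left_up & right_up & sideok & starts > 1L]
  }

  if (length(knots) == 0L && !any(w <= m)) {
    warning("trace lies entirely on the wrong side of its running median; ",
            "using a flat reference at the global extremum")
    v <- if (side == "below") min(y) else max(y)
    return(structure(list(knot_times = c(t[1], t[n]), knot_values = c(v, v),
                          side = side, degenerate = TRUE),
                     class = "fibsi_reference"))
  }

  kt <- t[knots]
  kv <- y[knots]
  ## endpoint clamping
  v1 <- if (side == "below") min(y[1], median_y[1]) else max(y[1], median_y[1])
  vn <- if (side == "below") min(y[n], median_y[n]) else max(y[n], median_y[n])
  if (length(knots) == 0L || knots[1] != 1L) { kt <- c(t[1], kt); kv <- c(v1, kv) }
  if (knots[length(knots)] %||% 0L != n) { kt <- c(kt, t[n]); kv <- c(kv, vn) }
  structure(list(knot_times = kt, knot_values = kv, side = side,
                 degenerate = FALSE),
            class = "fibsi_reference")
}

`%||%` <- function(a, b) if (length(a)) a else b

#' Evaluate a reference polyline at given times
#' @param reference A `"fibsi_reference"` object.
#' @param t Times (s) within the knot span.
#' @return Interpolated reference values.
#' @export
eval_reference <- function(reference, t) {
  stopifnot(inherits(reference, "fibsi_reference"))
  stats::approx(reference$knot_times, reference$knot_values, xout = t,
                rule = 2)$y
}

#' Ramer-Douglas-Peucker polyline simplification
#'
#' Recursively retains the point of maximum deviation from the chord joining
#' the current segment's endpoints whenever that deviation exceeds `epsilon`.
#' Deviation is measured vertically (in signal units at fixed time) by
#' default, which makes the simplification equivariant under rescaling the
#' signal axis; classical `"perpendicular"` point-to-chord distance is also
#' available. Ties in the maximum deviation break to the first (lowest) index,
#' so the output is deterministic.
#'
#' @param x,y Coordinates of the polyline (x strictly increasing for
#'   `method = "vertical"`).
#' @param epsilon Tolerance, in signal units (>= 0).
#' @param method `"vertical"` or `"perpendicular"`.
#' @return Integer vector of retained indices (always includes both
#'   endpoints), in increasing order.
#' @examples
#' rdp_simplify(1:5, c(0, 0, 5, 0, 0), epsilon = 1)  # keeps 1, 3, 5
#' @export
rdp_simplify <- function(x, y, epsilon, method = c("vertical", "perpendicular")) {
  method <- match.arg(method)
  n <- length(x)
  stopifnot(length(y) == n, n >= 2L)
  if (!is.finite(epsilon) || epsilon < 0)
    stop_fibsir("`epsilon` must be >= 0", "fibsir_bad_epsilon")
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  ## iterative stack version of the recursive algorithm
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i0 <- seg[1]; i1 <- seg[2]
    if (i1 - i0 < 2L) next
    idx <- (i0 + 1L):(i1 - 1L)
    d <- segment_deviation(x, y, i0, i1, idx, method)
    dmax <- max(d)
    if (dmax > epsilon) {
      imax <- idx[which.max(d)]   # first index on ties
      keep[imax] <- TRUE
      stack[[length(stack) + 1L]] <- c(imax, i1)
      stack[[length(stack) + 1L]] <- c(i0, imax)
    }
  }
  which(keep)
}

segment_deviation <- function(x, y, i0, i1, idx, method) {
  dx <- x[i1] - x[i0]
  dy <- y[i1] - y[i0]
  if (method == "vertical") {
    yhat <- y[i0] + dy * (x[idx] - x[i0]) / dx
    abs(y[idx] - yhat)
  } else {
    len <- sqrt(dx^2 + dy^2)
    if (len == 0) {
      sqrt((x[idx] - x[i0])^2 + (y[idx] - y[i0])^2)
    } else {
      abs(dy * x[idx] - dx * y[idx] + x[i1] * y[i0] - y[i1] * x[i0]) / len
    }
  }
}

#' Detect waveforms against a reference line (FIBSI detection)
#'
#' The residual is `polarity * (y - reference(t))`; maximal runs of strictly
#' positive residual are candidate events. Each run is RDP-simplified at
#' `epsilon`, and kept only if its maximum deviation exceeds `epsilon`
#' (i.e. the simplification retains an interior point). Event metrics are
#' computed from the raw, unsimplified residual within the run.
#'
#' @param trace A [trace()] object.
#' @param reference A `"fibsi_reference"` spanning the same times.
#' @param epsilon Detection tolerance in signal units.
#' @param polarity `+1` to detect deflections above the reference (calcium
#'   transients, outward currents), `-1` for deflections below it (inward
#'   currents); `-1` simply sign-flips the residual.
#' @param rdp_method Deviation metric passed to [rdp_simplify()].
#' @return A data frame of events (possibly 0 rows) with columns `cell_id`,
#'   `t_start`, `t_peak`, `t_end`, `amplitude`, `auc`, `duration`,
#'   `peak_offset`, `rise_time`, `boundary_truncated`.
#' @seealso [fibsi()] for the one-call interface.
#' @export
detect_events <- function(trace, reference, epsilon, polarity = 1,
                          rdp_method = "vertical") {
  stopifnot(inherits(trace, "trace"), inherits(reference, "fibsi_reference"))
  if (!polarity %in% c(-1, 1))
    stop_fibsir("`polarity` must be +1 or -1", "fibsir_bad_polarity")
  t <- trace$t
  n <- length(t)
  span <- range(reference$knot_times)
  if (t[1] < span[1] - 1e-9 || t[n] > span[2] + 1e-9)
    stop_fibsir("reference does not span the trace", "fibsir_bad_reference")
  resid <- polarity * (trace$y - eval_reference(reference, t))
  runs <- positive_runs(resid)
  runs <- runs[vapply(runs, function(rn) rn[2] - rn[1] >= 1L, logical(1))]
  ## the simplification sees each run plus its flanking baseline samples, so
  ## flat-topped waveforms still deviate from the chord; RDP retains an
  ## interior point iff the max deviation from the endpoint chord exceeds
  ## epsilon, so the keep-test needs only the first split
  kept <- vapply(runs, function(rn) {
    j0 <- max(1L, rn[1] - 1L); j1 <- min(n, rn[2] + 1L)
    max(segment_deviation(t, resid, j0, j1, (j0 + 1L):(j1 - 1L),
                          rdp_method)) > epsilon
  }, logical(1))
  runs <- runs[kept]
  out <- quantify_runs(trace$cell_id, t, resid, runs, n)
  validate_events(out, t[1], t[n])
  out
}

positive_runs <- function(resid) {
  pos <- resid > 0
  if (!any(pos)) return(list())
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(c, starts[r$values], ends[r$values])
}

quantify_runs <- function(cell_id, t, resid, runs, n) {
  if (!length(runs)) return(empty_events())
  nr <- length(runs)
  t_start <- t_end <- t_peak <- amp <- auc <- numeric(nr)
  bt <- logical(nr)
  for (q in seq_len(nr)) {
    i0 <- runs[[q]][1]; i1 <- runs[[q]][2]
    idx <- i0:i1
    rr <- resid[idx]
    ipk <- idx[which.max(rr)]           # first index on ties
    t_start[q] <- t[i0]; t_end[q] <- t[i1]; t_peak[q] <- t[ipk]
    amp[q] <- max(rr)
    auc[q] <- trapz(t[idx], rr)
    bt[q] <- (i0 == 1L || i1 == n)
  }
  data.frame(
    cell_id = cell_id, t_start = t_start, t_peak = t_peak, t_end = t_end,
    amplitude = amp, auc = auc, duration = t_end - t_start,
    peak_offset = t_peak - (t_start + t_end) / 2,
    rise_time = t_peak - t_start, boundary_truncated = bt,
    stringsAsFactors = FALSE
  )
}

trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

empty_events <- function() {
  data.frame(cell_id = character(0), t_start = numeric(0), t_peak = numeric(0),
             t_end = numeric(0), amplitude = numeric(0), auc = numeric(0),
             duration = numeric(0), peak_offset = numeric(0),
             rise_time = numeric(0), boundary_truncated = logical(0),
             stringsAsFactors = FALSE)
}

validate_events <- function(ev, t0, tN) {
  if (!nrow(ev)) return(invisible(ev))
  stopifnot(
    all(ev$t_start < ev$t_end),
    all(ev$t_start <= ev$t_peak & ev$t_peak <= ev$t_end),
    all(ev$amplitude > 0),
    all(ev$t_start >= t0 - 1e-9), all(ev$t_end <= tN + 1e-9),
    !is.unsorted(ev$t_start),
    all(diff(ev$t_start) > 0),
    all(utils::head(ev$t_end, -1) <= utils::tail(ev$t_start, -1) + 1e-12)
  )
  invisible(ev)
}

#' Robust noise estimate of a residual trace
#'
#' `1.4826 * median(|r - median(r)|)` — the MAD scaled to estimate the
#' Gaussian standard deviation, computed on the reference-subtracted trace.
#'
#' @param resid Residual vector.
#' @return Scalar noise estimate in signal units.
#' @export
robust_noise <- function(resid) {
  1.4826 * stats::median(abs(resid - stats::median(resid)))
}

#' FIBSI event detection on one trace
#'
#' One-call interface chaining [running_median()], [build_reference()] and
#' [detect_events()]. When `epsilon` is `NULL` it defaults to twice the
#' robust noise estimate ([robust_noise()]) of the reference-subtracted trace.
#'
#' Defaults follow the modality: calcium traces use a 5 s median window,
#' troughs below the median as the reference and polarity `+1`; current
#' traces use a 50 ms window, peaks above the median and polarity `-1`
#' (inward events).
#'
#' @param trace A [trace()] object.
#' @param window_s Running-median window (s); default 5 for calcium,
#'   0.05 for current.
#' @param side Side of the median to trace the reference on; default
#'   `"below"` for calcium, `"above"` for current.
#' @param polarity +1 or -1; default +1 for calcium, -1 for current.
#' @param epsilon Detection tolerance in signal units, or `NULL` for
#'   `epsilon_multiple * robust_noise(residual)`.
#' @param epsilon_multiple Multiple of the robust noise used when `epsilon`
#'   is `NULL`: 2 for calcium; 7 for current traces, where the far larger
#'   sample count (2 kHz) would otherwise let noise runs through.
#' @param rdp_method Deviation metric for [rdp_simplify()].
#' @return Object of class `"fibsi"`: list with the input `trace`, the
#'   running `median`, the `reference` polyline, the signed `residual`,
#'   `epsilon`, `noise`, and the `events` data frame.
#' @examples
#' sim <- simulate_calcium_network(calcium_network_params(n_cells = 1,
#'   frac_silent = 0, duration_s = 120, seed = 1))
#' fit <- fibsi(sim$traces[[1]])
#' summary(fit)
#' @export
fibsi <- function(trace, window_s = NULL, side = NULL, polarity = NULL,
                  epsilon = NULL, epsilon_multiple = NULL,
                  rdp_method = "vertical") {
  stopifnot(inherits(trace, "trace"))
  is_cur <- trace$modality == "current"
  if (is.null(window_s)) window_s <- if (is_cur) 0.05 else 5
  if (is.null(side)) side <- if (is_cur) "above" else "below"
  if (is.null(polarity)) polarity <- if (is_cur) -1 else 1
  if (is.null(epsilon_multiple)) epsilon_multiple <- if (is_cur) 7 else 2
  med <- running_median(trace, window_s)
  ref <- build_reference(trace, med, side)
  resid <- polarity * (trace$y - eval_reference(ref, trace$t))
  noise <- robust_noise(resid)
  if (is.null(epsilon)) epsilon <- epsilon_multiple * noise
  ev <- detect_events(trace, ref, epsilon, polarity, rdp_method)
  structure(list(trace = trace, median = med, reference = ref,
                 residual = resid, polarity = polarity, side = side,
                 window_s = window_s, epsilon = epsilon, noise = noise,
                 events = ev),
            class = "fibsi")
}

#' @export
print.fibsi <- function(x, ...) {
  cat(sprintf(
    "FIBSI fit: cell %s (%s)\n  window %g s, reference side '%s', polarity %+d\n  epsilon %.4g (robust noise %.4g)\n  %d events detected\n",
    x$trace$cell_id, x$trace$modality, x$window_s, x$side, x$polarity,
    x$epsilon, x$noise, nrow(x$events)))
  invisible(x)
}

#' @export
summary.fibsi <- function(object, ...) {
  ev <- object$events
  out <- list(
    cell_id = object$trace$cell_id,
    n_events = nrow(ev),
    duration_s = duration_of(object$trace),
    frequency_hz = nrow(ev) / duration_of(object$trace),
    mean_amplitude = if (nrow(ev)) mean(ev$amplitude) else NA_real_,
    mean_auc = if (nrow(ev)) mean(ev$auc) else NA_real_,
    epsilon = object$epsilon
  )
  class(out) <- "summary.fibsi"
  out
}

#' @export
print.summary.fibsi <- function(x, ...) {
  cat(sprintf(
    "cell %s: %d events over %.4g s (%.4g Hz); mean amplitude %.4g, mean AUC %.4g (epsilon %.4g)\n",
    x$cell_id, x$n_events, x$duration_s, x$frequency_hz,
    x$mean_amplitude, x$mean_auc, x$epsilon))
  invisible(x)
}

#' @export
residuals.fibsi <- function(object, ...) object$residual

#' @export
plot.fibsi <- function(x, show_events = TRUE, ...) {
  tr <- x$trace
  unit <- if (tr$modality == "current") "current (pA)" else "fluorescence (AU)"
  graphics::plot(tr$t, tr$y, type = "l", xlab = "time (s)", ylab = unit,
                 main = sprintf("%s: %d events", tr$cell_id, nrow(x$events)),
                 ...)
  graphics::lines(tr$t, x$median, col = "grey50", lty = 2)
  graphics::lines(tr$t, eval_reference(x$reference, tr$t), col = "red")
  if (show_events && nrow(x$events)) {
    ypk <- stats::approx(tr$t, tr$y, xout = x$events$t_peak)$y
    graphics::points(x$events$t_peak, ypk, pch = 4, col = "red")
  }
  invisible(x)
}
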