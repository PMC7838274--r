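#' Construct a uniformly sampled recording trace
#'
#' A `trace` is the basic unit every analysis in this package consumes: one
#' cell's uniformly sampled signal — fluorescence intensity in arbitrary units
#' (AU) for calcium imaging, or membrane current in pA for voltage clamp.
#'
#' @param y Numeric signal vector (AU or pA). All values must be finite.
#' @param t Optional time vector in seconds, strictly increasing and uniform
#'   (relative tolerance `1e-9`). If omitted, built from `sample_interval_s`.
#' @param sample_interval_s Sampling interval in seconds; required when `t`
#'   is missing, otherwise inferred and checked.
#' @param cell_id Identifier for the cell.
#' @param modality `"calcium"` (slow fluorescence) or `"current"`
#'   (voltage-clamp current).
#'
#' @return An object of class `"trace"`: a list with elements `cell_id`,
#'   `t`, `y`, `sample_interval_s`, `modality`.
#' @examples
#' tr <- trace(rnorm(100), sample_interval_s = 1, cell_id = "c1")
#' print(tr)
#' @export
trace <- function(y, t = NULL, sample_interval_s = NULL, cell_id = "cell",
                  modality = c("calcium", "current")) {
  modality <- match.arg(modality)
  y <- as.numeric(y)
  if (length(y) < 2L)
    stop("a trace needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(y)))
    stop("trace values must be finite", call. = FALSE)
  if (is.null(t)) {
    if (is.null(sample_interval_s))
      stop("provide either `t` or `sample_interval_s`", call. = FALSE)
    if (!is.finite(sample_interval_s) || sample_interval_s <= 0)
      stop("`sample_interval_s` must be > 0", call. = FALSE)
    t <- (seq_along(y) - 1) * sample_interval_s
  } else {
    t <- as.numeric(t)
    if (length(t) != length(y))
      stop("`t` and `y` must have equal length", call. = FALSE)
    if (!all(is.finite(t)))
      stop("time values must be finite", call. = FALSE)
    dt <- diff(t)
    if (any(dt <= 0))
      stop("`t` must be strictly increasing", call. = FALSE)
    if (diff(range(dt)) > 1e-9 * max(abs(dt)))
      stop("`t` must be uniformly sampled (relative tolerance 1e-9)",
           call. = FALSE)
    if (is.null(sample_interval_s)) sample_interval_s <- mean(dt)
  }
  structure(
    list(cell_id = as.character(cell_id), t = t, y = y,
         sample_interval_s = sample_interval_s, modality = modality),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> cell %s (%s): %d samples, dt = %g s, span %.6g-%.6g s\n",
              x$cell_id, x$modality, length(x$y), x$sample_interval_s,
              x$t[1], x$t[length(x$t)]))
  invisible(x)
}

#' @export
plot.trace <- function(x, ...) {
  unit <- if (x$modality == "current") "current (pA)" else "fluorescence (AU)"
  graphics::plot(x$t, x$y, type = "l", xlab = "time (s)", ylab = unit,
                 main = x$cell_id, ...)
  invisible(x)
}

duration_of <- function(tr) tr$t[length(tr$t)] - tr$t[1]

## Deterministic per-stream seed derived from one global seed, so that
## adding cells (higher stream ids) never perturbs existing streams.
substream_seed <- function(seed, stream) {
  s <- ((as.double(seed) %% 2147483647) * 48271) %% 2147483647
  as.integer((s + 1000003 * (as.double(stream) + 1)) %% 2147483647)
}

stop_fibsir <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "fibsir_error", "error")))
}
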