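#' Normalize a processed trace to the unit interval
#'
#' Min-max scaling `(x - min) / (max - min)` of a reference-subtracted
#' (FIBSI-processed) recording, the normalization applied before computing
#' Pearson adjacency. A constant trace maps to all zeros.
#'
#' @param x Numeric vector (typically `residuals()` of a [fibsi()] fit).
#' @return Vector in `[0, 1]`.
#' @examples
#' normalize_processed_trace(c(2, 4, 6))  # 0 0.5 1
#' @export
normalize_processed_trace <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Pearson adjacency matrix for co-recorded cells
#'
#' Pairwise Pearson correlations between the normalized, FIBSI-processed
#' recordings of cells imaged together in the same culture, plus each cell's
#' mean correlation with its partners on the Fisher-Z scale. Zero-variance
#' traces get correlation 0 with all partners and are flagged.
#'
#' @param residuals A list (or matrix with one column per cell) of equal
#'   length processed traces; names/colnames give cell ids.
#' @param normalize Min-max normalize each trace first (default `TRUE`).
#' @return Object of class `"adjacency"`: list with `cell_ids`, `r`
#'   (symmetric, unit diagonal), `mean_r_per_cell` (Fisher-Z
#'   back-transformed, diagonal excluded), `zero_variance` flags.
#' @export
build_adjacency <- function(residuals, normalize = TRUE) {
  if (is.list(residuals)) {
    lens <- lengths(residuals)
    if (length(unique(lens)) != 1L)
      stop_fibsir("co-recorded traces must have equal length",
                  "fibsir_ragged_traces")
    m <- do.call(cbind, residuals)
    if (!is.null(names(residuals))) colnames(m) <- names(residuals)
  } else {
    m <- as.matrix(residuals)
  }
  if (ncol(m) < 2L)
    stop_fibsir("need >= 2 co-recorded cells", "fibsir_too_few_cells")
  if (is.null(colnames(m))) colnames(m) <- sprintf("cell%03d", seq_len(ncol(m)))
  if (normalize) m <- apply(m, 2, normalize_processed_trace)
  zv <- apply(m, 2, function(col) stats::var(col) == 0)
  r <- matrix(0, ncol(m), ncol(m), dimnames = list(colnames(m), colnames(m)))
  ok <- !zv
  if (sum(ok) >= 2L) r[ok, ok] <- stats::cor(m[, ok, drop = FALSE])
  diag(r) <- 1
  out <- structure(list(cell_ids = colnames(m), r = r, zero_variance = zv),
                   class = "adjacency")
  out$mean_r_per_cell <- vapply(seq_len(ncol(m)), function(i)
    mean_pearson_fisher(out, i), numeric(1))
  names(out$mean_r_per_cell) <- colnames(m)
  out
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("<adjacency> %d cells; mean of per-cell Fisher-Z mean r = %.3f\n",
              length(x$cell_ids), mean(x$mean_r_per_cell)))
  if (any(x$zero_variance))
    cat(sprintf("  %d zero-variance cell(s) flagged (correlations set to 0)\n",
                sum(x$zero_variance)))
  invisible(x)
}

#' Fisher-Z mean Pearson correlation for one cell
#'
#' Off-diagonal correlations of the cell are transformed with
#' `z = arctanh(r)` (after clipping `|r|` at `1 - 1e-7`), averaged, and
#' back-transformed with `tanh`.
#'
#' @param adjacency An `"adjacency"` object (or a plain correlation matrix).
#' @param cell Cell index or id.
#' @return Scalar mean correlation.
#' @examples
#' r <- matrix(c(1, .3, .6, .3, 1, 0, .6, 0, 1), 3)
#' mean_pearson_fisher(r, 1)  # tanh(mean(atanh(c(.3, .6))))
#' @export
mean_pearson_fisher <- function(adjacency, cell) {
  r <- if (inherits(adjacency, "adjacency")) adjacency$r else as.matrix(adjacency)
  if (is.character(cell)) cell <- match(cell, rownames(r))
  if (ncol(r) < 2L)
    stop_fibsir("cell has no partners (single-cell culture)",
                "fibsir_too_few_cells")
  rr <- r[cell, -cell]
  z <- atanh(pmin(pmax(rr, -(1 - 1e-7)), 1 - 1e-7))
  tanh(mean(z))
}

#' Compare network synchrony between two conditions
#'
#' Per-cell Fisher-Z mean correlations are computed within each culture only
#' (cells are never correlated across cultures), pooled per condition, and
#' compared with a Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param cultures_a,cultures_b Lists of cultures; each culture is a list of
#'   processed traces (or an `"adjacency"` object).
#' @param label_a,label_b Condition labels.
#' @return List with per-condition `mean_r` vectors, the `wilcox.test`
#'   result (`test`), `p`, and a `low_power` flag when either condition has
#'   a single culture.
#' @export
condition_synchrony_compare <- function(cultures_a, cultures_b,
                                        label_a = "A", label_b = "B") {
  pool <- function(cultures) {
    if (!length(cultures))
      stop_fibsir("a condition has no cultures", "fibsir_empty_condition")
    unlist(lapply(cultures, function(cu) {
      adj <- if (inherits(cu, "adjacency")) cu else build_adjacency(cu)
      adj$mean_r_per_cell
    }))
  }
  a <- pool(cultures_a); b <- pool(cultures_b)
  ht <- stats::wilcox.test(a, b, exact = FALSE)
  list(mean_r = stats::setNames(list(a, b), c(label_a, label_b)),
       median_difference = stats::median(a) - stats::median(b),
       test = ht, p = ht$p.value,
       low_power = length(cultures_a) < 2L || length(cultures_b) < 2L)
}

#' Detect synchronous network waves from per-cell event peaks
#'
#' A wave is a time bin in which at least `min_fraction` of the co-recorded
#' cells have an event peak. The bin width and fraction are an explicit
#' operational criterion of this package (the raster "wave" annotation has
#' no published quantitative definition), recorded in the result.
#'
#' @param events Event data frame for the co-recorded cells (`cell_id`,
#'   `t_peak`).
#' @param n_cells Number of co-recorded cells (>= number represented in
#'   `events`).
#' @param bin_s Bin width (s), default 2.
#' @param min_fraction Minimum participating fraction, default 0.5.
#' @param t_range Recording span (s); default spans the observed peaks.
#' @return Data frame of wave bins: `t_start`, `t_mid`, `t_end`,
#'   `n_cells_active`, `fraction`; attribute `criterion` records the rule.
#' @export
detect_sync_waves <- function(events, n_cells, bin_s = 2, min_fraction = 0.5,
                              t_range = NULL) {
  crit <- list(bin_s = bin_s, min_fraction = min_fraction,
               definition = "package-defined: bin with >= min_fraction of cells peaking")
  empty <- data.frame(t_start = numeric(0), t_mid = numeric(0),
                      t_end = numeric(0), n_cells_active = integer(0),
                      fraction = numeric(0))
  attr(empty, "criterion") <- crit
  if (!nrow(events)) return(empty)
  t_range <- t_range %||% c(0, max(events$t_peak))
  breaks <- seq(t_range[1], t_range[2] + bin_s, by = bin_s)
  bin <- findInterval(events$t_peak, breaks, rightmost.closed = TRUE)
  active <- tapply(events$cell_id, bin, function(x) length(unique(x)))
  frac <- as.numeric(active) / n_cells
  sel <- frac >= min_fraction
  idx <- as.integer(names(active))[sel]
  out <- data.frame(t_start = breaks[idx],
                    t_mid = breaks[idx] + bin_s / 2,
                    t_end = breaks[idx] + bin_s,
                    n_cells_active = as.integer(active[sel]),
                    fraction = frac[sel])
  out <- out[order(out$t_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "criterion") <- crit
  out
}
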