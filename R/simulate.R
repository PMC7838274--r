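#' Parameters for the synthetic calcium-network generator
#'
#' Defines the study conditions emulated by [simulate_calcium_network()]:
#' a dish of co-recorded dorsal-horn neurons imaged around 1 frame/s, with a
#' silent subpopulation, per-cell Poisson-timed transients, slow baseline
#' drift, additive Gaussian noise, and network-wide synchronous waves in
#' which each cell participates with probability `coupling_p`.
#'
#' Amplitudes are lognormal with natural-scale mean `amp_mean` and standard
#' deviation `amp_sd` (AU). Transients are difference-of-exponential kernels
#' with time constants `rise_s` and `decay_s`, normalized to unit peak.
#' The first `round(frac_silent * n_cells)` cells are silent (no transient
#' sources; drift and noise only), a deterministic assignment that lets
#' condition effects address "all silent cells" reproducibly.
#'
#' @param n_cells Number of cells.
#' @param frac_silent Fraction of silent cells in `[0, 1]`.
#' @param duration_s Recording length (s).
#' @param frame_interval_s Sampling interval (s), default 1.
#' @param event_rate_hz Per-cell Poisson transient rate (Hz).
#' @param amp_mean,amp_sd Lognormal transient-amplitude mean and sd (AU).
#' @param rise_s,decay_s Transient kinetics (s); `rise_s < decay_s`.
#' @param sync_wave_rate_hz Poisson rate of network waves (Hz).
#' @param coupling_p Per-cell, per-wave participation probability.
#' @param noise_sd Additive Gaussian noise sd (AU).
#' @param drift_amp Amplitude of the slow sinusoidal baseline drift (AU);
#'   default `2 * noise_sd`.
#' @param baseline Resting fluorescence level (AU).
#' @param seed Integer seed; one global seed drives a deterministic
#'   sub-stream per cell, so adding cells never perturbs existing ones.
#' @return A `"calcium_network_params"` list.
#' @export
calcium_network_params <- function(n_cells = 50, frac_silent = 0.2,
                                   duration_s = 600, frame_interval_s = 1,
                                   event_rate_hz = 0.05,
                                   amp_mean = 50, amp_sd = 15,
                                   rise_s = 1.5, decay_s = 6,
                                   sync_wave_rate_hz = 0.01, coupling_p = 0.3,
                                   noise_sd = 1, drift_amp = 2 * noise_sd,
                                   baseline = 100, seed = 1) {
  p <- list(n_cells = as.integer(n_cells), frac_silent = frac_silent,
            duration_s = duration_s, frame_interval_s = frame_interval_s,
            event_rate_hz = event_rate_hz, amp_mean = amp_mean,
            amp_sd = amp_sd, rise_s = rise_s, decay_s = decay_s,
            sync_wave_rate_hz = sync_wave_rate_hz, coupling_p = coupling_p,
            noise_sd = noise_sd, drift_amp = drift_amp, baseline = baseline,
            seed = as.integer(seed))
  ## per-cell vectors (addressable by condition effects)
  n_silent <- round(p$frac_silent * p$n_cells)
  p$silent <- seq_len(p$n_cells) <= n_silent
  p$rate <- rep(p$event_rate_hz, p$n_cells)
  p$amp_scale <- rep(1, p$n_cells)
  p$coupling <- rep(p$coupling_p, p$n_cells)
  class(p) <- "calcium_network_params"
  validate_calcium_params(p)
  p
}

validate_calcium_params <- function(p) {
  num_ok <- function(x) all(is.finite(x))
  if (!num_ok(unlist(p[c("frac_silent", "duration_s", "frame_interval_s",
                         "event_rate_hz", "amp_mean", "amp_sd", "rise_s",
                         "decay_s", "sync_wave_rate_hz", "coupling_p",
                         "noise_sd", "drift_amp")])))
    stop_fibsir("all numeric parameters must be finite", "fibsir_bad_params")
  if (p$n_cells < 1) stop_fibsir("n_cells must be >= 1", "fibsir_bad_params")
  if (p$frac_silent < 0 || p$frac_silent > 1)
    stop_fibsir("frac_silent must lie in [0, 1]", "fibsir_bad_params")
  if (any(p$coupling < 0) || any(p$coupling > 1))
    stop_fibsir("coupling_p must lie in [0, 1]", "fibsir_bad_params")
  if (p$frame_interval_s <= 0)
    stop_fibsir("frame_interval_s must be > 0", "fibsir_bad_params")
  if (any(c(p$rate, p$sync_wave_rate_hz) < 0) || p$noise_sd < 0 ||
      p$drift_amp < 0 || any(p$amp_scale < 0))
    stop_fibsir("rates, noise, drift and scale factors must be >= 0",
                "fibsir_bad_params")
  if (p$rise_s <= 0 || p$decay_s <= p$rise_s)
    stop_fibsir("need 0 < rise_s < decay_s", "fibsir_bad_params")
  invisible(p)
}

## difference-of-exponentials kernel, unit peak, evaluated at times >= 0
dexp_kernel <- function(t, rise, decay) {
  tpk <- rise * decay / (decay - rise) * log(decay / rise)
  gmax <- exp(-tpk / decay) - exp(-tpk / rise)
  (exp(-t / decay) - exp(-t / rise)) / gmax
}

kernel_peak_delay <- function(rise, decay) {
  rise * decay / (decay - rise) * log(decay / rise)
}

lognormal_pars <- function(m, s) {
  if (m <= 0) stop_fibsir("amplitude mean must be > 0", "fibsir_bad_params")
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Simulate a calcium-imaging network recording with ground truth
#'
#' @param params A [calcium_network_params()] object.
#' @param condition Label recorded in the ground truth.
#' @return List with `traces` (list of [trace()] objects, one per cell) and
#'   `truth`: a list with `events` (data frame: `cell_id`, `onset_s`,
#'   `peak_s`, `amplitude`, `is_wave`), `wave_times`, `silent` (named logical),
#'   `condition`, and the resolved `params`.
#' @examples
#' sim <- simulate_calcium_network(calcium_network_params(n_cells = 4,
#'   duration_s = 120, seed = 7))
#' nrow(sim$truth$events)
#' @export
simulate_calcium_network <- function(params, condition = "synthetic") {
  p <- validate_calcium_params(params)
  nfr <- floor(p$duration_s / p$frame_interval_s) + 1L
  tt <- (seq_len(nfr) - 1) * p$frame_interval_s
  lp <- lognormal_pars(p$amp_mean, p$amp_sd)
  tpk <- kernel_peak_delay(p$rise_s, p$decay_s)

  ## network stream: synchronous wave times
  set.seed(substream_seed(p$seed, 0L))
  n_waves <- stats::rpois(1, p$sync_wave_rate_hz * p$duration_s)
  wave_times <- sort(stats::runif(n_waves, 0, p$duration_s))

  traces <- vector("list", p$n_cells)
  ev_list <- vector("list", p$n_cells)
  cell_ids <- sprintf("cell%03d", seq_len(p$n_cells))
  for (ci in seq_len(p$n_cells)) {
    set.seed(substream_seed(p$seed, ci))
    ## fixed draw order: noise, drift, cell events, wave participation
    noise <- stats::rnorm(nfr, 0, p$noise_sd)
    period <- stats::runif(1, 60, 180)
    phase <- stats::runif(1, 0, 2 * pi)
    drift <- p$drift_amp * sin(2 * pi * tt / period + phase)
    y <- p$baseline + drift + noise

    onsets <- numeric(0); amps <- numeric(0); is_wave <- logical(0)
    if (!p$silent[ci] && p$rate[ci] > 0) {
      ne <- stats::rpois(1, p$rate[ci] * p$duration_s)
      if (ne > 0) {
        onsets <- sort(stats::runif(ne, 0, p$duration_s))
        amps <- stats::rlnorm(ne, lp$meanlog, lp$sdlog) * p$amp_scale[ci]
        is_wave <- rep(FALSE, ne)
      }
    }
    if (n_waves > 0) {
      u <- stats::runif(n_waves)            # coupled across coupling levels
      part <- u < p$coupling[ci]
      wamp <- stats::rlnorm(n_waves, lp$meanlog, lp$sdlog) * p$amp_scale[ci]
      if (!p$silent[ci] && any(part)) {
        onsets <- c(onsets, wave_times[part])
        amps <- c(amps, wamp[part])
        is_wave <- c(is_wave, rep(TRUE, sum(part)))
      }
    }
    if (length(onsets)) {
      o <- order(onsets)
      onsets <- onsets[o]; amps <- amps[o]; is_wave <- is_wave[o]
      for (k in seq_along(onsets)) {
        i0 <- which(tt >= onsets[k])[1]
        if (is.na(i0)) next
        idx <- i0:nfr
        ker <- dexp_kernel(tt[idx] - onsets[k], p$rise_s, p$decay_s)
        kmax <- max(ker)
        if (kmax <= 0) next
        ## renormalize to the sampled maximum so the planted amplitude is
        ## the amplitude actually realized on the frame grid
        y[idx] <- y[idx] + amps[k] * ker / kmax
      }
      ev_list[[ci]] <- data.frame(cell_id = cell_ids[ci], onset_s = onsets,
                                  peak_s = onsets + tpk, amplitude = amps,
                                  is_wave = is_wave, stringsAsFactors = FALSE)
    }
    traces[[ci]] <- trace(y, t = tt, sample_interval_s = p$frame_interval_s,
                          cell_id = cell_ids[ci], modality = "calcium")
  }
  ev <- do.call(rbind, ev_list[!vapply(ev_list, is.null, logical(1))])
  if (is.null(ev))
    ev <- data.frame(cell_id = character(0), onset_s = numeric(0),
                     peak_s = numeric(0), amplitude = numeric(0),
                     is_wave = logical(0), stringsAsFactors = FALSE)
  silent <- stats::setNames(p$silent, cell_ids)
  list(traces = traces,
       truth = list(events = ev, wave_times = wave_times, silent = silent,
                    condition = condition, params = p))
}

#' Parameters for the synthetic sEPSC-recording generator
#'
#' Emulates a whole-cell voltage-clamp recording of spontaneous excitatory
#' postsynaptic currents: 180 s sampled at 2 kHz, events drawn from a planted
#' mixture of components, each component specifying its mixture weight,
#' amplitude distribution (Gaussian, pA) and interevent-interval distribution
#' (Gaussian, ms, truncated at one sample). Events are bi-exponential kernels
#' `A * (exp(-t/tau_decay) - exp(-t/tau_rise))`, peak-normalized to `A`, on
#' Gaussian noise. The default mixture plants the three clusters typically
#' seen in dorsal-horn sEPSC data: small;short, small;long, large.
#'
#' @param duration_s Recording length (s), default 180.
#' @param sample_rate_hz Sampling rate (Hz), default 2000.
#' @param cluster_specs Data frame with columns `weight`, `amp_mean_pA`,
#'   `amp_sd_pA`, `iei_mean_ms`, `iei_sd_ms` (one row per mixture component);
#'   weights must sum to 1.
#' @param tau_rise_ms,tau_decay_ms Kernel time constants (ms);
#'   `tau_rise_ms < tau_decay_ms`.
#' @param noise_sd_pA Gaussian noise sd (pA).
#' @param polarity `"inward"` (negative deflections, the sEPSC convention)
#'   or `"outward"`.
#' @param seed Integer seed.
#' @return An `"epsc_params"` list.
#' @export
epsc_params <- function(duration_s = 180, sample_rate_hz = 2000,
                        cluster_specs = default_epsc_clusters(),
                        tau_rise_ms = 0.5, tau_decay_ms = 4,
                        noise_sd_pA = 2,
                        polarity = c("inward", "outward"), seed = 1) {
  polarity <- match.arg(polarity)
  cs <- as.data.frame(cluster_specs)
  need <- c("weight", "amp_mean_pA", "amp_sd_pA", "iei_mean_ms", "iei_sd_ms")
  if (!all(need %in% names(cs)))
    stop_fibsir(paste("cluster_specs needs columns:",
                      paste(need, collapse = ", ")), "fibsir_bad_params")
  if (abs(sum(cs$weight) - 1) > 1e-8)
    stop_fibsir("mixture weights must sum to 1", "fibsir_bad_params")
  if (sample_rate_hz <= 0 || duration_s <= 0)
    stop_fibsir("duration and sample rate must be > 0", "fibsir_bad_params")
  if (!(tau_rise_ms > 0 && tau_rise_ms < tau_decay_ms))
    stop_fibsir("need 0 < tau_rise_ms < tau_decay_ms", "fibsir_bad_params")
  if (noise_sd_pA < 0)
    stop_fibsir("noise_sd_pA must be >= 0", "fibsir_bad_params")
  structure(list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 cluster_specs = cs, tau_rise_ms = tau_rise_ms,
                 tau_decay_ms = tau_decay_ms, noise_sd_pA = noise_sd_pA,
                 polarity = polarity, seed = as.integer(seed)),
            class = "epsc_params")
}

#' Default planted sEPSC mixture: small;short, small;long, large
#'
#' Amplitude means 15/15/80 pA and interevent-interval means 20/2000/200 ms,
#' all standard deviations 20% of the mean.
#' @return Data frame of component specifications for [epsc_params()].
#' @export
default_epsc_clusters <- function() {
  data.frame(
    component = c("small;short", "small;long", "large"),
    weight = c(0.4, 0.2, 0.4),
    amp_mean_pA = c(15, 15, 80),
    amp_sd_pA = c(3, 3, 16),
    iei_mean_ms = c(20, 2000, 200),
    iei_sd_ms = c(4, 400, 40),
    stringsAsFactors = FALSE
  )
}

#' Simulate a voltage-clamp sEPSC recording with ground truth
#'
#' Events are generated sequentially: each event draws a mixture component
#' (by weight), an interevent interval from that component's Gaussian
#' (truncated below at one sample), and an amplitude from its Gaussian
#' (truncated below at 1 pA).
#'
#' @param params An [epsc_params()] object.
#' @param cell_id Identifier carried on the output trace.
#' @return List with `trace` (a current [trace()]) and `truth`: data frame
#'   `events` (`onset_s`, `peak_s`, `amplitude_pA`, `iei_ms`, `component`)
#'   plus the resolved `params`.
#' @export
simulate_epsc_recording <- function(params, cell_id = "epsc_cell") {
  p <- params
  stopifnot(inherits(p, "epsc_params"))
  dt <- 1 / p$sample_rate_hz
  n <- floor(p$duration_s / dt) + 1L
  tt <- (seq_len(n) - 1) * dt
  cs <- p$cluster_specs
  set.seed(substream_seed(p$seed, 1L))
  noise <- stats::rnorm(n, 0, p$noise_sd_pA)

  onset <- numeric(0); amp <- numeric(0); comp <- integer(0); iei <- numeric(0)
  cur <- 0
  repeat {
    k <- sample.int(nrow(cs), 1L, prob = cs$weight)
    gap_ms <- max(stats::rnorm(1, cs$iei_mean_ms[k], cs$iei_sd_ms[k]),
                  1000 * dt)
    cur <- cur + gap_ms / 1000
    if (cur > p$duration_s) break
    onset <- c(onset, cur)
    amp <- c(amp, max(stats::rnorm(1, cs$amp_mean_pA[k], cs$amp_sd_pA[k]), 1))
    comp <- c(comp, k)
    iei <- c(iei, gap_ms)
  }
  iei[1] <- NA_real_   # no preceding event

  rise_s <- p$tau_rise_ms / 1000
  decay_s <- p$tau_decay_ms / 1000
  tpk <- kernel_peak_delay(rise_s, decay_s)
  sgn <- if (p$polarity == "inward") -1 else 1
  y <- noise
  span <- ceiling(10 * decay_s / dt)
  for (k in seq_along(onset)) {
    i0 <- floor(onset[k] / dt) + 1L
    if (tt[i0] < onset[k]) i0 <- i0 + 1L
    if (i0 > n) next
    idx <- i0:min(n, i0 + span)
    ker <- dexp_kernel(tt[idx] - onset[k], rise_s, decay_s)
    kmax <- max(ker)
    if (kmax <= 0) next
    ## renormalized to the sampled maximum: the planted amplitude is realized
    ## exactly on the sample grid
    y[idx] <- y[idx] + sgn * amp[k] * ker / kmax
  }
  ev <- data.frame(onset_s = onset, peak_s = onset + tpk,
                   amplitude_pA = amp, iei_ms = iei,
                   component = cs$component[comp],
                   component_id = comp, stringsAsFactors = FALSE)
  tr <- trace(y, t = tt, sample_interval_s = dt, cell_id = cell_id,
              modality = "current")
  list(trace = tr, truth = list(events = ev, params = p))
}

#' Describe a treatment/condition effect on generator parameters
#'
#' Multiplicative factors on event amplitude, event rate and wave coupling,
#' plus an optional silent-to-active switch, applied to all cells or to a
#' subset. Models pharmacological or trophic effects (e.g. a gap-junction
#' blocker as `coupling_factor < 1`, trophic unmasking as
#' `unsilence = TRUE`).
#'
#' @param amplitude_factor,rate_factor,coupling_factor Non-negative
#'   multiplicative factors (coupling is clipped to 1 after scaling).
#' @param unsilence If `TRUE`, switches the targeted silent cells to active.
#' @param cells Integer indices of the targeted cells (default: all).
#' @param label Condition label carried into the modified parameters.
#' @return A `"condition_effect"` list.
#' @export
condition_effect <- function(amplitude_factor = 1, rate_factor = 1,
                             coupling_factor = 1, unsilence = FALSE,
                             cells = NULL, label = "treated") {
  if (any(c(amplitude_factor, rate_factor, coupling_factor) < 0))
    stop_fibsir("effect factors must be >= 0", "fibsir_bad_params")
  structure(list(amplitude_factor = amplitude_factor,
                 rate_factor = rate_factor,
                 coupling_factor = coupling_factor,
                 unsilence = isTRUE(unsilence), cells = cells, label = label),
            class = "condition_effect")
}

#' Apply a condition effect to calcium-network parameters
#'
#' Returns new parameters; fields not targeted by the effect are unchanged.
#' `frac_silent` is recomputed from the per-cell silent flags.
#'
#' @param params A [calcium_network_params()] object.
#' @param effect A [condition_effect()].
#' @return Modified `"calcium_network_params"`.
#' @examples
#' p <- calcium_network_params(n_cells = 10, frac_silent = 0.5)
#' p2 <- apply_condition_effect(p, condition_effect(unsilence = TRUE))
#' p2$frac_silent  # 0
#' @export
apply_condition_effect <- function(params, effect) {
  stopifnot(inherits(params, "calcium_network_params"),
            inherits(effect, "condition_effect"))
  p <- params
  cells <- effect$cells %||% seq_len(p$n_cells)
  if (any(cells < 1 | cells > p$n_cells))
    stop_fibsir("effect cell indices out of range", "fibsir_bad_params")
  p$amp_scale[cells] <- p$amp_scale[cells] * effect$amplitude_factor
  p$rate[cells] <- p$rate[cells] * effect$rate_factor
  p$coupling[cells] <- pmin(p$coupling[cells] * effect$coupling_factor, 1)
  if (effect$unsilence) p$silent[cells] <- FALSE
  p$frac_silent <- mean(p$silent)
  p$condition <- effect$label
  validate_calcium_params(p)
  p
}

#' Score detected events against generator ground truth
#'
#' A truth event is recovered when some detected event's span
#' `[t_start - tol, t_end + tol]` contains its peak time; a detected event is
#' a true positive when it contains at least one truth peak. This containment
#' rule scores occasionally merged (overlapping) transients fairly.
#'
#' @param truth_peaks Numeric vector of true peak times (s) for one cell.
#' @param events Detected event data frame for the same cell.
#' @param tol_s Boundary tolerance (s).
#' @return List with `n_truth`, `n_detected`, `recall`, `precision`.
#' @export
score_detection <- function(truth_peaks, events, tol_s = 2) {
  n_truth <- length(truth_peaks)
  n_det <- nrow(events)
  if (n_truth == 0L && n_det == 0L)
    return(list(n_truth = 0L, n_detected = 0L, recall = NA_real_,
                precision = NA_real_))
  contains <- function(pk)
    any(events$t_start - tol_s <= pk & pk <= events$t_end + tol_s)
  hit_truth <- if (n_det) vapply(truth_peaks, contains, logical(1))
               else rep(FALSE, n_truth)
  tp_det <- if (n_det) vapply(seq_len(n_det), function(i) {
    any(truth_peaks >= events$t_start[i] - tol_s &
        truth_peaks <= events$t_end[i] + tol_s)
  }, logical(1)) else logical(0)
  list(n_truth = n_truth, n_detected = n_det,
       recall = if (n_truth) mean(hit_truth) else NA_real_,
       precision = if (n_det) mean(tp_det) else NA_real_)
}
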