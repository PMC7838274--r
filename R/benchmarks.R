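#' Synthetic benchmark: calcium event-detection recovery
#'
#' Simulates all-active calcium networks at the generator defaults (50 AU
#' lognormal transients on 1 AU noise, 0.05 Hz per cell; network waves off)
#' and scores FIBSI detection, with the 10% amplitude cutoff applied, by
#' the containment rule of [score_detection()]. Recall and precision are
#' pooled over all cells and seeds.
#'
#' @param seeds Integer seeds, one network per seed.
#' @param n_cells,duration_s Network size per seed.
#' @param tol_s Containment tolerance (s) for scoring.
#' @return List with pooled `recall`, `precision`, `n_truth`, `n_detected`.
#' @export
benchmark_calcium_detection <- function(seeds = 1:20, n_cells = 20,
                                        duration_s = 300, tol_s = 2) {
  tp_truth <- 0L; n_truth <- 0L; tp_det <- 0L; n_det <- 0L
  for (sd in seeds) {
    p <- calcium_network_params(n_cells = n_cells, frac_silent = 0,
                                duration_s = duration_s,
                                sync_wave_rate_hz = 0, seed = sd)
    sim <- simulate_calcium_network(p)
    for (tr in sim$traces) {
      ev <- apply_amplitude_cutoff(fibsi(tr)$events)
      pk <- sim$truth$events$peak_s[sim$truth$events$cell_id == tr$cell_id]
      sc <- score_detection(pk, ev, tol_s = tol_s)
      n_truth <- n_truth + sc$n_truth
      n_det <- n_det + sc$n_detected
      if (sc$n_truth) tp_truth <- tp_truth + round(sc$recall * sc$n_truth)
      if (sc$n_detected) tp_det <- tp_det + round(sc$precision * sc$n_detected)
    }
  }
  list(recall = tp_truth / n_truth, precision = tp_det / n_det,
       n_truth = n_truth, n_detected = n_det)
}

#' Synthetic benchmark: sEPSC cluster recovery
#'
#' Simulates 180 s voltage-clamp recordings with the default three-component
#' mixture ([default_epsc_clusters()]), runs the full sEPSC pipeline, and
#' reports per-seed detection recall (containment rule, 5 ms tolerance), the
#' silhouette-selected k, and the adjusted Rand index between cluster
#' assignments and the planted component labels of the matched events.
#'
#' The ARI here is computed with a small self-contained implementation (per
#' pair counting), keeping the benchmark free of optional dependencies.
#'
#' @param seeds Integer seeds, one recording per seed.
#' @return Data frame with one row per seed: `seed`, `recall`, `precision`,
#'   `k`, `ari`.
#' @export
benchmark_epsc_clustering <- function(seeds = 1:10) {
  out <- lapply(seeds, function(sd) {
    sim <- simulate_epsc_recording(epsc_params(seed = sd))
    res <- run_epsc_pipeline(sim$trace)
    ev <- res$fit$events
    tt <- sim$truth$events
    sc <- score_detection(tt$peak_s, ev, tol_s = 0.005)
    nearest <- vapply(ev$t_peak, function(pk) {
      i <- which.min(abs(tt$peak_s - pk))
      if (abs(tt$peak_s[i] - pk) <= 0.005) i else NA_integer_
    }, integer(1))
    rows <- attr(res$features, "event_rows")
    keep <- !is.na(nearest[rows])
    ari <- adjusted_rand_index(res$model$assignments[keep],
                               tt$component_id[nearest[rows][keep]])
    data.frame(seed = sd, recall = sc$recall, precision = sc$precision,
               k = res$model$k, ari = ari)
  })
  do.call(rbind, out)
}

#' Adjusted Rand index between two labelings
#' @param a,b Equal-length label vectors.
#' @return Scalar ARI in `[-1, 1]` (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  expected <- si * sj / ch2(n)
  (sij - expected) / ((si + sj) / 2 - expected)
}

#' Synthetic benchmark: synchrony across wave-coupling levels
#'
#' Simulates calcium networks at each coupling probability and returns the
#' median (over seeds) of the network-average per-cell Fisher-Z mean
#' Pearson correlation of the processed recordings.
#'
#' @param coupling_grid Wave-participation probabilities to sweep.
#' @param seeds Integer seeds per coupling level.
#' @param n_cells,duration_s Network size per seed.
#' @return Data frame: `coupling_p`, `median_mean_r`.
#' @export
benchmark_synchrony <- function(coupling_grid = c(0, 0.3, 0.6, 0.9),
                                seeds = 1:10, n_cells = 15,
                                duration_s = 300) {
  res <- lapply(coupling_grid, function(cp) {
    vals <- vapply(seeds, function(sd) {
      p <- calcium_network_params(n_cells = n_cells, frac_silent = 0,
                                  duration_s = duration_s,
                                  event_rate_hz = 0.02,
                                  sync_wave_rate_hz = 0.02,
                                  coupling_p = cp, seed = sd)
      sim <- simulate_calcium_network(p)
      adj <- build_adjacency(lapply(sim$traces, function(tr)
        residuals(fibsi(tr))))
      mean(adj$mean_r_per_cell)
    }, numeric(1))
    data.frame(coupling_p = cp, median_mean_r = stats::median(vals))
  })
  do.call(rbind, res)
}

#' Synthetic benchmark: gap-junction-blocker style decoupling
#'
#' Simulates a strongly coupled network and the same network after a
#' `coupling_factor` effect (same seed, so baselines, noise and wave draws
#' are shared), and reports the fraction of cells whose Fisher-Z mean
#' Pearson r decreased.
#'
#' @param seed Integer seed.
#' @param coupling_factor Multiplicative decoupling factor (default 0.25).
#' @param n_cells,duration_s Network size.
#' @return List with `fraction_decreased`, `mean_r_pre`, `mean_r_post`
#'   (per-cell vectors).
#' @export
benchmark_decoupling <- function(seed = 1, coupling_factor = 0.25,
                                 n_cells = 30, duration_s = 300) {
  p_pre <- calcium_network_params(n_cells = n_cells, frac_silent = 0,
                                  duration_s = duration_s,
                                  event_rate_hz = 0.02,
                                  sync_wave_rate_hz = 0.02,
                                  coupling_p = 0.8, seed = seed)
  p_post <- apply_condition_effect(
    p_pre, condition_effect(coupling_factor = coupling_factor,
                            label = "octanol"))
  mr <- function(p) {
    sim <- simulate_calcium_network(p)
    adj <- build_adjacency(lapply(sim$traces, function(tr)
      residuals(fibsi(tr))))
    adj$mean_r_per_cell
  }
  pre <- mr(p_pre); post <- mr(p_post)
  list(fraction_decreased = mean(post < pre),
       mean_r_pre = pre, mean_r_post = post)
}

#' Synthetic benchmark: end-to-end silent-fraction recovery
#'
#' Simulates a network with a silent subpopulation, runs the calcium
#' pipeline, and compares the estimated silent fraction (mean amplitude
#' below the configured threshold, no cutoff) to the generative truth.
#'
#' @param seeds Integer seeds.
#' @param n_cells Network size (default 100).
#' @param frac_silent Planted silent fraction (default 0.2).
#' @param duration_s Recording length per seed.
#' @return Data frame: `seed`, `true_fraction`, `estimated_fraction`.
#' @export
benchmark_silent_recovery <- function(seeds = 1:10, n_cells = 100,
                                      frac_silent = 0.2, duration_s = 300) {
  out <- lapply(seeds, function(sd) {
    p <- calcium_network_params(n_cells = n_cells, frac_silent = frac_silent,
                                duration_s = duration_s, seed = sd)
    sim <- simulate_calcium_network(p)
    res <- run_calcium_pipeline(sim$traces)
    data.frame(seed = sd, true_fraction = mean(sim$truth$silent),
               estimated_fraction = mean(res$summaries$is_silent))
  })
  do.call(rbind, out)
}

#' Synthetic benchmark: planted pre/post interaction (gap-junction blocker)
#'
#' Simulates paired pre/post recordings of one culture in which only a
#' planted "increase" subset of cells receives an amplitude effect
#' (multiplicative, via [apply_condition_effect()]); the remaining cells
#' are unaffected. Runs the two-way repeated-measures ANOVA with Sidak
#' contrasts on the per-cell mean fluctuation amplitudes, the analysis
#' used for gap-junction-blocker response groups.
#'
#' @param seed Integer seed.
#' @param n_cells Cells in the culture (default 79, split 40 affected /
#'   39 unaffected).
#' @param n_affected Number of cells receiving the effect.
#' @param amplitude_factor Planted multiplicative amplitude effect.
#' @param duration_s Recording length per phase.
#' @return List with the `"fibsir_comparison"` RM-ANOVA result (`anova`),
#'   the observed fold-change `grouping`, and the planted `group` factor.
#' @export
benchmark_planted_interaction <- function(seed = 1, n_cells = 79,
                                          n_affected = 40,
                                          amplitude_factor = 1.5,
                                          duration_s = 300) {
  p_pre <- calcium_network_params(n_cells = n_cells, frac_silent = 0,
                                  duration_s = duration_s,
                                  sync_wave_rate_hz = 0, seed = seed)
  p_post <- apply_condition_effect(
    p_pre, condition_effect(amplitude_factor = amplitude_factor,
                            cells = seq_len(n_affected), label = "treated"))
  p_post$seed <- substream_seed(seed, 999983L)   # independent post noise
  summarize <- function(p) {
    sim <- simulate_calcium_network(p)
    ev <- do.call(rbind, lapply(sim$traces, function(tr) fibsi(tr)$events))
    ids <- vapply(sim$traces, function(tr) tr$cell_id, character(1))
    summarize_cells(apply_amplitude_cutoff(ev), duration_s, cell_ids = ids)
  }
  pre <- summarize(p_pre)
  post <- summarize(p_post)
  planted <- factor(ifelse(seq_len(n_cells) <= n_affected,
                           "increase", "decrease"),
                    levels = c("decrease", "increase"))
  res <- paired_compare(pre$mean_amplitude, post$mean_amplitude,
                        method = "rm_anova_2way_sidak", group = planted)
  grouping <- fold_change_grouping(pre, post)
  list(anova = res, grouping = grouping, group = planted,
       pre = pre, post = post)
}
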