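test_that("zero-phase low-pass has unit DC gain and the right roll-off", {
  fs <- 2000
  tt <- seq(0, 2, by = 1 / fs)
  # constant trace unchanged
  trc <- trace(rep(-12, length(tt)), t = tt, modality = "current")
  expect_equal(lowpass_filter(trc, 200)$y, trc$y, tolerance = 1e-8)
  gain_at <- function(freq) {
    tr <- trace(sin(2 * pi * freq * tt), t = tt, modality = "current")
    yf <- lowpass_filter(tr, 200)$y
    core <- yf[200:(length(yf) - 200)]        # avoid edge transients
    max(abs(core))
  }
  expect_lt(gain_at(900), 10^(-20 / 20))      # > 20 dB attenuation
  expect_gt(gain_at(1), 0.99)                 # passband within 1%
  # peaks are not time-shifted
  pulse <- exp(-(tt - 1)^2 / (2 * 0.01^2))
  trp <- trace(pulse, t = tt, modality = "current")
  expect_lt(abs(tt[which.max(lowpass_filter(trp, 200)$y)] - 1), 0.002)
  expect_error(lowpass_filter(trc, 1000), class = "fibsir_bad_cutoff")
})

test_that("sEPSC detection finds planted events and rejects sub-epsilon noise", {
  # pure noise with epsilon above its excursions: empty
  set.seed(6)
  fs <- 2000
  tt <- seq(0, 10, by = 1 / fs)
  trn <- trace(rnorm(length(tt), 0, 2), t = tt, modality = "current")
  fitn <- detect_epscs(lowpass_filter(trn), epsilon = 30)
  expect_equal(nrow(fitn$events), 0L)
  # one planted 50 pA event on 2 pA noise
  cs <- data.frame(component = "only", weight = 1, amp_mean_pA = 50,
                   amp_sd_pA = 0, iei_mean_ms = 6000, iei_sd_ms = 0)
  sim <- simulate_epsc_recording(epsc_params(duration_s = 10,
                                             cluster_specs = cs, seed = 2))
  fit <- detect_epscs(lowpass_filter(sim$trace))
  expect_equal(nrow(fit$events), nrow(sim$truth$events))
  expect_true(all(abs(fit$events$t_peak - sim$truth$events$peak_s) <= 0.002))
  # Poisson-like count at high SNR over 180 s
  csp <- data.frame(component = "only", weight = 1, amp_mean_pA = 60,
                    amp_sd_pA = 6, iei_mean_ms = 200, iei_sd_ms = 40)
  simp <- simulate_epsc_recording(epsc_params(duration_s = 180,
                                              cluster_specs = csp, seed = 3))
  fitp <- detect_epscs(lowpass_filter(simp$trace))
  expect_lt(abs(nrow(fitp$events) - nrow(simp$truth$events)),
            0.05 * nrow(simp$truth$events))
})

test_that("raw matching re-measures amplitudes with the greedy tie rule", {
  cs <- data.frame(component = "only", weight = 1, amp_mean_pA = 40,
                   amp_sd_pA = 4, iei_mean_ms = 500, iei_sd_ms = 100)
  sim <- simulate_epsc_recording(epsc_params(duration_s = 20,
                                             cluster_specs = cs, seed = 4))
  filt <- lowpass_filter(sim$trace)
  fit <- detect_epscs(filt)
  # raw == filtered: identical amplitudes, all matched
  same <- match_filtered_to_raw(fit, filt)
  expect_true(all(same$events$matched))
  expect_equal(same$events$amplitude_pA, same$events$amplitude)
  # true raw trace: matched amplitudes at least the filtered ones
  m <- match_filtered_to_raw(fit, sim$trace)
  expect_true(all(m$events$matched))
  expect_true(all(m$events$amplitude_pA >= m$events$amplitude - 1e-9))
  # raw peak shifted +3 ms still matches and reports the raw amplitude
  shift <- round(0.003 * 2000)
  yshift <- c(rep(sim$trace$y[1], shift),
              sim$trace$y[1:(length(sim$trace$y) - shift)])
  rawsh <- trace(yshift, t = sim$trace$t, modality = "current")
  msh <- match_filtered_to_raw(fit, rawsh)
  expect_true(all(msh$events$matched))
  expect_true(all(abs(msh$events$raw_peak_s - msh$events$t_peak) <= 0.005))
  # two filtered events competing for one raw extremum: earlier wins
  fs <- 2000
  tt <- seq(0, 1, by = 1 / fs)
  raw1 <- -60 * exp(-abs(tt - 0.500) / 0.002)       # single raw peak
  fake_ref <- structure(list(knot_times = c(0, 1), knot_values = c(0, 0),
                             side = "above", degenerate = FALSE),
                        class = "fibsi_reference")
  fake_fit <- structure(list(
    trace = trace(raw1, t = tt, modality = "current"),
    reference = fake_ref, polarity = -1,
    events = data.frame(cell_id = "c", t_start = c(0.495, 0.499),
                        t_peak = c(0.498, 0.502), t_end = c(0.5, 0.504),
                        amplitude = c(30, 30), amplitude_pA = c(30, 30),
                        stringsAsFactors = FALSE)), class = "fibsi")
  comp <- match_filtered_to_raw(fake_fit,
                                trace(raw1, t = tt, modality = "current"))
  expect_true(comp$events$matched[1])
  expect_false(comp$events$matched[2])
  expect_equal(comp$events$amplitude_pA[2], 30)     # keeps filtered value
})

test_that("PAM clustering is exact on separated duplicates and tiny 1-D data", {
  # two point-masses of 10 identical events each split perfectly
  x <- rbind(matrix(rep(c(10, 5, 50), each = 10), ncol = 3),
             matrix(rep(c(2000, 80, 400), each = 10), ncol = 3))
  colnames(x) <- c("iei_ms", "amplitude_pA", "charge_transfer_pAms")
  m <- pam_cluster(x, 2)
  expect_equal(length(unique(m$assignments[1:10])), 1L)
  expect_equal(length(unique(m$assignments[11:20])), 1L)
  expect_gt(m$avg_silhouette, 0.99)
  expect_equal(m$objective, 0)
  # 12 points in 1-D: objective equals the exhaustive optimum
  set.seed(7)
  z <- matrix(sort(rnorm(12, sd = 5)), ncol = 1)
  m2 <- pam_cluster(z, 2, standardize = FALSE)
  expect_equal(m2$objective, pam2_oracle_objective(z))
  # k = n: every point its own medoid, objective 0
  mn <- pam_cluster(z, 12)
  expect_equal(mn$objective, 0)
  expect_equal(sort(mn$medoid_ids), 1:12)
  expect_error(pam_cluster(z, 13), class = "fibsir_bad_k")
})

test_that("event-order permutation changes assignments only by relabeling", {
  set.seed(8)
  x <- rbind(cbind(rnorm(20, 20, 4), rnorm(20, 15, 3), rnorm(20, 80, 15)),
             cbind(rnorm(20, 2000, 400), rnorm(20, 15, 3), rnorm(20, 80, 15)),
             cbind(rnorm(20, 200, 40), rnorm(20, 80, 16), rnorm(20, 450, 90)))
  colnames(x) <- c("iei_ms", "amplitude_pA", "charge_transfer_pAms")
  m <- pam_cluster(x, 3)
  perm <- sample(nrow(x))
  mp <- pam_cluster(x[perm, ], 3)
  expect_equal(adjusted_rand_index(m$assignments[perm], mp$assignments), 1)
})

test_that("silhouette-based k selection recovers planted component counts", {
  mk <- function(centers, n_each, seed) {
    set.seed(seed)
    x <- do.call(rbind, lapply(centers, function(ce)
      cbind(rnorm(n_each, ce[1], 0.2 * ce[1]),
            rnorm(n_each, ce[2], 0.2 * ce[2]),
            rnorm(n_each, ce[3], 0.2 * ce[3]))))
    colnames(x) <- c("iei_ms", "amplitude_pA", "charge_transfer_pAms")
    x
  }
  three <- list(c(20, 15, 85), c(2000, 15, 85), c(200, 80, 450))
  hits3 <- vapply(1:10, function(sd)
    select_k_silhouette(mk(three, 40, sd))$k == 3L, logical(1))
  expect_gte(sum(hits3), 9L)
  two <- list(c(20, 15, 85), c(2000, 80, 450))
  hits2 <- vapply(1:5, function(sd)
    select_k_silhouette(mk(two, 40, sd))$k == 2L, logical(1))
  expect_true(all(hits2))
  m <- select_k_silhouette(mk(three, 30, 1))
  expect_true(all(m$silhouette_profile$avg_silhouette >= -1 &
                  m$silhouette_profile$avg_silhouette <= 1))
  expect_error(select_k_silhouette(matrix(1, 10, 3)),
               class = "fibsir_degenerate_features")
})

test_that("cluster labels follow the amplitude-then-interval rule", {
  mk_model <- function(amps, ieis) {
    k <- length(amps)
    med <- cbind(iei_ms = ieis, amplitude_pA = amps,
                 charge_transfer_pAms = amps * 5)
    structure(list(k = k, medoid_ids = seq_len(k), assignments = seq_len(k),
                   avg_silhouette = 0.9,
                   silhouette_widths = rep(0.9, k),
                   objective = 0, medoids = med, labels = NULL),
              class = "cluster_model")
  }
  m3 <- label_clusters(mk_model(c(10, 12, 80), c(15, 900, 40)))
  expect_equal(m3$labels, c("small;short", "small;long", "large"))
  m2 <- label_clusters(mk_model(c(12, 70), c(500, 100)))
  expect_equal(sort(m2$labels), c("large", "small"))
  # near-equal amplitudes at k = 4 demote "large" to "medium"
  m4 <- label_clusters(mk_model(c(10, 12, 14, 15), c(15, 900, 100, 40)))
  expect_true("medium" %in% m4$labels)
  expect_equal(m4$labels[2], "small;long")
  expect_equal(anyDuplicated(m4$labels), 0L)
  m5 <- label_clusters(mk_model(c(10, 12, 14, 90), c(15, 900, 100, 40)))
  expect_equal(m5$labels, c("small;short", "small;long", "small;mid", "large"))
})

test_that("each neuron is clustered independently of other cells", {
  sim1 <- simulate_epsc_recording(epsc_params(duration_s = 40, seed = 31),
                                  cell_id = "n1")
  res_alone <- run_epsc_pipeline(sim1$trace)
  # clustering another cell first must not change this cell's model
  sim2 <- simulate_epsc_recording(epsc_params(duration_s = 40, seed = 32),
                                  cell_id = "n2")
  invisible(run_epsc_pipeline(sim2$trace))
  res_again <- run_epsc_pipeline(sim1$trace)
  expect_identical(res_alone$model$assignments, res_again$model$assignments)
  expect_identical(res_alone$model$k, res_again$model$k)
})
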