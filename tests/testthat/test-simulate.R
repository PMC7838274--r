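test_that("calcium generator is deterministic and respects zero rates", {
  p <- calcium_network_params(n_cells = 5, duration_s = 120, seed = 9)
  a <- simulate_calcium_network(p)
  b <- simulate_calcium_network(p)
  expect_identical(a$traces[[3]]$y, b$traces[[3]]$y)
  expect_identical(a$truth$events, b$truth$events)
  # no sources at all
  p0 <- calcium_network_params(n_cells = 4, frac_silent = 0, duration_s = 60,
                               event_rate_hz = 0, sync_wave_rate_hz = 0,
                               seed = 2)
  s0 <- simulate_calcium_network(p0)
  expect_equal(nrow(s0$truth$events), 0L)
  # trace length floor(duration/frame)+1
  expect_length(s0$traces[[1]]$y, 61L)
  # adding cells does not perturb existing sub-streams
  p6 <- calcium_network_params(n_cells = 6, duration_s = 120, seed = 9)
  s6 <- simulate_calcium_network(p6)
  expect_identical(s6$traces[[3]]$y, a$traces[[3]]$y)
})

test_that("silent cells carry drift and noise only", {
  p <- calcium_network_params(n_cells = 10, frac_silent = 0.5,
                              duration_s = 200, noise_sd = 1, seed = 4)
  sim <- simulate_calcium_network(p)
  silent_ids <- names(sim$truth$silent)[sim$truth$silent]
  expect_length(silent_ids, 5L)
  expect_false(any(sim$truth$events$cell_id %in% silent_ids))
  # fluctuation scale of a silent cell is drift + noise only
  ysil <- sim$traces[[1]]$y
  expect_lt(sd(ysil), p$drift_amp + 3 * p$noise_sd)
})

test_that("event counts follow the Poisson law", {
  # 3-sigma check at the example's scale
  p <- calcium_network_params(n_cells = 50, frac_silent = 0,
                              duration_s = 600, event_rate_hz = 0.05,
                              sync_wave_rate_hz = 0, seed = 123)
  sim <- simulate_calcium_network(p)
  lam <- 0.05 * 600 * 50
  expect_lt(abs(nrow(sim$truth$events) - lam), 3 * sqrt(lam))
  # chi-square goodness of fit of per-cell counts over 200 sub-streams
  p2 <- calcium_network_params(n_cells = 200, frac_silent = 0,
                               duration_s = 200, event_rate_hz = 0.05,
                               sync_wave_rate_hz = 0, seed = 77)
  sim2 <- simulate_calcium_network(p2)
  counts <- table(factor(sim2$truth$events$cell_id,
                         levels = names(sim2$truth$silent)))
  lam2 <- 0.05 * 200
  brk <- c(-Inf, qpois(c(0.15, 0.35, 0.5, 0.65, 0.85), lam2), Inf)
  obs <- table(cut(as.numeric(counts), brk))
  pr <- diff(ppois(c(-Inf, qpois(c(0.15, 0.35, 0.5, 0.65, 0.85), lam2), Inf),
                   lam2))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = pr / sum(pr)))
  expect_gt(gof$p.value, 0.01)
})

test_that("mean pairwise correlation is non-decreasing in wave coupling", {
  grid <- c(0, 0.3, 0.6, 0.9)
  meanr <- vapply(grid, function(cp) {
    vals <- vapply(1:10, function(sd) {
      p <- calcium_network_params(n_cells = 10, frac_silent = 0,
                                  duration_s = 200, event_rate_hz = 0.01,
                                  sync_wave_rate_hz = 0.03, coupling_p = cp,
                                  seed = sd)
      sim <- simulate_calcium_network(p)
      m <- vapply(sim$traces, function(tr) tr$y,
                  numeric(length(sim$traces[[1]]$y)))
      r <- cor(m)
      mean(r[upper.tri(r)])
    }, numeric(1))
    median(vals)
  }, numeric(1))
  expect_true(all(diff(meanr) > 0))
})

test_that("wave events land in participating cells at the wave times", {
  p <- calcium_network_params(n_cells = 8, frac_silent = 0, duration_s = 300,
                              event_rate_hz = 0, sync_wave_rate_hz = 0.02,
                              coupling_p = 1, seed = 31)
  sim <- simulate_calcium_network(p)
  expect_gt(length(sim$truth$wave_times), 0L)
  ev <- sim$truth$events
  expect_true(all(ev$is_wave))
  # with full coupling every cell gets every wave, within one frame
  for (w in sim$truth$wave_times) {
    near <- ev[abs(ev$onset_s - w) <= p$frame_interval_s, ]
    expect_setequal(unique(near$cell_id), names(sim$truth$silent))
  }
})

test_that("epsc generator normalizes kernels and respects polarity", {
  # single planted event with no noise peaks at the planted amplitude
  cs <- data.frame(component = "only", weight = 1, amp_mean_pA = 50,
                   amp_sd_pA = 0, iei_mean_ms = 5000, iei_sd_ms = 0)
  p <- epsc_params(duration_s = 12, cluster_specs = cs, noise_sd_pA = 0,
                   seed = 1)
  sim <- simulate_epsc_recording(p)
  expect_gte(nrow(sim$truth$events), 1L)
  expect_lt(abs(max(abs(sim$trace$y)) - 50) / 50, 0.001)
  expect_true(all(sim$trace$y <= 1e-9))       # inward: negative deflections
  p_out <- epsc_params(duration_s = 12, cluster_specs = cs, noise_sd_pA = 0,
                       polarity = "outward", seed = 1)
  expect_true(all(simulate_epsc_recording(p_out)$trace$y >= -1e-9))
})

test_that("planted interevent mixture is bimodal and means are recovered", {
  cs <- data.frame(component = c("short", "long"), weight = c(0.5, 0.5),
                   amp_mean_pA = c(20, 20), amp_sd_pA = c(2, 2),
                   iei_mean_ms = c(20, 2000), iei_sd_ms = c(4, 400))
  sim <- simulate_epsc_recording(epsc_params(duration_s = 180,
                                             cluster_specs = cs, seed = 6))
  ev <- sim$truth$events
  iei <- ev$iei_ms[-1]
  comp <- ev$component[-1]
  expect_lt(abs(mean(iei[comp == "short"]) - 20) / 20, 0.1)
  expect_lt(abs(mean(iei[comp == "long"]) - 2000) / 2000, 0.1)
  expect_gt(sum(iei < 100), 20)
  expect_gt(sum(iei > 1000), 20)
  expect_lt(sum(iei >= 100 & iei <= 1000), sum(iei < 100))
})

test_that("condition effects modify only the targeted parameters", {
  p <- calcium_network_params(n_cells = 10, frac_silent = 0.5, seed = 2)
  # identity effect changes nothing
  pid <- apply_condition_effect(p, condition_effect())
  expect_equal(pid$rate, p$rate)
  expect_equal(pid$amp_scale, p$amp_scale)
  expect_equal(pid$silent, p$silent)
  # unsilencing all silent cells zeroes the silent fraction
  pun <- apply_condition_effect(p, condition_effect(unsilence = TRUE))
  expect_equal(pun$frac_silent, 0)
  # subset amplitude effect halves that subset's fluctuations downstream
  pamp <- apply_condition_effect(
    p, condition_effect(amplitude_factor = 0.5, cells = 6:8))
  expect_equal(pamp$amp_scale, c(rep(1, 5), rep(0.5, 3), 1, 1))
  s1 <- simulate_calcium_network(p)
  s2 <- simulate_calcium_network(pamp)
  a1 <- s1$truth$events
  a2 <- s2$truth$events
  sub <- a1$cell_id %in% sprintf("cell%03d", 6:8)
  expect_equal(a2$amplitude[sub], a1$amplitude[sub] * 0.5)
  expect_equal(a2$amplitude[!sub], a1$amplitude[!sub])
  expect_error(condition_effect(amplitude_factor = -1),
               class = "fibsir_bad_params")
})

test_that("invalid generator parameters are rejected", {
  expect_error(calcium_network_params(frac_silent = 1.2),
               class = "fibsir_bad_params")
  expect_error(calcium_network_params(frame_interval_s = 0),
               class = "fibsir_bad_params")
  expect_error(calcium_network_params(event_rate_hz = -1),
               class = "fibsir_bad_params")
  expect_error(calcium_network_params(rise_s = 5, decay_s = 2),
               class = "fibsir_bad_params")
  expect_error(calcium_network_params(noise_sd = NaN),
               class = "fibsir_bad_params")
  bad_w <- default_epsc_clusters(); bad_w$weight <- bad_w$weight * 2
  expect_error(epsc_params(cluster_specs = bad_w),
               class = "fibsir_bad_params")
  expect_error(epsc_params(tau_rise_ms = 5, tau_decay_ms = 4),
               class = "fibsir_bad_params")
})

test_that("epsc generator is deterministic for a fixed seed", {
  a <- simulate_epsc_recording(epsc_params(duration_s = 20, seed = 12))
  b <- simulate_epsc_recording(epsc_params(duration_s = 20, seed = 12))
  expect_identical(a$trace$y, b$trace$y)
  expect_identical(a$truth$events, b$truth$events)
})
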