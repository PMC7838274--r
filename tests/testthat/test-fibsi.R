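test_that("running median matches the per-window sort oracle and edge rules", {
  tr <- trace(c(1, 9, 1, 9, 1), sample_interval_s = 1)
  expect_equal(running_median(tr, 3), c(5, 1, 9, 1, 5))
  # constant trace
  trc <- trace(rep(4.2, 20), sample_interval_s = 0.5)
  expect_equal(running_median(trc, 5), rep(4.2, 20))
  # one-sample window is the identity
  expect_equal(running_median(tr, 1), tr$y)
  # random trace vs direct truncated-window medians
  set.seed(42)
  y <- rnorm(200)
  trr <- trace(y, sample_interval_s = 1)
  for (w in c(5, 11, 25)) {
    h <- floor(w / 2)
    oracle <- vapply(seq_along(y), function(i)
      median(y[max(1, i - h):min(length(y), i + h)]), numeric(1))
    expect_equal(running_median(trr, w), oracle)
  }
  expect_error(running_median(tr, 0.5), class = "fibsir_bad_window")
})

test_that("reference polyline knots sit at troughs and span the trace", {
  # flat trace: reference identical to the trace
  trf <- trace(rep(3, 6), sample_interval_s = 1)
  ref <- build_reference(trf, running_median(trf, 3), "below")
  expect_equal(eval_reference(ref, trf$t), rep(3, 6))
  # triangular bump on a flat baseline: reference is the baseline
  trt <- trace(c(0, 0, 0, 5, 0, 0, 0) + 10, sample_interval_s = 1)
  reft <- build_reference(trt, running_median(trt, 3), "below")
  expect_equal(eval_reference(reft, trt$t), rep(10, 7))
  # sawtooth: knots at exactly the trough samples (brute-force local-min scan)
  y <- c(5, 1, 5, 2, 5, 0, 5)
  trs <- trace(y, sample_interval_s = 1)
  refs <- build_reference(trs, running_median(trs, 5), "below")
  troughs <- which(diff(sign(diff(y))) > 0) + 1L
  expect_true(all((troughs - 1) %in% refs$knot_times))
  expect_equal(refs$knot_values[match(troughs - 1, refs$knot_times)],
               y[troughs])
  # side = above mirrors side = below under sign flip
  tru <- trace(-y, sample_interval_s = 1)
  refu <- build_reference(tru, running_median(tru, 5), "above")
  expect_equal(refu$knot_values, -refs$knot_values)
  # trace entirely above its (shifted) reference side warns and degenerates
  trw <- trace(c(1, 2, 3, 4), sample_interval_s = 1)
  expect_warning(refw <- build_reference(trw, c(-10, -10, -10, -10), "below"),
                 "wrong side")
  expect_equal(unique(refw$knot_values), min(trw$y))
})

test_that("rdp_simplify matches the recursive oracle and honors epsilon", {
  # collinear points at epsilon 0 keep endpoints only
  expect_equal(rdp_simplify(1:10, 2 * (1:10) + 3, 0), c(1L, 10L))
  # epsilon above the largest interior deviation keeps endpoints only
  expect_equal(rdp_simplify(1:5, c(0, 0.2, 0.4, 0.1, 0), 1), c(1L, 5L))
  # oracle equivalence on random polylines, both deviation metrics
  set.seed(7)
  for (rep in 1:200) {
    n <- sample(3:50, 1)
    x <- sort(runif(n, 0, 10))
    y <- rnorm(n)
    eps <- runif(1, 0, 2)
    for (m in c("vertical", "perpendicular")) {
      expect_identical(rdp_simplify(x, y, eps, method = m),
                       sort(rdp_oracle(x, y, eps, method = m)))
    }
  }
  # retained deviations from the simplified polyline stay within epsilon
  set.seed(8)
  x <- sort(runif(40)); y <- rnorm(40); eps <- 0.5
  keep <- rdp_simplify(x, y, eps)
  yhat <- approx(x[keep], y[keep], xout = x)$y
  expect_lte(max(abs(y - yhat)), eps + 1e-12)
})

test_that("detect_events quantifies an analytic rectangle and empty residual", {
  flat_ref <- structure(list(knot_times = c(0, 8), knot_values = c(0, 0),
                             side = "below", degenerate = FALSE),
                        class = "fibsi_reference")
  trr <- trace(c(0, 0, 10, 10, 10, 10, 10, 0, 0), sample_interval_s = 1)
  ev <- detect_events(trr, flat_ref, epsilon = 1, polarity = 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$amplitude, 10)
  expect_equal(ev$auc, 40)
  expect_equal(ev$duration, 4)
  # all-zero residual gives no events
  trz <- trace(rep(0, 9), sample_interval_s = 1)
  expect_equal(nrow(detect_events(trz, flat_ref, 1, 1)), 0L)
  # polarity -1 detects the mirrored pulse
  trn <- trace(-trr$y, sample_interval_s = 1)
  evn <- detect_events(trn, flat_ref, 1, -1)
  expect_equal(evn$amplitude, 10)
  expect_error(detect_events(trr, flat_ref, 1, polarity = 0),
               class = "fibsir_bad_polarity")
})

test_that("event metrics follow the symmetry and ramp conventions", {
  flat_ref <- structure(list(knot_times = c(0, 10), knot_values = c(0, 0),
                             side = "below", degenerate = FALSE),
                        class = "fibsi_reference")
  tri <- trace(c(0, 1, 2, 3, 4, 3, 2, 1, 0, 0), sample_interval_s = 1)
  ev <- detect_events(tri, flat_ref, 0.5, 1)
  expect_equal(ev$peak_offset, 0)
  expect_equal(ev$rise_time, ev$duration / 2)
  ramp <- trace(c(0, 5, 4, 3, 2, 1, 0, 0, 0, 0), sample_interval_s = 1)
  evr <- detect_events(ramp, flat_ref, 0.5, 1)
  expect_equal(evr$rise_time, 0)
  expect_equal(evr$peak_offset, -evr$duration / 2)
})

test_that("amplitude and AUC of a smooth transient match fine-grid quadrature", {
  # gamma-shaped transient sampled on a fine grid, flat zero reference
  shape <- 3; rate <- 0.8
  tt <- seq(0, 30, by = 0.01)
  y <- 40 * dgamma(tt, shape, rate) / max(dgamma(tt, shape, rate))
  tr <- trace(y, t = tt, sample_interval_s = 0.01)
  ref <- structure(list(knot_times = range(tt), knot_values = c(0, 0),
                        side = "below", degenerate = FALSE),
                   class = "fibsi_reference")
  ev <- detect_events(tr, ref, epsilon = 0.5, polarity = 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$amplitude, 40, tolerance = 0.005)
  auc_oracle <- integrate(function(x) 40 * dgamma(x, shape, rate) /
                            max(dgamma(tt, shape, rate)), 0, 30)$value
  expect_equal(ev$auc, auc_oracle, tolerance = 0.005)
})

test_that("planted calcium transients are recovered with accurate onsets", {
  set.seed(11)
  noise_sd <- 1
  dt <- 1
  tt <- seq(0, 400, by = dt)
  onsets <- seq(30, 390, by = 40)           # 10 well-separated transients
  amps <- runif(10, 30, 60) * noise_sd      # >= 5x noise
  y <- 100 + rnorm(length(tt), 0, noise_sd)
  for (k in seq_along(onsets)) {
    idx <- which(tt >= onsets[k])
    y[idx] <- y[idx] + amps[k] *
      (exp(-(tt[idx] - onsets[k]) / 6) - exp(-(tt[idx] - onsets[k]) / 1.5)) /
      0.47247039                             # unit-peak normalization
  }
  fit <- fibsi(trace(y, t = tt, sample_interval_s = dt),
               epsilon = 2 * noise_sd)
  ev <- apply_amplitude_cutoff(fit$events)
  expect_equal(nrow(ev), 10L)
  expect_true(all(abs(ev$t_start - onsets) <= 2 * dt))
})

test_that("events are disjoint, ordered, within span, and equivariant", {
  sim <- simulate_calcium_network(calcium_network_params(
    n_cells = 1, frac_silent = 0, duration_s = 400, seed = 5))
  tr <- sim$traces[[1]]
  fit <- fibsi(tr)
  ev <- fit$events
  expect_true(all(ev$t_start < ev$t_end))
  expect_true(all(diff(ev$t_start) > 0))
  expect_true(all(head(ev$t_end, -1) <= tail(ev$t_start, -1)))
  expect_true(all(ev$t_start >= tr$t[1] & ev$t_end <= tr$t[length(tr$t)]))
  # scale equivariance: y and epsilon scaled by c
  cc <- 3.5
  fit2 <- fibsi(trace(cc * tr$y, t = tr$t, cell_id = tr$cell_id),
                epsilon = cc * fit$epsilon)
  expect_equal(fit2$events$t_start, ev$t_start)
  expect_equal(fit2$events$t_end, ev$t_end)
  expect_equal(fit2$events$amplitude, cc * ev$amplitude)
  expect_equal(fit2$events$auc, cc * ev$auc)
  # time-shift equivariance
  dlt <- 13.75
  fit3 <- fibsi(trace(tr$y, t = tr$t + dlt, cell_id = tr$cell_id),
                epsilon = fit$epsilon)
  expect_equal(fit3$events$t_peak, ev$t_peak + dlt)
})

test_that("fibsi methods print, summarize and expose residuals", {
  sim <- simulate_calcium_network(calcium_network_params(
    n_cells = 1, frac_silent = 0, duration_s = 120, seed = 3))
  fit <- fibsi(sim$traces[[1]])
  expect_s3_class(fit, "fibsi")
  expect_output(print(fit), "events detected")
  s <- summary(fit)
  expect_equal(s$n_events, nrow(fit$events))
  expect_length(residuals(fit), length(sim$traces[[1]]$y))
  expect_equal(fit$epsilon, 2 * fit$noise)
})
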