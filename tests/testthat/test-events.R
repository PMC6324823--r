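test_that("detector recovers noiseless event trains exactly", {
  set.seed(1)
  rec <- simulate_mepsc(2, amp_cv = 0, duration_s = 20, noise_sd = 0)
  es <- detect_events(rec)
  # every detection lands within one sample of a true onset
  dt <- vapply(es$events$time_s,
               function(t) min(abs(rec$events$time_s - t)), numeric(1))
  expect_true(all(dt <= 1 / rec$sample_rate_hz + 1e-12))
  # flat recording: empty series, not an error
  flat <- list(signal = rep(0, 5000), sample_rate_hz = 5000)
  expect_equal(nrow(detect_events(flat)$events), 0L)
})

test_that("detector reaches 95% sensitivity and precision at SNR 5", {
  set.seed(2)
  rec <- simulate_mepsc(5, amp_mean_pA = 12, amp_cv = 0.3, duration_s = 60,
                        noise_sd = 2.4)
  es <- detect_events(rec)
  m <- match_events(es$events$time_s, rec$events$time_s)
  expect_gte(m["sensitivity"], 0.95)
  expect_gte(m["precision"], 0.95)
})

test_that("rank binning reproduces the constructed-sequence bin means", {
  es <- make_series(sample(1:400), spacing_s = 0.05)
  bc <- bin_cumulative(list(es), "amplitude")
  expect_equal(bc$bin_values, seq(10.5, 390.5, by = 20))
  expect_equal(unname(bc$per_cell_means), mean(1:400))
})

test_that("cumulative bins are monotone and conserve the grand mean", {
  set.seed(3)
  cells <- lapply(1:6, function(i)
    make_series(rgamma(450, 9, 0.75), cell_id = paste0("c", i)))
  for (v in c("amplitude", "iei")) {
    bc <- bin_cumulative(cells, v)
    expect_true(all(diff(bc$bin_values) >= 0))
    expect_equal(mean(bc$bin_values), mean(bc$per_cell_means),
                 tolerance = 1e-12)
    for (i in seq_len(bc$n_cells)) {
      expect_equal(mean(bc$per_cell_bins[i, ]),
                   unname(bc$per_cell_means[i]), tolerance = 1e-12)
    }
  }
  # identical cells: cross-cell average equals the single-cell bins
  twin <- list(cells[[1]], cells[[1]])
  twin[[2]]$cell_id <- "c1b"
  bc1 <- bin_cumulative(list(cells[[1]]), "amplitude")
  bc2 <- bin_cumulative(twin, "amplitude")
  expect_equal(bc2$bin_values, bc1$bin_values)
})

test_that("cells with too few events are excluded with a log entry", {
  cells <- list(make_series(rgamma(450, 9, 0.75), cell_id = "full"),
                make_series(rgamma(100, 9, 0.75), cell_id = "short"))
  bc <- bin_cumulative(cells, "amplitude")
  expect_equal(bc$n_cells, 1L)
  expect_equal(bc$excluded$cell_id, "short")
  expect_match(bc$excluded$reason, "only 100")
  # for IEIs a cell needs n_events + 1 events
  at_400 <- list(make_series(rgamma(400, 9, 0.75), cell_id = "exactly400"))
  expect_equal(bin_cumulative(at_400, "amplitude")$n_cells, 1L)
  expect_error(bin_cumulative(at_400, "iei"), "no cell")
})

test_that("paired-pulse ratio recovers amplitudes under tail overlap", {
  # identical responses: ratio 1
  tr <- simulate_ppr_trace(50, 50, 50)
  expect_equal(ppr(tr, 50)$ratio, 1, tolerance = 1e-3)
  # overlapping tails, noiseless: subtraction recovers amp2 within 1%
  tr2 <- simulate_ppr_trace(100, 60, 50)
  r2 <- ppr(tr2, 50)
  expect_lt(abs(r2$amp2_pA - 60) / 60, 0.01)
  expect_lt(abs(r2$ratio - 0.6), 0.01)
  # depletion factor d on pulse 2: fitted ratio ~ 1 - d
  for (d in c(0.2, 0.5)) {
    tr_d <- simulate_ppr_trace(80, 80 * (1 - d), 100)
    expect_lt(abs(ppr(tr_d, 100)$ratio - (1 - d)), 0.01)
  }
  # invariant to uniform gain rescaling
  expect_equal(ppr(tr2 * 7, 50)$ratio, r2$ratio, tolerance = 1e-6)
  # first response at the noise floor is an error
  expect_error(ppr(simulate_ppr_trace(0.5, 0.5, 50), 50), "noise floor")
})

test_that("MK-801 decay fit recovers the release probability", {
  set.seed(4)
  peaks <- lapply(1:100, function(i)
    simulate_mk801(synapse_model(release_prob = 0.3), 50)$peak_pA)
  fit <- mk801_decay(peaks)
  expect_lt(abs(fit$survival - 0.7), 0.03)
  expect_equal(fit$release_prob_proxy, 1 - fit$survival)
  # degenerate flat series is flagged, not fitted
  flat <- mk801_decay(rep(5, 20))
  expect_true(flat$flat)
  expect_equal(flat$survival, 1)
  expect_error(mk801_decay(c(0, rep(1, 15))), "positive")
  expect_error(mk801_decay(rep(1, 5)), "10 sweeps")
})

test_that("fitted MK-801 survival is monotone in release probability", {
  ps <- seq(0.1, 0.9, by = 0.2)
  surv <- vapply(ps, function(p) {
    set.seed(round(1000 * p))
    peaks <- lapply(1:40, function(i)
      simulate_mk801(synapse_model(release_prob = p), 50)$peak_pA)
    mk801_decay(peaks)$survival
  }, numeric(1))
  expect_equal(cor(ps, surv, method = "spearman"), -1)
})

test_that("Sr2+ quantal analysis matches spontaneous quantal statistics", {
  m0 <- synapse_model(5, 0, 0.3, quantal_cv = 0, noise_sd = 0)
  set.seed(5)
  ev <- simulate_sr_release(m0, 500, 200)
  qa <- sr_quantal_analysis(ev, 500)
  expect_equal(qa$mean_amplitude_pA, m0$quantal_mean_ampa)
  # evoked vs spontaneous means agree for identical quantal parameters
  set.seed(6)
  ev2 <- simulate_sr_release(synapse_model(), 500, 3000)
  qa2 <- sr_quantal_analysis(ev2, 500)
  set.seed(7)
  sp <- simulate_mepsc(5, amp_mean_pA = 12, amp_cv = 0.3, duration_s = 60,
                       noise_sd = 0)
  tt <- t.test(qa2$amplitudes_pA, sp$events$amplitude_pA)
  expect_gt(tt$p.value, 0.01)
  # higher release probability shortens the asynchronous IEI
  set.seed(8)
  lo <- sr_quantal_analysis(
    simulate_sr_release(synapse_model(10, 0, 0.2), 500, 3000), 500)
  set.seed(8)
  hi <- sr_quantal_analysis(
    simulate_sr_release(synapse_model(10, 0, 0.4), 500, 3000), 500)
  expect_lt(hi$mean_iei_ms, lo$mean_iei_ms)
  # Poisson property: doubling the event rate halves the mean IEI
  set.seed(9)
  iei5 <- mean(diff(simulate_mepsc(5, duration_s = 200)$events$time_s))
  set.seed(9)
  iei10 <- mean(diff(simulate_mepsc(10, duration_s = 200)$events$time_s))
  expect_lt(abs(iei10 / iei5 - 0.5), 0.05)
  expect_error(sr_quantal_analysis(ev[0, ], 500), "no events")
})
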