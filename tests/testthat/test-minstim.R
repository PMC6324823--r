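test_that("qc_filter applies the strict 30 MOhm / 20% rules", {
  mk_cell <- function(id, rs, drift) {
    set.seed(1)
    simulate_minstim(synapse_model(), 5, cell_id = id,
                     series_resistance_mohm = rs,
                     resistance_drift_fraction = drift)
  }
  cells <- list(mk_cell("ok", 29, 0.10),
                mk_cell("rs_at_cut", 30, 0.10),
                mk_cell("drifty", 15, 0.25),
                mk_cell("drift_at_cut", 15, 0.20))
  cells[[5]] <- mk_cell("no_qc", 15, 0.05)
  cells[[5]]$qc <- NULL
  res <- qc_filter(cells)
  expect_equal(vapply(res$retained, `[[`, "", "cell_id"), "ok")
  expect_setequal(res$exclusions$cell_id,
                  c("rs_at_cut", "drifty", "drift_at_cut", "no_qc"))
  expect_match(res$exclusions$reason[res$exclusions$cell_id == "no_qc"],
               "missing")
  expect_match(res$exclusions$reason[res$exclusions$cell_id == "rs_at_cut"],
               "series")
})

test_that("trial classification matches ground truth at high SNR", {
  set.seed(2)
  ds <- simulate_minstim(synapse_model(noise_sd = 0), 100)
  expect_identical(classify_trials(ds), !ds$trials$truth_failure)
  set.seed(3)
  ds2 <- simulate_minstim(synapse_model(noise_sd = 1), 2000)
  agree <- mean(classify_trials(ds2) == !ds2$trials$truth_failure)
  expect_gte(agree, 0.99)
  # trace-based classification agrees with ground truth when noiseless
  set.seed(4)
  ds3 <- simulate_minstim(synapse_model(noise_sd = 0), 30,
                          render_traces = TRUE)
  ds3$trials$baseline_rms_pA <- NULL  # force the trace path
  expect_identical(classify_trials(ds3), !ds3$trials$truth_failure)
})

test_that("silent_fraction implements 1 - ln(F-60)/ln(F+40)", {
  expect_equal(silent_fraction(0.3, 0.3), 0)
  # algebraic identity: F-60 = (1-p)^3, F+40 = (1-p)^5 gives exactly 0.4
  for (p in seq(0.1, 0.9, by = 0.2)) {
    expect_equal(silent_fraction((1 - p)^3, (1 - p)^5), 0.4)
  }
  # negative estimates are legitimate and returned unclipped
  expect_equal(silent_fraction(0.25, 0.35), 1 - log(0.25) / log(0.35))
  expect_lt(silent_fraction(0.25, 0.35), 0)
  # degenerate failure rates are signaled, never silent NaN
  expect_error(silent_fraction(0, 0.5), class = "silentsyn_undefined_estimator")
  expect_error(silent_fraction(0.5, 1), class = "silentsyn_undefined_estimator")
  expect_error(silent_fraction(0.5, 0), class = "silentsyn_undefined_estimator")
})

test_that("silent_fraction is strictly monotone in F-60 at fixed F+40", {
  # more AMPA failures at -60 mV (holding the composite rate fixed) means
  # fewer AMPA-active synapses, i.e. a larger silent fraction:
  # d/dF60 [1 - ln(F60)/ln(F40)] = -1/(F60 ln F40) > 0
  f60 <- seq(0.05, 0.95, by = 0.05)
  vals <- silent_fraction(f60, rep(0.2, length(f60)))
  expect_true(all(diff(vals) > 0))
})

test_that("analyze_cell reports potency, success rate and silent fraction", {
  # all-success cell with constant 20 pA peaks
  ds <- structure(list(
    cell_id = "c", qc = list(series_resistance_mohm = 10,
                             input_resistance_drift_fraction = 0),
    spec = trace_spec(),
    trials = data.frame(
      holding_potential_mV = rep(c(-60, 40), each = 4),
      peak_pA = c(rep(20, 4), c(15, 0, 15, 0)),
      baseline_rms_pA = 1)), class = "minstim_dataset")
  res <- analyze_cell(ds)
  expect_equal(res$potency_pA, 20)
  expect_equal(res$success_rate, 1)
  expect_equal(res$f_plus40, 0.5)
  # f60 = 0 (all successes) leaves the estimator undefined but keeps potency
  expect_false(res$estimator_defined)
  expect_true(is.na(res$silent_fraction))
  # degenerate cell: no successes at -60 mV
  ds$trials$peak_pA[1:4] <- 0
  res2 <- analyze_cell(ds)
  expect_true(is.na(res2$silent_fraction))
  expect_true(is.na(res2$potency_pA))
  expect_equal(res2$success_rate, 0)
  # a potential with zero trials is an error
  ds$trials <- ds$trials[ds$trials$holding_potential_mV == -60, ]
  expect_error(analyze_cell(ds), "both holding potentials")
})

test_that("analyze_cell is invariant under trial permutation", {
  set.seed(5)
  ds <- simulate_minstim(synapse_model(5, 0.4, 0.3), 100)
  perm <- sample(nrow(ds$trials))
  ds_p <- ds
  ds_p$trials <- ds$trials[perm, ]
  expect_equal(analyze_cell(ds), analyze_cell(ds_p))
})

test_that("estimator recovery holds across the silent-fraction range", {
  # property: mean cohort estimate within 2 points of the realized fraction
  for (s in c(0, 0.5, 0.8)) {
    set.seed(100 + round(100 * s))
    cells <- lapply(1:200, function(i)
      simulate_minstim(synapse_model(5, s, 0.3), 200))
    realized <- cells[[1]]$model$realized_silent_fraction
    est <- analyze_cohort(cells)$summary$mean_silent_fraction
    expect_lt(abs(est - realized), 0.02)
  }
})

test_that("ampa_nmda_ratio reads the +40 trace 50 ms after its peak", {
  spec <- trace_spec(trace_ms = 150)
  fs <- spec$sample_rate_hz
  n <- round(spec$trace_ms / 1000 * fs)
  tt <- seq_len(n) / fs
  t0 <- spec$baseline_ms / 1000
  # rectangular pulses make the 50-ms offset value exact
  tr60 <- ifelse(tt > t0 & tt <= t0 + 0.01, 100, 0)
  tr40 <- ifelse(tt > t0 & tt <= t0 + 0.002, 60,
                 ifelse(tt > t0 + 0.002 & tt <= t0 + 0.1, 50, 0))
  expect_equal(ampa_nmda_ratio(tr60, tr40, spec), 2)
  # pure NMDA cell: tiny AMPA peak over a large NMDA current
  tr60_silent <- ifelse(tt > t0 & tt <= t0 + 0.01, 0.5, 0)
  expect_lt(ampa_nmda_ratio(tr60_silent, tr40, spec), 0.011)
  # denominator at the noise floor is flagged
  expect_error(ampa_nmda_ratio(tr60, tr60 * 0, spec), "noise floor")
})

test_that("ampa_nmda_ratio grows with the AMPA-active fraction", {
  spec <- trace_spec(trace_ms = 150, window_nmda_ms = c(5, 100))
  ratios <- vapply(c(0.8, 0.4, 0), function(s) {
    set.seed(42)
    ds <- simulate_minstim(synapse_model(10, s, 0.5, noise_sd = 0), 60,
                           spec = spec, render_traces = TRUE)
    m60 <- ds$trials$holding_potential_mV == -60
    ampa_nmda_ratio(colMeans(ds$traces$minus60),
                    colMeans(ds$traces$plus40), spec)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("nmda_potency subtracts the failure average at the success peak", {
  set.seed(6)
  spec <- trace_spec()
  ds <- simulate_minstim(synapse_model(5, 0, 0.3, quantal_cv = 0,
                                       noise_sd = 0),
                         1500, spec = spec, render_traces = TRUE)
  res <- nmda_potency(ds)
  expect_true(res$failure_corrected)
  # conditional expectation: E[quanta | >= 1 released] * q
  p <- 0.3; n <- 5; q <- 10
  expected <- n * p / (1 - (1 - p)^n) * q
  expect_lt(abs(res$potency_pA - expected) / expected, 0.05)
  # failure traces identically zero: potency equals success-average peak
  ds2 <- ds
  keep <- which(ds2$trials$holding_potential_mV == 40)
  fails <- !classify_trials(ds2)[keep]
  ds2$traces$plus40[fails, ] <- 0
  res2 <- nmda_potency(ds2)
  succ_avg <- colMeans(ds2$traces$plus40[!fails, , drop = FALSE])
  expect_equal(res2$potency_pA, max(succ_avg), tolerance = 1e-10)
})
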