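#!/usr/bin/env Rscript
# Minimal-stimulation study: does the failure-rate estimator
# 1 - ln(F-60)/ln(F+40) recover the programmed silent-synapse fraction?
#
# Simulates cohorts of 200 cells (5 synapses/afferent, p = 0.3, 200 trials
# per holding potential) across silent fractions 0, 0.25 (realized 0.4 at
# n = 5 rounds to 2/5), 0.5 and 0.8, classifies trials at 3x baseline RMS,
# and compares the cohort-mean estimate with the realized fraction.

library(silentsyn)

dir.create("results", showWarnings = FALSE)
seed <- 20260101

rows <- lapply(c(0, 0.25, 0.4, 0.5, 0.8), function(s) {
  set.seed(derive_seed(seed, round(100 * s) + 1L))
  cells <- lapply(1:200, function(i) simulate_minstim(synapse_model(5, s, 0.3), 200))
  realized <- cells[[1]]$model$realized_silent_fraction
  res <- analyze_cohort(cells)
  data.frame(programmed_s = s, realized_s = realized,
             mean_estimate = res$summary$mean_silent_fraction,
             error = res$summary$mean_silent_fraction - realized,
             n_negative_cells = sum(res$cells$silent_fraction < 0,
                                    na.rm = TRUE),
             n_undefined = 200 - res$summary$n_estimator_defined,
             mean_potency_pA = res$summary$mean_potency_pA,
             mean_success_rate = res$summary$mean_success_rate)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/minstim_recovery.csv", row.names = FALSE)
print(tab, digits = 3)
cat("\nMax |error| across the silent-fraction grid:",
    signif(max(abs(tab$error)), 2),
    "\nNegative per-cell estimates occur at low silent fractions and are",
    "retained unclipped in the cohort means.\n")
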