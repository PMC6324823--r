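#!/usr/bin/env Rscript
# Visual water task study: recovery of acuity and orientation thresholds
# (70% accuracy criterion) from synthetic psychometric observers under the
# staircase protocols (rising spatial frequency; 5-degree orientation steps).

library(silentsyn)

dir.create("results", showWarnings = FALSE)
seed <- 20260105

lev <- c(0.086, seq(0.15, 0.80, by = 0.05))
obs_a <- psychometric_observer(0.47, slope = 200, lapse_rate = 0.02,
                               task = "acuity")
obs_o <- psychometric_observer(23, slope = 5, lapse_rate = 0.02,
                               task = "orientation")

set.seed(derive_seed(seed, 1L))
acu <- replicate(200, {
  log <- simulate_vwt_session(obs_a, lev, trials_per_block = 40)
  tryCatch(acuity_threshold(log), error = function(e) NA_real_)
})
set.seed(derive_seed(seed, 2L))
ori <- replicate(200, {
  log <- simulate_vwt_session(obs_o, trials_per_block = 40)
  tryCatch(orientation_threshold(log), error = function(e) NA_real_)
})

target <- max(lev[lev <= obs_a$true_threshold])
tab <- data.frame(
  task = c("acuity", "orientation"),
  true_threshold = c(0.47, 23),
  modal_recovered = c(as.numeric(names(sort(-table(acu)))[1]),
                      as.numeric(names(sort(-table(ori)))[1])),
  exact_or_one_step = c(mean(acu == target, na.rm = TRUE),
                        mean(abs(ori - 25) <= 5, na.rm = TRUE)))
write.csv(tab, "results/vwt_recovery.csv", row.names = FALSE)
print(tab, digits = 3)
cat("\nThresholds are step-quantized to the tested level grid;",
    "the acuity observer is recovered at the largest tested level below",
    "its true threshold.\n")
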