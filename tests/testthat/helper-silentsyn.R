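# shared fixtures built in code

# match detected to ground-truth event times within a tolerance (s);
# returns sensitivity and precision
match_events <- function(detected_s, truth_s, tol_s = 0.003) {
  sens <- mean(vapply(truth_s, function(t) any(abs(detected_s - t) < tol_s),
                      logical(1)))
  prec <- mean(vapply(detected_s, function(t) any(abs(truth_s - t) < tol_s),
                      logical(1)))
  c(sensitivity = sens, precision = prec)
}

# event series with prescribed amplitudes at regular spacing
make_series <- function(amplitudes, spacing_s = 0.1, cell_id = "cell1") {
  n <- length(amplitudes)
  event_series(data.frame(time_s = seq_len(n) * spacing_s,
                          amplitude_pA = amplitudes),
               recording_duration_s = (n + 1) * spacing_s, cell_id = cell_id)
}

# behavioral trial log with exact per-block accuracies
make_log <- function(levels, accuracies, trials_per_block = 20) {
  stopifnot(length(levels) == length(accuracies))
  do.call(rbind, lapply(seq_along(levels), function(i) {
    n_ok <- round(accuracies[i] * trials_per_block)
    data.frame(block_id = i, level = levels[i],
               correct = c(rep(TRUE, n_ok),
                           rep(FALSE, trials_per_block - n_ok)))
  }))
}

# flat-amplitude, flat-phase imaging ground truth
flat_gt <- function(amp_c, amp_i, shape = c(8, 8), phase = 0, ...) {
  imaging_ground_truth(matrix(amp_c, shape[1], shape[2]),
                       matrix(amp_i, shape[1], shape[2]),
                       matrix(phase, shape[1], shape[2]), ...)
}
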