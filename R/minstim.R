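#' Quality-control filter for minimal-stimulation recordings
#'
#' Retains cells with a series resistance smaller than 30 Mohm and changes
#' of series/input resistance of less than 20% (both strict inequalities).
#' Cells with missing QC fields are rejected with an explicit reason.
#'
#' @param cells list of \code{minstim_dataset} objects.
#' @param max_series_mohm series-resistance cutoff (exclusive).
#' @param max_drift_fraction resistance-drift cutoff (exclusive).
#' @return list with \code{$retained} (the passing datasets) and
#'   \code{$exclusions} (data.frame: \code{cell_id}, \code{reason}).
#' @export
qc_filter <- function(cells, max_series_mohm = 30, max_drift_fraction = 0.20) {
  reasons <- character(0); ids <- character(0)
  keep <- logical(length(cells))
  for (i in seq_along(cells)) {
    ds <- cells[[i]]
    qc <- ds$qc
    id <- if (is.null(ds$cell_id)) paste0("cell", i) else ds$cell_id
    if (is.null(qc) || is.null(qc$series_resistance_mohm) ||
        is.null(qc$input_resistance_drift_fraction) ||
        is.na(qc$series_resistance_mohm) ||
        is.na(qc$input_resistance_drift_fraction)) {
      ids <- c(ids, id); reasons <- c(reasons, "missing QC fields")
    } else if (qc$series_resistance_mohm >= max_series_mohm) {
      ids <- c(ids, id)
      reasons <- c(reasons, sprintf("series resistance %.3g MOhm >= %g MOhm",
                                    qc$series_resistance_mohm, max_series_mohm))
    } else if (qc$input_resistance_drift_fraction >= max_drift_fraction) {
      ids <- c(ids, id)
      reasons <- c(reasons, sprintf("resistance drift %.3g >= %g",
                                    qc$input_resistance_drift_fraction,
                                    max_drift_fraction))
    } else {
      keep[i] <- TRUE
    }
  }
  list(retained = cells[keep],
       exclusions = data.frame(cell_id = ids, reason = reasons,
                               stringsAsFactors = FALSE))
}

# peak within a potential-appropriate window of a trace matrix;
# window in ms after stimulus onset (spec$baseline_ms)
window_peak <- function(traces, spec, window_ms) {
  i0 <- floor((spec$baseline_ms + window_ms[1]) / 1000 * spec$sample_rate_hz) + 1L
  i1 <- min(ncol(traces),
            ceiling((spec$baseline_ms + window_ms[2]) / 1000 * spec$sample_rate_hz))
  if (i1 < i0) stop("empty response window", call. = FALSE)
  apply(traces[, i0:i1, drop = FALSE], 1, max)
}

baseline_rms <- function(traces, spec) {
  n_base <- floor(spec$baseline_ms / 1000 * spec$sample_rate_hz)
  if (n_base < 1L) stop("zero-length baseline segment", call. = FALSE)
  sqrt(rowMeans(traces[, seq_len(n_base), drop = FALSE]^2))
}

#' Classify minimal-stimulation trials as successes or failures
#'
#' Algorithmic surrogate for visual success/failure scoring: a trial is a
#' success iff its peak within the potential-appropriate response window
#' exceeds \code{k_sd} times the baseline RMS.  At -60 mV the AMPA window of
#' the trace spec is used; at +40 mV the composite window, which extends over
#' the slow NMDA component (the +40 mV response is a composite AMPA+NMDA
#' current).  With rendered traces the peak and baseline RMS are measured on
#' the trace; otherwise the stored per-trial peak and baseline RMS are used.
#'
#' @param ds a \code{minstim_dataset}.
#' @param k_sd detection threshold in baseline-RMS units (default 3).
#' @return logical vector, \code{TRUE} for successes, aligned with
#'   \code{ds$trials}.
#' @export
classify_trials <- function(ds, k_sd = 3) {
  stopifnot(inherits(ds, "minstim_dataset"))
  tr <- ds$trials
  if (!is.null(ds$traces)) {
    spec <- ds$spec
    m60 <- tr$holding_potential_mV == -60
    peak <- rms <- numeric(nrow(tr))
    peak[m60] <- window_peak(ds$traces$minus60, spec, spec$window_ampa_ms)
    peak[!m60] <- window_peak(ds$traces$plus40, spec, spec$window_nmda_ms)
    rms[m60] <- baseline_rms(ds$traces$minus60, spec)
    rms[!m60] <- baseline_rms(ds$traces$plus40, spec)
  } else {
    peak <- tr$peak_pA
    rms <- tr$baseline_rms_pA
  }
  peak > k_sd * rms
}

#' Silent-synapse fraction from failure rates
#'
#' The failure-rate estimator of the silent-synapse fraction:
#' \deqn{s = 1 - \ln(F_{-60}) / \ln(F_{+40})}
#' where \eqn{F_{-60}} is the failure rate at -60 mV (AMPA-only) and
#' \eqn{F_{+40}} at +40 mV (composite response).  Under the binomial release
#' model with \eqn{N_a} AMPA-active of \eqn{N} synapses and uniform release
#' probability \eqn{p}, \eqn{F_{-60} = (1-p)^{N_a}} and
#' \eqn{F_{+40} = (1-p)^{N}}, so the estimator returns exactly
#' \eqn{1 - N_a/N}.  Sampling variability in the failure rates can make the
#' estimate negative; negative values are returned unclipped.
#'
#' @param f60 failure rate at -60 mV, in \code{(0, 1]}.
#' @param f40 failure rate at +40 mV, in \code{(0, 1)}.
#' @return the estimated silent fraction (possibly negative).  If
#'   \code{f60 = 0} or \code{f40} is 0 or 1 the estimator has no value and
#'   an error of class \code{silentsyn_undefined_estimator} is signaled.
#' @export
silent_fraction <- function(f60, f40) {
  stopifnot(is.numeric(f60), is.numeric(f40), length(f60) == length(f40))
  bad <- is.na(f60) | is.na(f40) | f60 <= 0 | f40 <= 0 | f40 >= 1 | f60 > 1
  if (any(bad)) {
    stop(structure(
      class = c("silentsyn_undefined_estimator", "error", "condition"),
      list(message = paste0(
             "silent-synapse estimator undefined: requires 0 < F-60 <= 1 ",
             "and 0 < F+40 < 1 (got F-60 = ", f60[which(bad)[1]],
             ", F+40 = ", f40[which(bad)[1]], ")"),
           call = sys.call(-1))))
  }
  1 - log(f60) / log(f40)
}

#' Analyze one minimal-stimulation cell
#'
#' Classifies trials at both holding potentials, computes the two failure
#' rates, the silent-synapse fraction, synaptic potency (mean success peak
#' at -60 mV, failures excluded) and the success rate
#' (\eqn{1 - F_{-60}}).  When a failure rate makes the estimator undefined
#' (no successes or no failures at the relevant potential) the silent
#' fraction is reported as \code{NA} with \code{estimator_defined = FALSE};
#' potency and success rate are still reported where computable.
#'
#' @param ds a \code{minstim_dataset} containing trials at both potentials.
#' @param k_sd classification threshold passed to
#'   \code{\link{classify_trials}}.
#' @return one-row data.frame: \code{cell_id}, \code{f_minus60},
#'   \code{f_plus40}, \code{silent_fraction}, \code{estimator_defined},
#'   \code{potency_pA}, \code{success_rate}, \code{n_minus60},
#'   \code{n_plus40}.
#' @export
analyze_cell <- function(ds, k_sd = 3) {
  stopifnot(inherits(ds, "minstim_dataset"))
  success <- classify_trials(ds, k_sd = k_sd)
  vh <- ds$trials$holding_potential_mV
  m60 <- vh == -60
  p40 <- vh == 40
  if (!any(m60) || !any(p40)) {
    stop("both holding potentials (-60 and +40 mV) must be represented",
         call. = FALSE)
  }
  f60 <- mean(!success[m60])
  f40 <- mean(!success[p40])
  # a cell with no successes at -60 mV (F-60 = 1) gives the estimator no
  # usable value either: reported undefined, like the F+40 boundary cases
  sf <- if (f60 >= 1) NA_real_ else {
    tryCatch(silent_fraction(f60, f40),
             silentsyn_undefined_estimator = function(e) NA_real_)
  }
  peaks60 <- ds$trials$peak_pA[m60 & success]
  data.frame(
    cell_id = ds$cell_id,
    f_minus60 = f60,
    f_plus40 = f40,
    silent_fraction = sf,
    estimator_defined = !is.na(sf),
    potency_pA = if (length(peaks60)) mean(peaks60) else NA_real_,
    success_rate = 1 - f60,
    n_minus60 = sum(m60),
    n_plus40 = sum(p40),
    stringsAsFactors = FALSE
  )
}

#' Analyze a cohort of minimal-stimulation cells
#'
#' Applies \code{\link{analyze_cell}} to every dataset and returns the
#' per-cell table together with a group summary.  Cells whose estimator is
#' undefined are excluded from the silent-fraction mean (and logged via the
#' \code{estimator_defined} column) but still contribute to potency and
#' success-rate summaries.  Negative silent fractions enter the mean
#' unclipped.
#'
#' @param cells list of \code{minstim_dataset} objects.
#' @param k_sd classification threshold.
#' @return list with \code{$cells} (per-cell table) and \code{$summary}
#'   (one-row data.frame of group means and counts).
#' @export
analyze_cohort <- function(cells, k_sd = 3) {
  per_cell <- do.call(rbind, lapply(cells, analyze_cell, k_sd = k_sd))
  ok <- per_cell$estimator_defined
  summary <- data.frame(
    n_cells = nrow(per_cell),
    n_estimator_defined = sum(ok),
    mean_silent_fraction = mean(per_cell$silent_fraction[ok]),
    mean_potency_pA = mean(per_cell$potency_pA, na.rm = TRUE),
    mean_success_rate = mean(per_cell$success_rate),
    mean_f_minus60 = mean(per_cell$f_minus60),
    mean_f_plus40 = mean(per_cell$f_plus40)
  )
  list(cells = per_cell, summary = summary)
}

#' AMPA/NMDA receptor current ratio
#'
#' Measured as the peak current at -60 mV divided by the amplitude of the
#' +40 mV trace 50 ms after its own peak, by which time the AMPA component
#' has returned to baseline and the remaining current is NMDA-mediated.
#'
#' @param trace_minus60,trace_plus40 stimulus-aligned traces (pA,
#'   positive-going responses).
#' @param spec the \code{\link{trace_spec}} shared by both traces.
#' @param delay_ms delay after the +40 mV peak at which the NMDA current is
#'   read (default 50 ms).
#' @param noise_floor_pA denominators at or below this magnitude make the
#'   ratio unreliable and signal an error.
#' @return the AMPA/NMDA ratio (scalar).
#' @export
ampa_nmda_ratio <- function(trace_minus60, trace_plus40, spec = trace_spec(),
                            delay_ms = 50, noise_floor_pA = 1) {
  i_base <- floor(spec$baseline_ms / 1000 * spec$sample_rate_hz)
  post60 <- trace_minus60[(i_base + 1L):length(trace_minus60)]
  post40 <- trace_plus40[(i_base + 1L):length(trace_plus40)]
  ampa_peak <- max(abs(post60))
  i_peak40 <- which.max(abs(post40))
  i_nmda <- i_peak40 + round(delay_ms / 1000 * spec$sample_rate_hz)
  if (i_nmda > length(post40)) {
    stop("+40 mV trace too short to read 50 ms after its peak", call. = FALSE)
  }
  nmda_amp <- abs(post40[i_nmda])
  if (nmda_amp <= noise_floor_pA) {
    stop("NMDA amplitude at peak + ", delay_ms,
         " ms is below the noise floor; ratio unreliable", call. = FALSE)
  }
  ampa_peak / nmda_amp
}

#' NMDA-receptor potency from +40 mV minimal-stimulation trials
#'
#' Success traces are pooled and averaged; the peak amplitude of the
#' averaged success trace is measured and the amplitude of the averaged
#' failure trace at the same time point is subtracted.  This corrects the
#' success-average peak for any baseline structure shared with failures.
#'
#' @param ds a \code{minstim_dataset} with rendered traces.
#' @param k_sd classification threshold.
#' @return list with \code{$potency_pA}, \code{$n_success},
#'   \code{$n_failure} and \code{$failure_corrected} (\code{FALSE} when no
#'   failure traces existed, in which case the uncorrected success-average
#'   peak is returned).
#' @export
nmda_potency <- function(ds, k_sd = 3) {
  stopifnot(inherits(ds, "minstim_dataset"))
  if (is.null(ds$traces)) {
    stop("nmda_potency() requires rendered traces", call. = FALSE)
  }
  spec <- ds$spec
  p40 <- ds$trials$holding_potential_mV == 40
  success <- classify_trials(ds, k_sd = k_sd)[p40]
  traces <- ds$traces$plus40
  if (!any(success)) stop("no success traces at +40 mV", call. = FALSE)
  avg_succ <- colMeans(traces[success, , drop = FALSE])
  i_base <- floor(spec$baseline_ms / 1000 * spec$sample_rate_hz)
  i_peak <- i_base + which.max(abs(avg_succ[(i_base + 1L):length(avg_succ)]))
  if (any(!success)) {
    avg_fail <- colMeans(traces[!success, , drop = FALSE])
    pot <- avg_succ[i_peak] - avg_fail[i_peak]
    corrected <- TRUE
  } else {
    pot <- avg_succ[i_peak]
    corrected <- FALSE
  }
  list(potency_pA = unname(pot), n_success = sum(success),
       n_failure = sum(!success), failure_corrected = corrected)
}
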