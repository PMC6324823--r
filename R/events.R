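#' Detect miniature EPSC events in a continuous recording
#'
#' Threshold-crossing detector on a boxcar-smoothed, baseline-subtracted
#' signal.  The baseline is the median of the smoothed signal and the noise
#' scale its median absolute deviation (robust to the sparse events riding
#' on it).  An event is a contiguous region where the smoothed signal
#' exceeds \code{threshold_sd} noise SDs above baseline for at least
#' \code{min_duration_ms} (isolated noise spikes are too brief to qualify);
#' the event time is the region onset and the amplitude baseline-to-peak on
#' the raw signal.  Events closer than the refractory interval are merged,
#' keeping the larger peak.  The detector is a stated surrogate: published
#' datasets rarely document their detection algorithm, so all its knobs are
#' configurable.
#'
#' @param recording list with \code{$signal} (numeric, pA) and
#'   \code{$sample_rate_hz}, as returned by \code{\link{simulate_mepsc}}.
#' @param threshold_sd detection threshold in noise-SD units.
#' @param refractory_ms minimum separation between distinct events, ms.
#' @param smooth_ms causal boxcar width, ms.
#' @param min_duration_ms minimum time above threshold, ms.
#' @return an \code{event_series}: list with \code{$events} (data.frame
#'   \code{time_s}, \code{amplitude_pA}, times strictly increasing),
#'   \code{$recording_duration_s}.  A flat recording yields an empty series.
#' @export
detect_events <- function(recording, threshold_sd = 3, refractory_ms = 5,
                          smooth_ms = 2, min_duration_ms = 2.5) {
  sig <- recording$signal
  fs <- recording$sample_rate_hz
  refr <- refractory_ms / 1000
  dur <- length(sig) / fs
  if (dur <= refr) stop("recording shorter than the refractory period",
                        call. = FALSE)
  k <- max(1L, round(smooth_ms / 1000 * fs))
  sm <- as.numeric(stats::filter(sig, rep(1 / k, k), sides = 1))
  sm[seq_len(k - 1L)] <- sig[seq_len(k - 1L)]
  base <- stats::median(sm)
  noise <- stats::mad(sm)
  thr <- base + threshold_sd * noise
  above <- sm > thr
  if (!any(above)) {
    return(event_series(data.frame(time_s = numeric(0),
                                   amplitude_pA = numeric(0)), dur))
  }
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  min_len <- max(1L, round(min_duration_ms / 1000 * fs))
  long_enough <- (ends - starts + 1L) >= min_len
  starts <- starts[long_enough]; ends <- ends[long_enough]
  if (!length(starts)) {
    return(event_series(data.frame(time_s = numeric(0),
                                   amplitude_pA = numeric(0)), dur))
  }
  base_raw <- stats::median(sig)
  peak_amp <- onset <- numeric(length(starts))
  for (i in seq_along(starts)) {
    seg <- sig[starts[i]:ends[i]]
    peak_amp[i] <- max(seg) - base_raw
    onset[i] <- (starts[i] - 1L) / fs
  }
  # refractory merge: within refr of the previous kept event, keep larger
  keep_t <- keep_a <- numeric(0)
  for (i in seq_along(onset)) {
    if (length(keep_t) && onset[i] - keep_t[length(keep_t)] < refr) {
      if (peak_amp[i] > keep_a[length(keep_a)]) {
        keep_a[length(keep_a)] <- peak_amp[i]
      }
    } else {
      keep_t <- c(keep_t, onset[i])
      keep_a <- c(keep_a, peak_amp[i])
    }
  }
  event_series(data.frame(time_s = keep_t, amplitude_pA = keep_a), dur)
}

#' Construct an event series
#'
#' @param events data.frame with \code{time_s} (strictly increasing) and
#'   \code{amplitude_pA} (> 0).
#' @param recording_duration_s total recording duration, s.
#' @param cell_id identifier.
#' @return an object of class \code{event_series}.
#' @export
event_series <- function(events, recording_duration_s, cell_id = "cell1") {
  stopifnot(is.data.frame(events),
            all(c("time_s", "amplitude_pA") %in% names(events)))
  if (nrow(events) > 1 && any(diff(events$time_s) <= 0)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  structure(list(cell_id = cell_id, events = events,
                 recording_duration_s = recording_duration_s),
            class = "event_series")
}

# the per-cell value vector for a binning variable
event_values <- function(es, variable) {
  ev <- es$events
  switch(variable,
         amplitude = ev$amplitude_pA,
         iei = diff(ev$time_s) * 1000,  # ms
         stop("unknown variable: ", variable, call. = FALSE))
}

#' 400-event / 20-bin cumulative distribution procedure
#'
#' Per cell, the first \code{n_events} values of the chosen variable (in
#' recording order, for determinism) are sorted and partitioned into
#' \code{n_bins} rank (quantile) bins of equal count; each bin is summarized
#' by its mean.  Bin means are then averaged across cells for the cumulative
#' probability plot; per-cell overall means are also returned for the inset
#' bar summaries.  For inter-event intervals a cell must supply
#' \code{n_events} intervals, i.e. \code{n_events + 1} events.  Cells with
#' too few values are excluded and logged, not an error.
#'
#' @param cells list of \code{event_series}.
#' @param variable \code{"amplitude"} (pA) or \code{"iei"} (ms).
#' @param n_events values used per cell (default 400).
#' @param n_bins number of rank bins (default 20; must divide
#'   \code{n_events}).
#' @param equal_width use equal-width bins over the per-cell range instead
#'   of rank bins (alternative binning; conservation then no longer holds
#'   exactly).
#' @return a \code{binned_cumulative}: list with \code{$bin_values} (length
#'   \code{n_bins}, cross-cell averages, non-decreasing), \code{$per_cell_bins}
#'   (matrix cells x bins), \code{$per_cell_means}, \code{$n_cells},
#'   \code{$excluded} (data.frame of excluded cells with reasons).
#' @export
bin_cumulative <- function(cells, variable = c("amplitude", "iei"),
                           n_events = 400L, n_bins = 20L,
                           equal_width = FALSE) {
  variable <- match.arg(variable)
  if (n_events %% n_bins != 0) {
    stop("`n_bins` must divide `n_events`", call. = FALSE)
  }
  per_bin <- n_events %/% n_bins
  rows <- list(); means <- numeric(0); ids <- character(0)
  exc_id <- exc_why <- character(0)
  for (es in cells) {
    vals <- event_values(es, variable)
    if (length(vals) < n_events) {
      exc_id <- c(exc_id, es$cell_id)
      exc_why <- c(exc_why, sprintf("only %d %s values (< %d)",
                                    length(vals), variable, n_events))
      next
    }
    v <- sort(vals[seq_len(n_events)])
    if (equal_width) {
      br <- seq(min(v), max(v), length.out = n_bins + 1L)
      idx <- pmin(findInterval(v, br, rightmost.closed = TRUE), n_bins)
      bm <- tapply(v, factor(idx, levels = seq_len(n_bins)), mean)
      bm <- as.numeric(bm)
    } else {
      bm <- colMeans(matrix(v, nrow = per_bin))
    }
    rows[[length(rows) + 1L]] <- bm
    means <- c(means, mean(v))
    ids <- c(ids, es$cell_id)
  }
  if (!length(rows)) stop("no cell has enough events", call. = FALSE)
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  structure(
    list(bin_values = colMeans(m), per_cell_bins = m,
         per_cell_means = stats::setNames(means, ids),
         n_cells = length(ids), variable = variable,
         excluded = data.frame(cell_id = exc_id, reason = exc_why,
                               stringsAsFactors = FALSE)),
    class = "binned_cumulative"
  )
}

#' Simulate a paired-pulse trace
#'
#' Two double-exponential EPSCs separated by the interstimulus interval,
#' with Gaussian noise; used to exercise the paired-pulse ratio analysis.
#'
#' @param amp1_pA,amp2_pA true response amplitudes.
#' @param interval_ms interstimulus interval (e.g. 50, 100, 200 ms).
#' @param spec a \code{\link{trace_spec}}; the trace extends
#'   \code{interval_ms + trace_ms} past the first stimulus.
#' @param noise_sd baseline noise SD, pA.
#' @return numeric trace (pA) sampled at \code{spec$sample_rate_hz}, first
#'   stimulus at \code{spec$baseline_ms}.
#' @export
simulate_ppr_trace <- function(amp1_pA, amp2_pA, interval_ms,
                               spec = trace_spec(), noise_sd = 0) {
  fs <- spec$sample_rate_hz
  n <- round((spec$baseline_ms + interval_ms + spec$trace_ms) / 1000 * fs)
  tt <- seq_len(n) / fs
  resp <- function(amp, t0_ms) {
    t0 <- t0_ms / 1000
    ifelse(tt > t0,
           amp * epsc_kernel(pmax(tt - t0, 0), spec$tau_rise_ampa_ms,
                             spec$tau_decay_ampa_ms), 0)
  }
  resp(amp1_pA, spec$baseline_ms) +
    resp(amp2_pA, spec$baseline_ms + interval_ms) +
    stats::rnorm(n, 0, noise_sd)
}

#' Paired-pulse ratio with tail subtraction
#'
#' Measures the amplitudes of two closely spaced evoked responses.  The tail
#' of response 1 under response 2 is removed by fitting a double-exponential
#' decay to the post-peak segment of response 1 and extrapolating it across
#' the second response window; the single-trace fit avoids needing a paired
#' blank sweep.  The ratio amp2/amp1 indexes release probability.
#'
#' @param trace numeric paired-pulse trace, stimulus 1 at
#'   \code{spec$baseline_ms}.
#' @param interval_ms interstimulus interval, ms.
#' @param spec the \code{\link{trace_spec}} used to render/acquire the
#'   trace.
#' @param noise_floor_pA minimum credible first-response amplitude.
#' @return a \code{ppr_measure}: list with \code{interval_ms},
#'   \code{amp1_pA}, \code{amp2_pA}, \code{ratio}.
#' @export
ppr <- function(trace, interval_ms, spec = trace_spec(),
                noise_floor_pA = 1) {
  fs <- spec$sample_rate_hz
  i_stim1 <- floor(spec$baseline_ms / 1000 * fs) + 1L
  i_stim2 <- floor((spec$baseline_ms + interval_ms) / 1000 * fs) + 1L
  if (i_stim2 >= length(trace)) stop("trace ends before second stimulus",
                                     call. = FALSE)
  base <- mean(trace[seq_len(i_stim1 - 1L)])
  seg1 <- trace[i_stim1:(i_stim2 - 1L)]
  i_pk1 <- which.max(seg1)
  amp1 <- seg1[i_pk1] - base
  if (amp1 <= noise_floor_pA) {
    stop("first response amplitude at or below the noise floor",
         call. = FALSE)
  }
  # fit the decay of response 1 from its peak to just before stimulus 2
  tail_idx <- (i_stim1 + i_pk1 - 1L):(i_stim2 - 1L)
  t_tail <- (tail_idx - (i_stim1 + i_pk1 - 1L)) / fs * 1000  # ms from peak
  y_tail <- trace[tail_idx] - base
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a1 * exp(-t / td1) + a2 * exp(-t / td2),
      data = list(y = y_tail, t = t_tail),
      start = list(a1 = amp1 * 0.8, td1 = spec$tau_decay_ampa_ms,
                   a2 = amp1 * 0.2, td2 = spec$tau_decay_ampa_ms * 4),
      lower = c(0, 1e-3, 0, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  win2 <- i_stim2:min(length(trace),
                      i_stim2 + as.integer(interval_ms / 1000 * fs))
  t2 <- (win2 - (i_stim1 + i_pk1 - 1L)) / fs * 1000
  tail2 <- if (!is.null(fit)) {
    cf <- stats::coef(fit)
    cf["a1"] * exp(-t2 / cf["td1"]) + cf["a2"] * exp(-t2 / cf["td2"])
  } else {
    # fall back to single-exponential extrapolation from the log-linear fit
    pos <- y_tail > 0
    lf <- stats::lm(log(y_tail[pos]) ~ t_tail[pos])
    exp(stats::coef(lf)[1] + stats::coef(lf)[2] * t2)
  }
  amp2 <- max(trace[win2] - base - tail2)
  structure(list(interval_ms = interval_ms, amp1_pA = amp1,
                 amp2_pA = amp2, ratio = amp2 / amp1),
            class = "ppr_measure")
}

#' MK-801 decay analysis
#'
#' Normalizes the per-sweep NMDA-receptor EPSC peak series and fits a single
#' exponential in sweep number, \eqn{y_k = e^{-b(k-1)}}.  The fitted
#' per-sweep survival \eqn{e^{-b}} is a proxy for \eqn{1 - p}: under certain
#' open-channel block, the expected normalized peak at sweep \eqn{k} is
#' \eqn{(1-p)^{k-1}}.  A list of per-cell series is averaged sweep-wise
#' before normalization (single noisy sweeps are poor normalizers).
#'
#' @param peaks numeric vector of per-sweep peaks for one cell, or a list of
#'   such vectors (a cohort; equal lengths required).
#' @return list with \code{$normalized} (curve, sweep 1 = 1),
#'   \code{$block_per_sweep} (fitted \eqn{1 - e^{-b}}), \code{$survival}
#'   (\eqn{e^{-b}}), \code{$release_prob_proxy} (\eqn{1 - e^{-b}}),
#'   \code{$n_sweeps}, \code{$flat} (\code{TRUE} for a degenerate
#'   no-decrement series, in which case survival is reported as 1).
#' @export
mk801_decay <- function(peaks) {
  if (is.list(peaks) && !is.data.frame(peaks)) {
    lens <- vapply(peaks, length, integer(1))
    if (length(unique(lens)) != 1L) {
      stop("all cells must have the same number of sweeps", call. = FALSE)
    }
    curve <- colMeans(do.call(rbind, peaks))
  } else if (is.data.frame(peaks)) {
    curve <- peaks$peak_pA
  } else {
    curve <- as.numeric(peaks)
  }
  n <- length(curve)
  if (n < 10L) stop("at least 10 sweeps required", call. = FALSE)
  if (curve[1] <= 0) stop("first peak must be positive", call. = FALSE)
  y <- curve / curve[1]
  k <- seq_len(n) - 1
  flat <- stats::sd(y) < 1e-12
  if (flat) {
    return(list(normalized = y, block_per_sweep = 0, survival = 1,
                release_prob_proxy = 0, n_sweeps = n, flat = TRUE))
  }
  # variance-weighted exponential fit: sweep-mean variance scales with its
  # mean (quantal counting noise), so iterate weights from the fitted curve
  fit <- minpack.lm::nlsLM(y ~ a * exp(-b * k), data = list(y = y, k = k),
                           start = list(a = 1, b = 0.2), lower = c(0, 0))
  for (it in 1:3) {
    w <- 1 / pmax(stats::fitted(fit), 0.01)
    fit <- minpack.lm::nlsLM(y ~ a * exp(-b * k), data = list(y = y, k = k),
                             start = as.list(stats::coef(fit)),
                             lower = c(0, 0), weights = w)
  }
  b <- unname(stats::coef(fit)["b"])
  list(normalized = y, block_per_sweep = 1 - exp(-b), survival = exp(-b),
       release_prob_proxy = 1 - exp(-b), n_sweeps = n, flat = FALSE)
}

#' Quantal analysis of strontium-desynchronized release
#'
#' Restricts asynchronous events to the post-stimulus window and summarizes
#' the quantal amplitude distribution — the Sr2+ analogue of the mEPSC
#' analysis, specific to the stimulated pathway.  Inter-event intervals are
#' computed between consecutive events within a stimulus.
#'
#' @param events data.frame from \code{\link{simulate_sr_release}}
#'   (\code{stimulus}, \code{latency_ms}, \code{amplitude_pA}).
#' @param window_ms analysis window after each stimulus, ms.
#' @return list with \code{$mean_amplitude_pA}, \code{$amplitudes_pA},
#'   \code{$iei_ms} (within-stimulus), \code{$mean_iei_ms}, \code{$n_events}.
#' @export
sr_quantal_analysis <- function(events, window_ms = 500) {
  if (window_ms <= 0) stop("`window_ms` must be > 0", call. = FALSE)
  ev <- events[events$latency_ms <= window_ms, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no events in the analysis window", call. = FALSE)
  ieis <- unlist(lapply(split(ev$latency_ms, ev$stimulus), function(l) {
    if (length(l) > 1) diff(sort(l)) else numeric(0)
  }), use.names = FALSE)
  list(mean_amplitude_pA = mean(ev$amplitude_pA),
       amplitudes_pA = ev$amplitude_pA,
       iei_ms = ieis,
       mean_iei_ms = if (length(ieis)) mean(ieis) else NA_real_,
       n_events = nrow(ev))
}
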