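#' Generative model of one afferent connection
#'
#' Parameters of a single glutamatergic axon contacting one pyramidal neuron.
#' In cortex one axon forms on average about five synapses with a target
#' cell; a fraction of these may be AMPA-silent: they carry NMDA-receptor
#' responses (visible at +40 mV) but no AMPA-receptor response (invisible at
#' -60 mV).  The realized number of silent synapses is
#' \code{round(n_synapses * silent_fraction)}; the realizable silent fraction
#' (\code{n_silent / n_synapses}) is stored as ground truth so estimator
#' recovery is judged against an attainable target.
#'
#' @param n_synapses positive integer, synapses per afferent.
#' @param silent_fraction fraction of synapses lacking AMPA responses, in
#'   \code{[0, 1]}.
#' @param release_prob per-synapse, per-stimulus vesicle release probability,
#'   in \code{[0, 1]} (0 and 1 are degenerate but useful limiting cases).
#' @param quantal_mean_ampa mean quantal AMPA amplitude, pA (magnitude).
#' @param quantal_cv coefficient of variation of quantal amplitudes (>= 0).
#'   Quantal amplitudes are gamma-distributed (positive support),
#'   parameterized by mean and CV.
#' @param quantal_mean_nmda mean quantal NMDA amplitude, pA.  Silent and
#'   AMPA-active synapses are assumed equally detectable at +40 mV.
#' @param noise_sd baseline recording noise SD, pA.
#' @return an object of class \code{synapse_model}.
#' @export
synapse_model <- function(n_synapses = 5L, silent_fraction = 0,
                          release_prob = 0.3, quantal_mean_ampa = 12,
                          quantal_cv = 0.3, quantal_mean_nmda = 10,
                          noise_sd = 1) {
  if (!is.numeric(n_synapses) || length(n_synapses) != 1L ||
      n_synapses < 1 || n_synapses != round(n_synapses)) {
    stop("`n_synapses` must be a positive integer", call. = FALSE)
  }
  if (silent_fraction < 0 || silent_fraction > 1) {
    stop("`silent_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (release_prob < 0 || release_prob > 1) {
    stop("`release_prob` must lie in [0, 1]", call. = FALSE)
  }
  if (quantal_cv < 0) stop("`quantal_cv` must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  n_silent <- as.integer(round(n_synapses * silent_fraction))
  structure(
    list(
      n_synapses = as.integer(n_synapses),
      n_silent = n_silent,
      n_active = as.integer(n_synapses) - n_silent,
      silent_fraction = silent_fraction,
      realized_silent_fraction = n_silent / n_synapses,
      release_prob = release_prob,
      quantal_mean_ampa = quantal_mean_ampa,
      quantal_cv = quantal_cv,
      quantal_mean_nmda = quantal_mean_nmda,
      noise_sd = noise_sd
    ),
    class = "synapse_model"
  )
}

#' @export
print.synapse_model <- function(x, ...) {
  cat("<synapse_model>", x$n_synapses, "synapses (", x$n_silent,
      "silent ), p =", x$release_prob,
      ", q_AMPA =", x$quantal_mean_ampa, "pA\n")
  invisible(x)
}

#' Trace synthesis and analysis-window specification
#'
#' Sampling and kinetic parameters used to render synthetic EPSC traces and
#' to place the response windows for success/failure classification.  The
#' AMPA window (default 1--20 ms post-stimulus) captures the fast component
#' at -60 mV; the composite window at +40 mV (default 5--60 ms) extends over
#' the slow NMDA-receptor component.
#'
#' @param sample_rate_hz sampling rate, Hz.
#' @param baseline_ms pre-stimulus baseline duration, ms.
#' @param window_ampa_ms numeric length-2, response window at -60 mV
#'   (ms after stimulus).
#' @param window_nmda_ms numeric length-2, response window at +40 mV.
#' @param tau_rise_ampa_ms,tau_decay_ampa_ms AMPA double-exponential
#'   kinetics, ms.
#' @param tau_rise_nmda_ms,tau_decay_nmda_ms NMDA kinetics, ms.
#' @param trace_ms total rendered trace duration, ms.
#' @return an object of class \code{trace_spec}.
#' @export
trace_spec <- function(sample_rate_hz = 10000, baseline_ms = 10,
                       window_ampa_ms = c(1, 20), window_nmda_ms = c(5, 60),
                       tau_rise_ampa_ms = 0.5, tau_decay_ampa_ms = 5,
                       tau_rise_nmda_ms = 5, tau_decay_nmda_ms = 50,
                       trace_ms = 100) {
  stopifnot(sample_rate_hz > 0, baseline_ms >= 0,
            length(window_ampa_ms) == 2L, length(window_nmda_ms) == 2L)
  if (tau_rise_ampa_ms >= tau_decay_ampa_ms ||
      tau_rise_nmda_ms >= tau_decay_nmda_ms) {
    stop("rise time constant must be smaller than decay time constant",
         call. = FALSE)
  }
  if (baseline_ms + max(window_ampa_ms, window_nmda_ms) > trace_ms) {
    stop("response window falls outside the trace", call. = FALSE)
  }
  structure(
    list(sample_rate_hz = sample_rate_hz, baseline_ms = baseline_ms,
         window_ampa_ms = window_ampa_ms, window_nmda_ms = window_nmda_ms,
         tau_rise_ampa_ms = tau_rise_ampa_ms,
         tau_decay_ampa_ms = tau_decay_ampa_ms,
         tau_rise_nmda_ms = tau_rise_nmda_ms,
         tau_decay_nmda_ms = tau_decay_nmda_ms,
         trace_ms = trace_ms),
    class = "trace_spec"
  )
}

# gamma draws parameterized by mean and CV; cv = 0 degenerates to the mean
rquantal <- function(n, mean, cv) {
  if (n == 0L) return(numeric(0))
  if (cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

# unit-peak double-exponential synaptic kernel sampled at `times` (s >= 0)
epsc_kernel <- function(times_s, tau_rise_ms, tau_decay_ms) {
  tr <- tau_rise_ms / 1000
  td <- tau_decay_ms / 1000
  g <- exp(-times_s / td) - exp(-times_s / tr)
  t_peak <- tr * td / (td - tr) * log(td / tr)
  g / (exp(-t_peak / td) - exp(-t_peak / tr))
}

#' Simulate a minimal-stimulation experiment
#'
#' Draws per-trial evoked responses at the two holding potentials of the
#' minimal-stimulation protocol.  At -60 mV every AMPA-active synapse
#' releases independently with probability \code{release_prob} and
#' contributes a gamma-distributed quantal AMPA amplitude; at +40 mV all
#' synapses (silent and active) contribute NMDA-mediated amplitudes in the
#' same way.  The trial peak is the summed quantal amplitude plus Gaussian
#' baseline noise; a trial is a ground-truth failure iff zero synapses
#' released.  With \code{render_traces = TRUE} full traces are synthesized
#' from the double-exponential kinetics in \code{spec}.
#'
#' @param model a \code{\link{synapse_model}}.
#' @param n_trials_per_vh trials recorded at each holding potential (>= 1).
#' @param spec a \code{\link{trace_spec}} (used when rendering traces).
#' @param cell_id identifier attached to the dataset.
#' @param render_traces render full traces (needed for trace-based
#'   classification, AMPA/NMDA ratio and NMDA potency); peak-only mode is
#'   much lighter and sufficient for failure-rate work.
#' @param series_resistance_mohm,resistance_drift_fraction recording QC
#'   metadata attached to the cell.
#' @return a \code{minstim_dataset}: list with \code{$trials} (one row per
#'   trial: \code{holding_potential_mV}, \code{peak_pA},
#'   \code{baseline_rms_pA}, \code{truth_failure}, \code{n_released}),
#'   \code{$qc}, \code{$model}, \code{$spec} and optionally \code{$traces}
#'   (list of two matrices, trials x samples).
#' @export
simulate_minstim <- function(model, n_trials_per_vh, spec = trace_spec(),
                             cell_id = "cell1", render_traces = FALSE,
                             series_resistance_mohm = 15,
                             resistance_drift_fraction = 0.05) {
  stopifnot(inherits(model, "synapse_model"), n_trials_per_vh >= 1)
  n_tr <- as.integer(n_trials_per_vh)

  draw_vh <- function(n_syn, q_mean) {
    released <- stats::rbinom(n_tr, n_syn, model$release_prob)
    amp <- vapply(released, function(k) sum(rquantal(k, q_mean, model$quantal_cv)),
                  numeric(1))
    list(released = released, amp = amp)
  }
  ampa <- draw_vh(model$n_active, model$quantal_mean_ampa)
  nmda <- draw_vh(model$n_synapses, model$quantal_mean_nmda)

  trials <- data.frame(
    holding_potential_mV = rep(c(-60, 40), each = n_tr),
    amplitude_true_pA = c(ampa$amp, nmda$amp),
    n_released = c(ampa$released, nmda$released),
    truth_failure = c(ampa$released, nmda$released) == 0L
  )
  trials$peak_pA <- trials$amplitude_true_pA +
    stats::rnorm(nrow(trials), 0, model$noise_sd)
  trials$baseline_rms_pA <- rep(max(model$noise_sd, .Machine$double.eps),
                                nrow(trials))

  ds <- structure(
    list(cell_id = cell_id, trials = trials,
         qc = list(series_resistance_mohm = series_resistance_mohm,
                   input_resistance_drift_fraction = resistance_drift_fraction),
         model = model, spec = spec),
    class = "minstim_dataset"
  )

  if (render_traces) {
    n_samp <- round(spec$trace_ms / 1000 * spec$sample_rate_hz)
    tt <- seq_len(n_samp) / spec$sample_rate_hz
    t0 <- spec$baseline_ms / 1000
    post <- pmax(tt - t0, 0)
    k_ampa <- ifelse(tt > t0,
                     epsc_kernel(post, spec$tau_rise_ampa_ms,
                                 spec$tau_decay_ampa_ms), 0)
    k_nmda <- ifelse(tt > t0,
                     epsc_kernel(post, spec$tau_rise_nmda_ms,
                                 spec$tau_decay_nmda_ms), 0)
    mk <- function(amp, kernel) {
      noise <- matrix(stats::rnorm(n_tr * n_samp, 0, model$noise_sd),
                      nrow = n_tr)
      outer(amp, rep(1, n_samp)) * matrix(kernel, n_tr, n_samp, byrow = TRUE) +
        noise
    }
    ds$traces <- list(minus60 = mk(ampa$amp, k_ampa),
                      plus40 = mk(nmda$amp, k_nmda))
  }
  ds
}

#' Simulate a use-dependent NMDA-receptor block (MK-801) experiment
#'
#' In the MK-801 assay, NMDA-receptor EPSCs are evoked repeatedly at +40 mV
#' in the presence of the open-channel blocker: each synapse that releases
#' on a given stimulus contributes its NMDA quantum and is then permanently
#' blocked.  With certain blocking, the expected normalized peak at sweep
#' \eqn{k} is \eqn{(1-p)^{k-1}}, so the decay rate indexes the presynaptic
#' release probability \eqn{p}.
#'
#' @param model a \code{\link{synapse_model}} (all synapses, silent and
#'   active, carry NMDA responses).
#' @param n_stimuli number of sweeps (>= 1).
#' @return data.frame with \code{sweep}, \code{peak_pA} (noisy),
#'   \code{n_released}, \code{n_unblocked} (before the sweep).
#' @export
simulate_mk801 <- function(model, n_stimuli = 50L) {
  stopifnot(inherits(model, "synapse_model"), n_stimuli >= 1)
  n_stimuli <- as.integer(n_stimuli)
  unblocked <- rep(TRUE, model$n_synapses)
  peak <- n_rel <- n_unb <- numeric(n_stimuli)
  for (k in seq_len(n_stimuli)) {
    n_unb[k] <- sum(unblocked)
    release <- unblocked & (stats::runif(model$n_synapses) < model$release_prob)
    n_rel[k] <- sum(release)
    peak[k] <- sum(rquantal(sum(release), model$quantal_mean_nmda,
                            model$quantal_cv)) +
      stats::rnorm(1, 0, model$noise_sd)
    unblocked <- unblocked & !release
  }
  data.frame(sweep = seq_len(n_stimuli), peak_pA = peak,
             n_released = n_rel, n_unblocked = n_unb)
}

#' Simulate strontium-desynchronized evoked release
#'
#' Substituting Sr2+ for Ca2+ desynchronizes vesicle release: each releasing
#' synapse emits its quantum at a random latency within the post-stimulus
#' window, so individual quantal amplitudes are resolvable as discrete
#' asynchronous events.
#'
#' @param model a \code{\link{synapse_model}} (AMPA-active synapses release).
#' @param window_ms post-stimulus asynchronous window, ms (> 0).
#' @param n_stimuli number of stimuli.
#' @return data.frame of events: \code{stimulus}, \code{latency_ms} (uniform
#'   in the window), \code{amplitude_pA}.
#' @export
simulate_sr_release <- function(model, window_ms = 500, n_stimuli = 100L) {
  stopifnot(inherits(model, "synapse_model"))
  if (window_ms <= 0) stop("`window_ms` must be > 0", call. = FALSE)
  n_stimuli <- as.integer(n_stimuli)
  released <- stats::rbinom(n_stimuli, model$n_active, model$release_prob)
  n_ev <- sum(released)
  if (n_ev == 0L) {
    return(data.frame(stimulus = integer(0), latency_ms = numeric(0),
                      amplitude_pA = numeric(0)))
  }
  ev <- data.frame(
    stimulus = rep(seq_len(n_stimuli), released),
    latency_ms = stats::runif(n_ev, 0, window_ms),
    amplitude_pA = rquantal(n_ev, model$quantal_mean_ampa, model$quantal_cv)
  )
  ev[order(ev$stimulus, ev$latency_ms), , drop = FALSE]
}

#' Simulate a continuous mEPSC recording
#'
#' Miniature EPSCs recorded in TTX arise as a Poisson process; amplitudes
#' are i.i.d. gamma draws rendered as double-exponential transients on a
#' Gaussian noise baseline.
#'
#' @param rate_hz event rate, Hz (> 0).
#' @param amp_mean_pA,amp_cv quantal amplitude distribution (mean, CV).
#' @param duration_s recording duration, s (> 0).
#' @param noise_sd baseline noise SD, pA.
#' @param sample_rate_hz sampling rate for the rendered signal.
#' @param tau_rise_ms,tau_decay_ms transient kinetics.
#' @return list with \code{$signal} (numeric vector, pA, positive-going
#'   events), \code{$sample_rate_hz}, \code{$duration_s} and
#'   \code{$events} (ground truth: \code{time_s}, \code{amplitude_pA}).
#' @export
simulate_mepsc <- function(rate_hz, amp_mean_pA = 12, amp_cv = 0.3,
                           duration_s = 120, noise_sd = 1,
                           sample_rate_hz = 5000,
                           tau_rise_ms = 0.5, tau_decay_ms = 5) {
  if (rate_hz <= 0) stop("`rate_hz` must be > 0", call. = FALSE)
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  n_ev <- stats::rpois(1, rate_hz * duration_s)
  times <- sort(stats::runif(n_ev, 0, duration_s))
  amps <- rquantal(n_ev, amp_mean_pA, amp_cv)

  n_samp <- round(duration_s * sample_rate_hz)
  signal <- stats::rnorm(n_samp, 0, noise_sd)
  # render each transient over 8 decay time constants
  k_len <- round(8 * tau_decay_ms / 1000 * sample_rate_hz)
  k_t <- seq(0, k_len - 1) / sample_rate_hz
  kernel <- epsc_kernel(k_t, tau_rise_ms, tau_decay_ms)
  for (i in seq_len(n_ev)) {
    i0 <- floor(times[i] * sample_rate_hz) + 1L
    idx <- i0:min(i0 + k_len - 1L, n_samp)
    signal[idx] <- signal[idx] + amps[i] * kernel[seq_along(idx)]
  }
  list(signal = signal, sample_rate_hz = sample_rate_hz,
       duration_s = duration_s,
       events = data.frame(time_s = times, amplitude_pA = amps))
}
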