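#' Ground truth for a periodic-stimulus intrinsic-signal experiment
#'
#' Per-pixel response amplitude for each eye (fractional reflectance change,
#' conventionally reported in units of 1e-4), a retinotopic phase field
#' (stimulus position encoded as response phase, radians in [0, 2pi)), and
#' acquisition metadata for a continuously presented temporally periodic
#' stimulus.
#'
#' @param amplitude_contra,amplitude_ipsi H x W non-negative matrices.
#' @param phase H x W matrix of response phases, radians.
#' @param stim_freq stimulus frequency, Hz.
#' @param frame_rate acquisition frame rate, Hz.
#' @param n_frames frames to synthesize; must span at least 5 stimulus
#'   cycles.
#' @param noise_sd per-pixel, per-frame Gaussian noise SD.
#' @param pink_amplitude amplitude of an optional 1/f temporal noise
#'   component (0 disables it; slow hemodynamic-like drift).
#' @return an object of class \code{imaging_ground_truth}.
#' @export
imaging_ground_truth <- function(amplitude_contra, amplitude_ipsi, phase,
                                 stim_freq = 0.125, frame_rate = 7.5,
                                 n_frames = 600, noise_sd = 0,
                                 pink_amplitude = 0) {
  stopifnot(is.matrix(amplitude_contra), is.matrix(amplitude_ipsi),
            is.matrix(phase))
  if (!all(dim(amplitude_contra) == dim(amplitude_ipsi)) ||
      !all(dim(amplitude_contra) == dim(phase))) {
    stop("amplitude and phase fields must share one shape", call. = FALSE)
  }
  if (any(amplitude_contra < 0) || any(amplitude_ipsi < 0)) {
    stop("amplitude fields must be non-negative", call. = FALSE)
  }
  cycles <- n_frames / frame_rate * stim_freq
  if (cycles < 5) {
    stop("n_frames must span at least 5 stimulus cycles (needs >= ",
         ceiling(5 * frame_rate / stim_freq), " frames)", call. = FALSE)
  }
  structure(list(amplitude_contra = amplitude_contra,
                 amplitude_ipsi = amplitude_ipsi,
                 phase = phase %% (2 * pi),
                 stim_freq = stim_freq, frame_rate = frame_rate,
                 n_frames = as.integer(n_frames), noise_sd = noise_sd,
                 pink_amplitude = pink_amplitude),
            class = "imaging_ground_truth")
}

# 1/f temporal noise, one column per pixel (T x P)
pink_noise_matrix <- function(n_t, n_p, amplitude) {
  w <- matrix(stats::rnorm(n_t * n_p), n_t, n_p)
  f <- stats::mvfft(w)
  freq <- c(1, seq_len(n_t - 1))  # avoid dividing DC by 0
  filt <- 1 / sqrt(pmin(freq, n_t - freq + 1))
  y <- Re(stats::mvfft(f * filt, inverse = TRUE)) / n_t
  amplitude * y / stats::sd(as.numeric(y))
}

#' Simulate a periodic-stimulus reflectance movie
#'
#' Each pixel's time series is
#' \eqn{A \cos(2\pi f_{stim} t - \phi) + \epsilon}, with \eqn{A} the eye's
#' amplitude field and \eqn{\phi} the retinotopic phase field, plus Gaussian
#' (and optionally 1/f) noise.
#'
#' @param gt an \code{\link{imaging_ground_truth}}.
#' @param eye \code{"contra"} or \code{"ipsi"} (selects the amplitude
#'   field).
#' @param run_id identifier carried in the movie metadata.
#' @return a \code{response_movie}: list with \code{$frames} (T x H x W
#'   array), \code{$frame_rate}, \code{$stim_freq}, \code{$eye},
#'   \code{$run_id}.
#' @export
simulate_movie <- function(gt, eye = c("contra", "ipsi"), run_id = "run1") {
  stopifnot(inherits(gt, "imaging_ground_truth"))
  eye <- match.arg(eye)
  amp <- if (eye == "contra") gt$amplitude_contra else gt$amplitude_ipsi
  h <- nrow(amp); w <- ncol(amp); n_t <- gt$n_frames
  tt <- (seq_len(n_t) - 1) / gt$frame_rate
  arg <- outer(2 * pi * gt$stim_freq * tt, as.numeric(gt$phase), `-`)
  x <- cos(arg) * rep(as.numeric(amp), each = n_t)  # T x (H*W)
  if (gt$noise_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, gt$noise_sd)
  }
  if (gt$pink_amplitude > 0) {
    x <- x + pink_noise_matrix(n_t, h * w, gt$pink_amplitude)
  }
  structure(list(frames = array(x, dim = c(n_t, h, w)),
                 frame_rate = gt$frame_rate, stim_freq = gt$stim_freq,
                 eye = eye, run_id = run_id),
            class = "response_movie")
}

#' Temporal binning of a frame stack
#'
#' Non-overlapping means of \code{factor} consecutive frames (the standard
#' 30 Hz to 7.5 Hz reduction uses \code{factor = 4}).  A trailing remainder
#' that does not fill a bin is dropped with a message.
#'
#' @param movie a \code{response_movie}.
#' @param factor frames per bin.
#' @return the binned \code{response_movie} (frame rate divided by
#'   \code{factor}).
#' @export
temporal_bin <- function(movie, factor = 4L) {
  stopifnot(inherits(movie, "response_movie"))
  n_t <- dim(movie$frames)[1]
  if (n_t < factor) stop("fewer frames than the binning factor", call. = FALSE)
  n_out <- n_t %/% factor
  drop <- n_t - n_out * factor
  if (drop > 0) {
    message("temporal_bin: dropping ", drop, " trailing frame(s)")
  }
  d <- dim(movie$frames)
  x <- matrix(movie$frames[seq_len(n_out * factor), , ], nrow = n_out * factor)
  grp <- rep(seq_len(n_out), each = factor)
  binned <- rowsum(x, grp) / factor
  movie$frames <- array(binned, dim = c(n_out, d[2], d[3]))
  movie$frame_rate <- movie$frame_rate / factor
  movie
}

#' Extract amplitude and phase maps at the stimulus frequency
#'
#' Per pixel, the time series is regressed jointly on an intercept, a
#' linear trend and the cosine/sine pair at the stimulus frequency; the
#' response amplitude is the modulus of the quadrature coefficients
#' (equal to 2/T times the Fourier projection over whole cycles) and the
#' retinotopic phase their argument, wrapped to [0, 2pi).  The trend term
#' absorbs slow drift that would otherwise leak into the stimulus band.
#'
#' @param movie a \code{response_movie}.
#' @param detrend subtract a per-pixel linear trend first (default TRUE).
#' @return a \code{retino_maps}: list with \code{$amplitude} (H x W,
#'   >= 0), \code{$phase} (H x W in [0, 2pi)), \code{$stim_freq},
#'   \code{$eye}.
#' @export
fourier_extract <- function(movie, detrend = TRUE) {
  stopifnot(inherits(movie, "response_movie"))
  f <- movie$stim_freq; fr <- movie$frame_rate
  if (f >= fr / 2) stop("stimulus frequency must be below Nyquist",
                        call. = FALSE)
  d <- dim(movie$frames)
  n_t <- d[1]
  if (n_t < fr / f) {
    stop("stimulus frequency unresolvable: need at least ",
         ceiling(fr / f), " frames (one full cycle)", call. = FALSE)
  }
  x <- matrix(movie$frames, nrow = n_t)  # T x P
  tt <- (seq_len(n_t) - 1) / fr
  cb <- cos(2 * pi * f * tt); sb <- sin(2 * pi * f * tt)
  # joint least squares on {1, t, cos, sin} so the trend cannot leak into
  # the quadrature pair (and vice versa); reduces to the plain projection
  # over integer cycles
  dm <- if (detrend) cbind(1, tt, cb, sb) else cbind(1, cb, sb)
  beta <- solve(crossprod(dm), crossprod(dm, x))
  a <- beta[nrow(beta) - 1L, ]
  b <- beta[nrow(beta), ]
  structure(list(amplitude = matrix(sqrt(a^2 + b^2), d[2], d[3]),
                 phase = matrix(atan2(b, a) %% (2 * pi), d[2], d[3]),
                 stim_freq = f, eye = movie$eye),
            class = "retino_maps")
}

#' Ocular-dominance analysis of contra/ipsi amplitude maps
#'
#' For each responsive pixel the OD score is \eqn{(C - I)/(C + I)}, with C
#' and I the raw response magnitudes to contralateral and ipsilateral eye
#' stimulation; the ocular dominance index (ODI) is the mean OD score over
#' responsive pixels.  ODI ranges from -1 to 1; negative values indicate
#' ipsilateral and positive values contralateral dominance.  The default
#' responsive mask keeps pixels whose contra or ipsi amplitude exceeds 30%
#' of the 99th-percentile contra amplitude (scale-free and robust to hot
#' pixels); pixels with \eqn{C + I = 0} are excluded from the mask.
#'
#' @param contra,ipsi \code{retino_maps} (or plain amplitude matrices) from
#'   the two eyes, co-registered and of equal shape.
#' @param responsive_mask optional logical H x W matrix overriding the
#'   default rule.
#' @param mask_fraction fraction of the 99th-percentile contra amplitude
#'   used by the default rule.
#' @return an \code{od_map}: list with \code{$od_score} (H x W, NA outside
#'   the mask), \code{$odi}, \code{$responsive_mask}.
#' @export
od_analysis <- function(contra, ipsi, responsive_mask = NULL,
                        mask_fraction = 0.30) {
  c_amp <- if (inherits(contra, "retino_maps")) contra$amplitude else contra
  i_amp <- if (inherits(ipsi, "retino_maps")) ipsi$amplitude else ipsi
  if (!all(dim(c_amp) == dim(i_amp))) {
    stop("contra and ipsi maps must be co-registered (same shape)",
         call. = FALSE)
  }
  if (is.null(responsive_mask)) {
    thr <- mask_fraction * stats::quantile(c_amp, 0.99, names = FALSE)
    responsive_mask <- (c_amp > thr) | (i_amp > thr)
  }
  responsive_mask <- responsive_mask & (c_amp + i_amp) > 0
  score <- matrix(NA_real_, nrow(c_amp), ncol(c_amp))
  score[responsive_mask] <- (c_amp[responsive_mask] - i_amp[responsive_mask]) /
    (c_amp[responsive_mask] + i_amp[responsive_mask])
  structure(list(od_score = score,
                 odi = mean(score[responsive_mask]),
                 responsive_mask = responsive_mask),
            class = "od_map")
}

#' Block-average run ODIs into an animal ODI
#'
#' Run-level ODIs are grouped into consecutive blocks of \code{block_size}
#' runs (one ODI per block); a trailing remainder of runs is dropped and
#' logged.  Animals with fewer than \code{min_blocks} block ODIs are
#' discarded; otherwise the animal ODI is the mean of its block ODIs.
#'
#' @param run_odis numeric vector of per-run ODIs, in acquisition order.
#' @param block_size runs per block (default 4).
#' @param min_blocks minimum block ODIs to keep the animal (default 3).
#' @return list with \code{$block_odis}, \code{$odi} (NA when excluded),
#'   \code{$excluded}, \code{$n_dropped_runs}.
#' @export
odi_blocks <- function(run_odis, block_size = 4L, min_blocks = 3L) {
  n <- length(run_odis)
  n_blocks <- n %/% block_size
  dropped <- n - n_blocks * block_size
  if (dropped > 0) {
    message("odi_blocks: dropping ", dropped, " trailing run(s)")
  }
  if (n_blocks == 0L) {
    return(list(block_odis = numeric(0), odi = NA_real_, excluded = TRUE,
                n_dropped_runs = dropped))
  }
  block_odis <- as.numeric(
    rowsum(run_odis[seq_len(n_blocks * block_size)],
           rep(seq_len(n_blocks), each = block_size)) / block_size)
  excluded <- n_blocks < min_blocks
  list(block_odis = block_odis,
       odi = if (excluded) NA_real_ else mean(block_odis),
       excluded = excluded, n_dropped_runs = dropped)
}

# wrapped difference a - b in (-pi, pi]
circ_diff <- function(a, b) atan2(sin(a - b), cos(a - b))

# mean resultant direction
circ_mean <- function(x) atan2(mean(sin(x)), mean(cos(x)))

#' Retinotopic map scatter
#'
#' Local smoothness of the phase (retinotopy) map: for each masked pixel,
#' the absolute circular difference between its phase and the circular mean
#' phase of the surrounding neighborhood (center excluded), averaged over
#' the mask.  Zero for a locally planar map; approaches pi/2 for i.i.d.
#' uniform phases.  The formula is a surrogate for published map-quality
#' scores whose exact definition is not restated here; lower is smoother.
#'
#' @param phase H x W phase matrix (radians) or a \code{retino_maps}.
#' @param mask logical H x W matrix of pixels to score (default: all).
#' @param neighborhood odd side length of the square neighborhood
#'   (default 5).
#' @return mean absolute circular deviation, radians (>= 0).
#' @export
map_scatter <- function(phase, mask = NULL, neighborhood = 5L) {
  if (inherits(phase, "retino_maps")) phase <- phase$phase
  h <- nrow(phase); w <- ncol(phase)
  if (neighborhood %% 2 != 1) stop("`neighborhood` must be odd", call. = FALSE)
  if (neighborhood > min(h, w)) {
    stop("neighborhood larger than the map", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  r <- (neighborhood - 1L) %/% 2L
  devs <- numeric(0)
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    ri <- max(1, i - r):min(h, i + r)
    rj <- max(1, j - r):min(w, j + r)
    nb_mask <- mask[ri, rj, drop = FALSE]
    nb_mask[i - min(ri) + 1L, j - min(rj) + 1L] <- FALSE  # exclude center
    nb <- phase[ri, rj, drop = FALSE][nb_mask]
    if (!length(nb)) next
    devs <- c(devs, abs(circ_diff(phase[i, j], circ_mean(nb))))
  }
  mean(devs)
}
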