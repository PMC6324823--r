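#' Derive a per-stage seed from the master seed
#'
#' Counter-based derivation so stages can be rerun independently yet
#' reproducibly from one master seed.  Results stay within the 32-bit
#' integer range.
#'
#' @param master master seed (integer).
#' @param stage_index stage counter (1, 2, ...).
#' @return integer seed.
#' @export
derive_seed <- function(master, stage_index) {
  as.integer((as.numeric(master) %% 1e6) * 2039 + 104729 * stage_index) %%
    2147483647L
}

#' Write a trial/event table as delimited text
#'
#' Tables are UTF-8, comma-delimited, with a mandatory header; units are
#' encoded in the column names (e.g. \code{amplitude_pA}).
#'
#' @param x data.frame, \code{minstim_dataset} or \code{event_series}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trial_table <- function(x, path) {
  df <- if (inherits(x, "minstim_dataset")) {
    cbind(cell_id = x$cell_id, x$trials,
          series_resistance_mohm = x$qc$series_resistance_mohm,
          input_resistance_drift_fraction = x$qc$input_resistance_drift_fraction)
  } else if (inherits(x, "event_series")) {
    cbind(cell_id = x$cell_id, x$events,
          recording_duration_s = x$recording_duration_s)
  } else {
    x
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a typed trial/event table
#'
#' Reads a comma-delimited table with header and dispatches on its columns:
#' minimal-stimulation trials (\code{holding_potential_mV} + \code{peak_pA}),
#' event series (\code{time_s} + \code{amplitude_pA}), or a behavioral trial
#' log (\code{block_id} + \code{level} + \code{correct}).  Amplitude/level
#' columns are validated numeric, with the offending line named on failure.
#' An empty file (header only) yields an empty dataset of the detected
#' type; a table whose columns match no known type is an error naming the
#' unknown columns.
#'
#' @param path path to the CSV.
#' @return a \code{minstim_dataset}, \code{event_series}, or trial-log
#'   data.frame.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_numeric <- function(col) {
    v <- df[[col]]
    if (is.character(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(suppress) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric value in column `", col, "` at data line ",
             bad[1], call. = FALSE)
      }
      df[[col]] <<- suppress
    }
  }
  nm <- names(df)
  if (all(c("holding_potential_mV", "peak_pA") %in% nm)) {
    for (cc in intersect(c("peak_pA", "baseline_rms_pA"), nm)) check_numeric(cc)
    qc <- list(
      series_resistance_mohm =
        if ("series_resistance_mohm" %in% nm) df$series_resistance_mohm[1] else NA,
      input_resistance_drift_fraction =
        if ("input_resistance_drift_fraction" %in% nm)
          df$input_resistance_drift_fraction[1] else NA)
    trials <- df[, intersect(c("holding_potential_mV", "peak_pA",
                               "baseline_rms_pA", "amplitude_true_pA",
                               "n_released", "truth_failure"), nm),
                 drop = FALSE]
    structure(list(cell_id = if ("cell_id" %in% nm && nrow(df))
                     df$cell_id[1] else "cell1",
                   trials = trials, qc = qc, model = NULL,
                   spec = trace_spec()),
              class = "minstim_dataset")
  } else if (all(c("time_s", "amplitude_pA") %in% nm)) {
    for (cc in c("time_s", "amplitude_pA")) check_numeric(cc)
    event_series(df[, c("time_s", "amplitude_pA")],
                 recording_duration_s =
                   if ("recording_duration_s" %in% nm && nrow(df))
                     df$recording_duration_s[1] else NA_real_,
                 cell_id = if ("cell_id" %in% nm && nrow(df))
                   df$cell_id[1] else "cell1")
  } else if (all(c("block_id", "level", "correct") %in% nm)) {
    check_numeric("level")
    df$correct <- as.logical(df$correct)
    df
  } else {
    stop("unrecognized table type; unknown columns: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
}

# min/max-normalized multi-frame TIFF with a JSON sidecar carrying the
# scale so signed reflectance values round-trip exactly in 32-bit float
write_stack <- function(mats, prefix, meta) {
  lo <- min(vapply(mats, min, numeric(1)))
  hi <- max(vapply(mats, max, numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  norm <- lapply(mats, function(m) (m - lo) / scale)
  tiff::writeTIFF(norm, paste0(prefix, ".tif"), bits.per.sample = 32)
  meta$value_min <- lo
  meta$value_scale <- scale
  meta$n_frames <- length(mats)
  meta$shape <- dim(mats[[1]])
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

read_stack <- function(prefix) {
  sidecar <- paste0(prefix, ".json")
  if (!file.exists(sidecar)) {
    stop("missing JSON sidecar: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  mats <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  if (length(mats) != meta$n_frames ||
      !all(dim(mats[[1]]) == meta$shape)) {
    stop("TIFF shape does not match sidecar metadata", call. = FALSE)
  }
  mats <- lapply(mats, function(m) m * meta$value_scale + meta$value_min)
  list(mats = mats, meta = meta)
}

#' Write a response movie (multi-frame TIFF + JSON sidecar)
#'
#' @param movie a \code{response_movie}.
#' @param prefix output path prefix (writes \code{<prefix>.tif} and
#'   \code{<prefix>.json}).
#' @return the prefix, invisibly.
#' @export
write_movie <- function(movie, prefix) {
  stopifnot(inherits(movie, "response_movie"))
  n_t <- dim(movie$frames)[1]
  mats <- lapply(seq_len(n_t), function(i) movie$frames[i, , ])
  write_stack(mats, prefix,
              list(frame_rate = movie$frame_rate,
                   stim_freq = movie$stim_freq, eye = movie$eye,
                   run_id = movie$run_id))
  invisible(prefix)
}

#' Read a response movie written by \code{\link{write_movie}}
#'
#' @param prefix path prefix.
#' @return a \code{response_movie}.
#' @export
read_movie <- function(prefix) {
  s <- read_stack(prefix)
  if (is.null(s$meta$frame_rate) || is.null(s$meta$stim_freq)) {
    stop("sidecar must carry frame_rate and stim_freq", call. = FALSE)
  }
  frames <- array(0, dim = c(length(s$mats), s$meta$shape[1], s$meta$shape[2]))
  for (i in seq_along(s$mats)) frames[i, , ] <- s$mats[[i]]
  structure(list(frames = frames, frame_rate = s$meta$frame_rate,
                 stim_freq = s$meta$stim_freq,
                 eye = if (is.null(s$meta$eye)) NA else s$meta$eye,
                 run_id = if (is.null(s$meta$run_id)) NA else s$meta$run_id),
            class = "response_movie")
}

#' Write / read a multi-channel puncta image
#'
#' @param channels named list of H x W matrices.
#' @param prefix path prefix.
#' @param pixel_nm pixel size carried in the sidecar.
#' @return the prefix (write) or a list \code{$channels}, \code{$pixel_nm}
#'   (read).
#' @export
write_puncta_image <- function(channels, prefix, pixel_nm = 6) {
  write_stack(channels, prefix,
              list(channel_names = names(channels), pixel_nm = pixel_nm))
  invisible(prefix)
}

#' @rdname write_puncta_image
#' @export
read_puncta_image <- function(prefix) {
  s <- read_stack(prefix)
  ch <- s$mats
  names(ch) <- unlist(s$meta$channel_names)
  list(channels = ch, pixel_nm = s$meta$pixel_nm)
}

#' Default pipeline configuration
#'
#' All stage parameters of the end-to-end synthetic pipeline with their
#' defaults; the master seed is mandatory and every stochastic stage runs
#' under a seed derived from it (see \code{\link{derive_seed}}).
#'
#' @param seed master seed (mandatory).
#' @param out_dir output directory.
#' @return a named list (a run config).
#' @export
default_run_config <- function(seed, out_dir) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    minstim = list(n_cells = 20, n_synapses = 5, silent_fraction = 0.4,
                   release_prob = 0.3, n_trials_per_vh = 100,
                   quantal_mean_ampa = 12, quantal_mean_nmda = 10,
                   quantal_cv = 0.3, noise_sd = 1, k_sd = 3),
    mepsc = list(n_cells = 3, rate_hz = 5, duration_s = 120,
                 amp_mean_pA = 12, amp_cv = 0.3, noise_sd = 1),
    mk801 = list(n_cells = 30, n_sweeps = 50, release_prob = 0.3),
    odi = list(shape = c(32, 32), n_runs = 12, stim_freq = 0.125,
               frame_rate = 7.5, n_frames = 300, amp_contra = 3,
               amp_ipsi = 3 * 0.7 / 1.3, noise_sd = 0.3),
    puncta = list(n_puncta = 12, radius_px = 10, image_shape = c(256, 256),
                  pixel_nm = 6, coloc_fraction = 0.95, min_area_px = 200),
    vwt = list(n_animals = 10, true_threshold = 0.47, slope = 200,
               lapse_rate = 0.02, trials_per_block = 40)
  )
}

#' Read / write a run config (YAML)
#'
#' @param config a run-config list.
#' @param path YAML path.
#' @return the config list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must carry a seed", call. = FALSE)
  cfg
}

#' Run the full synthetic pipeline
#'
#' Generates every raw-data type with the configured ground truth, runs the
#' corresponding analysis stage, and writes one results table per stage plus
#' a provenance manifest (tool version, config, per-file MD5 hashes) under
#' \code{config$out_dir}.  Deterministic given the master seed: two runs
#' with the same config produce byte-identical tables.  The config is
#' validated before anything is written.
#'
#' @param config a run config (list, see \code{\link{default_run_config}},
#'   or a YAML path).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  need <- c("seed", "out_dir", "minstim", "mepsc", "mk801", "odi", "puncta",
            "vwt")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop("config missing stage input(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    paths <<- c(paths, p)
  }

  # minimal stimulation
  cf <- config$minstim
  set.seed(derive_seed(config$seed, 1L))
  cells <- lapply(seq_len(cf$n_cells), function(i) {
    simulate_minstim(
      synapse_model(cf$n_synapses, cf$silent_fraction, cf$release_prob,
                    cf$quantal_mean_ampa, cf$quantal_cv,
                    cf$quantal_mean_nmda, cf$noise_sd),
      cf$n_trials_per_vh, cell_id = sprintf("cell%03d", i))
  })
  res <- analyze_cohort(cells, k_sd = cf$k_sd)
  put(res$cells, "minstim_cells.csv")
  put(res$summary, "minstim_summary.csv")

  # mEPSC cumulative distributions
  cf <- config$mepsc
  set.seed(derive_seed(config$seed, 2L))
  series <- lapply(seq_len(cf$n_cells), function(i) {
    rec <- simulate_mepsc(cf$rate_hz, cf$amp_mean_pA, cf$amp_cv,
                          cf$duration_s, cf$noise_sd)
    es <- detect_events(rec)
    es$cell_id <- sprintf("cell%03d", i)
    es
  })
  bc <- bin_cumulative(series, "amplitude")
  put(data.frame(bin = seq_along(bc$bin_values),
                 mean_amplitude_pA = bc$bin_values), "mepsc_bins.csv")

  # MK-801 decay
  cf <- config$mk801
  set.seed(derive_seed(config$seed, 3L))
  peaks <- lapply(seq_len(cf$n_cells), function(i) {
    simulate_mk801(synapse_model(release_prob = cf$release_prob),
                   cf$n_sweeps)$peak_pA
  })
  dec <- mk801_decay(peaks)
  put(data.frame(sweep = seq_len(dec$n_sweeps), normalized = dec$normalized),
      "mk801_curve.csv")
  put(data.frame(survival = dec$survival,
                 release_prob_proxy = dec$release_prob_proxy),
      "mk801_fit.csv")

  # ocular dominance
  cf <- config$odi
  set.seed(derive_seed(config$seed, 4L))
  shape <- cf$shape
  phase <- matrix(rep(seq(0, 2 * pi, length.out = shape[2]),
                      each = shape[1]), shape[1], shape[2])
  gt <- imaging_ground_truth(
    matrix(cf$amp_contra, shape[1], shape[2]),
    matrix(cf$amp_ipsi, shape[1], shape[2]), phase,
    stim_freq = cf$stim_freq, frame_rate = cf$frame_rate,
    n_frames = cf$n_frames, noise_sd = cf$noise_sd)
  run_odis <- vapply(seq_len(cf$n_runs), function(r) {
    mc <- fourier_extract(simulate_movie(gt, "contra",
                                         run_id = sprintf("run%02d", r)))
    mi <- fourier_extract(simulate_movie(gt, "ipsi",
                                         run_id = sprintf("run%02d", r)))
    od_analysis(mc, mi)$odi
  }, numeric(1))
  blk <- odi_blocks(run_odis)
  put(data.frame(run = seq_along(run_odis), odi = run_odis), "odi_runs.csv")
  put(data.frame(animal_odi = blk$odi, n_blocks = length(blk$block_odis),
                 excluded = blk$excluded), "odi_animal.csv")

  # puncta colocalization and density
  cf <- config$puncta
  set.seed(derive_seed(config$seed, 5L))
  img <- simulate_puncta_image(cf$n_puncta, cf$radius_px, cf$image_shape,
                               cf$pixel_nm, cf$coloc_fraction)
  min_area <- min(cf$min_area_px, floor(pi * cf$radius_px^2 * 0.8))
  pa <- segment_puncta(img$channels$munc13, min_area_px = min_area,
                       pixel_nm = cf$pixel_nm)
  pb <- segment_puncta(img$channels$psd95, min_area_px = min_area,
                       pixel_nm = cf$pixel_nm)
  pairs <- colocalize(pa, pb)
  dens <- synapse_density(nrow(pairs), img$image_area_um2)
  put(data.frame(n_munc13 = nrow(pa), n_psd95 = nrow(pb),
                 n_synapses = nrow(pairs),
                 coloc_fraction = nrow(pairs) / max(nrow(pb), 1L),
                 density_per_um3 = dens), "puncta_summary.csv")

  # visual water task
  cf <- config$vwt
  set.seed(derive_seed(config$seed, 6L))
  thr <- vapply(seq_len(cf$n_animals), function(i) {
    obs <- psychometric_observer(cf$true_threshold, cf$slope, cf$lapse_rate,
                                 "acuity")
    log <- simulate_vwt_session(obs, trials_per_block = cf$trials_per_block)
    tryCatch(acuity_threshold(log), error = function(e) NA_real_)
  }, numeric(1))
  put(data.frame(animal = seq_len(cf$n_animals),
                 acuity_threshold_cpd = thr), "vwt_thresholds.csv")

  cfg_path <- file.path(config$out_dir, "run_config.yaml")
  write_run_config(config, cfg_path)
  manifest <- list(
    tool = "silentsyn",
    version = as.character(utils::packageVersion("silentsyn")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
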