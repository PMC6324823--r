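#' Simulate a 3-channel synaptic puncta image
#'
#' Disk-shaped puncta with controlled channel membership and pairwise
#' overlap, emulating semi-thin-section immunofluorescence with a
#' presynaptic marker (Munc13-1) and the PSD-93/PSD-95 paralog channels.
#' Each Munc13-1 punctum is co-placed with a punctum in the chosen paralog
#' channel with probability \code{coloc_fraction} (centers offset by
#' \code{offset_frac} of the radius, giving a large mask overlap); the
#' remaining paralog puncta are placed at separate, non-overlapping sites.
#' Puncta are laid out on a jittered grid so distinct puncta never touch.
#'
#' @param n_puncta number of Munc13-1 puncta (paralog puncta count equals
#'   this).
#' @param radius_px punctum radius, pixels.
#' @param image_shape c(height, width), pixels.
#' @param pixel_nm pixel size, nm (default 6).
#' @param coloc_fraction probability that a paralog punctum is co-placed
#'   with a Munc13-1 punctum.
#' @param paralog \code{"psd95"} or \code{"psd93"} (channel receiving the
#'   paralog puncta).
#' @param offset_frac center offset of co-placed pairs, as a fraction of
#'   the radius.
#' @param intensity foreground intensity of each punctum.
#' @param noise_sd additive Gaussian image noise SD.
#' @return list with \code{$channels} (named list of H x W matrices:
#'   \code{munc13}, \code{psd93}, \code{psd95}), \code{$truth} (data.frame:
#'   punctum id, channel, center, radius, \code{coloc} flag for paralog
#'   puncta), \code{$pixel_nm}, \code{$image_area_um2}.
#' @export
simulate_puncta_image <- function(n_puncta, radius_px = 10,
                                  image_shape = c(256, 256), pixel_nm = 6,
                                  coloc_fraction = 0.95,
                                  paralog = c("psd95", "psd93"),
                                  offset_frac = 0.3, intensity = 1,
                                  noise_sd = 0) {
  paralog <- match.arg(paralog)
  h <- image_shape[1]; w <- image_shape[2]
  if (2 * radius_px + 2 > min(h, w)) {
    stop("puncta larger than the image", call. = FALSE)
  }
  spacing <- ceiling(4 * radius_px + 4)
  gx <- seq(spacing %/% 2, w - spacing %/% 2, by = spacing)
  gy <- seq(spacing %/% 2, h - spacing %/% 2, by = spacing)
  slots <- expand.grid(y = gy, x = gx)
  coloc <- stats::runif(n_puncta) < coloc_fraction
  n_sites <- n_puncta + sum(!coloc)
  if (n_sites > nrow(slots)) {
    stop("too many puncta for the image: ", n_sites, " sites needed, ",
         nrow(slots), " available", call. = FALSE)
  }
  sites <- slots[sample.int(nrow(slots), n_sites), , drop = FALSE]
  jit <- radius_px / 2
  sites$x <- sites$x + stats::runif(n_sites, -jit, jit)
  sites$y <- sites$y + stats::runif(n_sites, -jit, jit)

  ch <- list(munc13 = matrix(0, h, w), psd93 = matrix(0, h, w),
             psd95 = matrix(0, h, w))
  draw_disk <- function(img, cx, cy, r, val) {
    xs <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
    ys <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
    for (x in xs) {
      dy <- sqrt(pmax(r^2 - (x - cx)^2, 0))
      yy <- ys[ys >= cy - dy & ys <= cy + dy]
      img[yy, x] <- val
    }
    img
  }
  rows <- list()
  theta <- stats::runif(n_puncta, 0, 2 * pi)
  for (i in seq_len(n_puncta)) {
    cx <- sites$x[i]; cy <- sites$y[i]
    ch$munc13 <- draw_disk(ch$munc13, cx, cy, radius_px, intensity)
    rows[[length(rows) + 1L]] <- data.frame(
      id = i, channel = "munc13", x = cx, y = cy, radius_px = radius_px,
      coloc = NA)
    if (coloc[i]) {
      px <- cx + offset_frac * radius_px * cos(theta[i])
      py <- cy + offset_frac * radius_px * sin(theta[i])
    } else {
      k <- n_puncta + sum(!coloc[seq_len(i)])
      px <- sites$x[k]; py <- sites$y[k]
    }
    ch[[paralog]] <- draw_disk(ch[[paralog]], px, py, radius_px, intensity)
    rows[[length(rows) + 1L]] <- data.frame(
      id = i, channel = paralog, x = px, y = py, radius_px = radius_px,
      coloc = coloc[i])
  }
  if (noise_sd > 0) {
    ch <- lapply(ch, function(m) m + matrix(stats::rnorm(h * w, 0, noise_sd),
                                            h, w))
  }
  list(channels = ch, truth = do.call(rbind, rows), pixel_nm = pixel_nm,
       image_area_um2 = (h * pixel_nm / 1000) * (w * pixel_nm / 1000))
}

#' Segment puncta-like objects in one channel
#'
#' Threshold by intensity (Otsu by default, or an absolute cutoff),
#' label connected components, and discard objects smaller than the size
#' threshold (200 px^2 by default; at 6 nm pixels this corresponds to about
#' 7,200 nm^2).  The manual splitting of fused puncta used in interactive
#' workflows is replaced by an optional watershed split.
#'
#' @param image single-channel 2-D numeric matrix.
#' @param method \code{"otsu"} or \code{"absolute"}.
#' @param threshold absolute intensity cutoff when
#'   \code{method = "absolute"}.
#' @param min_area_px object-size threshold in pixels^2 (objects strictly
#'   smaller are discarded).
#' @param pixel_nm pixel size, nm, for the physical-area column.
#' @param watershed split touching puncta with an intensity watershed.
#' @return a \code{puncta_set}: data.frame with \code{label},
#'   \code{area_px}, \code{area_nm2}, \code{centroid_x}, \code{centroid_y};
#'   the labeled image (small objects zeroed) is attached as attribute
#'   \code{"labels"} and the pixel size as \code{"pixel_nm"}.
#' @export
segment_puncta <- function(image, method = c("otsu", "absolute"),
                           threshold = NULL, min_area_px = 200,
                           pixel_nm = 6, watershed = FALSE) {
  method <- match.arg(method)
  if (!is.matrix(image) || length(image) == 0L) {
    stop("`image` must be a non-empty 2-D matrix", call. = FALSE)
  }
  if (method == "otsu") {
    rng <- range(image)
    if (diff(rng) == 0) {
      mask <- matrix(FALSE, nrow(image), ncol(image))
    } else {
      norm <- (image - rng[1]) / diff(rng)
      thr <- EBImage::otsu(EBImage::Image(norm))
      mask <- norm > thr
    }
  } else {
    if (is.null(threshold)) stop("absolute method needs `threshold`",
                                 call. = FALSE)
    mask <- image > threshold
  }
  labels <- if (watershed && any(mask)) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    EBImage::imageData(EBImage::watershed(dm))
  } else {
    EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  }
  labels <- matrix(as.integer(labels), nrow(image), ncol(image))
  if (max(labels) == 0L) {
    res <- data.frame(label = integer(0), area_px = integer(0),
                      area_nm2 = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0))
  } else {
    areas <- tabulate(labels[labels > 0L], nbins = max(labels))
    keep <- which(areas >= min_area_px)
    labels[!(labels %in% keep)] <- 0L
    idx <- which(labels > 0L, arr.ind = TRUE)
    lab <- labels[labels > 0L]
    cx <- tapply(idx[, 2], lab, mean)
    cy <- tapply(idx[, 1], lab, mean)
    res <- data.frame(label = as.integer(names(cx)),
                      area_px = areas[as.integer(names(cx))],
                      area_nm2 = areas[as.integer(names(cx))] * pixel_nm^2,
                      centroid_x = as.numeric(cx),
                      centroid_y = as.numeric(cy))
    rownames(res) <- NULL
  }
  attr(res, "labels") <- labels
  attr(res, "pixel_nm") <- pixel_nm
  class(res) <- c("puncta_set", "data.frame")
  res
}

#' Colocalize puncta across two channels
#'
#' A punctum pair is a candidate match iff its mask intersection exceeds
#' \code{min_overlap} of the denominator area — by default the smaller
#' punctum's area, which makes the >5% rule symmetric in the two channels.
#' Each punctum is matched to at most one partner: candidate pairs are
#' accepted in decreasing order of overlap fraction (ties broken by label
#' order).
#'
#' @param a,b \code{puncta_set} objects from \code{\link{segment_puncta}},
#'   same image geometry.
#' @param min_overlap overlap-fraction cutoff (strict >; default 0.05).
#' @param denominator \code{"smaller"}, \code{"a"}, \code{"b"} or
#'   \code{"union"}.
#' @return data.frame of matched pairs: \code{label_a}, \code{label_b},
#'   \code{intersection_px}, \code{overlap_fraction}.
#' @export
colocalize <- function(a, b, min_overlap = 0.05,
                       denominator = c("smaller", "a", "b", "union")) {
  denominator <- match.arg(denominator)
  la <- attr(a, "labels"); lb <- attr(b, "labels")
  if (!all(dim(la) == dim(lb))) {
    stop("channels must share image geometry", call. = FALSE)
  }
  empty <- data.frame(label_a = integer(0), label_b = integer(0),
                      intersection_px = integer(0),
                      overlap_fraction = numeric(0))
  both <- la > 0L & lb > 0L
  if (!any(both)) return(empty)
  inter <- table(la[both], lb[both])
  pairs <- as.data.frame(inter, stringsAsFactors = FALSE)
  names(pairs) <- c("label_a", "label_b", "intersection_px")
  pairs <- pairs[pairs$intersection_px > 0, , drop = FALSE]
  pairs$label_a <- as.integer(pairs$label_a)
  pairs$label_b <- as.integer(pairs$label_b)
  area_a <- stats::setNames(a$area_px, a$label)
  area_b <- stats::setNames(b$area_px, b$label)
  aa <- area_a[as.character(pairs$label_a)]
  bb <- area_b[as.character(pairs$label_b)]
  denom <- switch(denominator,
                  smaller = pmin(aa, bb),
                  a = aa, b = bb,
                  union = aa + bb - pairs$intersection_px)
  pairs$overlap_fraction <- pairs$intersection_px / denom
  pairs <- pairs[pairs$overlap_fraction > min_overlap, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  pairs <- pairs[order(-pairs$overlap_fraction, pairs$label_a,
                       pairs$label_b), , drop = FALSE]
  used_a <- used_b <- integer(0)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (!(pairs$label_a[i] %in% used_a) && !(pairs$label_b[i] %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, pairs$label_a[i])
      used_b <- c(used_b, pairs$label_b[i])
    }
  }
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Synapse density per cubic micrometre
#'
#' Synapses are puncta with overlapping presynaptic (Munc13-1) and
#' postsynaptic (PSD-93 or PSD-95) signals; density is their count divided
#' by the imaged tissue volume (image area times section thickness).
#'
#' @param n_synapses matched synapse count.
#' @param image_area_um2 imaged area, um^2.
#' @param thickness_nm section thickness, nm (default 500, semi-thin
#'   sections).
#' @return density, synapses per um^3.
#' @export
synapse_density <- function(n_synapses, image_area_um2, thickness_nm = 500) {
  if (image_area_um2 <= 0 || thickness_nm <= 0) {
    stop("image area and thickness must be positive", call. = FALSE)
  }
  n_synapses / (image_area_um2 * thickness_nm / 1000)
}

#' Normalize western-blot band intensities to per-blot controls
#'
#' Each band intensity is divided by the mean intensity of the control
#' group for the same protein on the same blot, so the control-group mean
#' is 1 per blot and protein by construction; within-blot ratios are
#' invariant to per-blot gain.  Rows whose (blot, protein) lacks a control
#' sample are flagged and excluded.
#'
#' @param table data.frame with columns \code{protein}, \code{sample_id},
#'   \code{group}, \code{band_intensity}, \code{blot_id}.
#' @param control_group group label of the control condition.
#' @return list with \code{$table} (input rows plus
#'   \code{relative_amount}) and \code{$excluded} (rows without a control,
#'   with reason).
#' @export
normalize_blot <- function(table, control_group = "control") {
  need <- c("protein", "sample_id", "group", "band_intensity", "blot_id")
  if (!all(need %in% names(table))) {
    stop("blot table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(table$blot_id, table$protein, drop = TRUE)
  ctrl_mean <- tapply(
    ifelse(table$group == control_group, table$band_intensity, NA_real_),
    key, mean, na.rm = TRUE)
  cm <- as.numeric(ctrl_mean[as.character(key)])
  ok <- is.finite(cm) & !is.nan(cm)
  out <- table[ok, , drop = FALSE]
  out$relative_amount <- table$band_intensity[ok] / cm[ok]
  excluded <- table[!ok, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- "no control sample on this blot for this protein"
  } else {
    excluded$reason <- character(0)
  }
  list(table = out, excluded = excluded)
}
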