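# Nucleus segmentation from a single fluorescence channel.
#
# Operator chain: Gaussian smooth -> per-frame background subtraction
# (percentile) -> global threshold (Otsu on the smoothed, background-
# subtracted frame, plus an additive offset) -> fill holes -> split touching
# regions by watershed on the distance transform, seeded at local maxima at
# least split_min_distance apart -> area filter. Coordinates are (row, col);
# labelling is 4-connected.

#' Segmentation parameters
#'
#' @param smoothing_sigma Gaussian smoothing SD in pixels (0 disables)
#' @param background_percentile percentile of smoothed pixel values
#'   subtracted as per-frame background (most pixels are background, so the
#'   median is a robust default)
#' @param threshold_method \code{"otsu"} (threshold scales with the data, so
#'   label maps are invariant to positive rescaling) or \code{"fixed"}
#' @param threshold_offset additive offset on the Otsu threshold, or the
#'   absolute threshold when \code{threshold_method = "fixed"} (AFU above
#'   background)
#' @param min_area,max_area area filter bounds in pixels
#' @param split_min_distance minimum distance (pixels) between watershed
#'   seeds when splitting touching nuclei
#' @return an object of class \code{seg_params}
#' @export
seg_params <- function(smoothing_sigma = 1.5,
                       background_percentile = 50,
                       threshold_method = c("otsu", "fixed"),
                       threshold_offset = 0,
                       min_area = 20,
                       max_area = 4000,
                       split_min_distance = 8) {
  threshold_method <- match.arg(threshold_method)
  if (min_area >= max_area) stop("min_area must be < max_area")
  if (smoothing_sigma < 0) stop("smoothing_sigma must be >= 0")
  structure(list(smoothing_sigma = smoothing_sigma,
                 background_percentile = background_percentile,
                 threshold_method = threshold_method,
                 threshold_offset = threshold_offset,
                 min_area = min_area, max_area = max_area,
                 split_min_distance = split_min_distance),
            class = "seg_params")
}

# Label-map constructor: integer matrix plus per-label summary table.
label_map <- function(labels, frame_index = 1L) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) > 0) {
    area <- tabulate(labels, nbins = max(ids))[ids]
    idx <- which(labels > 0)
    rows <- ((idx - 1) %% nrow(labels)) + 1
    cols <- ((idx - 1) %/% nrow(labels)) + 1
    lab <- labels[idx]
    tab <- data.frame(
      label = ids,
      area = area,
      centroid_row = as.numeric(tapply(rows, lab, mean)[as.character(ids)]),
      centroid_col = as.numeric(tapply(cols, lab, mean)[as.character(ids)])
    )
  } else {
    tab <- data.frame(label = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
  }
  structure(list(frame_index = as.integer(frame_index), labels = labels,
                 table = tab),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> frame %d: %d nuclei\n", x$frame_index,
              nrow(x$table)))
  invisible(x)
}

# Gaussian smooth + percentile background subtraction; shared by global and
# local segmentation. The returned matrix carries the MAD of the smoothed
# frame (a noise-scale estimate, since most pixels are background) as
# attribute "noise_mad".
smooth_subtract <- function(raster, params, percentile = NULL) {
  sm <- raster
  if (params$smoothing_sigma > 0) {
    sm <- as.matrix(EBImage::gblur(raster, sigma = params$smoothing_sigma))
  }
  pct <- percentile %||% params$background_percentile
  bg <- as.numeric(quantile(sm, pct / 100))
  out <- pmax(sm - bg, 0)
  attr(out, "noise_mad") <- mad(sm)
  out
}

# Otsu threshold on the smoothed, background-subtracted frame. Intensities
# are normalized by their maximum before the 256-bin histogram, so the
# threshold scales with the data and label maps are invariant under
# positive rescaling of the raster.
otsu_threshold <- function(sub) {
  mx <- max(sub)
  as.numeric(EBImage::otsu(EBImage::Image(sub / mx), range = c(0, 1))) * mx
}

# Seeded watershed split: seeds are distance-transform local maxima at least
# split_min_distance apart; ties between equal maxima resolved toward the
# lowest (row, col) seed.
split_touching <- function(mask, split_min_distance) {
  dm <- as.matrix(EBImage::distmap(mask))
  if (max(dm) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  bsz <- max(3L, 2L * floor(split_min_distance / 2) + 1L)
  dil <- as.matrix(EBImage::dilate(dm, EBImage::makeBrush(bsz, shape = "disc")))
  seed_px <- (dm >= dil) & (dm > 1)
  seeds <- as.matrix(EBImage::bwlabel(seed_px))
  ns <- max(seeds)
  if (ns > 1) {
    # merge seed plateaus closer than split_min_distance (keep lower id)
    idx <- which(seeds > 0)
    rows <- ((idx - 1) %% nrow(seeds)) + 1
    cols <- ((idx - 1) %/% nrow(seeds)) + 1
    lab <- seeds[idx]
    cr <- tapply(rows, lab, mean); cc <- tapply(cols, lab, mean)
    remap <- seq_len(ns)
    for (a in seq_len(ns - 1)) {
      for (b in seq(a + 1, ns)) {
        if (remap[b] != b) next
        if ((cr[a] - cr[b])^2 + (cc[a] - cc[b])^2 < split_min_distance^2) {
          remap[b] <- remap[a]
        }
      }
    }
    if (any(remap != seq_len(ns))) {
      seeds[idx] <- remap[lab]
    }
  }
  if (max(seeds) == 0) return(as.matrix(EBImage::bwlabel(mask)))
  lab <- EBImage::propagate(EBImage::Image(max(dm) - dm),
                            seeds = EBImage::Image(seeds),
                            mask = EBImage::Image(mask))
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

#' Segment nuclei in one frame
#'
#' @param raster 2-D numeric intensity matrix (finite, non-negative)
#' @param params a [seg_params()] object
#' @param frame_index frame number recorded in the result (1-based)
#' @return a \code{label_map}: integer labels (0 = background) with a
#'   per-label area/centroid table. A constant or saturated frame yields an
#'   empty label map with a warning, never an error.
#' @export
segment_nuclei <- function(raster, params = seg_params(), frame_index = 1L) {
  stopifnot(is.matrix(raster))
  if (any(!is.finite(raster))) stop("raster must be finite")
  if (any(raster < 0)) stop("raster must be non-negative")
  if (diff(range(raster)) == 0) {
    warning("constant raster: returning empty label map")
    return(label_map(matrix(0L, nrow(raster), ncol(raster)), frame_index))
  }
  sub <- smooth_subtract(raster, params)
  mx <- max(sub)
  if (mx == 0) {
    warning("no signal above background: returning empty label map")
    return(label_map(matrix(0L, nrow(raster), ncol(raster)), frame_index))
  }
  thr <- if (params$threshold_method == "otsu") {
    otsu_threshold(sub) + params$threshold_offset
  } else {
    params$threshold_offset
  }
  # noise floor: most pixels are background, so the MAD of the smoothed
  # frame estimates the residual noise scale; a threshold inside it means
  # the frame carries no real foreground (scale-invariant guard)
  noise_floor <- 6 * attr(sub, "noise_mad")
  mask <- sub > max(thr, noise_floor)
  mask <- as.matrix(EBImage::fillHull(mask)) > 0
  labs <- split_touching(mask, params$split_min_distance)
  # area filter and consecutive relabelling
  if (max(labs) > 0) {
    areas <- tabulate(labs, nbins = max(labs))
    keep <- which(areas >= params$min_area & areas <= params$max_area)
    remap <- integer(max(labs))
    remap[keep] <- seq_along(keep)
    pos <- labs > 0
    labs[pos] <- remap[labs[pos]]
  }
  label_map(labs, frame_index)
}

#' Locally re-segment a nucleus from a prior mask
#'
#' Recovers dim nuclei (typically G1, when PCNA is lowest) that the global
#' threshold under-segments: within the dilated bounding box of a mask from
#' an adjacent frame, a local threshold is recomputed and the connected
#' component maximally overlapping the prior mask is returned.
#'
#' @param raster 2-D intensity matrix
#' @param prior_mask logical matrix (the cell's mask in an adjacent frame)
#' @param params a [seg_params()] object
#' @return logical matrix of the refined mask (all-FALSE when
#'   \code{prior_mask} is empty or nothing is found)
#' @export
local_resegment <- function(raster, prior_mask, params = seg_params()) {
  stopifnot(is.matrix(raster), is.matrix(prior_mask),
            all(dim(raster) == dim(prior_mask)))
  out <- matrix(FALSE, nrow(raster), ncol(raster))
  idx <- which(prior_mask)
  if (length(idx) == 0) return(out)
  rows <- ((idx - 1) %% nrow(raster)) + 1
  cols <- ((idx - 1) %/% nrow(raster)) + 1
  pad <- ceiling(2 * max(params$smoothing_sigma, 1))
  r0 <- max(1, min(rows) - pad); r1 <- min(nrow(raster), max(rows) + pad)
  c0 <- max(1, min(cols) - pad); c1 <- min(ncol(raster), max(cols) + pad)
  crop <- raster[r0:r1, c0:c1, drop = FALSE]
  if (diff(range(crop)) == 0) return(out)
  # the crop is foreground-dominated by construction, so the local
  # background is a low percentile rather than the global default
  sub <- smooth_subtract(crop, params,
                         percentile = min(params$background_percentile, 10))
  mx <- max(sub)
  if (mx == 0) return(out)
  thr <- otsu_threshold(sub)
  mask <- as.matrix(EBImage::fillHull(sub > thr)) > 0
  labs <- as.matrix(EBImage::bwlabel(mask))
  if (max(labs) == 0) return(out)
  prior_crop <- prior_mask[r0:r1, c0:c1, drop = FALSE]
  ov <- vapply(seq_len(max(labs)), function(l) sum(labs == l & prior_crop),
               numeric(1))
  if (max(ov) == 0) return(out)
  best <- which.max(ov)  # which.max takes the first (lowest label) on ties
  out[r0:r1, c0:c1] <- labs == best
  out
}

# IoU between two logical masks (used throughout validation).
#' Intersection-over-union of two masks
#' @param a,b logical matrices of equal dimension
#' @return Jaccard index in `[0, 1]`
#' @export
mask_iou <- function(a, b) {
  i <- sum(a & b); u <- sum(a | b)
  if (u == 0) return(NA_real_)
  i / u
}
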