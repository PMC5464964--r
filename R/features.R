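# Per-track feature series: nuclear mean and within-nucleus intensity
# distribution width (pixel SD), the two quantities carrying all cell-cycle
# information in a PCNA reporter.

# Per-frame background: the 5th percentile of pixels outside every nucleus
# mask (robust to sparse fields).
frame_background <- function(raster, labels, probs = 0.05) {
  out <- raster[labels == 0]
  if (length(out) == 0) return(0)
  as.numeric(quantile(out, probs))
}

# Erode the foreground by 1 px before intensity statistics: mask boundaries
# carry partial-volume pixels whose inclusion couples the nuclear mean and
# SD to the exact threshold, so statistics are taken over the mask core.
erode_support <- function(labels) {
  er <- as.matrix(EBImage::erode(labels > 0, EBImage::makeBrush(5, "disc")))
  er > 0
}

#' Compute per-track feature series
#'
#' For every frame of a track: background-subtracted nuclear mean intensity,
#' the within-nucleus pixel-intensity standard deviation ("distribution
#' width", a proxy for replication-foci granularity), and mask area;
#' optionally the chromatin-channel distribution width. Temporal smoothing
#' is a running median of window \code{w}. Frames where the track has no
#' mask are NA (missing, never interpolated).
#'
#' @param track_id track identifier
#' @param tracks a \code{cell_tracks} object
#' @param stack a \code{frame_stack} (or plain named list of H x W x T
#'   arrays)
#' @param labelmaps list of \code{label_map} objects matching the tracking
#'   run
#' @param channel channel used for the nuclear mean/SD (default
#'   \code{"pcna"})
#' @param chromatin_channel optional channel for \code{chromatin_sd}
#'   (\code{NULL} to skip)
#' @param w running-median smoothing window in frames
#' @param width_stat \code{"sd"} (default) or \code{"iqr"} for the
#'   distribution-width statistic
#' @return a data.frame of class \code{track_features} with one row per
#'   movie frame: frame, time_h, present, nuclear_mean, nuclear_sd, area,
#'   chromatin_sd, and smoothed variants (suffix \code{_s})
#' @export
compute_feature_series <- function(track_id, tracks, stack, labelmaps,
                                   channel = "pcna",
                                   chromatin_channel = "chromatin",
                                   w = 3, width_stat = c("sd", "iqr")) {
  width_stat <- match.arg(width_stat)
  channels <- if (inherits(stack, "frame_stack")) stack$channels else stack
  interval <- if (inherits(stack, "frame_stack")) stack$frame_interval else NA
  n_frames <- tracks$n_frames
  det <- tracks$detections[tracks$detections$track_id == track_id, ]
  if (nrow(det) == 0) stop("unknown track id ", track_id)
  if (!is.null(chromatin_channel) && !chromatin_channel %in% names(channels)) {
    chromatin_channel <- NULL
  }
  width_fun <- if (width_stat == "sd") sd else function(x) IQR(x)
  nm <- ns <- ar <- cs <- rep(NA_real_, n_frames)
  for (k in seq_len(nrow(det))) {
    f <- det$frame[k]
    full <- labelmaps[[f]]$labels == det$label[k]
    if (!any(full)) next
    core <- full & erode_support(labelmaps[[f]]$labels)
    mask <- if (any(core)) core else full
    bg <- frame_background(channels[[channel]][, , f], labelmaps[[f]]$labels)
    px <- channels[[channel]][, , f][mask] - bg
    nm[f] <- mean(px)
    ns[f] <- width_fun(px)
    ar[f] <- sum(full)
    if (!is.null(chromatin_channel)) {
      cpx <- channels[[chromatin_channel]][, , f][mask]
      cs[f] <- width_fun(cpx)
    }
  }
  out <- data.frame(frame = seq_len(n_frames),
                    time_h = frames_to_hours(seq_len(n_frames),
                                             if (is.na(interval)) 1 else interval),
                    present = !is.na(nm),
                    nuclear_mean = nm, nuclear_sd = ns, area = ar,
                    chromatin_sd = cs)
  out$nuclear_mean_s <- running_median(nm, w)
  out$nuclear_sd_s <- running_median(ns, w)
  out$chromatin_sd_s <- running_median(cs, w)
  attr(out, "track_id") <- track_id
  attr(out, "frame_interval") <- interval
  class(out) <- c("track_features", "data.frame")
  out
}

#' Compute feature series for every track
#'
#' Vectorized driver over [compute_feature_series()] sharing per-frame
#' background computation.
#'
#' @inheritParams compute_feature_series
#' @return named list (by track id) of \code{track_features} tables
#' @export
compute_all_features <- function(tracks, stack, labelmaps, channel = "pcna",
                                 chromatin_channel = "chromatin", w = 3) {
  channels <- if (inherits(stack, "frame_stack")) stack$channels else stack
  interval <- if (inherits(stack, "frame_stack")) stack$frame_interval else NA
  n_frames <- tracks$n_frames
  det <- tracks$detections
  ids <- sort(unique(det$track_id))
  if (!is.null(chromatin_channel) && !chromatin_channel %in% names(channels)) {
    chromatin_channel <- NULL
  }
  # per-frame per-label statistics in one pass
  nm <- ns <- ar <- cs <- matrix(NA_real_, n_frames, length(ids),
                                 dimnames = list(NULL, ids))
  for (f in seq_len(n_frames)) {
    lm <- labelmaps[[f]]$labels
    rows <- det[det$frame == f, ]
    if (nrow(rows) == 0) next
    bg <- frame_background(channels[[channel]][, , f], lm)
    x <- channels[[channel]][, , f]
    core <- erode_support(lm)
    idx <- which(lm > 0 & core)
    if (length(idx) == 0) idx <- which(lm > 0)
    lab <- lm[idx]
    vals <- x[idx] - bg
    mu <- tapply(vals, lab, mean)
    s <- tapply(vals, lab, sd)
    a <- tapply(lm[lm > 0], lm[lm > 0], length)
    cstat <- if (!is.null(chromatin_channel)) {
      tapply(channels[[chromatin_channel]][, , f][idx], lab, sd)
    }
    key <- as.character(rows$label)
    col <- as.character(rows$track_id)
    nm[f, col] <- mu[key]
    ns[f, col] <- s[key]
    ar[f, col] <- a[key]
    if (!is.null(cstat)) cs[f, col] <- cstat[key]
  }
  out <- lapply(as.character(ids), function(id) {
    fr <- data.frame(frame = seq_len(n_frames),
                     time_h = frames_to_hours(seq_len(n_frames),
                                              if (is.na(interval)) 1 else interval),
                     present = !is.na(nm[, id]),
                     nuclear_mean = nm[, id], nuclear_sd = ns[, id],
                     area = ar[, id], chromatin_sd = cs[, id])
    fr$nuclear_mean_s <- running_median(fr$nuclear_mean, w)
    fr$nuclear_sd_s <- running_median(fr$nuclear_sd, w)
    fr$chromatin_sd_s <- running_median(fr$chromatin_sd, w)
    attr(fr, "track_id") <- as.integer(id)
    attr(fr, "frame_interval") <- interval
    class(fr) <- c("track_features", "data.frame")
    fr
  })
  names(out) <- ids
  out
}
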