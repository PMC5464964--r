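# Evaluation against synthetic-movie ground truth: track-to-cell matching
# and tracking quality metrics.

#' Match pipeline tracks to ground-truth cells
#'
#' Each detection is assigned to the true cell whose mask it maximally
#' overlaps; a track's cell is the majority vote over its detections.
#'
#' @param analysis a \code{movie_analysis}
#' @param truth the \code{truth} element of a [simulate_movie()] result
#' @return data.frame with columns track_id, cell_id (NA when a track
#'   overlaps no true cell), purity (fraction of the track's detections
#'   voting for the majority cell)
#' @export
match_tracks_to_truth <- function(analysis, truth) {
  det <- analysis$tracks$detections
  votes <- integer(nrow(det))
  for (k in seq_len(nrow(det))) {
    f <- det$frame[k]
    mask <- analysis$labelmaps[[f]]$labels == det$label[k]
    tl <- truth$labels[[f]][mask]
    tl <- tl[tl > 0]
    votes[k] <- if (length(tl) > 0) {
      as.integer(names(sort(table(tl), decreasing = TRUE))[1])
    } else NA_integer_
  }
  sp <- split(votes, det$track_id)
  out <- data.frame(
    track_id = as.integer(names(sp)),
    cell_id = vapply(sp, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) return(NA_integer_)
      as.integer(names(sort(table(v), decreasing = TRUE))[1])
    }, integer(1)),
    purity = vapply(sp, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) return(NA_real_)
      max(table(v)) / length(v)
    }, numeric(1))
  )
  rownames(out) <- NULL
  out
}

#' Pair tracks between two analyses of the same movie
#'
#' Tracks from two runs (e.g. PCNA-based and chromatin-based segmentation)
#' are paired 1:1 when they map to the same ground-truth cell.
#'
#' @param analysis_a,analysis_b two \code{movie_analysis} objects
#' @param truth ground truth shared by both
#' @return data.frame with cell_id, track_a, track_b
#' @export
pair_tracks_by_truth <- function(analysis_a, analysis_b, truth) {
  ma <- match_tracks_to_truth(analysis_a, truth)
  mb <- match_tracks_to_truth(analysis_b, truth)
  # keep the longest (most detections) track per cell in each run
  len_a <- table(analysis_a$tracks$detections$track_id)
  len_b <- table(analysis_b$tracks$detections$track_id)
  pick <- function(m, len) {
    m <- m[!is.na(m$cell_id), ]
    m$len <- as.integer(len[as.character(m$track_id)])
    m <- m[order(m$cell_id, -m$len), ]
    m[!duplicated(m$cell_id), c("cell_id", "track_id")]
  }
  a <- pick(ma, len_a); names(a)[2] <- "track_a"
  b <- pick(mb, len_b); names(b)[2] <- "track_b"
  merge(a, b, by = "cell_id")
}
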