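# Linking per-frame label maps into tracks, gap closing, division detection
# and lineage assembly.

#' Linking parameters
#'
#' @param min_jaccard minimum Jaccard overlap for an overlap-based link
#' @param max_displacement centroid fallback radius in pixels for labels with
#'   no qualifying overlap
#' @param max_gap maximum number of missing frames bridged by
#'   [close_gaps()]
#' @param division_window frames after a track's end in which daughter
#'   births are considered
#' @param division_radius centroid radius (pixels) for daughter candidates
#' @param nebd_lookback frames before a track's end searched for the NEBD
#'   intensity-drop signature
#' @param nebd_drop minimum fractional drop of nuclear PCNA identifying NEBD
#' @param area_drop fractional area drop below the rolling median that
#'   triggers local re-segmentation in [resegment_tracks()]
#' @return an object of class \code{link_params}
#' @export
link_params <- function(min_jaccard = 0.2,
                        max_displacement = 6,
                        max_gap = 2,
                        division_window = 3,
                        division_radius = 24,
                        nebd_lookback = 5,
                        nebd_drop = 0.3,
                        area_drop = 0.3) {
  structure(list(min_jaccard = min_jaccard,
                 max_displacement = max_displacement,
                 max_gap = as.integer(max_gap),
                 division_window = as.integer(division_window),
                 division_radius = division_radius,
                 nebd_lookback = as.integer(nebd_lookback),
                 nebd_drop = nebd_drop,
                 area_drop = area_drop),
            class = "link_params")
}

# detections table helpers ---------------------------------------------------

new_cell_tracks <- function(detections, n_frames, params) {
  detections <- detections[order(detections$track_id, detections$frame), ]
  rownames(detections) <- NULL
  structure(list(detections = detections, n_frames = as.integer(n_frames),
                 params = params),
            class = "cell_tracks")
}

#' @export
print.cell_tracks <- function(x, ...) {
  cat(sprintf("<cell_tracks> %d tracks over %d frames (%d detections)\n",
              length(unique(x$detections$track_id)), x$n_frames,
              nrow(x$detections)))
  invisible(x)
}

#' Link per-frame label maps into tracks
#'
#' Greedy assignment by maximal Jaccard overlap between consecutive frames;
#' ties broken by larger overlap area, then smaller centroid distance, then
#' lower label. Labels without a qualifying overlap fall back to the
#' nearest unmatched centroid within \code{max_displacement}; labels
#' unmatched after both rules start (or end) a track.
#'
#' @param labelmaps list of \code{label_map} objects, one per frame
#' @param params a [link_params()] object
#' @return a \code{cell_tracks} object whose \code{detections} table has
#'   columns track_id, frame, label, centroid_row, centroid_col, area
#' @export
link_frames <- function(labelmaps, params = link_params()) {
  stopifnot(length(labelmaps) >= 1)
  n_frames <- length(labelmaps)
  det <- list()
  t0 <- labelmaps[[1]]$table
  next_track <- nrow(t0)
  cur <- if (nrow(t0) > 0) {
    data.frame(track_id = seq_len(nrow(t0)), frame = 1L, t0)
  } else {
    data.frame(track_id = integer(0), frame = integer(0), label = integer(0),
               area = integer(0), centroid_row = numeric(0),
               centroid_col = numeric(0))
  }
  det[[1]] <- cur
  for (f in seq_len(n_frames - 1)) {
    A <- labelmaps[[f]]$labels; B <- labelmaps[[f + 1]]$labels
    ta <- det[[f]]; tb <- labelmaps[[f + 1]]$table
    assigned_b <- rep(NA_integer_, nrow(tb))   # track id per new label
    if (nrow(ta) > 0 && nrow(tb) > 0) {
      both <- A > 0 & B > 0
      if (any(both)) {
        ov <- table(A[both], B[both])
        pairs <- as.data.frame(ov, stringsAsFactors = FALSE)
        pairs <- pairs[pairs$Freq > 0, ]
        names(pairs) <- c("la", "lb", "inter")
        pairs$la <- as.integer(as.character(pairs$la))
        pairs$lb <- as.integer(as.character(pairs$lb))
        area_a <- ta$area[match(pairs$la, ta$label)]
        area_b <- tb$area[match(pairs$lb, tb$label)]
        pairs$jac <- pairs$inter / (area_a + area_b - pairs$inter)
        ra <- ta[match(pairs$la, ta$label), ]
        rb <- tb[match(pairs$lb, tb$label), ]
        pairs$dist <- sqrt((ra$centroid_row - rb$centroid_row)^2 +
                             (ra$centroid_col - rb$centroid_col)^2)
        pairs <- pairs[pairs$jac >= params$min_jaccard, ]
        if (nrow(pairs) > 0) {
          pairs <- pairs[order(-pairs$jac, -pairs$inter, pairs$dist,
                               pairs$la, pairs$lb), ]
          used_a <- integer(0)
          for (k in seq_len(nrow(pairs))) {
            la <- pairs$la[k]; lb <- pairs$lb[k]
            bi <- match(lb, tb$label)
            if (la %in% used_a || !is.na(assigned_b[bi])) next
            assigned_b[bi] <- ta$track_id[match(la, ta$label)]
            used_a <- c(used_a, la)
          }
        }
      }
      # centroid fallback for still-unmatched labels
      free_a <- ta[!ta$track_id %in% assigned_b, , drop = FALSE]
      for (bi in which(is.na(assigned_b))) {
        if (nrow(free_a) == 0) break
        d <- sqrt((free_a$centroid_row - tb$centroid_row[bi])^2 +
                    (free_a$centroid_col - tb$centroid_col[bi])^2)
        j <- which.min(d)
        if (d[j] <= params$max_displacement) {
          assigned_b[bi] <- free_a$track_id[j]
          free_a <- free_a[-j, , drop = FALSE]
        }
      }
    }
    if (nrow(tb) > 0) {
      births <- which(is.na(assigned_b))
      if (length(births) > 0) {
        assigned_b[births] <- next_track + seq_along(births)
        next_track <- next_track + length(births)
      }
      det[[f + 1]] <- data.frame(track_id = assigned_b, frame = f + 1L, tb)
    } else {
      det[[f + 1]] <- det[[1]][0, ]
    }
  }
  new_cell_tracks(do.call(rbind, det), n_frames, params)
}

# per-track first/last summary used by gap closing and division detection
track_ends <- function(detections) {
  sp <- split(detections, detections$track_id)
  data.frame(
    track_id = as.integer(names(sp)),
    first = vapply(sp, function(d) min(d$frame), integer(1)),
    last = vapply(sp, function(d) max(d$frame), integer(1)),
    first_row = vapply(sp, function(d) d$centroid_row[which.min(d$frame)], numeric(1)),
    first_col = vapply(sp, function(d) d$centroid_col[which.min(d$frame)], numeric(1)),
    last_row = vapply(sp, function(d) d$centroid_row[which.max(d$frame)], numeric(1)),
    last_col = vapply(sp, function(d) d$centroid_col[which.max(d$frame)], numeric(1)),
    first_area = vapply(sp, function(d) d$area[which.min(d$frame)], numeric(1)),
    last_area = vapply(sp, function(d) d$area[which.max(d$frame)], numeric(1)),
    row.names = NULL
  )
}

#' Close short tracking gaps
#'
#' A terminated track and a later-born track are merged when the gap is at
#' most \code{max_gap} frames, the centroid displacement is at most
#' \code{max_displacement * gap}, and the area ratio across the gap lies in
#' `[0.5, 2]`. Candidates are resolved greedily by smallest displacement.
#'
#' @param tracks a \code{cell_tracks} object
#' @param max_gap maximum bridged gap in frames (0 = identity)
#' @return a \code{cell_tracks} object with merged track ids
#' @export
close_gaps <- function(tracks, max_gap = tracks$params$max_gap) {
  stopifnot(inherits(tracks, "cell_tracks"))
  if (max_gap < 1) return(tracks)
  det <- tracks$detections
  repeat {
    te <- track_ends(det)
    cand <- list()
    for (i in seq_len(nrow(te))) {
      if (te$last[i] >= tracks$n_frames) next
      gaps <- te$first - te$last[i] - 1L
      ok <- which(gaps >= 1 & gaps <= max_gap)
      for (j in ok) {
        disp <- sqrt((te$last_row[i] - te$first_row[j])^2 +
                       (te$last_col[i] - te$first_col[j])^2)
        ratio <- te$first_area[j] / te$last_area[i]
        if (disp <= tracks$params$max_displacement * gaps[j] &&
            ratio >= 0.5 && ratio <= 2) {
          cand[[length(cand) + 1]] <- data.frame(
            from = te$track_id[i], to = te$track_id[j], disp = disp)
        }
      }
    }
    if (length(cand) == 0) break
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$disp, cand$from, cand$to), ]
    used <- logical(0)
    merged_any <- FALSE
    taken_from <- integer(0); taken_to <- integer(0)
    for (k in seq_len(nrow(cand))) {
      if (cand$from[k] %in% taken_from || cand$to[k] %in% taken_to) next
      det$track_id[det$track_id == cand$to[k]] <- cand$from[k]
      taken_from <- c(taken_from, cand$from[k])
      taken_to <- c(taken_to, cand$to[k])
      merged_any <- TRUE
    }
    if (!merged_any) break
  }
  new_cell_tracks(det, tracks$n_frames, tracks$params)
}

#' Detect divisions and assemble the lineage forest
#'
#' A mother track ending at frame f is linked to exactly two tracks born
#' within \code{division_window} frames after f, both with centroids within
#' \code{division_radius} of the mother's last centroid. Among candidate
#' pairs, the pair whose summed area best matches the mother's pre-division
#' area is preferred. The mother must show the NEBD signature — a drop of at
#' least \code{nebd_drop} in smoothed nuclear PCNA — within the last
#' \code{nebd_lookback} frames of its life. A single plausible daughter is
#' never linked (the track simply terminates).
#'
#' @param tracks a \code{cell_tracks} object
#' @param nuclear_mean optional named list (by track id) of per-frame nuclear
#'   PCNA mean vectors (NA-padded to the movie length), used for the NEBD
#'   check; when NULL the signature check is skipped
#' @param params a [link_params()] object
#' @return an object of class \code{lineage}: the tracks, a
#'   \code{divisions} table (mother, frame, daughter_a, daughter_b) and a
#'   \code{parent} vector indexed by track id
#' @export
detect_divisions <- function(tracks, nuclear_mean = NULL,
                             params = tracks$params) {
  stopifnot(inherits(tracks, "cell_tracks"))
  te <- track_ends(tracks$detections)
  parent <- rep(NA_integer_, max(te$track_id))
  divisions <- data.frame(mother = integer(0), frame = integer(0),
                          daughter_a = integer(0), daughter_b = integer(0))
  has_nebd <- function(tid, last_frame) {
    if (is.null(nuclear_mean)) return(TRUE)
    x <- nuclear_mean[[as.character(tid)]]
    if (is.null(x)) return(TRUE)
    lo <- max(1, last_frame - params$nebd_lookback)
    xs <- running_median(x[lo:last_frame], 3)
    xs <- xs[!is.na(xs)]
    if (length(xs) < 2) return(FALSE)
    any(xs[-1] <= (1 - params$nebd_drop) * cummax(xs)[-length(xs)])
  }
  taken <- integer(0)
  for (i in order(te$last)) {
    if (te$last[i] >= tracks$n_frames) next
    mid <- te$track_id[i]
    born <- which(te$first > te$last[i] &
                    te$first <= te$last[i] + params$division_window &
                    !te$track_id %in% c(taken, mid))
    if (length(born) < 2) next
    d <- sqrt((te$first_row[born] - te$last_row[i])^2 +
                (te$first_col[born] - te$last_col[i])^2)
    born <- born[d <= params$division_radius]
    if (length(born) < 2) next
    if (!has_nebd(mid, te$last[i])) next
    # rank candidate pairs by |area_a + area_b - mother area|
    pairs <- t(combn(born, 2))
    mism <- abs(te$first_area[pairs[, 1]] + te$first_area[pairs[, 2]] -
                  te$last_area[i]) / te$last_area[i]
    best <- pairs[which.min(mism), ]
    da <- te$track_id[best[1]]; db <- te$track_id[best[2]]
    parent[c(da, db)] <- mid
    divisions <- rbind(divisions,
                       data.frame(mother = mid, frame = te$last[i],
                                  daughter_a = min(da, db),
                                  daughter_b = max(da, db)))
    taken <- c(taken, da, db)
  }
  structure(list(tracks = tracks, divisions = divisions, parent = parent),
            class = "lineage")
}

#' @export
print.lineage <- function(x, ...) {
  cat(sprintf("<lineage> %d tracks, %d divisions\n",
              length(unique(x$tracks$detections$track_id)),
              nrow(x$divisions)))
  invisible(x)
}

#' Post-tracking local re-segmentation
#'
#' Operationalizes the local re-segmentation refinement: for every frame
#' where a track's segmented area falls more than \code{area_drop} below its
#' rolling median area, the nucleus is re-segmented locally
#' ([local_resegment()]) using the previous frame's mask as the prior, and
#' the label map and detection are updated when the refined mask is larger.
#'
#' @param tracks a \code{cell_tracks} object
#' @param rasters list of 2-D intensity matrices (one per frame)
#' @param labelmaps list of \code{label_map} objects (updated copies are
#'   returned)
#' @param seg a [seg_params()] object
#' @param params a [link_params()] object
#' @return list with updated \code{tracks} and \code{labelmaps}
#' @export
resegment_tracks <- function(tracks, rasters, labelmaps,
                             seg = seg_params(), params = tracks$params) {
  det <- tracks$detections
  for (tid in unique(det$track_id)) {
    rows <- which(det$track_id == tid)
    rows <- rows[order(det$frame[rows])]
    if (length(rows) < 3) next
    areas <- det$area[rows]
    med <- running_median(areas, min(5, length(areas)))
    low <- which(areas < (1 - params$area_drop) * med)
    for (k in low) {
      if (k == 1) next
      f <- det$frame[rows[k]]
      f_prev <- det$frame[rows[k - 1]]
      prior <- labelmaps[[f_prev]]$labels == det$label[rows[k - 1]]
      ref <- local_resegment(rasters[[f]], prior, seg)
      new_area <- sum(ref)
      if (new_area <= areas[k]) next
      lm <- labelmaps[[f]]$labels
      old_label <- det$label[rows[k]]
      # claim only pixels that are background or already ours
      claim <- ref & (lm == 0 | lm == old_label)
      lm[lm == old_label] <- 0L
      lm[claim] <- old_label
      labelmaps[[f]] <- label_map(lm, labelmaps[[f]]$frame_index)
      idx <- which(claim)
      det$area[rows[k]] <- length(idx)
      det$centroid_row[rows[k]] <- mean(((idx - 1) %% nrow(lm)) + 1)
      det$centroid_col[rows[k]] <- mean(((idx - 1) %/% nrow(lm)) + 1)
    }
  }
  list(tracks = new_cell_tracks(det, tracks$n_frames, tracks$params),
       labelmaps = labelmaps)
}
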