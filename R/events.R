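# Cell-cycle event detection and phase assignment from PCNA feature series.
#
# All detectors operate on relative changes of the series, so every event
# estimate is invariant under global positive rescaling of the intensities.

#' Classification parameters
#'
#' @param baseline_window post-birth window (hours) whose median defines the
#'   G1 baseline PCNA level
#' @param rise_fraction fractional rise over baseline marking a G1/S
#'   candidate
#' @param persistence frames the rise must persist
#' @param d_min minimum fractional single-step drop of smoothed nuclear PCNA
#'   marking NEBD
#' @param q_frac fractional loss of the birth-window PCNA level required for
#'   quiescence
#' @param t_q minimum duration (hours) of the non-increasing decline run
#' @param q_tol per-step tolerance (fraction of the running minimum) within
#'   which the decline run still counts as non-increasing
#' @param w running-median smoothing window, frames
#' @return an object of class \code{class_params}
#' @export
class_params <- function(baseline_window = 4,
                         rise_fraction = 0.10,
                         persistence = 3,
                         d_min = 0.3,
                         q_frac = 0.4,
                         t_q = 24,
                         q_tol = 0.05,
                         w = 3) {
  structure(list(baseline_window = baseline_window,
                 rise_fraction = rise_fraction,
                 persistence = as.integer(persistence),
                 d_min = d_min, q_frac = q_frac, t_q = t_q, q_tol = q_tol,
                 w = as.integer(w)),
            class = "class_params")
}

# smoothed nuclear mean accessor tolerant of plain numeric vectors
series_smoothed <- function(series, w = 3) {
  if (is.data.frame(series)) {
    if (!is.null(series$nuclear_mean_s)) return(series$nuclear_mean_s)
    return(running_median(series$nuclear_mean, w))
  }
  running_median(as.numeric(series), w)
}

series_interval <- function(series, frame_interval) {
  if (!is.null(frame_interval) && !is.na(frame_interval)) return(frame_interval)
  iv <- attr(series, "frame_interval")
  if (!is.null(iv) && !is.na(iv)) return(iv)
  stop("frame_interval must be supplied")
}

#' Detect mitosis (NEBD) events
#'
#' Flags frame f when the smoothed nuclear PCNA mean at f+1 is at most
#' (1 - d_min) of its value at f — the abrupt drop caused by reporter
#' redistribution into the cytoplasm at nuclear envelope breakdown. When a
#' chromatin distribution-width series is available, a local maximum of it
#' within +/-2 frames is additionally required (chromatin condensation
#' check).
#'
#' @param series a \code{track_features} table or numeric nuclear-mean
#'   vector (length >= 3)
#' @param d_min minimum fractional drop (default 0.3)
#' @param use_chromatin require the chromatin width confirmation when the
#'   series carries a chromatin_sd column
#' @return integer vector of NEBD frames (possibly empty)
#' @export
detect_mitosis_events <- function(series, d_min = 0.3, use_chromatin = TRUE) {
  x <- series_smoothed(series)
  if (sum(!is.na(x)) < 3) stop("series must have at least 3 observed frames")
  n <- length(x)
  drop <- which(x[-1] <= (1 - d_min) * x[-n] & !is.na(x[-1]) & !is.na(x[-n]))
  if (length(drop) == 0) return(integer(0))
  csd <- if (is.data.frame(series)) {
    series$chromatin_sd_s %||% series$chromatin_sd
  }
  if (use_chromatin && !is.null(csd) && any(!is.na(csd))) {
    keep <- vapply(drop, function(f) {
      win <- max(1, f - 2):min(n, f + 2)
      v <- csd[win]
      if (all(is.na(v))) return(TRUE)
      peak <- win[which.max(v)]
      # the chromatin width must peak inside the window rather than at a
      # monotone edge continuing outside it
      lo <- max(1, f - 4):max(1, f - 3)
      ref <- csd[lo]
      max(v, na.rm = TRUE) > 1.2 * median(ref, na.rm = TRUE) ||
        all(is.na(ref))
    }, logical(1))
    drop <- drop[keep]
  }
  # consecutive drop frames belong to one event: keep the first
  if (length(drop) > 1) drop <- drop[c(TRUE, diff(drop) > 2)]
  as.integer(drop)
}

# Two-segment flat-then-ramp least-squares changepoint for
# y = a + s * max(0, t - tau): integer grid search over candidate knots,
# then continuous refinement of tau inside the best grid cell. The
# sub-frame refinement removes the one-frame quantization bias that an
# integer knot carries, which matters when onset lags between two
# reporters are compared. Returns tau on the frame scale (numeric).
flat_ramp_changepoint <- function(y, frames) {
  ok <- !is.na(y)
  y <- y[ok]; frames <- frames[ok]
  n <- length(y)
  if (n < 4) return(as.numeric(frames[1]))
  rss_at <- function(tau) {
    ramp <- pmax(0, frames - tau)
    fit <- .lm.fit(cbind(1, ramp), y)
    sum(fit$residuals^2)
  }
  grid_rss <- vapply(seq_len(n - 2), function(ci) rss_at(frames[ci]),
                     numeric(1))
  ci <- which.min(grid_rss)
  lo <- frames[max(1, ci - 1)]
  hi <- frames[min(n - 2, ci + 1)]
  if (hi <= lo) return(as.numeric(frames[ci]))
  opt <- optimize(rss_at, lower = lo, upper = hi)
  opt$minimum
}

#' Detect the G1/S transition (PCNA expression onset)
#'
#' The G1 baseline is the median smoothed nuclear PCNA over the first
#' \code{baseline_window} hours after birth. The candidate onset is the
#' first frame whose smoothed level exceeds baseline * (1 + rise_fraction)
#' and stays at or above that level for \code{persistence} frames; the
#' estimate is then refined by a two-segment flat-then-ramp least-squares
#' changepoint fit over `[birth, candidate + persistence]` and the
#' changepoint frame is returned.
#'
#' @param series \code{track_features} table or numeric nuclear-mean vector
#' @param birth_frame the track's birth frame (1-based)
#' @param params a [class_params()] object
#' @param frame_interval frame interval in minutes (taken from the series
#'   attribute when absent)
#' @return the G1/S frame, or NA with attribute \code{flag} when the track
#'   is too short or no onset exists
#' @export
detect_g1s <- function(series, birth_frame = 1L, params = class_params(),
                       frame_interval = NULL) {
  iv <- series_interval(series, frame_interval)
  x <- series_smoothed(series, params$w)
  n <- length(x)
  wf <- max(2L, as.integer(round(params$baseline_window * 60 / iv)))
  base_idx <- birth_frame:min(n, birth_frame + wf - 1L)
  obs <- which(!is.na(x[base_idx]))
  if (max(0, n - birth_frame + 1L) < wf || length(obs) < 2) {
    return(structure(NA_integer_, flag = "track_shorter_than_baseline_window"))
  }
  baseline <- median(x[base_idx], na.rm = TRUE)
  thr <- baseline * (1 + params$rise_fraction)
  m <- params$persistence
  cand <- NA_integer_
  run <- 0L
  for (f in seq(birth_frame, n)) {
    if (!is.na(x[f]) && x[f] >= thr) {
      run <- run + 1L
      if (run >= m) { cand <- f - m + 1L; break }
    } else {
      run <- 0L
    }
  }
  if (is.na(cand)) return(structure(NA_integer_, flag = "no_onset"))
  fit_idx <- birth_frame:min(n, cand + m)
  cp <- flat_ramp_changepoint(x[fit_idx], fit_idx)
  # the event frame is the first frame past the fitted onset time; the
  # continuous estimate is kept as an attribute for lag analyses
  structure(as.integer(max(birth_frame, ceiling(cp))), changepoint = cp)
}

#' Detect the S/G2 transition (end of S phase)
#'
#' The within-nucleus PCNA distribution width rises with replication-foci
#' growth and peaks at the end of S phase; the S/G2 frame is the argmax of
#' the smoothed width over the open interval (g1s_frame, nebd_frame), ties
#' broken toward the latest frame.
#'
#' @param series \code{track_features} table or numeric nuclear-SD vector
#' @param g1s_frame,nebd_frame bounding event frames (both required)
#' @return the S/G2 frame, or NA with attribute \code{flag} when the
#'   interval is shorter than 3 frames or the width carries no signal
#' @export
detect_sg2 <- function(series, g1s_frame, nebd_frame) {
  if (is.na(g1s_frame) || is.na(nebd_frame)) {
    return(structure(NA_integer_, flag = "missing_bounding_event"))
  }
  stopifnot(g1s_frame < nebd_frame)
  y <- if (is.data.frame(series)) {
    series$nuclear_sd_s %||% running_median(series$nuclear_sd, 3)
  } else {
    running_median(as.numeric(series), 3)
  }
  idx <- seq(g1s_frame + 1L, nebd_frame - 1L)
  idx <- idx[idx >= 1 & idx <= length(y)]
  v <- y[idx]
  if (sum(!is.na(v)) < 3) {
    return(structure(NA_integer_, flag = "interval_too_short"))
  }
  rng <- range(v, na.rm = TRUE)
  if (diff(rng) <= .Machine$double.eps * max(abs(rng), 1)) {
    return(structure(NA_integer_, flag = "flat_width"))
  }
  mx <- max(v, na.rm = TRUE)
  as.integer(max(idx[!is.na(v) & v == mx]))
}

#' Classify quiescence (G0) from gradual PCNA loss
#'
#' A track is quiescent when (a) no G1/S onset was detected and (b) the
#' smoothed nuclear PCNA falls below (1 - q_frac) of its birth-window level
#' along a non-increasing run (per-step tolerance \code{q_tol} of the
#' running minimum) lasting at least \code{t_q} hours. The decline onset is
#' the first frame of the qualifying run.
#'
#' @inheritParams detect_g1s
#' @param g1s_frame the result of [detect_g1s()] for this track (NA when
#'   absent)
#' @return list(quiescent, decline_onset_frame, flag); flag is
#'   \code{"track_too_short"} when the track does not span \code{t_q} hours
#' @export
classify_quiescence <- function(series, birth_frame = 1L,
                                g1s_frame = NA_integer_,
                                params = class_params(),
                                frame_interval = NULL) {
  iv <- series_interval(series, frame_interval)
  x <- series_smoothed(series, params$w)
  obs <- which(!is.na(x))
  span_h <- if (length(obs) > 1) (max(obs) - min(obs)) * iv / 60 else 0
  if (span_h < params$t_q) {
    return(list(quiescent = NA, decline_onset_frame = NA_integer_,
                flag = "track_too_short"))
  }
  if (!is.na(g1s_frame)) {
    return(list(quiescent = FALSE, decline_onset_frame = NA_integer_,
                flag = NA_character_))
  }
  wf <- max(2L, as.integer(round(params$baseline_window * 60 / iv)))
  base <- median(x[birth_frame:min(length(x), birth_frame + wf - 1L)],
                 na.rm = TRUE)
  need <- as.integer(ceiling(params$t_q * 60 / iv))
  # scan for the longest non-increasing (within tolerance) run
  runs <- integer(0)
  start <- NA_integer_; runmin <- Inf
  qualify_start <- NA_integer_
  for (f in seq(birth_frame, length(x))) {
    v <- x[f]
    if (is.na(v)) next
    if (is.na(start)) {
      start <- f; runmin <- v
      next
    }
    if (v <= runmin * (1 + params$q_tol)) {
      runmin <- min(runmin, v)
      if (f - start >= need - 1L && runmin < (1 - params$q_frac) * base) {
        qualify_start <- start
        break
      }
    } else {
      start <- f; runmin <- v
    }
  }
  if (!is.na(qualify_start)) {
    list(quiescent = TRUE, decline_onset_frame = qualify_start,
         flag = NA_character_)
  } else {
    list(quiescent = FALSE, decline_onset_frame = NA_integer_,
         flag = NA_character_)
  }
}

#' Annotate all cell-cycle events of one track
#'
#' Runs [detect_g1s()], [detect_mitosis_events()], [detect_sg2()] and
#' [classify_quiescence()] and checks event ordering.
#'
#' @param series a \code{track_features} table
#' @param birth_frame birth frame (1-based); tracks starting at frame 1 or
#'   created by a detected division have a known birth
#' @param division_frame division frame from the lineage (NA when the track
#'   does not divide)
#' @param params a [class_params()] object
#' @param frame_interval minutes (from series attribute when NULL)
#' @return an object of class \code{phase_annotation}: list with
#'   birth_frame, g1s_frame, sg2_frame, nebd_frame, division_frame,
#'   quiescent, decline_onset_frame, flags, and per-frame \code{phase}
#'   labels
#' @export
annotate_track <- function(series, birth_frame = 1L,
                           division_frame = NA_integer_,
                           params = class_params(), frame_interval = NULL) {
  iv <- series_interval(series, frame_interval)
  flags <- character(0)
  if (sum(series$present) < 3) {
    ann <- list(track_id = attr(series, "track_id"),
                birth_frame = birth_frame,
                g1s_frame = NA_integer_, sg2_frame = NA_integer_,
                nebd_frame = NA_integer_, division_frame = NA_integer_,
                quiescent = FALSE, decline_onset_frame = NA_integer_,
                flags = "track_too_short", n_frames = nrow(series),
                phase = rep("unknown", nrow(series)))
    class(ann) <- "phase_annotation"
    return(ann)
  }
  g1s <- detect_g1s(series, birth_frame, params, iv)
  if (!is.null(attr(g1s, "flag"))) flags <- c(flags, attr(g1s, "flag"))
  nebd_events <- detect_mitosis_events(series, params$d_min)
  nebd_events <- nebd_events[nebd_events > birth_frame]
  if (!is.na(g1s)) nebd_events <- nebd_events[nebd_events > g1s]
  nebd <- if (length(nebd_events) > 0) nebd_events[1] else NA_integer_
  sg2 <- if (!is.na(g1s) && !is.na(nebd) && g1s < nebd) {
    detect_sg2(series, g1s, nebd)
  } else {
    structure(NA_integer_, flag = "missing_bounding_event")
  }
  if (!is.null(attr(sg2, "flag"))) flags <- c(flags, attr(sg2, "flag"))
  q <- classify_quiescence(series, birth_frame, g1s, params, iv)
  if (!is.na(q$flag)) flags <- c(flags, q$flag)
  if (is.na(division_frame) && !is.na(nebd)) {
    # a track that ends shortly after its NEBD divides at its last frame
    last <- max(series$frame[series$present])
    if (last - nebd <= 6) division_frame <- last
  }
  events <- c(birth = birth_frame, g1s = as.integer(g1s),
              sg2 = as.integer(sg2), nebd = nebd,
              division = as.integer(division_frame))
  present <- events[!is.na(events)]
  ordered <- all(diff(present[intersect(c("birth", "g1s", "sg2", "nebd"),
                                        names(present))]) > 0)
  if (!is.na(events["nebd"]) && !is.na(events["division"]) &&
      events["division"] < events["nebd"]) {
    ordered <- FALSE
  }
  if (!ordered) flags <- c(flags, "event_order_violation")
  ann <- list(track_id = attr(series, "track_id"),
              birth_frame = birth_frame,
              g1s_frame = as.integer(g1s), sg2_frame = as.integer(sg2),
              nebd_frame = nebd, division_frame = as.integer(division_frame),
              quiescent = isTRUE(q$quiescent),
              decline_onset_frame = q$decline_onset_frame,
              flags = flags,
              n_frames = nrow(series))
  ann$phase <- if (ordered) {
    assign_phases(ann, nrow(series))
  } else {
    rep("unknown", nrow(series))
  }
  class(ann) <- "phase_annotation"
  ann
}

#' Per-frame phase labels from annotated events
#'
#' G1 = `[birth, g1s)`, S = `[g1s, sg2)`, G2 = `[sg2, nebd)`,
#' M = `[nebd, division]`, G0 from the quiescence-decline onset onward;
#' frames outside resolvable events are \code{"unknown"}.
#'
#' @param annotation a \code{phase_annotation} (or compatible list of event
#'   frames)
#' @param n_frames movie length in frames
#' @return character vector of per-frame phase labels
#' @export
assign_phases <- function(annotation, n_frames) {
  a <- annotation
  phase <- rep("unknown", n_frames)
  mark <- function(from, to, lab) {
    if (is.na(from) || is.na(to) || from > to) return()
    idx <- max(1, from):min(n_frames, to)
    phase[idx] <<- lab
  }
  if (isTRUE(a$quiescent)) {
    onset <- a$decline_onset_frame
    if (!is.na(onset)) {
      mark(a$birth_frame, onset - 1L, "G1")
      mark(onset, n_frames, "G0")
    }
    return(phase)
  }
  g1_end <- if (!is.na(a$g1s_frame)) a$g1s_frame - 1L else NA_integer_
  mark(a$birth_frame, g1_end, "G1")
  if (!is.na(a$g1s_frame)) {
    s_end <- if (!is.na(a$sg2_frame)) a$sg2_frame - 1L else NA_integer_
    mark(a$g1s_frame, s_end, "S")
  }
  if (!is.na(a$sg2_frame) && !is.na(a$nebd_frame)) {
    mark(a$sg2_frame, a$nebd_frame - 1L, "G2")
  }
  if (!is.na(a$nebd_frame)) {
    div <- if (!is.na(a$division_frame)) a$division_frame else a$nebd_frame
    mark(a$nebd_frame, div, "M")
  }
  phase
}

#' @export
print.phase_annotation <- function(x, ...) {
  ev <- c(birth = x$birth_frame, g1s = x$g1s_frame, sg2 = x$sg2_frame,
          nebd = x$nebd_frame, division = x$division_frame)
  cat("<phase_annotation> track", x$track_id %||% NA, "|",
      paste(names(ev), ifelse(is.na(ev), "-", ev), sep = "=", collapse = " "),
      if (x$quiescent) "| quiescent", "\n")
  invisible(x)
}

#' Align track series on a common event
#'
#' Each track's series is placed on a common time grid with t = 0 at the
#' chosen event; positions outside the track's span are NA (missing, never
#' extrapolated). Tracks lacking the event are excluded.
#'
#' @param feature_list named list of \code{track_features} tables (or plain
#'   numeric series)
#' @param annotations named list of \code{phase_annotation} objects (same
#'   names)
#' @param event one of \code{"birth"}, \code{"g1s"}, \code{"nebd"}
#' @param window half-width of the aligned grid in hours
#' @param frame_interval minutes
#' @param value column of the feature table to align (default
#'   \code{"nuclear_mean"})
#' @return matrix (tracks x time points) with a \code{time_h} attribute;
#'   excluded track ids are in attribute \code{excluded}
#' @export
align_tracks <- function(feature_list, annotations,
                         event = c("g1s", "birth", "nebd"),
                         window = 12, frame_interval = NULL,
                         value = "nuclear_mean") {
  event <- match.arg(event)
  ids <- names(feature_list)
  iv <- series_interval(feature_list[[1]], frame_interval)
  k <- as.integer(floor(window * 60 / iv))
  offsets <- seq(-k, k)
  keep <- character(0); excluded <- character(0)
  rows <- list()
  for (id in ids) {
    ann <- annotations[[id]]
    ef <- switch(event, birth = ann$birth_frame, g1s = ann$g1s_frame,
                 nebd = ann$nebd_frame)
    if (is.null(ef) || is.na(ef)) { excluded <- c(excluded, id); next }
    s <- feature_list[[id]]
    y <- if (is.data.frame(s)) s[[value]] else as.numeric(s)
    pos <- ef + offsets
    v <- rep(NA_real_, length(offsets))
    ok <- pos >= 1 & pos <= length(y)
    v[ok] <- y[pos[ok]]
    rows[[id]] <- v
    keep <- c(keep, id)
  }
  if (length(rows) == 0) {
    m <- matrix(numeric(0), 0, length(offsets))
  } else {
    m <- do.call(rbind, rows)
  }
  colnames(m) <- sprintf("%+.3f", offsets * iv / 60)
  rownames(m) <- keep
  attr(m, "time_h") <- offsets * iv / 60
  attr(m, "event") <- event
  attr(m, "excluded") <- excluded
  m
}
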