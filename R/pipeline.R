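# Pipeline orchestration: the in-R driver (process_movie) and the staged
# command interface (run_pipeline) that backs the CLI.

#' Run segmentation, tracking and classification on a stack
#'
#' The core analysis chain: per-frame segmentation on the chosen channel,
#' greedy overlap linking, gap closing, post-tracking local re-segmentation
#' of under-segmented (dim G1) frames, division detection with the NEBD
#' intensity-drop check, feature extraction on the PCNA channel, and event
#' annotation of every track.
#'
#' @param stack a \code{frame_stack}
#' @param seg_channel channel segmented (\code{"pcna"} or the chromatin
#'   channel)
#' @param feature_channel channel quantified for features (PCNA)
#' @param seg,link,classify parameter blocks
#' @param resegment run the post-tracking local re-segmentation refinement
#' @param progress print stage progress
#' @return list of class \code{movie_analysis}: labelmaps, tracks, lineage,
#'   features (per track), annotations (per track)
#' @export
process_movie <- function(stack, seg_channel = "pcna",
                          feature_channel = "pcna",
                          seg = seg_params(), link = link_params(),
                          classify = class_params(),
                          resegment = TRUE, progress = FALSE) {
  chans <- stack$channels
  if (!seg_channel %in% names(chans)) {
    stop("segmentation channel not in stack: ", seg_channel)
  }
  n_frames <- dim(chans[[seg_channel]])[3]
  say <- function(...) if (progress) message(...)
  say("segmenting ", n_frames, " frames on ", seg_channel)
  labelmaps <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    labelmaps[[f]] <- segment_nuclei(chans[[seg_channel]][, , f], seg, f)
  }
  say("linking")
  tracks <- link_frames(labelmaps, link)
  tracks <- close_gaps(tracks)
  if (resegment) {
    say("local re-segmentation")
    rasters <- lapply(seq_len(n_frames), function(f) chans[[seg_channel]][, , f])
    rs <- resegment_tracks(tracks, rasters, labelmaps, seg, link)
    tracks <- rs$tracks; labelmaps <- rs$labelmaps
  }
  say("features")
  features <- compute_all_features(tracks, stack, labelmaps,
                                   channel = feature_channel,
                                   chromatin_channel =
                                     if ("chromatin" %in% names(chans)) "chromatin",
                                   w = classify$w)
  say("divisions")
  nm_hint <- lapply(features, function(fr) fr$nuclear_mean)
  lineage <- detect_divisions(tracks, nm_hint, link)
  say("annotation")
  iv <- stack$frame_interval
  annotations <- list()
  te <- track_ends(tracks$detections)
  div_by_mother <- lineage$divisions
  for (id in names(features)) {
    tid <- as.integer(id)
    birth <- te$first[te$track_id == tid]
    division <- NA_integer_
    hit <- which(div_by_mother$mother == tid)
    if (length(hit) == 1) division <- div_by_mother$frame[hit]
    ann <- annotate_track(features[[id]], birth_frame = birth,
                          division_frame = division, params = classify,
                          frame_interval = iv)
    if (birth > 1 && is.na(lineage$parent[tid])) {
      ann$flags <- c(ann$flags, "birth_unobserved")
    }
    annotations[[id]] <- ann
  }
  structure(list(labelmaps = labelmaps, tracks = tracks, lineage = lineage,
                 features = features, annotations = annotations,
                 seg_channel = seg_channel, frame_interval = iv),
            class = "movie_analysis")
}

#' @export
print.movie_analysis <- function(x, ...) {
  n_div <- nrow(x$lineage$divisions)
  n_g1s <- sum(vapply(x$annotations, function(a) !is.na(a$g1s_frame), logical(1)))
  cat(sprintf("<movie_analysis> %d tracks (seg: %s), %d divisions, %d G1/S onsets\n",
              length(x$features), x$seg_channel, n_div, n_g1s))
  invisible(x)
}

#' Extract compartment measurements for every track, frame and channel
#'
#' @param analysis a \code{movie_analysis}
#' @param stack the \code{frame_stack} the analysis was run on
#' @param channels channels to measure (default: all non-chromatin)
#' @param ring list(r_inner, r_outer)
#' @param calibration a [calibration_config()]; rows for channels with a
#'   tagged fraction gain a \code{corrected} column (intensity / fraction)
#' @return long data.frame: track_id, frame, channel, compartment, raw,
#'   corrected
#' @export
measure_reporters <- function(analysis, stack,
                              channels = setdiff(names(stack$channels),
                                                 "chromatin"),
                              ring = list(r_inner = 2, r_outer = 6),
                              calibration = calibration_config()) {
  det <- analysis$tracks$detections
  out <- list()
  for (ch in channels) {
    for (f in sort(unique(det$frame))) {
      lm <- analysis$labelmaps[[f]]
      rows <- det[det$frame == f, ]
      if (nrow(rows) == 0 || nrow(lm$table) == 0) next
      res <- extract_frame_compartments(stack$channels[[ch]][, , f],
                                        lm$labels,
                                        ring$r_inner, ring$r_outer)
      m <- match(rows$label, res$label)
      fr <- calibration$tagged_fraction[ch]
      for (cmp in c("nuclear", "cytoplasmic")) {
        raw <- if (cmp == "nuclear") res$nuclear_mean[m] else res$cytoplasmic_mean[m]
        out[[length(out) + 1]] <- data.frame(
          track_id = rows$track_id, frame = f, channel = ch,
          compartment = cmp, raw = raw,
          corrected = if (!is.na(fr)) raw / fr else raw)
      }
    }
  }
  do.call(rbind, out)
}

#' Per-movie summary report
#'
#' Aggregates phase-length distributions, the quiescent fraction, the
#' cyclin D1 class I fraction and the sister correlation when computable.
#'
#' @param analysis a \code{movie_analysis}
#' @param d1_channel optional cyclin-D1-like channel measurements for
#'   class assignment (defaults to the PCNA feature series being skipped;
#'   class fractions are NA without a co-reporter)
#' @return list of class \code{movie_report}
#' @export
report_movie <- function(analysis, d1_channel = NULL) {
  iv <- analysis$frame_interval
  ann <- analysis$annotations
  g1 <- vapply(ann, function(a) {
    if (!is.na(a$g1s_frame)) (a$g1s_frame - a$birth_frame) * iv / 60 else NA_real_
  }, numeric(1))
  s_len <- vapply(ann, function(a) {
    if (!is.na(a$g1s_frame) && !is.na(a$sg2_frame))
      (a$sg2_frame - a$g1s_frame) * iv / 60 else NA_real_
  }, numeric(1))
  g2_len <- vapply(ann, function(a) {
    if (!is.na(a$sg2_frame) && !is.na(a$nebd_frame))
      (a$nebd_frame - a$sg2_frame) * iv / 60 else NA_real_
  }, numeric(1))
  decided <- vapply(ann, function(a) !"track_too_short" %in% a$flags, logical(1))
  quiescent <- vapply(ann, function(a) isTRUE(a$quiescent), logical(1))
  structure(list(
    n_tracks = length(ann),
    n_divisions = nrow(analysis$lineage$divisions),
    g1_hours = g1[!is.na(g1)],
    s_hours = s_len[!is.na(s_len)],
    g2_hours = g2_len[!is.na(g2_len)],
    quiescent_fraction = if (any(decided)) mean(quiescent[decided]) else NA_real_
  ), class = "movie_report")
}

#' @export
print.movie_report <- function(x, ...) {
  fmt <- function(v) if (length(v)) sprintf("%.1f +/- %.1f h (n=%d)",
                                            mean(v), sd(v), length(v)) else "n/a"
  cat("<movie_report>\n",
      sprintf("  tracks: %d, divisions: %d\n", x$n_tracks, x$n_divisions),
      sprintf("  G1: %s\n", fmt(x$g1_hours)),
      sprintf("  S:  %s\n", fmt(x$s_hours)),
      sprintf("  G2: %s\n", fmt(x$g2_hours)),
      sprintf("  quiescent fraction: %s\n",
              ifelse(is.na(x$quiescent_fraction), "n/a",
                     sprintf("%.2f", x$quiescent_fraction))), sep = "")
  invisible(x)
}

#' Run a pipeline stage
#'
#' Stages: \code{simulate} (writes a synthetic stack + ground truth),
#' \code{segment}, \code{track}, \code{classify}, \code{quantify},
#' \code{report}, or \code{all} (simulate when \code{config$sim} is set,
#' then the full chain). Outputs are CSV/TIFF/structured-text files under
#' \code{config$output_dir}, each carrying the config hash.
#'
#' @param command one of simulate, segment, track, classify, quantify,
#'   report, all
#' @param config a \code{pipeline_config} (or path to a YAML config)
#' @return exit status: 0 on success (invisibly); errors propagate unless
#'   \code{.capture = TRUE}
#' @param .capture return a nonzero status instead of throwing
#' @export
run_pipeline <- function(command = c("all", "simulate", "segment", "track",
                                     "classify", "quantify", "report"),
                         config = pipeline_config(), .capture = FALSE) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_pipeline_config(config)
  runner <- function() {
    out <- config$output_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    # provenance hash covers the scientific configuration, not the paths
    cfg_for_hash <- unclass(config)
    cfg_for_hash$output_dir <- NULL
    hash <- config_hash(cfg_for_hash)
    stack_dir <- file.path(out, "stack")
    need_sim <- command %in% c("simulate", "all") ||
      !file.exists(file.path(stack_dir, "metadata.yml"))
    if (need_sim && !is.null(config$sim)) {
      mov <- simulate_movie(config$sim)
      write_stack(mov$stack, stack_dir)
      write_label_maps(lapply(seq_along(mov$truth$labels), function(f) {
        label_map(mov$truth$labels[[f]], f)
      }), file.path(out, "truth_labels.tif"))
      write_versioned_csv(mov$truth$cells, file.path(out, "truth_cells.csv"),
                          hash)
      if (command == "simulate") return(0L)
    }
    stack <- read_stack(stack_dir, config)
    analysis <- process_movie(stack,
                              seg_channel = config$channels$pcna,
                              feature_channel = config$channels$pcna,
                              seg = config$seg, link = config$link,
                              classify = config$classify)
    write_label_maps(analysis$labelmaps, file.path(out, "labels.tif"))
    write_tracks_csv(analysis$lineage, file.path(out, "tracks.csv"), hash)
    write_lineage(analysis$lineage, file.path(out, "lineage.txt"))
    if (command %in% c("segment", "track")) return(0L)
    write_events_csv(analysis$annotations, file.path(out, "events.csv"), hash)
    write_phases_csv(analysis$annotations, file.path(out, "phases.csv"), hash)
    if (command == "classify") return(0L)
    meas <- measure_reporters(analysis, stack,
                              ring = config$ring,
                              calibration = config$calibration)
    write_versioned_csv(meas, file.path(out, "measurements.csv"), hash)
    if (command == "quantify") return(0L)
    rep <- report_movie(analysis)
    rpt <- data.frame(
      metric = c("n_tracks", "n_divisions", "g1_mean_h", "s_mean_h",
                 "g2_mean_h", "quiescent_fraction"),
      value = c(rep$n_tracks, rep$n_divisions,
                if (length(rep$g1_hours)) mean(rep$g1_hours) else NA,
                if (length(rep$s_hours)) mean(rep$s_hours) else NA,
                if (length(rep$g2_hours)) mean(rep$g2_hours) else NA,
                rep$quiescent_fraction))
    write_versioned_csv(rpt, file.path(out, "report.csv"), hash)
    # config echo for provenance
    yaml::write_yaml(list(hash = hash,
                          frame_interval = config$frame_interval,
                          channels = config$channels,
                          seed = config$seed),
                     file.path(out, "config_echo.yml"))
    0L
  }
  if (.capture) {
    status <- tryCatch(runner(), error = function(e) {
      message("pipeline error: ", conditionMessage(e)); 1L
    })
    invisible(status)
  } else {
    invisible(runner())
  }
}
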