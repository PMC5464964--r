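# File formats: multi-page TIFF stacks (one file per channel, float32),
# 16-bit TIFF label maps, CSV tables with versioned headers, a structured
# text lineage format, and a YAML config. All frame indices in files are
# 0-based; all times are hours. Every file written next to a config carries
# the producing config hash in the metadata echo.

#' Write a frame stack to disk
#'
#' One multi-page 16-bit TIFF per channel plus a \code{metadata.yml}
#' declaring channel roles, frame interval, pixel size and intensity scale.
#' Intensities are stored as value/scale on the 16-bit grid (quantization
#' step scale/65535 AFU); a write/read cycle is exactly idempotent.
#'
#' @param stack a \code{frame_stack}
#' @param dir output directory (created if needed)
#' @param scale intensity divisor applied before writing (values are stored
#'   as value/scale; chosen automatically as a power of two covering the
#'   data when NULL)
#' @return the directory, invisibly
#' @export
write_stack <- function(stack, dir, scale = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chans <- names(stack$channels)
  if (is.null(scale)) {
    mx <- max(vapply(stack$channels, max, numeric(1)))
    scale <- 2^ceiling(log2(max(mx, 1)))
  }
  for (ch in chans) {
    arr <- stack$channels[[ch]]
    pages <- lapply(seq_len(dim(arr)[3]), function(f) {
      pmin(pmax(arr[, , f] / scale, 0), 1)
    })
    tiff::writeTIFF(pages, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 16L)
  }
  meta <- list(channels = as.list(chans),
               frame_interval = stack$frame_interval,
               pixel_size = stack$pixel_size,
               n_frames = dim(stack$channels[[1]])[3],
               intensity_scale = scale)
  yaml::write_yaml(meta, file.path(dir, "metadata.yml"))
  invisible(dir)
}

#' Read a frame stack from disk
#'
#' Reads the per-channel TIFFs written by [write_stack()] and validates the
#' channel roles declared in \code{config} against what is present.
#'
#' @param dir directory holding \code{metadata.yml} and channel TIFFs
#' @param config optional pipeline config (list); when it declares channel
#'   roles (\code{channels} entry mapping role -> channel name), every
#'   declared channel must exist or an error names the missing role
#' @return a \code{frame_stack}
#' @export
read_stack <- function(dir, config = NULL) {
  metafile <- file.path(dir, "metadata.yml")
  if (!file.exists(metafile)) stop("no metadata.yml in ", dir)
  meta <- yaml::read_yaml(metafile)
  chans <- unlist(meta$channels)
  declared <- if (!is.null(config$channels)) unlist(config$channels) else chans
  roles <- names(declared) %||% declared
  missing <- !declared %in% chans | !file.exists(file.path(dir, paste0(declared, ".tif")))
  if (any(missing)) {
    stop("declared channel role(s) not present in stack: ",
         paste0(roles[missing], " (", declared[missing], ")", collapse = ", "))
  }
  depth <- integer(0)
  arrs <- list()
  for (ch in chans) {
    f <- file.path(dir, paste0(ch, ".tif"))
    if (!file.exists(f)) stop("channel file missing: ", f)
    info <- tiff::readTIFF(f, payload = FALSE, all = TRUE)
    if (is.data.frame(info)) {
      depth <- c(depth, unique(info$bits.per.sample))
    } else {
      depth <- c(depth, unique(vapply(info, function(p) p$bits.per.sample,
                                      numeric(1))))
    }
    pages <- tiff::readTIFF(f, all = TRUE)
    arr <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * meta$intensity_scale
    arrs[[ch]] <- arr
  }
  if (length(unique(depth)) > 1) {
    stop("mixed bit depths across channels: ", paste(unique(depth), collapse = ", "))
  }
  structure(list(channels = arrs,
                 frame_interval = meta$frame_interval,
                 pixel_size = meta$pixel_size,
                 times = frames_to_hours(seq_len(meta$n_frames),
                                         meta$frame_interval)),
            class = "frame_stack")
}

#' Write label maps as 16-bit TIFF
#'
#' @param labelmaps list of \code{label_map} objects
#' @param path output TIFF file (one page per frame)
#' @return path, invisibly
#' @export
write_label_maps <- function(labelmaps, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  pages <- lapply(labelmaps, function(lm) {
    if (max(lm$labels) > 65535) stop("label exceeds 16-bit range")
    lm$labels / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read label maps from a 16-bit TIFF
#'
#' @param path TIFF file written by [write_label_maps()]
#' @return list of \code{label_map} objects
#' @export
read_label_maps <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(seq_along(pages), function(f) {
    label_map(matrix(as.integer(round(pages[[f]] * 65535)),
                     nrow(pages[[f]]), ncol(pages[[f]])), f)
  })
}

csv_header_version <- "pcnatrack-csv-v1"

write_versioned_csv <- function(df, path, hash = NULL) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", csv_header_version,
                    if (!is.null(hash)) paste0(" config=", hash)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_versioned_csv <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Write the tracks table
#'
#' Columns: track_id, frame (0-based), label, centroid_row, centroid_col,
#' area, parent_track.
#'
#' @param lineage a \code{lineage} (or a bare \code{cell_tracks}, in which
#'   case parents are NA)
#' @param path CSV path
#' @param hash optional config hash echoed in the header
#' @return path, invisibly
#' @export
write_tracks_csv <- function(lineage, path, hash = NULL) {
  tracks <- if (inherits(lineage, "lineage")) lineage$tracks else lineage
  parent <- if (inherits(lineage, "lineage")) lineage$parent else NULL
  det <- tracks$detections
  det$parent_track <- if (!is.null(parent)) parent[det$track_id] else NA_integer_
  det$frame <- det$frame - 1L
  write_versioned_csv(det, path, hash)
}

#' Write per-track event annotations
#'
#' One row per track: birth, g1s, sg2, nebd, division (0-based frames),
#' quiescent flag, decline onset and quality flags.
#'
#' @param annotations named list of \code{phase_annotation}
#' @param path CSV path
#' @param hash optional config hash
#' @return path, invisibly
#' @export
write_events_csv <- function(annotations, path, hash = NULL) {
  f0 <- function(x) ifelse(is.na(x), NA_integer_, as.integer(x) - 1L)
  df <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(track_id = a$track_id %||% NA_integer_,
               birth = f0(a$birth_frame), g1s = f0(a$g1s_frame),
               sg2 = f0(a$sg2_frame), nebd = f0(a$nebd_frame),
               division = f0(a$division_frame),
               quiescent = a$quiescent,
               decline_onset = f0(a$decline_onset_frame),
               flags = paste(a$flags, collapse = ";"))
  }))
  write_versioned_csv(df, path, hash)
}

#' Write per-frame phase labels
#'
#' Long format: track_id, frame (0-based), phase.
#'
#' @inheritParams write_events_csv
#' @export
write_phases_csv <- function(annotations, path, hash = NULL) {
  df <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(track_id = a$track_id %||% NA_integer_,
               frame = seq_along(a$phase) - 1L, phase = a$phase)
  }))
  write_versioned_csv(df, path, hash)
}

#' Write the lineage as structured text
#'
#' One division record per line: \code{division <mother> <frame0> <dA> <dB>}.
#'
#' @param lineage a \code{lineage}
#' @param path output file
#' @return path, invisibly
#' @export
write_lineage <- function(lineage, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  lines <- c(paste0("# pcnatrack-lineage-v1"),
             sprintf("division %d %d %d %d",
                     lineage$divisions$mother, lineage$divisions$frame - 1L,
                     lineage$divisions$daughter_a, lineage$divisions$daughter_b))
  writeLines(lines, path)
  invisible(path)
}

#' Read a lineage text file
#'
#' @param path file written by [write_lineage()]
#' @return data.frame with columns mother, frame (1-based), daughter_a,
#'   daughter_b
#' @export
read_lineage <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(mother = integer(0), frame = integer(0),
                      daughter_a = integer(0), daughter_b = integer(0)))
  }
  parts <- do.call(rbind, strsplit(lines, " "))
  data.frame(mother = as.integer(parts[, 2]),
             frame = as.integer(parts[, 3]) + 1L,
             daughter_a = as.integer(parts[, 4]),
             daughter_b = as.integer(parts[, 5]))
}

#' Default pipeline configuration
#'
#' @param channels named list mapping roles (pcna, chromatin, co-reporter
#'   names) to channel names in the stack; the pcna role is mandatory
#' @param frame_interval minutes
#' @param pixel_size micrometres per pixel
#' @param seg,link,classify,sim parameter blocks
#' @param ring list(r_inner, r_outer) cytoplasmic ring radii in pixels
#' @param calibration a [calibration_config()]
#' @param seed integer seed
#' @param output_dir where pipeline stages write their outputs
#' @return a list of class \code{pipeline_config}
#' @export
pipeline_config <- function(channels = list(pcna = "pcna",
                                            chromatin = "chromatin"),
                            frame_interval = 10,
                            pixel_size = 1,
                            seg = seg_params(),
                            link = link_params(),
                            classify = class_params(),
                            sim = NULL,
                            ring = list(r_inner = 2, r_outer = 6),
                            calibration = calibration_config(),
                            seed = 1,
                            output_dir = "pcnatrack-out") {
  if (is.null(channels$pcna)) stop("the pcna channel role must be declared")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  cfg <- list(channels = channels, frame_interval = frame_interval,
              pixel_size = pixel_size, seg = seg, link = link,
              classify = classify, sim = sim, ring = ring,
              calibration = calibration, seed = as.integer(seed),
              output_dir = output_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified entries fall back to the package defaults of
#' [pipeline_config()]; parameter blocks (\code{seg}, \code{link},
#' \code{classify}, \code{sim}, \code{calibration}) are merged field-wise.
#'
#' @param path YAML file
#' @return a \code{pipeline_config}
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  block <- function(ctor, name) {
    args <- raw[[name]]
    if (is.null(args)) ctor() else do.call(ctor, args)
  }
  pipeline_config(
    channels = raw$channels %||% list(pcna = "pcna", chromatin = "chromatin"),
    frame_interval = raw$frame_interval %||% 10,
    pixel_size = raw$pixel_size %||% 1,
    seg = block(seg_params, "seg"),
    link = block(link_params, "link"),
    classify = block(class_params, "classify"),
    sim = if (!is.null(raw$sim)) do.call(simulation_params, raw$sim),
    ring = raw$ring %||% list(r_inner = 2, r_outer = 6),
    calibration = block(calibration_config, "calibration"),
    seed = raw$seed %||% 1,
    output_dir = raw$output_dir %||% dirname(path)
  )
}
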