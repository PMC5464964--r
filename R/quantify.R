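# Quantitative nuclear/cytoplasmic reporter extraction, calibration to
# total-protein estimates, and the population / single-cell statistics.

#' Calibration configuration
#'
#' Tagged-allele fractions convert single-allele fluorescence to
#' total-protein estimates (division by the fraction); defaults follow
#' quantitative western blot estimates: cyclin A2 expressed at similar
#' levels to the untagged allele (0.5), cyclin B1 tagged allele carrying
#' 30% of the total pool, cyclin D1 73%.
#'
#' @param tagged_fraction named numeric vector of fractions in (0, 1]
#' @param reference_exposure reference exposure time in ms
#' @param fluorophore_factor AFU per standard unit, from a
#'   purified-fluorophore calibration (1 = report AFU)
#' @return an object of class \code{calibration_config}
#' @export
calibration_config <- function(tagged_fraction = c(cycA2 = 0.5, cycB1 = 0.30,
                                                   cycD1 = 0.73),
                               reference_exposure = 100,
                               fluorophore_factor = 1) {
  if (any(tagged_fraction <= 0 | tagged_fraction > 1)) {
    stop("tagged_fraction values must lie in (0, 1]")
  }
  if (reference_exposure <= 0) stop("reference_exposure must be positive")
  structure(list(tagged_fraction = tagged_fraction,
                 reference_exposure = reference_exposure,
                 fluorophore_factor = fluorophore_factor),
            class = "calibration_config")
}

# All-label compartment extraction for one frame. Rings are annuli between
# dilations r_inner and r_outer of each nucleus; pixels inside any nucleus
# or claimed by more than one ring are dropped (conservative and
# deterministic). Background is the background_percentile of pixels outside
# all masks and rings.
extract_frame_compartments <- function(raster, labels, r_inner = 2,
                                       r_outer = 6,
                                       background_percentile = 5) {
  stopifnot(r_inner >= 0, r_outer > r_inner)
  ids <- sort(unique(labels[labels > 0]))
  dimr <- dim(raster)
  nuc_any <- labels > 0
  ring_count <- matrix(0L, dimr[1], dimr[2])
  ring_of <- vector("list", length(ids))
  names(ring_of) <- ids
  brush_in <- if (r_inner > 0) EBImage::makeBrush(2L * r_inner + 1L, "disc")
  brush_out <- EBImage::makeBrush(2L * r_outer + 1L, "disc")
  for (k in seq_along(ids)) {
    l <- ids[k]
    m <- labels == l
    # crop to a padded bounding box for speed
    idx <- which(m)
    rows <- ((idx - 1) %% dimr[1]) + 1; cols <- ((idx - 1) %/% dimr[1]) + 1
    r0 <- max(1, min(rows) - r_outer - 1); r1 <- min(dimr[1], max(rows) + r_outer + 1)
    c0 <- max(1, min(cols) - r_outer - 1); c1 <- min(dimr[2], max(cols) + r_outer + 1)
    sub <- m[r0:r1, c0:c1, drop = FALSE]
    douter <- as.matrix(EBImage::dilate(sub, brush_out))
    dinner <- if (r_inner > 0) as.matrix(EBImage::dilate(sub, brush_in)) else sub
    ringsub <- douter & !dinner
    ring <- matrix(FALSE, dimr[1], dimr[2])
    ring[r0:r1, c0:c1] <- ringsub
    ring_of[[k]] <- which(ring)
    ring_count[ring] <- ring_count[ring] + 1L
  }
  free <- !nuc_any & ring_count == 0L
  bg <- if (any(free)) {
    as.numeric(quantile(raster[free], background_percentile / 100))
  } else 0
  res <- data.frame(label = ids, nuclear_mean = NA_real_,
                    cytoplasmic_mean = NA_real_, nuclear_area = NA_integer_,
                    ring_area = NA_integer_, background = bg,
                    flag = NA_character_)
  for (k in seq_along(ids)) {
    l <- ids[k]
    res$nuclear_mean[k] <- mean(raster[labels == l]) - bg
    res$nuclear_area[k] <- sum(labels == l)
    ring_px <- ring_of[[k]]
    ring_px <- ring_px[!nuc_any[ring_px] & ring_count[ring_px] == 1L]
    res$ring_area[k] <- length(ring_px)
    if (length(ring_px) > 0) {
      res$cytoplasmic_mean[k] <- mean(raster[ring_px]) - bg
    } else {
      res$flag[k] <- "empty_ring"
    }
  }
  res
}

#' Extract nuclear and cytoplasmic mean intensities for one cell
#'
#' The nuclear mean is the background-subtracted mean over the nucleus mask;
#' the cytoplasmic mean is taken over the annulus between dilations
#' \code{r_inner} and \code{r_outer} of the nucleus, excluding all nuclei
#' and pixels contested by another cell's annulus. Background is the
#' \code{background_percentile} of pixels outside all masks and rings in
#' the frame.
#'
#' @param raster 2-D intensity matrix
#' @param labelmap a \code{label_map} (or plain integer label matrix)
#' @param label the cell's label in this frame
#' @param r_inner,r_outer ring dilation radii in pixels
#' @param background_percentile background percentile (default 5)
#' @return list(nuclear_mean, cytoplasmic_mean, background, flag);
#'   \code{cytoplasmic_mean} is NA with flag \code{"empty_ring"} when the
#'   annulus is empty after exclusions
#' @export
extract_compartment_intensities <- function(raster, labelmap, label,
                                            r_inner = 2, r_outer = 6,
                                            background_percentile = 5) {
  labels <- if (inherits(labelmap, "label_map")) labelmap$labels else labelmap
  if (!label %in% labels) stop("label ", label, " not present in label map")
  res <- extract_frame_compartments(raster, labels, r_inner, r_outer,
                                    background_percentile)
  row <- res[res$label == label, ]
  list(nuclear_mean = row$nuclear_mean,
       cytoplasmic_mean = row$cytoplasmic_mean,
       background = row$background,
       flag = row$flag)
}

#' Correct a single-allele intensity to a total-protein estimate
#'
#' With a fraction f of the protein pool carried by the tagged allele, the
#' total-protein estimate is intensity / f (e.g. cyclin B1 with f = 0.30:
#' an intensity of 3 estimates a total of 10).
#'
#' @param intensity measured intensity (AFU); vectorized
#' @param f tagged-allele fraction in (0, 1]
#' @return total-level estimate in AFU
#' @export
correct_for_tagged_fraction <- function(intensity, f) {
  if (length(f) != 1 || !is.finite(f) || f <= 0 || f > 1) {
    stop("tagged fraction must lie in (0, 1]")
  }
  intensity / f
}

#' Standardize an intensity across exposure times and fluorophores
#'
#' Linear exposure-normalized standardization:
#' intensity * (reference_exposure / exposure) / fluorophore_factor.
#'
#' @param intensity measured intensity (AFU); vectorized
#' @param exposure exposure time in ms (positive)
#' @param calib a [calibration_config()]
#' @return standardized intensity
#' @export
standardize_intensity <- function(intensity, exposure,
                                  calib = calibration_config()) {
  if (length(exposure) != 1 || !is.finite(exposure) || exposure <= 0) {
    stop("exposure must be a positive scalar")
  }
  intensity * (calib$reference_exposure / exposure) / calib$fluorophore_factor
}

#' Population summary of an aligned series matrix
#'
#' Per time point over non-missing values: mean, 2.5th and 97.5th
#' percentiles (the band containing 95% of the values) and the number of
#' contributing tracks.
#'
#' @param mat aligned matrix from [align_tracks()] (tracks x time points)
#' @return data.frame of class \code{population_summary} with columns
#'   time_h, mean, lower, upper, n
#' @export
population_summary <- function(mat) {
  if (sum(apply(!is.na(mat), 1, any)) < 2) {
    stop("need at least 2 contributing tracks")
  }
  time_h <- attr(mat, "time_h") %||% seq_len(ncol(mat))
  out <- data.frame(
    time_h = time_h,
    mean = apply(mat, 2, function(v) if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_),
    lower = apply(mat, 2, function(v) if (any(!is.na(v))) quantile(v, 0.025, na.rm = TRUE, names = FALSE) else NA_real_),
    upper = apply(mat, 2, function(v) if (any(!is.na(v))) quantile(v, 0.975, na.rm = TRUE, names = FALSE) else NA_real_),
    n = apply(mat, 2, function(v) sum(!is.na(v)))
  )
  rownames(out) <- NULL
  class(out) <- c("population_summary", "data.frame")
  out
}

#' Plot a population summary
#'
#' Mean curve with the 95%-of-values band.
#'
#' @param x a \code{population_summary}
#' @param ... passed to [graphics::plot()]
#' @export
plot.population_summary <- function(x, ...) {
  ok <- x$n >= 1
  plot(x$time_h[ok], x$mean[ok], type = "n",
       xlab = "time (h)", ylab = "intensity (AFU)", ...)
  band <- ok & x$n >= 2
  graphics::polygon(c(x$time_h[band], rev(x$time_h[band])),
                    c(x$lower[band], rev(x$upper[band])),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(x$time_h[ok], x$mean[ok], lwd = 2, col = "steelblue4")
  invisible(x)
}

#' Detect the onset of a nuclear-level decrease
#'
#' The onset is the first frame after birth starting a run of at least
#' \code{m} frames with negative smoothed first difference.
#'
#' @param series numeric series (AFU over frames) or a feature table column
#' @param birth_frame first frame considered
#' @param m run length in frames (default 3)
#' @param w smoothing window for the running median (default 3)
#' @return onset frame, or NA when the series never decreases persistently
#' @export
detect_decrease_onset <- function(series, birth_frame = 1L, m = 3, w = 3) {
  y <- running_median(as.numeric(series), w)
  d <- diff(y)
  neg <- d < 0
  neg[is.na(neg)] <- FALSE
  run <- 0L
  for (f in seq(max(1, birth_frame), length(d))) {
    if (neg[f]) {
      run <- run + 1L
      if (run >= m) return(as.integer(f - m + 1L))
    } else {
      run <- 0L
    }
  }
  NA_integer_
}

#' Least-squares slope of a series around a time point
#'
#' @param series numeric series (one value per frame)
#' @param t centre frame
#' @param window window width in frames (default 5, centred on t)
#' @param frame_interval minutes per frame (slope is returned per hour)
#' @return slope in AFU/hour, or NA with fewer than 3 observed points
#' @export
slope_at <- function(series, t, window = 5, frame_interval = 60) {
  y <- as.numeric(series)
  half <- floor(window / 2)
  idx <- max(1, t - half):min(length(y), t + half)
  ok <- !is.na(y[idx])
  if (sum(ok) < 3) return(NA_real_)
  hours <- frames_to_hours(idx[ok], frame_interval)
  unname(coef(lm.fit(cbind(1, hours), y[idx][ok]))[2])
}

#' Classify G1-phase cyclin D1 kinetics into class I or II
#'
#' Class I: nuclear cyclin D1 continuously decreasing since mitosis — the
#' smoothed series is non-increasing (each step at most +tau of the birth
#' level) from birth to the G1/S transition (or to the track end when G1/S
#' is absent) and shows a net decrease of more than tau of the birth level.
#' Everything else, including an exactly constant series, is class II.
#'
#' @param series numeric nuclear cyclin D1 series
#' @param birth_frame,g1s_frame bounding frames (g1s NA allowed)
#' @param tau tolerance as a fraction of the birth level (default 0.02)
#' @param w smoothing window
#' @return \code{"I"}, \code{"II"}, or NA with attribute flag when the G1
#'   span is shorter than 3 frames
#' @export
classify_cyclinD1_class <- function(series, birth_frame = 1L,
                                    g1s_frame = NA_integer_, tau = 0.02,
                                    w = 3) {
  y <- running_median(as.numeric(series), w)
  end <- if (!is.na(g1s_frame)) g1s_frame else length(y)
  idx <- seq(birth_frame, min(end, length(y)))
  y <- y[idx]
  ok <- !is.na(y)
  if (sum(ok) < 3) {
    return(structure(NA_character_, flag = "g1_span_too_short"))
  }
  y <- y[ok]
  lev0 <- y[1]
  tol <- tau * abs(lev0)
  non_increasing <- all(diff(y) <= tol)
  net_decrease <- (lev0 - y[length(y)]) > tol
  if (non_increasing && net_decrease) "I" else "II"
}

#' Sister-cell statistics
#'
#' For every division with both daughters tracked at least
#' \code{initial_window} hours: each sister's initial reporter level (mean
#' over the first \code{initial_window} h after birth), cyclin D1 kinetic
#' class, and G1 length. Summaries: Spearman's rho (average-rank ties)
#' between sister initial levels, the class-concordance fraction, and a
#' two-sided Mann-Whitney U test comparing G1 lengths between class I and
#' class II cells.
#'
#' @param lineage a \code{lineage} object
#' @param feature_list named list (track id) of feature tables or numeric
#'   nuclear series used for the initial level and classification
#' @param annotations named list of \code{phase_annotation} objects
#' @param initial_window hours after birth averaged for the initial level
#' @param frame_interval minutes
#' @param tau class-I tolerance passed to [classify_cyclinD1_class()]
#' @return list of class \code{sister_statistics}: \code{pairs} table,
#'   \code{rho} (NA with fewer than 3 pairs), \code{class_concordance},
#'   \code{mw} (the Mann-Whitney result or NULL)
#' @export
sister_statistics <- function(lineage, feature_list, annotations,
                              initial_window = 1, frame_interval = NULL,
                              tau = 0.02) {
  stopifnot(inherits(lineage, "lineage"))
  iv <- series_interval(feature_list[[1]], frame_interval)
  need <- as.integer(ceiling(initial_window * 60 / iv))
  get_series <- function(id) {
    s <- feature_list[[as.character(id)]]
    if (is.data.frame(s)) s$nuclear_mean else as.numeric(s)
  }
  rowlist <- list()
  for (k in seq_len(nrow(lineage$divisions))) {
    dv <- lineage$divisions[k, ]
    vals <- lapply(c(dv$daughter_a, dv$daughter_b), function(id) {
      ann <- annotations[[as.character(id)]]
      if (is.null(ann)) return(NULL)
      y <- get_series(id)
      birth <- ann$birth_frame
      idx <- birth:min(length(y), birth + need - 1L)
      if (sum(!is.na(y[idx])) < need) return(NULL)
      g1 <- if (!is.na(ann$g1s_frame)) (ann$g1s_frame - birth) * iv / 60 else NA_real_
      cls <- classify_cyclinD1_class(y, birth, ann$g1s_frame, tau)
      list(level = mean(y[idx], na.rm = TRUE), g1 = g1,
           class = as.character(cls))
    })
    if (any(vapply(vals, is.null, logical(1)))) next
    rowlist[[length(rowlist) + 1]] <- data.frame(
      mother = dv$mother, frame = dv$frame,
      daughter_a = dv$daughter_a, daughter_b = dv$daughter_b,
      level_a = vals[[1]]$level, level_b = vals[[2]]$level,
      g1_a = vals[[1]]$g1, g1_b = vals[[2]]$g1,
      class_a = vals[[1]]$class, class_b = vals[[2]]$class
    )
  }
  pairs <- if (length(rowlist) > 0) do.call(rbind, rowlist) else
    data.frame(mother = integer(0), frame = integer(0),
               daughter_a = integer(0), daughter_b = integer(0),
               level_a = numeric(0), level_b = numeric(0),
               g1_a = numeric(0), g1_b = numeric(0),
               class_a = character(0), class_b = character(0))
  rho <- if (nrow(pairs) >= 3) spearman_rho(pairs$level_a, pairs$level_b) else NA_real_
  conc <- if (nrow(pairs) > 0) {
    ok <- !is.na(pairs$class_a) & !is.na(pairs$class_b)
    if (any(ok)) mean(pairs$class_a[ok] == pairs$class_b[ok]) else NA_real_
  } else NA_real_
  cls <- c(pairs$class_a, pairs$class_b)
  g1 <- c(pairs$g1_a, pairs$g1_b)
  gi <- g1[cls == "I" & !is.na(cls) & !is.na(g1)]
  gii <- g1[cls == "II" & !is.na(cls) & !is.na(g1)]
  mw <- if (length(gi) >= 1 && length(gii) >= 1) mann_whitney(gi, gii) else NULL
  structure(list(pairs = pairs, rho = rho, class_concordance = conc, mw = mw),
            class = "sister_statistics")
}

#' @export
print.sister_statistics <- function(x, ...) {
  cat(sprintf("<sister_statistics> %d pairs | rho = %s | class concordance = %s\n",
              nrow(x$pairs),
              ifelse(is.na(x$rho), "NA", sprintf("%.3f", x$rho)),
              ifelse(is.na(x$class_concordance), "NA",
                     sprintf("%.2f", x$class_concordance))))
  if (!is.null(x$mw)) {
    cat(sprintf("  G1 length class I vs II: U = %g, p = %.4g (%s)\n",
                x$mw$U, x$mw$p.value, x$mw$method))
  }
  invisible(x)
}
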