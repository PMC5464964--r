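# Synthetic movie generator: simulation parameters and per-cell programs.
#
# A CellProgram is a deterministic description of one cell's reporter dynamics
# and geometry; the renderer realizes it as pixels. The defaults encode the
# reporter behaviour the package is designed to detect: nuclear PCNA stays
# low and flat through G1, ramps ~2-fold across S phase while replication
# foci grow, plateaus in G2, drops abruptly at nuclear envelope breakdown
# (NEBD) when the reporter disperses into the cytoplasm, and the cell then
# divides into two daughters. In quiescence (starvation) mode there is no S
# entry and PCNA declines exponentially instead.

#' Simulation parameters for the synthetic movie generator
#'
#' Defaults are the study conditions the pipeline is validated under:
#' G1 duration 7.7 +/- 3.0 h (truncated normal, floor 1 h), S phase 10 h
#' (the PCNA ramp spans S), G2 4 h, mitosis 0.5 h, a 2-fold PCNA plateau,
#' and co-reporter onsets lagging the PCNA ramp onset by 45 min
#' (cyclin-A2-like channel) and 16 min (hGem-like channel).
#'
#' @param n_cells number of founder cells placed at t = 0
#' @param n_frames number of frames in the movie
#' @param frame_interval frame interval in minutes
#' @param image_size c(rows, cols) image dimensions in pixels
#' @param nucleus_radius c(mean, sd) of the nuclear semi-major axis, pixels
#' @param background_level camera background offset, arbitrary fluorescence
#'   units (AFU)
#' @param gaussian_sd additive Gaussian read-noise SD in AFU (0 disables)
#' @param poisson_scale scale of the Poisson shot-noise component; rendered
#'   intensity x becomes rpois(x * scale) / scale (0 disables)
#' @param motion_sd per-frame random-walk step SD of nucleus centres, pixels
#' @param g1_mean,g1_sd mean and SD of the G1 duration distribution, hours
#' @param s_duration S-phase duration, hours (the PCNA ramp spans S)
#' @param g2_duration G2 duration, hours
#' @param m_duration NEBD-to-division duration, hours
#' @param pcna_base baseline nuclear PCNA level in AFU
#' @param pcna_plateau_fold plateau level as a fold of \code{pcna_base}
#' @param ramp_duration duration of the PCNA ramp, hours
#' @param chromatin_level nuclear level of the chromatin channel, AFU
#' @param coreporter_onset_offsets named numeric vector of co-reporter onset
#'   lags in minutes relative to the PCNA ramp onset; names become channel
#'   names. Use \code{NULL} for no co-reporter channels.
#' @param quiescent logical; simulate serum-starvation (G0) mode: no S entry,
#'   exponential PCNA decline
#' @param decline_halftime PCNA decline half-time in quiescence mode, hours
#' @param min_spacing minimum centre-to-centre distance between founder
#'   nuclei, pixels
#' @param seed integer RNG seed; identical parameters (including seed) give
#'   bit-identical movies and ground truth
#' @return an object of class \code{sim_params}
#' @export
simulation_params <- function(n_cells = 20,
                              n_frames = 121,
                              frame_interval = 10,
                              image_size = c(256, 256),
                              nucleus_radius = c(8, 0.8),
                              background_level = 10,
                              gaussian_sd = 2,
                              poisson_scale = 1,
                              motion_sd = 0.3,
                              g1_mean = 7.7,
                              g1_sd = 3.0,
                              s_duration = 10,
                              g2_duration = 4,
                              m_duration = 0.5,
                              pcna_base = 100,
                              pcna_plateau_fold = 2,
                              ramp_duration = 10,
                              chromatin_level = 120,
                              coreporter_onset_offsets = c(cycA2 = 45, hGem = 16),
                              quiescent = FALSE,
                              decline_halftime = 16,
                              min_spacing = NULL,
                              seed = 1) {
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (g1_mean <= 0) stop("distribution mean must be positive (g1_mean)")
  if (pcna_plateau_fold < 1) stop("pcna_plateau_fold must be >= 1")
  if (any(c(s_duration, g2_duration, m_duration) <= 0)) {
    stop("phase durations must be positive")
  }
  if (!is.null(coreporter_onset_offsets) && length(coreporter_onset_offsets) &&
      is.null(names(coreporter_onset_offsets))) {
    stop("coreporter_onset_offsets must be named by channel")
  }
  min_spacing <- min_spacing %||% (5 * nucleus_radius[1])
  # capacity check: founders must fit without overlap at t = 0
  if (n_cells * min_spacing^2 > 1.6 * prod(image_size)) {
    stop("image_size too small to hold ", n_cells,
         " non-overlapping nuclei at spacing ", min_spacing)
  }
  p <- list(n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
            frame_interval = frame_interval, image_size = as.integer(image_size),
            nucleus_radius = nucleus_radius, background_level = background_level,
            gaussian_sd = gaussian_sd, poisson_scale = poisson_scale,
            motion_sd = motion_sd, g1_mean = g1_mean, g1_sd = g1_sd,
            s_duration = s_duration, g2_duration = g2_duration,
            m_duration = m_duration, pcna_base = pcna_base,
            pcna_plateau_fold = pcna_plateau_fold, ramp_duration = ramp_duration,
            chromatin_level = chromatin_level,
            coreporter_onset_offsets = coreporter_onset_offsets,
            quiescent = quiescent, decline_halftime = decline_halftime,
            min_spacing = min_spacing, seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

#' Construct a single cell program
#'
#' Low-level constructor; most users call [build_cell_program()] (which draws
#' durations from the distributions in a [simulation_params()] object) or
#' [simulate_movie()]. With all defaults the ramp onset falls 8--10 h after
#' birth and the plateau is 2-fold over baseline.
#'
#' @param birth_time birth (end of the mother's mitosis), hours
#' @param g1_duration,s_duration,g2_duration,m_duration phase durations, hours
#' @param ramp_start_offset PCNA ramp onset, hours after birth; defaults to
#'   \code{g1_duration}, or a uniform draw in `[8, 10]` when neither is given
#' @param ramp_duration ramp duration in hours; 0 gives a step at S begin
#' @param pcna_base,pcna_plateau_fold baseline PCNA (AFU) and plateau fold
#' @param center,radii,angle nucleus geometry: centre (row, col) in pixels,
#'   semi-axes in pixels, orientation in radians
#' @param quiescent logical quiescence-mode flag
#' @param decline_onset,decline_halftime quiescence decline onset (hours) and
#'   exponential half-time (hours)
#' @param coreporters named list of co-reporter programs, each a list with
#'   \code{onset_time} (hours), \code{base}, \code{slope} (AFU/h),
#'   \code{cyto} (AFU)
#' @param cell_id,parent_id integer identifiers (parent NA for founders)
#' @return an object of class \code{cell_program}
#' @export
cell_program <- function(birth_time = 0,
                         g1_duration = NULL,
                         s_duration = 10,
                         g2_duration = 4,
                         m_duration = 0.5,
                         ramp_start_offset = NULL,
                         ramp_duration = 10,
                         pcna_base = 100,
                         pcna_plateau_fold = 2,
                         center = c(64, 64),
                         radii = c(8, 7),
                         angle = 0,
                         quiescent = FALSE,
                         decline_onset = birth_time,
                         decline_halftime = 16,
                         coreporters = list(),
                         cell_id = 1L,
                         parent_id = NA_integer_) {
  if (is.null(g1_duration) && is.null(ramp_start_offset)) {
    ramp_start_offset <- runif(1, 8, 10)
    g1_duration <- ramp_start_offset
  } else if (is.null(ramp_start_offset)) {
    ramp_start_offset <- g1_duration
  } else if (is.null(g1_duration)) {
    g1_duration <- ramp_start_offset
  }
  if (any(c(g1_duration, s_duration, g2_duration, m_duration) <= 0)) {
    stop("all phase durations must be positive")
  }
  if (pcna_plateau_fold < 1) stop("pcna_plateau_fold must be >= 1")
  if (ramp_duration < 0) stop("ramp_duration must be >= 0")
  nebd_time <- birth_time + g1_duration + s_duration + g2_duration
  division_time <- nebd_time + m_duration
  stopifnot(birth_time < birth_time + ramp_start_offset,
            birth_time + ramp_start_offset < nebd_time,
            nebd_time < division_time)
  p <- list(cell_id = as.integer(cell_id), parent_id = as.integer(parent_id),
            birth_time = birth_time, g1_duration = g1_duration,
            s_duration = s_duration, g2_duration = g2_duration,
            m_duration = m_duration, ramp_start_offset = ramp_start_offset,
            ramp_duration = ramp_duration, pcna_base = pcna_base,
            pcna_plateau_fold = pcna_plateau_fold,
            s_begin = birth_time + ramp_start_offset,
            s_end = birth_time + ramp_start_offset + s_duration,
            nebd_time = nebd_time, division_time = division_time,
            center = center, radii = radii, angle = angle,
            quiescent = quiescent, decline_onset = decline_onset,
            decline_halftime = decline_halftime,
            coreporters = coreporters,
            foci_count_range = c(4, 10),
            foci_sigma_range = c(1, 1.3),
            foci_fraction_range = c(0, 0.5),
            # persistent foci layout: positions uniform over the whole
            # nucleus (unit-ellipse coordinates), drawn once per cell; the
            # first count(t) are active at time t. Uniform coverage keeps
            # the nuclear mean unbiased when statistics are taken over any
            # sub-region of the nucleus.
            foci_uv = {
              th <- runif(24, 0, 2 * pi)
              rad <- sqrt(runif(24))
              cbind(u = rad * cos(th), v = rad * sin(th))
            })
  class(p) <- "cell_program"
  p
}

#' Draw a cell program from simulation parameters
#'
#' G1 duration is drawn from a truncated normal (mean \code{g1_mean}, SD
#' \code{g1_sd}, floor 1 h); S, G2 and M durations are fixed by the
#' parameters; the PCNA ramp onset coincides with S begin. Co-reporter
#' programs are created for every entry of \code{coreporter_onset_offsets},
#' switching on at the programmed lag after the PCNA ramp onset. Uses the
#' current RNG state; seed control lives in [simulate_movie()].
#'
#' @param params a [simulation_params()] object
#' @param birth_time birth time in hours
#' @param center,radii,angle nucleus geometry (drawn when NULL)
#' @param cell_id,parent_id identifiers
#' @return a [cell_program()] object
#' @export
build_cell_program <- function(params, birth_time = 0, center = NULL,
                               radii = NULL, angle = NULL,
                               cell_id = 1L, parent_id = NA_integer_) {
  stopifnot(inherits(params, "sim_params"))
  g1 <- rtruncnorm(1, params$g1_mean, params$g1_sd, floor = 1)
  if (is.null(radii)) {
    a <- max(3, rnorm(1, params$nucleus_radius[1], params$nucleus_radius[2]))
    ratio <- runif(1, 1.0, 1.3)
    radii <- c(a, a / ratio)
  }
  if (is.null(angle)) angle <- runif(1, 0, pi)
  if (is.null(center)) center <- params$image_size / 2
  s_begin <- birth_time + g1
  cor_prog <- list()
  offs <- params$coreporter_onset_offsets
  for (nm in names(offs)) {
    # basal level pre-onset, linear accumulation after onset until NEBD
    cor_prog[[nm]] <- list(onset_time = s_begin + offs[[nm]] / 60,
                           base = if (nm == "hGem") 10 else 20,
                           slope = if (nm == "hGem") 10 else 12.5,
                           cyto = if (nm == "hGem") 5 else 10)
  }
  decline_onset <- if (params$quiescent) birth_time + runif(1, 0, 2) else birth_time
  prog <- cell_program(birth_time = birth_time, g1_duration = g1,
               s_duration = params$s_duration, g2_duration = params$g2_duration,
               m_duration = params$m_duration,
               ramp_duration = params$ramp_duration,
               pcna_base = params$pcna_base,
               pcna_plateau_fold = params$pcna_plateau_fold,
               center = center, radii = radii, angle = angle,
               quiescent = params$quiescent, decline_onset = decline_onset,
               decline_halftime = params$decline_halftime,
               coreporters = cor_prog, cell_id = cell_id,
               parent_id = parent_id)
  attr(prog, "chromatin_level") <- params$chromatin_level
  prog
}

# True programmed nuclear level of a channel at time t (hours). Vectorized
# over t. NA outside the cell's lifetime.
program_nuclear_level <- function(program, channel, t) {
  p <- program
  alive <- t >= p$birth_time & (p$quiescent | t < p$division_time)
  out <- rep(NA_real_, length(t))
  if (channel == "pcna") {
    if (p$quiescent) {
      lev <- p$pcna_base *
        2^(-pmax(0, t - p$decline_onset) / p$decline_halftime)
    } else {
      plateau <- p$pcna_base * p$pcna_plateau_fold
      lev <- if (p$ramp_duration == 0) {
        ifelse(t < p$s_begin, p$pcna_base, plateau)
      } else {
        ifelse(t < p$s_begin, p$pcna_base,
               pmin(plateau, p$pcna_base +
                      (plateau - p$pcna_base) *
                      (t - p$s_begin) / p$ramp_duration))
      }
      # NEBD: reporter redistributes into the cytoplasm; the nuclear region
      # retains 45% of its pre-NEBD mean until division
      lev <- ifelse(t >= p$nebd_time, 0.45 * plateau, lev)
    }
  } else if (channel == "chromatin") {
    lev <- rep(attr(program, "chromatin_level") %||% 120, length(t))
  } else {
    cp <- p$coreporters[[channel]]
    if (is.null(cp)) return(out)
    lev <- cp$base + pmax(0, t - cp$onset_time) * cp$slope
    if (!p$quiescent) lev <- ifelse(t >= p$nebd_time, cp$base, lev)
  }
  out[alive] <- lev[alive]
  out
}

# True programmed cytoplasmic level of a channel at time t (hours).
program_cyto_level <- function(program, channel, t) {
  p <- program
  alive <- t >= p$birth_time & (p$quiescent | t < p$division_time)
  out <- rep(NA_real_, length(t))
  if (channel == "pcna") {
    # interphase PCNA is predominantly nuclear; at NEBD the reporter
    # disperses cell-wide
    lev <- rep(0.03 * p$pcna_base, length(t))
    if (!p$quiescent) {
      lev <- ifelse(t >= p$nebd_time,
                    0.2 * p$pcna_base * p$pcna_plateau_fold, lev)
    }
  } else if (channel == "chromatin") {
    lev <- rep(0, length(t))
  } else {
    cp <- p$coreporters[[channel]]
    if (is.null(cp)) return(out)
    lev <- rep(cp$cyto, length(t))
  }
  out[alive] <- lev[alive]
  out
}

# Replication-foci schedule at time t: spot count, spot sigma (px) and the
# fraction of total nuclear signal concentrated in foci all interpolate
# across S-phase progress, so foci start small and sparse and end larger and
# brighter. Foci redistribute nuclear signal rather than add to it: the
# nuclear mean stays at the programmed level while the within-nucleus
# distribution width grows through S phase.
foci_state <- function(program, t) {
  p <- program
  if (p$quiescent || t < p$s_begin || t >= p$s_end) {
    return(list(count = 0L, radius = 0, fraction = 0))
  }
  prog <- (t - p$s_begin) / p$s_duration
  cr <- p$foci_count_range %||% c(4, 10)
  sr <- p$foci_sigma_range %||% c(1, 1.3)
  fr <- p$foci_fraction_range %||% c(0, 0.5)
  list(count = as.integer(round(cr[1] + diff(cr) * prog)),
       radius = sr[1] + diff(sr) * prog,
       fraction = fr[1] + diff(fr) * prog)
}

#' @export
print.cell_program <- function(x, ...) {
  cat("<cell_program> id", x$cell_id,
      if (!is.na(x$parent_id)) paste0("(daughter of ", x$parent_id, ")"), "\n")
  if (x$quiescent) {
    cat(sprintf("  quiescent; decline onset %.2f h, half-time %.1f h\n",
                x$decline_onset, x$decline_halftime))
  } else {
    cat(sprintf("  birth %.2f h | S %.2f-%.2f h | NEBD %.2f h | division %.2f h\n",
                x$birth_time, x$s_begin, x$s_end, x$nebd_time, x$division_time))
  }
  invisible(x)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("<sim_params> %d cells, %d frames @ %g min, %dx%d px%s\n",
              x$n_cells, x$n_frames, x$frame_interval,
              x$image_size[1], x$image_size[2],
              if (x$quiescent) " [quiescence mode]" else ""))
  invisible(x)
}
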