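# Rendering of cell programs into multi-channel rasters, and the full movie
# simulator with ground truth.

# Channels rendered for a parameter set: PCNA and chromatin always, plus any
# configured co-reporters.
sim_channels <- function(params) {
  c("pcna", "chromatin", names(params$coreporter_onset_offsets))
}

#' Render one frame of a synthetic movie
#'
#' Realizes a list of cell programs as a multi-channel raster at time
#' \code{t}. Nuclei are filled ellipses; the PCNA channel carries replication
#' foci (Gaussian spots) during S phase and shows the NEBD redistribution
#' drop during M; the chromatin channel condenses to a smaller, brighter
#' region during M (raising its within-nucleus pixel spread); co-reporter
#' channels follow their onset programs. Noise is a Poisson component scaled
#' by \code{poisson_scale} plus additive Gaussian read noise; both can be
#' disabled. Uses the current RNG state (seed control in
#' [simulate_movie()]).
#'
#' @param programs list of [cell_program()] objects
#' @param t frame time in hours
#' @param params a [simulation_params()] object
#' @param centers optional matrix (cells x 2) of nucleus centres overriding
#'   the programs' static centres (used by [simulate_movie()] for motion)
#' @return list with \code{channels} (named list of matrices, AFU) and
#'   \code{labels} (integer matrix; 0 = background, i = programs index,
#'   every rendered nucleus pixel belongs to exactly one label)
#' @export
render_frame <- function(programs, t, params, centers = NULL) {
  dim <- params$image_size
  chans <- sim_channels(params)
  canvas <- lapply(chans, function(ch) {
    matrix(params$background_level, dim[1], dim[2])
  })
  names(canvas) <- chans
  labels <- matrix(0L, dim[1], dim[2])
  # distance-to-centre map for label conflict resolution
  labdist <- matrix(Inf, dim[1], dim[2])

  live <- which(vapply(programs, function(p) {
    t >= p$birth_time && (p$quiescent || t < p$division_time)
  }, logical(1)))

  for (i in live) {
    p <- programs[[i]]
    ctr <- if (is.null(centers)) p$center else centers[i, ]
    in_m <- !p$quiescent && t >= p$nebd_time

    # cytoplasm: a larger concentric ellipse; contributions add
    cyt_px <- ellipse_pixels(ctr, p$radii * 1.8, p$angle, dim)
    nuc_px <- ellipse_pixels(ctr, p$radii, p$angle, dim)
    if (nrow(nuc_px) == 0) next
    nuc_idx <- nuc_px[, 1] + (nuc_px[, 2] - 1L) * dim[1]
    cyt_idx <- cyt_px[, 1] + (cyt_px[, 2] - 1L) * dim[1]

    for (ch in chans) {
      cyto <- program_cyto_level(p, ch, t)
      nuc <- program_nuclear_level(p, ch, t)
      if (!is.na(cyto) && cyto > 0) {
        canvas[[ch]][cyt_idx] <- canvas[[ch]][cyt_idx] + cyto
      }
      if (is.na(nuc)) next
      if (ch == "chromatin" && in_m) {
        # condensed chromatin: 50% area, 2x intensity inside the nucleus
        canvas[[ch]][nuc_idx] <- params$background_level + 0.2 * nuc
        cond <- ellipse_pixels(ctr, p$radii * sqrt(0.5), p$angle, dim)
        if (nrow(cond) > 0) {
          cond_idx <- cond[, 1] + (cond[, 2] - 1L) * dim[1]
          canvas[[ch]][cond_idx] <- params$background_level + 2 * nuc
        }
      } else {
        # nuclear signal replaces the cytoplasmic contribution
        canvas[[ch]][nuc_idx] <- params$background_level + nuc
      }
    }

    # replication foci on the PCNA channel: a growing fraction of the
    # nuclear signal is concentrated into Gaussian spots (redistribution, so
    # the nuclear mean stays at the programmed level while the pixel SD
    # rises through S phase)
    fs <- foci_state(p, t)
    if (fs$count > 0 && fs$fraction > 0) {
      lev <- program_nuclear_level(p, "pcna", t)
      if (!is.na(lev) && lev > 0) {
        spot <- numeric(length(nuc_idx))
        ca <- cos(p$angle); sa <- sin(p$angle)
        nlay <- nrow(p$foci_uv)
        for (k in seq_len(min(fs$count, nlay))) {
          u <- p$foci_uv[k, 1] * p$radii[1]
          v <- p$foci_uv[k, 2] * p$radii[2]
          fc <- c(ctr[1] + u * ca - v * sa, ctr[2] + u * sa + v * ca)
          d2 <- (nuc_px[, 1] - fc[1])^2 + (nuc_px[, 2] - fc[2])^2
          spot <- spot + exp(-d2 / (2 * fs$radius^2))
        }
        tot <- sum(spot)
        if (tot > 0) {
          scale <- fs$fraction * lev * length(nuc_idx) / tot
          canvas[["pcna"]][nuc_idx] <- params$background_level +
            (1 - fs$fraction) * lev + scale * spot
        }
      }
    }

    # truth labels; overlap resolved to the nearer centre
    d2 <- (nuc_px[, 1] - ctr[1])^2 + (nuc_px[, 2] - ctr[2])^2
    take <- d2 < labdist[nuc_idx]
    labels[nuc_idx[take]] <- p$cell_id
    labdist[nuc_idx[take]] <- d2[take]
  }

  # noise
  for (ch in chans) {
    x <- canvas[[ch]]
    if (params$poisson_scale > 0) {
      x <- matrix(rpois(length(x), pmax(x, 0) * params$poisson_scale) /
                    params$poisson_scale, dim[1], dim[2])
    }
    if (params$gaussian_sd > 0) {
      x <- x + matrix(rnorm(length(x), 0, params$gaussian_sd), dim[1], dim[2])
    }
    canvas[[ch]] <- pmax(x, 0)
  }
  list(channels = canvas, labels = labels)
}

# Place founder centres with a minimum pairwise spacing; rejection sampling
# with a retry budget.
place_founders <- function(n, dim, spacing, margin, retries = 5000) {
  centers <- matrix(NA_real_, n, 2)
  placed <- 0
  for (try in seq_len(retries)) {
    cand <- c(runif(1, margin, dim[1] - margin), runif(1, margin, dim[2] - margin))
    if (placed == 0 ||
        min((centers[seq_len(placed), 1] - cand[1])^2 +
            (centers[seq_len(placed), 2] - cand[2])^2) >= spacing^2) {
      placed <- placed + 1
      centers[placed, ] <- cand
      if (placed == n) return(centers)
    }
  }
  stop("could not place ", n, " non-overlapping nuclei within the retry budget")
}

#' Simulate a ground-truthed synthetic time-lapse movie
#'
#' Generates founder cell programs from \code{params}, recursively spawns
#' daughter programs at each division falling inside the movie span, renders
#' every frame, and records complete ground truth: per-frame true label
#' maps, the true lineage, per-cell true event times (birth, S begin = ramp
#' onset, S end, NEBD, division, quiescence-decline onset) and per-cell true
#' nuclear/cytoplasmic level series for every channel. Fully deterministic
#' under \code{params$seed}.
#'
#' @param params a [simulation_params()] object
#' @return a list of class \code{synthetic_movie} with elements
#'   \describe{
#'     \item{stack}{a \code{frame_stack}: named list of H x W x T channel
#'       arrays plus acquisition metadata}
#'     \item{truth}{a list with \code{labels} (list of integer label
#'       matrices), \code{cells} (per-cell event table, hours),
#'       \code{levels} (per channel, \code{nuclear} and \code{cyto}
#'       matrices of programmed levels, frames x cells), and
#'       \code{centers} (T x cells x 2 array of true centres)}
#'     \item{programs}{the realized cell programs}
#'     \item{params}{the input parameters}
#'   }
#' @export
simulate_movie <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    dim <- params$image_size
    t_end <- frames_to_hours(params$n_frames, params$frame_interval)
    margin <- 2.2 * params$nucleus_radius[1]
    centers0 <- place_founders(params$n_cells, dim, params$min_spacing, margin)

    times <- frames_to_hours(seq_len(params$n_frames), params$frame_interval)
    programs <- list()
    paths <- list()
    # random-walk centre path for one program, frozen from its birth frame;
    # clamped so the whole cell (cytoplasm included) stays in view
    walk_path <- function(p) {
      alive <- which(times >= p$birth_time &
                       (p$quiescent | times < p$division_time))
      if (length(alive) == 0) return(NULL)
      bnd <- 1.9 * max(p$radii)
      steps_r <- c(0, rnorm(length(alive) - 1, 0, params$motion_sd))
      steps_c <- c(0, rnorm(length(alive) - 1, 0, params$motion_sd))
      cbind(frame = alive,
            row = pmin(pmax(p$center[1] + cumsum(steps_r), bnd),
                       dim[1] - bnd),
            col = pmin(pmax(p$center[2] + cumsum(steps_c), bnd),
                       dim[2] - bnd))
    }
    for (i in seq_len(params$n_cells)) {
      programs[[i]] <- build_cell_program(params, birth_time = 0,
                                          center = centers0[i, ],
                                          cell_id = i)
      paths[[i]] <- walk_path(programs[[i]])
    }
    # spawn daughters for divisions inside the movie span, placed at the
    # mother's position at division time
    queue <- seq_len(params$n_cells)
    next_id <- params$n_cells + 1L
    while (length(queue) > 0) {
      i <- queue[1]; queue <- queue[-1]
      p <- programs[[i]]
      if (p$quiescent || p$division_time >= t_end || is.null(paths[[i]])) next
      last <- nrow(paths[[i]])
      mother_pos <- paths[[i]][last, c("row", "col")]
      theta <- runif(1, 0, 2 * pi)
      off <- 1.35 * mean(p$radii)
      # pick a division axis keeping both daughters in bounds (a clamped
      # daughter would collapse back onto the mother's position)
      bnd_d <- 1.9 * max(p$radii) / sqrt(2)
      for (k in 0:7) {
        cand <- theta + k * pi / 4
        dvec <- c(cos(cand), sin(cand)) * off
        ok <- all(mother_pos + dvec >= bnd_d) &&
          all(mother_pos + dvec <= dim - bnd_d) &&
          all(mother_pos - dvec >= bnd_d) &&
          all(mother_pos - dvec <= dim - bnd_d)
        if (ok) break
      }
      for (d in 1:2) {
        ctr <- mother_pos + if (d == 1) dvec else -dvec
        ctr <- pmin(pmax(ctr, bnd_d), dim - bnd_d)
        dp <- build_cell_program(params, birth_time = p$division_time,
                                 center = ctr, radii = p$radii / sqrt(2),
                                 angle = p$angle, cell_id = next_id,
                                 parent_id = p$cell_id)
        programs[[next_id]] <- dp
        paths[[next_id]] <- walk_path(dp)
        queue <- c(queue, next_id)
        next_id <- next_id + 1L
      }
    }
    n_all <- length(programs)

    centers <- array(NA_real_, c(params$n_frames, n_all, 2))
    for (i in seq_len(n_all)) {
      if (is.null(paths[[i]])) next
      centers[paths[[i]][, "frame"], i, 1] <- paths[[i]][, "row"]
      centers[paths[[i]][, "frame"], i, 2] <- paths[[i]][, "col"]
    }

    chans <- sim_channels(params)
    stack <- lapply(chans, function(ch) array(0, c(dim[1], dim[2], params$n_frames)))
    names(stack) <- chans
    labels <- vector("list", params$n_frames)
    for (f in seq_len(params$n_frames)) {
      ctrs <- matrix(centers[f, , ], ncol = 2)
      fr <- render_frame(programs, times[f], params, centers = ctrs)
      for (ch in chans) stack[[ch]][, , f] <- fr$channels[[ch]]
      labels[[f]] <- fr$labels
    }

    # ground-truth tables
    cells <- data.frame(
      cell_id = vapply(programs, `[[`, integer(1), "cell_id"),
      parent_id = vapply(programs, `[[`, integer(1), "parent_id"),
      birth_time = vapply(programs, `[[`, numeric(1), "birth_time"),
      s_begin = vapply(programs, function(p) if (p$quiescent) NA_real_ else p$s_begin, numeric(1)),
      s_end = vapply(programs, function(p) if (p$quiescent) NA_real_ else p$s_end, numeric(1)),
      nebd_time = vapply(programs, function(p) if (p$quiescent) NA_real_ else p$nebd_time, numeric(1)),
      division_time = vapply(programs, function(p) if (p$quiescent) NA_real_ else p$division_time, numeric(1)),
      quiescent = vapply(programs, `[[`, logical(1), "quiescent"),
      decline_onset = vapply(programs, function(p) if (p$quiescent) p$decline_onset else NA_real_, numeric(1))
    )
    levels <- list()
    for (ch in chans) {
      nucm <- sapply(programs, function(p) program_nuclear_level(p, ch, times))
      cytm <- sapply(programs, function(p) program_cyto_level(p, ch, times))
      nucm <- matrix(nucm, nrow = params$n_frames)
      cytm <- matrix(cytm, nrow = params$n_frames)
      colnames(nucm) <- colnames(cytm) <- cells$cell_id
      levels[[ch]] <- list(nuclear = nucm, cyto = cytm)
    }

    out <- list(
      stack = structure(list(channels = stack,
                             frame_interval = params$frame_interval,
                             pixel_size = 1,
                             times = times),
                        class = "frame_stack"),
      truth = list(labels = labels, cells = cells, levels = levels,
                   centers = centers),
      programs = programs,
      params = params
    )
    class(out) <- "synthetic_movie"
    out
  })
}

#' @export
print.synthetic_movie <- function(x, ...) {
  cat(sprintf("<synthetic_movie> %d cells (%d founders), %d frames @ %g min, channels: %s\n",
              nrow(x$truth$cells), x$params$n_cells, x$params$n_frames,
              x$params$frame_interval,
              paste(names(x$stack$channels), collapse = ", ")))
  invisible(x)
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<frame_stack> %dx%d px, %d frames @ %g min, channels: %s\n",
              d[1], d[2], d[3], x$frame_interval,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}
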