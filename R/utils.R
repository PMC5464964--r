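# Time units: hours internally everywhere; frame_interval is minutes (the unit
# microscope software reports). All conversions go through these two helpers.

#' Convert frame indices to hours
#'
#' Frames are 1-based internally; frame 1 is acquired at t = 0 h.
#'
#' @param frame integer frame index (1-based)
#' @param frame_interval frame interval in minutes
#' @return time in hours
#' @export
frames_to_hours <- function(frame, frame_interval) {
  (frame - 1) * frame_interval / 60
}

#' Convert a time in hours to the nearest frame index
#'
#' @param hours time in hours
#' @param frame_interval frame interval in minutes
#' @return 1-based frame index
#' @export
hours_to_frames <- function(hours, frame_interval) {
  as.integer(round(hours * 60 / frame_interval)) + 1L
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Truncated-normal draw by rejection; `floor` is the lower truncation bound.
rtruncnorm <- function(n, mean, sd, floor = 1) {
  if (!is.finite(mean) || mean <= 0) {
    stop("distribution mean must be positive, got ", mean)
  }
  if (sd < 0) stop("distribution sd must be non-negative, got ", sd)
  if (sd == 0) return(rep(max(mean, floor), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= floor
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Running median with window w (odd); ends handled by shrinking the window,
# NA values passed through untouched positions.
running_median <- function(x, w = 3) {
  n <- length(x)
  if (n == 0 || w <= 1) return(x)
  w <- min(w, if (n %% 2 == 1) n else n - 1)
  if (w < 3) return(x)
  if (anyNA(x)) {
    out <- rep(NA_real_, n)
    ok <- !is.na(x)
    if (sum(ok) >= 3) {
      out[ok] <- running_median(x[ok], w)
    } else {
      out[ok] <- x[ok]
    }
    return(out)
  }
  as.numeric(stats::runmed(x, k = w, endrule = "median"))
}

# Deterministic polynomial hash of a config list, for output provenance.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 0
  for (b in bytes) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Filled-ellipse pixel mask helper: returns (row, col) index matrix of pixels
# inside the ellipse, clipped to an image of dimension dim = c(nrow, ncol).
ellipse_pixels <- function(center, radii, angle, dim) {
  rmax <- max(radii)
  r0 <- max(1L, floor(center[1] - rmax)); r1 <- min(dim[1], ceiling(center[1] + rmax))
  c0 <- max(1L, floor(center[2] - rmax)); c1 <- min(dim[2], ceiling(center[2] + rmax))
  if (r0 > r1 || c0 > c1) return(cbind(row = integer(0), col = integer(0)))
  rr <- r0:r1; cc <- c0:c1
  dr <- rep(rr - center[1], times = length(cc))
  dc <- rep(cc - center[2], each = length(rr))
  ca <- cos(angle); sa <- sin(angle)
  u <- (dr * ca + dc * sa) / radii[1]
  v <- (-dr * sa + dc * ca) / radii[2]
  inside <- u * u + v * v <= 1
  cbind(row = rep(rr, times = length(cc))[inside],
        col = rep(cc, each = length(rr))[inside])
}
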