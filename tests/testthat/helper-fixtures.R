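# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small proliferating demo movie with both channels and a cyclin-A2-like
# co-reporter, plus its PCNA-segmentation analysis.
demo_movie <- function() {
  cached("demo_movie", function() {
    p <- simulation_params(n_cells = 6, n_frames = 100, frame_interval = 15,
                           image_size = c(200, 200), seed = 42,
                           coreporter_onset_offsets = c(cycA2 = 45))
    simulate_movie(p)
  })
}

demo_analysis <- function() {
  cached("demo_analysis", function() process_movie(demo_movie()$stack))
}

# Starvation-mode movie: no S entry, gradual PCNA decline.
quiescent_movie <- function() {
  cached("quiescent_movie", function() {
    p <- simulation_params(n_cells = 6, n_frames = 91, frame_interval = 20,
                           image_size = c(200, 200), seed = 5,
                           quiescent = TRUE, coreporter_onset_offsets = NULL)
    simulate_movie(p)
  })
}

quiescent_analysis <- function() {
  cached("quiescent_analysis", function() process_movie(quiescent_movie()$stack))
}

# Full-scale paired-segmentation benchmark (shared by the validation
# blocks; ~90 s, computed once).
acceptance_benchmark <- function() {
  cached("acceptance_benchmark", function() benchmark_paired_runs(seed = 1))
}

# Noise-free raster with hard-edged elliptical nuclei at given centres.
disc_raster <- function(centers, radius = 8, level = 100, bg = 10,
                        dim = c(128, 128)) {
  r <- matrix(bg, dim[1], dim[2])
  for (k in seq_len(nrow(centers))) {
    px <- pcnatrack:::ellipse_pixels(centers[k, ], c(radius, radius), 0, dim)
    r[px[, 1] + (px[, 2] - 1) * dim[1]] <- level
  }
  r
}

# Frame index of an event time in hours (1-based, matching the renderer's
# convention that frame f is acquired at (f-1) * interval).
truth_frame <- function(hours, frame_interval) {
  round(hours * 60 / frame_interval) + 1
}

# Brute-force oracles ---------------------------------------------------

# Spearman's rho via the closed-form rank formula (valid without ties) or
# explicit Pearson on average ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  if (!anyDuplicated(x) && !anyDuplicated(y)) {
    1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  } else {
    num <- sum((rx - mean(rx)) * (ry - mean(ry)))
    num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
}

# Exhaustive-enumeration Mann-Whitney using recursive subset generation
# (independent of the package's combn-based path).
oracle_mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  z <- c(x, y); N <- n1 + n2
  r <- rank(z)
  u_of <- function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  us <- c()
  rec <- function(start, chosen) {
    if (length(chosen) == n1) {
      us <<- c(us, u_of(chosen)); return()
    }
    if (start > N) return()
    rec(start + 1, c(chosen, start))
    if (N - start >= n1 - length(chosen)) rec(start + 1, chosen)
  }
  rec(1, integer(0))
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  list(U = u_obs, p.value = min(1, 2 * min(p_le, p_ge)))
}
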