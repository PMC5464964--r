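# Compartment extraction, calibration and population statistics.

test_that("nuclear and cytoplasmic levels are recovered from a known cell", {
  # one nucleus (level 50 above bg) inside a cytoplasm ring region (level 20)
  dim_img <- c(96, 96)
  bg <- 10
  nuc <- pcnatrack:::ellipse_pixels(c(48, 48), c(8, 8), 0, dim_img)
  cyt <- pcnatrack:::ellipse_pixels(c(48, 48), c(15, 15), 0, dim_img)
  r <- matrix(bg, dim_img[1], dim_img[2])
  r[cyt[, 1] + (cyt[, 2] - 1) * dim_img[1]] <- bg + 20
  r[nuc[, 1] + (nuc[, 2] - 1) * dim_img[1]] <- bg + 50
  set.seed(1)
  r <- r + matrix(rnorm(prod(dim_img), 0, 1), dim_img[1], dim_img[2])
  lab <- matrix(0L, dim_img[1], dim_img[2])
  lab[nuc[, 1] + (nuc[, 2] - 1) * dim_img[1]] <- 1L
  got <- extract_compartment_intensities(r, lab, 1, r_inner = 2, r_outer = 6)
  expect_equal(got$nuclear_mean, 50, tolerance = 2 * 1)
  expect_equal(got$cytoplasmic_mean, 20, tolerance = 2 * 1)
  # background-only channel: both means about zero
  r0 <- matrix(bg, dim_img[1], dim_img[2]) +
    matrix(rnorm(prod(dim_img), 0, 1), dim_img[1], dim_img[2])
  # means within 2x the noise SD of zero (the 5th-percentile background
  # convention sits ~1.6 sigma below the background mean)
  got0 <- extract_compartment_intensities(r0, lab, 1)
  expect_lt(abs(got0$nuclear_mean), 2)
  expect_lt(abs(got0$cytoplasmic_mean), 2)
  # unknown label errors
  expect_error(extract_compartment_intensities(r, lab, 9), "not present")
})

test_that("adjacent cells exclude each other's nuclei and contested ring pixels", {
  dim_img <- c(80, 120)
  r <- matrix(0, dim_img[1], dim_img[2])
  lab <- matrix(0L, dim_img[1], dim_img[2])
  for (k in 1:2) {
    ctr <- c(40, 40 + (k - 1) * 22)  # rings overlap between the nuclei
    px <- pcnatrack:::ellipse_pixels(ctr, c(8, 8), 0, dim_img)
    lab[px[, 1] + (px[, 2] - 1) * dim_img[1]] <- k
    r[px[, 1] + (px[, 2] - 1) * dim_img[1]] <- 100 * k
  }
  res <- pcnatrack:::extract_frame_compartments(r, lab, r_inner = 2, r_outer = 6)
  # ring means see only background (0), not the neighbour nucleus (100/200)
  expect_lt(abs(res$cytoplasmic_mean[1]), 1e-9)
  expect_lt(abs(res$cytoplasmic_mean[2]), 1e-9)
  # contested mid-zone pixels are dropped: each ring is smaller than the
  # ring of the same nucleus in isolation
  lab_iso <- lab; lab_iso[lab_iso == 2] <- 0L
  iso <- pcnatrack:::extract_frame_compartments(r, lab_iso,
                                                r_inner = 2, r_outer = 6)
  expect_lt(res$ring_area[1], iso$ring_area[1])
})

test_that("tagged-fraction correction matches the allele arithmetic", {
  expect_equal(correct_for_tagged_fraction(3.0, 0.30), 10.0)
  expect_equal(correct_for_tagged_fraction(73.0, 0.73), 100.0)
  expect_equal(correct_for_tagged_fraction(42, 1), 42)
  # output never smaller than input on (0, 1]
  for (f in c(0.1, 0.5, 0.99, 1)) {
    expect_gte(correct_for_tagged_fraction(7, f), 7)
  }
  expect_error(correct_for_tagged_fraction(1, 0), "0, 1")
  expect_error(correct_for_tagged_fraction(1, 1.2), "0, 1")
})

test_that("standardization is linear in intensity and inverse in exposure", {
  calib <- calibration_config(reference_exposure = 100, fluorophore_factor = 1)
  expect_equal(standardize_intensity(55, 100, calib), 55)
  expect_equal(standardize_intensity(55, 50, calib), 110)
  a <- standardize_intensity(13, 70, calib)
  b <- standardize_intensity(29, 70, calib)
  expect_equal(a + b, standardize_intensity(13 + 29, 70, calib))
  calib2 <- calibration_config(reference_exposure = 100, fluorophore_factor = 4)
  expect_equal(standardize_intensity(80, 100, calib2), 20)
  expect_error(standardize_intensity(1, 0, calib), "positive")
  expect_error(calibration_config(tagged_fraction = c(x = 1.5)), "0, 1")
})

test_that("population summary bands hold 95% of the values", {
  set.seed(2)
  n_tracks <- 200; n_t <- 15
  mat <- matrix(rnorm(n_tracks * n_t, 50, 5), n_tracks, n_t)
  attr(mat, "time_h") <- seq_len(n_t)
  ps <- population_summary(mat)
  # mean curve equals independently computed column means
  expect_equal(ps$mean, colMeans(mat), ignore_attr = TRUE)
  expect_true(all(ps$lower <= ps$mean & ps$mean <= ps$upper))
  # empirical coverage: fraction outside the band is at most 5% plus
  # a discreteness allowance
  outside <- mean(t(mat) < ps$lower | t(mat) > ps$upper)
  expect_lte(outside, 0.05 + 2 / n_tracks)
  # identical tracks: zero-width band equal to the common curve
  same <- matrix(rep(1:10, each = 5), 5, 10)
  attr(same, "time_h") <- 1:10
  ps2 <- population_summary(same)
  expect_equal(ps2$lower, ps2$upper)
  expect_equal(ps2$mean, as.numeric(1:10))
  expect_error(population_summary(matrix(1, 1, 3)), "2")
})

test_that("decrease onset finds the breakpoint and ignores monotone rises", {
  set.seed(3)
  x <- c(seq(100, 160, length.out = 25), seq(159, 80, length.out = 25)) +
    rnorm(50, 0, 1)
  est <- detect_decrease_onset(x, birth_frame = 1)
  expect_lte(abs(est - 25), 2)
  expect_true(is.na(detect_decrease_onset(seq(1, 100, length.out = 40))))
  # onset invariant under positive scaling
  expect_equal(detect_decrease_onset(x * 11), est)
})

test_that("slope_at fits local slopes in AFU per hour", {
  expect_equal(slope_at(rep(5, 20), 10, frame_interval = 60), 0)
  # series c * t (hours): slope c
  t_h <- frames_to_hours(1:20, 30)
  expect_equal(slope_at(3 * t_h, 10, frame_interval = 30), 3, tolerance = 1e-9)
  expect_true(is.na(slope_at(c(1, 2), 1, frame_interval = 10)))
  # near-zero mean slope across many noisy constant series
  set.seed(4)
  slopes <- replicate(60, slope_at(rep(40, 11) + rnorm(11, 0, 2), 6,
                                   frame_interval = 10))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lte(abs(mean(slopes)), 2 * se + 1e-6)
})

test_that("cyclin D1 kinetic classes follow the decrease rule", {
  dec <- seq(100, 60, length.out = 20)
  expect_equal(classify_cyclinD1_class(dec, 1, 20), "I")
  risefall <- c(seq(80, 120, length.out = 10), seq(118, 90, length.out = 10))
  expect_equal(classify_cyclinD1_class(risefall, 1, 20), "II")
  # exactly constant: class II under the tolerance tie-break
  expect_equal(classify_cyclinD1_class(rep(70, 15), 1, 15), "II")
  # too-short span: flagged
  got <- classify_cyclinD1_class(c(5, 4), 1, 2)
  expect_true(is.na(got))
  expect_match(attr(got, "flag"), "short")
})

test_that("sister statistics: rho, concordance and the G1-length test", {
  # construct a lineage with 5 divisions and controlled daughter series
  set.seed(5)
  n_frames <- 60L
  iv <- 10
  det <- list(); anns <- list(); feats <- list()
  div <- data.frame(mother = integer(0), frame = integer(0),
                    daughter_a = integer(0), daughter_b = integer(0))
  tid <- 1L
  for (k in 1:5) {
    lev <- 40 + 10 * k
    for (d in 1:2) {
      birth <- 10L
      g1_len <- if (d == 1) 8L + k else 20L + k  # frames
      series <- rep(NA_real_, n_frames)
      idx <- birth:n_frames
      # class I daughters decrease through G1; class II rise then fall
      series[idx] <- if (d == 1) {
        lev - 0.8 * (idx - birth)
      } else {
        lev + 15 * sin(pmin((idx - birth) / 20, 1) * pi)
      }
      feats[[as.character(tid)]] <- series
      anns[[as.character(tid)]] <- list(birth_frame = birth,
                                        g1s_frame = birth + g1_len)
      if (d == 1) da <- tid else db <- tid
      tid <- tid + 1L
    }
    div <- rbind(div, data.frame(mother = 100L + k, frame = 9L,
                                 daughter_a = da, daughter_b = db))
  }
  lin <- structure(list(tracks = NULL, divisions = div,
                        parent = integer(0)), class = "lineage")
  ss <- sister_statistics(lin, feats, anns, initial_window = 1,
                          frame_interval = iv)
  expect_equal(nrow(ss$pairs), 5)
  # identical initial levels within each pair: rho = 1
  expect_equal(ss$rho, 1)
  # class I vs II never concordant here
  expect_equal(ss$class_concordance, 0)
  expect_equal(sort(unique(c(ss$pairs$class_a, ss$pairs$class_b))), c("I", "II"))
  # class I cells were built with shorter G1: Mann-Whitney agrees
  expect_lt(ss$mw$p.value, 0.05)
  expect_identical(ss$mw$method, "exact")
  # the package statistics agree with the oracles on these data
  expect_equal(ss$rho, oracle_spearman(ss$pairs$level_a, ss$pairs$level_b))
})

test_that("measured reporter levels track programmed compartment levels", {
  mov <- demo_movie()
  an <- demo_analysis()
  meas <- measure_reporters(an, mov$stack, channels = "cycA2",
                            calibration = calibration_config())
  m <- match_tracks_to_truth(an, mov$truth)
  tru_lv <- mov$truth$levels$cycA2
  errs_nuc <- c()
  for (tid in m$track_id[m$cell_id %in% 1:6]) {
    cell <- m$cell_id[m$track_id == tid]
    sub <- meas[meas$track_id == tid & meas$compartment == "nuclear", ]
    true_v <- tru_lv$nuclear[sub$frame, as.character(cell)]
    ok <- !is.na(sub$raw) & !is.na(true_v)
    errs_nuc <- c(errs_nuc, abs(sub$raw[ok] - true_v[ok]))
  }
  # nuclear recovery within partial-pixel and background-percentile bounds
  # (noise sd 2; full-mask means include boundary pixels)
  expect_lt(median(errs_nuc), 8)
  # corrected column applies the tagged fraction (cycA2: 0.5)
  sub <- meas[meas$channel == "cycA2" & !is.na(meas$raw), ]
  expect_equal(sub$corrected, sub$raw / 0.5)
})
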