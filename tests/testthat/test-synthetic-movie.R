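# The ground-truthed movie generator.

test_that("cell programs honour their invariants and defaults", {
  set.seed(1)
  # bare constructor: ramp onset 8-10 h after birth, 2-fold plateau
  for (k in 1:10) {
    p <- cell_program()
    expect_gte(p$ramp_start_offset, 8)
    expect_lte(p$ramp_start_offset, 10)
    expect_equal(p$pcna_plateau_fold, 2)
    expect_equal(p$ramp_duration, 10)
    expect_lt(p$birth_time, p$s_begin)
    expect_lt(p$s_begin, p$nebd_time)
    expect_lt(p$nebd_time, p$division_time)
    expect_equal(p$g1_duration + p$s_duration + p$g2_duration,
                 p$nebd_time - p$birth_time)
  }
  # params-driven builds: G1 from the truncated normal, floored at 1 h
  sp <- simulation_params(seed = 1)
  g1 <- replicate(200, build_cell_program(sp)$g1_duration)
  expect_true(all(g1 >= 1))
  expect_equal(mean(g1), 7.7, tolerance = 0.15)
  # invalid distribution parameters are rejected with a message
  expect_error(simulation_params(g1_mean = -1), "positive")
  expect_error(cell_program(g1_duration = 0), "positive")
})

test_that("identical seeds give identical programs and movies", {
  sp <- simulation_params(n_cells = 3, n_frames = 8, image_size = c(96, 96),
                          seed = 77)
  a <- simulate_movie(sp)
  b <- simulate_movie(sp)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$labels, b$truth$labels)
  expect_identical(a$truth$cells, b$truth$cells)
  # and the global RNG stream is left untouched
  set.seed(9); before <- runif(3)
  set.seed(9); invisible(simulate_movie(sp)); after <- runif(3)
  expect_identical(before, after)
})

test_that("zero ramp duration degenerates to a step at S begin", {
  p <- cell_program(g1_duration = 5, ramp_duration = 0, pcna_base = 50)
  t <- c(4.99, 5.01)
  lev <- pcnatrack:::program_nuclear_level(p, "pcna", t)
  expect_equal(lev, c(50, 100))
})

test_that("noise-free rendering hits the programmed nuclear level", {
  sp <- simulation_params(n_cells = 1, n_frames = 2, image_size = c(96, 96),
                          gaussian_sd = 0, poisson_scale = 0,
                          motion_sd = 0, seed = 3,
                          coreporter_onset_offsets = NULL)
  set.seed(3)
  prog <- build_cell_program(sp, center = c(48, 48), cell_id = 1L)
  fr <- render_frame(list(prog), t = 1, sp)
  inside <- fr$labels == 1
  expect_gt(sum(inside), 100)
  expect_equal(mean(fr$channels$pcna[inside]) - sp$background_level,
               sp$pcna_base, tolerance = 0.01 * sp$pcna_base)
  # zero cells: background-only frame, empty label map
  empty <- render_frame(list(), t = 1, sp)
  expect_equal(max(empty$labels), 0)
  expect_equal(mean(empty$channels$pcna), sp$background_level, tolerance = 0.1)
})

test_that("within-nucleus pixel SD increases with foci signal fraction", {
  sp <- simulation_params(n_cells = 1, n_frames = 2, image_size = c(96, 96),
                          gaussian_sd = 0, poisson_scale = 0, motion_sd = 0,
                          seed = 4, coreporter_onset_offsets = NULL)
  sds <- vapply(c(0, 0.1, 0.25, 0.4), function(fr) {
    set.seed(4)
    prog <- build_cell_program(sp, center = c(48, 48), cell_id = 1L)
    prog$foci_fraction_range <- c(fr, fr)
    t_mid_s <- prog$s_begin + 5
    f <- render_frame(list(prog), t = t_mid_s, sp)
    sd(f$channels$pcna[f$labels == 1])
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
  # and foci leave the nuclear mean at the programmed level
  set.seed(4)
  prog <- build_cell_program(sp, center = c(48, 48), cell_id = 1L)
  t_mid_s <- prog$s_begin + 5
  f <- render_frame(list(prog), t = t_mid_s, sp)
  lev <- pcnatrack:::program_nuclear_level(prog, "pcna", t_mid_s)
  expect_equal(mean(f$channels$pcna[f$labels == 1]) - sp$background_level,
               lev, tolerance = 0.02 * lev)
})

test_that("ground truth is consistent: labels, lineage, ordering", {
  mov <- demo_movie()
  tru <- mov$truth
  # labels disjoint by construction; areas bounded by the image
  for (f in c(1, 50, 100)) {
    lab <- tru$labels[[f]]
    expect_lte(sum(lab > 0), prod(dim(lab)))
  }
  # every non-quiescent cell: birth < S begin < S end < NEBD < division
  cells <- tru$cells[!tru$cells$quiescent, ]
  expect_true(all(cells$birth_time < cells$s_begin))
  expect_true(all(cells$s_begin < cells$s_end))
  expect_true(all(cells$s_end < cells$nebd_time))
  expect_true(all(cells$nebd_time < cells$division_time))
  # division events in the truth lineage match programs dividing in-span
  t_end <- max(mov$stack$times)
  n_div <- sum(!is.na(cells$division_time) & cells$division_time < t_end)
  n_daughters <- sum(!is.na(tru$cells$parent_id))
  expect_equal(n_daughters, 2 * n_div)
  # daughters' birth equals the mother's division time
  dtr <- tru$cells[!is.na(tru$cells$parent_id), ]
  expect_equal(dtr$birth_time,
               tru$cells$division_time[match(dtr$parent_id, tru$cells$cell_id)])
})

test_that("single-frame movies and capacity limits behave", {
  sp <- simulation_params(n_cells = 2, n_frames = 1, image_size = c(96, 96),
                          seed = 6, coreporter_onset_offsets = NULL)
  mov <- simulate_movie(sp)
  expect_equal(length(mov$truth$labels), 1)
  expect_true(all(is.na(mov$truth$cells$parent_id)))
  expect_error(simulation_params(n_cells = 100, image_size = c(64, 64)),
               "too small")
})

test_that("quiescence mode declines without S entry and ends below start", {
  mov <- quiescent_movie()
  tru <- mov$truth
  expect_true(all(tru$cells$quiescent))
  expect_true(all(is.na(tru$cells$s_begin)))
  lv <- tru$levels$pcna$nuclear
  n <- nrow(lv)
  expect_true(all(lv[n, ] < lv[1, ]))
  # ~48 h at half-time 16 h: roughly an 8-fold decline programmed over the
  # full window; within the 30 h movie the drop is already substantial
  expect_true(all(lv[n, ] / lv[1, ] < 0.5))
  # rendered movie agrees: mean in-nucleus intensity falls
  first <- mov$stack$channels$pcna[, , 1][tru$labels[[1]] > 0]
  last <- mov$stack$channels$pcna[, , n][tru$labels[[n]] > 0]
  expect_lt(mean(last), 0.6 * mean(first))
})
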