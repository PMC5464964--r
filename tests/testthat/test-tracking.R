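# Linking, gap closing, division detection and lineage assembly.

# static label maps: same nuclei at fixed positions over n frames
static_labelmaps <- function(n_frames = 6) {
  ctrs <- rbind(c(30, 30), c(30, 90), c(90, 60))
  r <- disc_raster(ctrs, radius = 8, level = 100, bg = 10)
  lm <- segment_nuclei(r, seg_params(smoothing_sigma = 0))
  lapply(seq_len(n_frames), function(f) {
    pcnatrack:::label_map(lm$labels, f)
  })
}

test_that("static nuclei yield one full-length track each", {
  lms <- static_labelmaps(6)
  tr <- link_frames(lms, link_params())
  sp <- split(tr$detections, tr$detections$track_id)
  expect_equal(length(sp), 3)
  expect_true(all(vapply(sp, nrow, integer(1)) == 6))
  # no label assigned to two tracks in the same frame
  det <- tr$detections
  expect_false(any(duplicated(det[, c("frame", "label")])))
})

test_that("a single frame gives tracks of length one", {
  lms <- static_labelmaps(1)
  tr <- link_frames(lms, link_params())
  expect_true(all(table(tr$detections$track_id) == 1))
})

test_that("moving nuclei stay on one track and match the truth lineage", {
  mov <- demo_movie()
  an <- demo_analysis()
  m <- match_tracks_to_truth(an, mov$truth)
  # purity 1.0 at default density and motion
  expect_true(all(m$purity == 1))
  # founders tracked from frame 1 in one unbroken track each
  det <- an$tracks$detections
  founders <- det$track_id[det$frame == 1]
  for (tid in founders) {
    frames <- sort(det$frame[det$track_id == tid])
    expect_true(all(diff(frames) == 1))
  }
})

test_that("close_gaps bridges short dropouts and respects its bounds", {
  lms <- static_labelmaps(7)
  # delete one detection of nucleus 2 at frame 4 (1-frame dropout)
  lab4 <- lms[[4]]$labels
  drop_label <- 2L
  lab4[lab4 == drop_label] <- 0L
  lms[[4]] <- pcnatrack:::label_map(lab4, 4L)
  tr <- link_frames(lms, link_params())
  n_before <- length(unique(tr$detections$track_id))
  expect_equal(n_before, 4)  # broken into two pieces
  merged <- close_gaps(tr, max_gap = 2)
  expect_equal(length(unique(merged$detections$track_id)), 3)
  # max_gap = 0 is the identity
  same <- close_gaps(tr, max_gap = 0)
  expect_identical(same$detections$track_id, tr$detections$track_id)
  # a gap exceeding max_gap stays two tracks
  lms2 <- static_labelmaps(9)
  for (f in 4:6) {  # 3-frame dropout
    lab <- lms2[[f]]$labels
    lab[lab == drop_label] <- 0L
    lms2[[f]] <- pcnatrack:::label_map(lab, f)
  }
  tr2 <- link_frames(lms2, link_params())
  merged2 <- close_gaps(tr2, max_gap = 2)
  expect_equal(length(unique(merged2$detections$track_id)), 4)
})

test_that("every true division is recovered with exactly two daughters", {
  mov <- demo_movie()
  an <- demo_analysis()
  tru <- mov$truth$cells
  m <- match_tracks_to_truth(an, mov$truth)
  true_mothers <- sort(unique(tru$parent_id[!is.na(tru$parent_id)]))
  div <- an$lineage$divisions
  # each detected mother has exactly 2 daughters by construction; verify
  # the detected set covers every true division and no track mothers twice
  expect_equal(nrow(div), length(true_mothers))
  expect_false(any(duplicated(div$mother)))
  detected_cells <- sort(m$cell_id[match(div$mother, m$track_id)])
  expect_equal(detected_cells, true_mothers)
  # daughters map to the true daughters of that mother
  for (k in seq_len(nrow(div))) {
    mother_cell <- m$cell_id[match(div$mother[k], m$track_id)]
    da <- m$cell_id[match(div$daughter_a[k], m$track_id)]
    db <- m$cell_id[match(div$daughter_b[k], m$track_id)]
    expect_setequal(tru$cell_id[which(tru$parent_id == mother_cell)], c(da, db))
    # division frame within 2 frames of truth
    true_f <- floor(tru$division_time[mother_cell] * 60 / 15) + 1
    expect_lte(abs(div$frame[k] - true_f), 2)
  }
  # acyclic parenthood
  parent <- an$lineage$parent
  for (tid in seq_along(parent)) {
    seen <- integer(0); cur <- tid
    while (!is.na(parent[cur])) {
      expect_false(cur %in% seen)
      seen <- c(seen, cur); cur <- parent[cur]
    }
  }
})

test_that("a movie without divisions yields a forest of parentless tracks", {
  an <- quiescent_analysis()
  expect_equal(nrow(an$lineage$divisions), 0)
  expect_true(all(is.na(an$lineage$parent)))
})

test_that("PCNA-channel and chromatin-channel tracks pair one-to-one", {
  mov <- demo_movie()
  an_p <- demo_analysis()
  an_c <- cached("demo_analysis_chromatin", function() {
    process_movie(mov$stack, seg_channel = "chromatin")
  })
  pairs <- pair_tracks_by_truth(an_p, an_c, mov$truth)
  # every founder cell is paired across the two segmentations
  expect_gte(nrow(pairs), 6)
  expect_false(any(duplicated(pairs$track_a)))
  expect_false(any(duplicated(pairs$track_b)))
  # per-cell areas agree within 15% outside M phase
  det_a <- an_p$tracks$detections; det_c <- an_c$tracks$detections
  for (k in which(pairs$cell_id %in% 1:6)) {
    ta <- det_a[det_a$track_id == pairs$track_a[k], ]
    tc <- det_c[det_c$track_id == pairs$track_b[k], ]
    common <- intersect(ta$frame, tc$frame)
    cell <- pairs$cell_id[k]
    nebd_f <- floor(mov$truth$cells$nebd_time[cell] * 60 / 15) + 1
    common <- common[common < nebd_f - 1]  # exclude M phase
    if (length(common) < 10) next
    ratio <- ta$area[match(common, ta$frame)] / tc$area[match(common, tc$frame)]
    expect_lt(median(abs(ratio - 1)), 0.15)
  }
})
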