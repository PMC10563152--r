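sim_small <- function(seed, ...) {
  simulate_video(sim_config(image_size = c(128, 128), n_effectors = 1,
                            n_targets = 1, n_frames = 6, onset_frame = 2,
                            seed = seed, ...))
}

test_that("stand-in cell segmentation matches simulated cells", {
  sim <- sim_small(3)
  tr <- sim$truth
  seg <- segment_cells_standin(sim$video$frames[[1]])
  expect_setequal(names(seg), c("effector", "target"))
  for (ch in names(seg)) {
    truth_cells <- Filter(function(cr) cr$cell_type == ch, tr$cells)
    expect_equal(n_instances(seg[[ch]]$labels), length(truth_cells))
    for (cr in truth_cells) {
      best <- max(vapply(seq_len(n_instances(seg[[ch]]$labels)), function(j)
        iou(seg[[ch]]$labels == j, cr$masks[[1]]), numeric(1)))
      expect_gte(best, 0.6)
    }
  }
  # constant channel errors
  fr <- sim$video$frames[[1]]
  fr$channels$effector <- matrix(5, 128, 128)
  expect_error(segment_cells_standin(fr), "constant")
})

test_that("contact detection applies the strictly-more-than-three rule", {
  blank <- matrix(FALSE, 8, 8)
  spot <- matrix(FALSE, 8, 8); spot[4, 4] <- TRUE
  mk <- function(overlap_frames, n = 10) {
    masks <- lapply(seq_len(n), function(t)
      if (t %in% overlap_frames) spot else blank)
    cell_record(1, "effector", masks, matrix(4, n, 2))
  }
  other <- cell_record(2, "target",
                       lapply(1:10, function(t) spot), matrix(4, 10, 2))
  # frames 2..6 (0-based): 5 frames -> qualified
  ci <- detect_contacts(mk(3:7), other)
  expect_equal(nrow(ci), 1)
  expect_equal(ci$start_frame, 2L)
  expect_equal(ci$end_frame, 6L)
  # 3 frames: not qualified
  expect_equal(nrow(detect_contacts(mk(3:5), other)), 0)
  # no overlap at all
  expect_equal(nrow(detect_contacts(mk(integer(0)), other)), 0)
  # two separated qualified runs stay maximal and distinct
  ci2 <- detect_contacts(mk(c(1:4, 7:10)), other)
  expect_equal(nrow(ci2), 2)
  expect_true(all(ci2$end_frame - ci2$start_frame + 1L == 4))
})

test_that("annexin validity thresholds at IoU 0.1, strictly", {
  cellm <- disk_image(64, 64, c(32, 32), 10, 0, 1) > 0      # 317 px
  mk_channel <- function(mask) {
    ch <- matrix(0, 64, 64); ch[mask] <- 1000; ch
  }
  # large overlap: valid
  a1 <- annexin_validity(mk_channel(cellm), cellm)
  expect_true(a1$valid)
  expect_gt(a1$iou_vs_cell, 0.9)
  # small spot far away: invalid
  far <- disk_image(64, 64, c(10, 10), 3, 0, 1) > 0
  a2 <- annexin_validity(mk_channel(far), cellm)
  expect_false(a2$valid)
  # constant channel: IoU 0, invalid (documented convention)
  a3 <- annexin_validity(matrix(0, 64, 64), cellm)
  expect_equal(a3$iou_vs_cell, 0)
  expect_false(a3$valid)
  # just above the boundary: IoU 2/18 > 0.1 is valid
  ann2 <- matrix(0, 64, 64); ann2[c(9:10, 30:37), 1] <- 1000
  cell2 <- matrix(FALSE, 64, 64); cell2[1:10, 1] <- TRUE
  a5 <- annexin_validity(ann2, cell2)
  expect_equal(a5$iou_vs_cell, 2 / 18)
  expect_true(a5$valid)
  # exact boundary: IoU == 0.1 is invalid (strict "above")
  ann3 <- matrix(0, 64, 64); ann3[c(10, 30:34), 1] <- 1000
  cell3 <- matrix(FALSE, 64, 64); cell3[6:10, 1] <- TRUE
  a6 <- annexin_validity(ann3, cell3)
  expect_equal(a6$iou_vs_cell, 0.1)
  expect_false(a6$valid)
})

test_that("validity is monotone as the annexin mask grows within the cell", {
  cellm <- disk_image(64, 64, c(32, 32), 10, 0, 1) > 0
  last_iou <- -1
  for (r in c(2, 4, 6, 8, 10)) {
    ann <- matrix(0, 64, 64)
    ann[disk_image(64, 64, c(32, 32), r, 0, 1) > 0] <- 1000
    a <- annexin_validity(ann, cellm)
    expect_gte(a$iou_vs_cell, last_iou)
    last_iou <- a$iou_vs_cell
  }
})

test_that("localization classification splits at IoU 0.5, strictly", {
  mk <- function(i) list(iou_vs_cell = i, valid = TRUE,
                         distribution = NA_character_)
  expect_equal(classify_localization(mk(0.7))$distribution, "even")
  expect_equal(classify_localization(mk(0.2))$distribution, "localized")
  expect_equal(classify_localization(mk(0.5))$distribution, "localized")
})

test_that("synapse delineation yields a boundary band between abutting cells", {
  a <- disk_image(64, 64, c(32, 22), 10, 0, 1) > 0
  b <- disk_image(64, 64, c(32, 43), 10, 0, 1) > 0   # abutting disks
  syn <- delineate_synapse(a, b, dilation_radius = 3)
  expect_true(any(syn))
  # the band lies within each dilated mask
  br <- EBImage::makeBrush(7, "disc")
  expect_true(all(syn[!(EBImage::dilate(a, br) > 0)] == FALSE))
  expect_true(all(syn[!(EBImage::dilate(b, br) > 0)] == FALSE))
  # far-apart disks: empty
  c2 <- disk_image(64, 64, c(32, 54), 4, 0, 1) > 0
  far <- disk_image(64, 64, c(32, 10), 4, 0, 1) > 0
  expect_false(any(delineate_synapse(far, c2, 3)))
  expect_error(delineate_synapse(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)),
               "non-empty")
})

test_that("localization PCC ranks even vs synapse-localized signal", {
  cellm <- disk_image(80, 80, c(40, 30), 12, 0, 1) > 0
  effm <- disk_image(80, 80, c(40, 55), 12, 0, 1) > 0
  syn <- delineate_synapse(effm, cellm, 3)
  stopifnot(any(syn))
  # uniform over the cell: cell correlation dominates
  even_ch <- matrix(0, 80, 80); even_ch[cellm] <- 1000
  p1 <- localization_pcc(even_ch, cellm, syn)
  expect_gt(p1$pcc_vs_cell, p1$pcc_vs_synapse)
  # concentrated in the synapse band: synapse correlation dominates
  loc_ch <- matrix(0, 80, 80); loc_ch[syn] <- 1000
  p2 <- localization_pcc(loc_ch, cellm, syn)
  expect_gt(p2$pcc_vs_synapse, p2$pcc_vs_cell)
  expect_error(localization_pcc(matrix(0, 80, 80), cellm, syn),
               "zero-variance")
})

test_that("event summaries tally validity, killing and localization", {
  ev <- function(valid, killing, distribution = NA_character_)
    list(annexin_valid = valid, killing = killing,
         distribution = distribution)
  events <- c(lapply(1:3, function(i) ev(TRUE, TRUE, "localized")),
              lapply(1:7, function(i) ev(FALSE, i <= 2)))
  s <- summarize_events(events)
  expect_equal(s$n_events, 10L)
  expect_equal(s$fraction_annexin_valid, 0.3)
  expect_equal(s$by_killing$n_events, c(5L, 5L))
  expect_equal(s$by_killing$n_annexin_valid, c(3L, 0L))
  expect_equal(unname(s$localization[["localized"]]), 3L)
  # all killing
  s2 <- summarize_events(lapply(1:4, function(i) ev(TRUE, TRUE)))
  expect_equal(s2$by_killing$n_events[s2$by_killing$killing == FALSE], 0L)
  # empty input
  expect_equal(summarize_events(list())$n_events, 0L)
})
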