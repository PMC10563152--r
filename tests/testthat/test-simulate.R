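# small, fast configuration shared by simulator tests
small_cfg <- function(...) {
  sim_config(image_size = c(128, 128), n_effectors = 1, n_targets = 1,
             cell_radius_px = c(8, 11), n_frames = 6, onset_frame = 2,
             ...)
}

test_that("simulator is deterministic and respects the onset frame", {
  cfg <- small_cfg(seed = 9)
  a <- simulate_video(cfg)
  b <- simulate_video(cfg)
  expect_identical(a, b)

  counts <- vapply(a$truth$apobd_instances, n_instances, integer(1))
  expect_true(all(counts[1:2] == 0L))       # frames before onset
  expect_true(all(counts[3:6] >= 1L))       # frames at/after onset
  # body count stays within the configured burst range
  expect_true(all(counts[3:6] >= 3 & counts[3:6] <= 12))
})

test_that("a no-onset config yields no ApoBD instances in any frame", {
  cfg <- small_cfg(seed = 2)
  cfg$onset_frame <- NULL
  sim <- simulate_video(cfg)
  expect_true(all(vapply(sim$truth$apobd_instances, n_instances,
                         integer(1)) == 0L))
  expect_false(sim$truth$annexin_valid)
})

test_that("truth geometry, extracellular placement and contact overlap", {
  # onset late enough that the full pre-onset contact run fits
  sim <- simulate_video(sim_config(image_size = c(128, 128),
                                   n_effectors = 1, n_targets = 1,
                                   cell_radius_px = c(8, 11), n_frames = 6,
                                   onset_frame = 4, seed = 4))
  tr <- sim$truth
  for (t in seq_along(sim$video$frames)) {
    expect_identical(dim(tr$apobd_instances[[t]]),
                     dim(sim$video$frames[[t]]$phase))
    # ApoBD pixels never overlap cell pixels
    cm <- Reduce(`|`, lapply(tr$cells, function(cr) cr$masks[[t]]))
    expect_equal(sum(tr$apobd_instances[[t]] > 0 & cm), 0)
  }
  # forced killing contact: masks overlap throughout the interval
  expect_gte(length(tr$contact_intervals), 1)
  ci <- tr$contact_intervals[[1]]
  for (t in ci$start_frame:ci$end_frame) {
    expect_true(any(tr$cells[[ci$effector_id]]$masks[[t + 1]] &
                    tr$cells[[ci$target_id]]$masks[[t + 1]]))
  }
  expect_gte(ci$end_frame - ci$start_frame + 1L, 4)
})

test_that("annexin channel is nonzero only for annexin-valid events", {
  hits <- logical(0)
  for (s in 1:10) {
    sim <- simulate_video(small_cfg(seed = s, annexin_positive_prob = 0.5))
    any_sig <- any(vapply(sim$video$frames, function(f)
      any(f$channels$annexin > 0), logical(1)))
    expect_equal(any_sig, sim$truth$annexin_valid)
    hits <- c(hits, sim$truth$annexin_valid)
  }
  expect_true(any(hits) && !all(hits))  # both outcomes occur
})

test_that("label sequences obey the protocol constraints", {
  seqs <- simulate_label_sequences(40, length = 10,
                                   max_positive_fraction = 0.5,
                                   min_run = 3, seed = 7)
  expect_length(seqs, 80)
  for (s in seqs) {
    expect_lte(sum(s$labels), 5)
    r <- rle(s$labels == 1L)
    longest <- if (any(r$values)) max(r$lengths[r$values]) else 0L
    if (s$is_event) {
      expect_gte(longest, 3)
      oc <- oracle_onset(s$labels, 3)
      expect_equal(s$onset, oc$onset_frame)
    } else {
      expect_lte(longest, 2)
      expect_null(s$onset)
    }
  }
  # reproducible
  expect_identical(seqs, simulate_label_sequences(40, seed = 7))
})

test_that("infeasible sequence constraints error out", {
  expect_error(simulate_label_sequences(5, length = 10,
                                        max_positive_fraction = 0.1,
                                        min_run = 3),
               "infeasible")
  expect_error(simulate_label_sequences(5, length = 2, min_run = 3),
               "length")
})

test_that("simulated ApoBDs inside the filter band survive the blob filters", {
  # bodies drawn well inside the area band; the weak-label pipeline should
  # re-identify most of them (IoU-matched at 0.5)
  total <- 0L; matched <- 0L
  for (s in 1:3) {
    cfg <- sim_config(image_size = c(192, 192), n_effectors = 1,
                      n_targets = 1, n_frames = 3, onset_frame = 0,
                      apobd_area_px = c(30, 150),
                      apobd_count_at_burst = c(4, 8), seed = s)
    sim <- simulate_video(cfg)
    tr <- sim$truth
    t <- 2L
    cm <- Reduce(`|`, lapply(tr$cells, function(cr) cr$masks[[t + 1]]))
    seg <- segment_apobds_reference(sim$video$frames[[t + 1]], cm)
    lab <- tr$apobd_instances[[t + 1]]
    for (i in seq_len(n_instances(lab))) {
      total <- total + 1L
      tmask <- lab == i
      ious <- vapply(seq_len(n_instances(seg$instances)), function(j)
        iou(tmask, seg$instances == j), numeric(1))
      if (length(ious) && max(ious) >= 0.5) matched <- matched + 1L
    }
  }
  expect_gte(matched / total, 0.8)
})
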