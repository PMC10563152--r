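test_that("8-bit rescaling maps extremes and constants as documented", {
  img <- matrix(c(0, 65535, 100, 300), 2, 2)
  out <- rescale_to_8bit(img)
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 1], 255)
  expect_equal(rescale_to_8bit(matrix(7, 3, 3)), matrix(0, 3, 3))
  two <- rescale_to_8bit(matrix(c(100, 300), 2, 1))
  expect_equal(sort(as.vector(two)), c(0, 255))
})

test_that("LoG detection finds isolated Gaussian spots at the right place", {
  h <- 120; w <- 120
  gauss_spot <- function(img, center, sigma, amp) {
    d2 <- outer((seq_len(nrow(img)) - center[1])^2,
                (seq_len(ncol(img)) - center[2])^2, "+")
    img + amp * exp(-d2 / (2 * sigma^2))
  }
  img <- matrix(20, h, w)
  img <- gauss_spot(img, c(50, 60), 2, 150)
  b <- detect_blobs_log(img, threshold = 10)
  expect_equal(nrow(b), 1)
  expect_lte(abs(b$row - 50), 1)
  expect_lte(abs(b$col - 60), 1)
  expect_equal(b$polarity, 1)
  # response at the detected maximum agrees with direct convolution
  expect_equal(b$response,
               -oracle_log_response(img, b$row, b$col, b$sigma),
               tolerance = 0.05)

  # two separated spots, one dark
  img2 <- matrix(128, h, w)
  img2 <- gauss_spot(img2, c(30, 30), 2, 100)
  img2 <- gauss_spot(img2, c(80, 90), 3, -100)
  b2 <- detect_blobs_log(img2, threshold = 10)
  expect_equal(nrow(b2), 2)
  expect_setequal(b2$polarity, c(1, -1))

  # blank image: nothing
  expect_equal(nrow(detect_blobs_log(matrix(5, 64, 64))), 0)
  expect_error(detect_blobs_log(img, sigma_range = numeric()), "sigma")
})

test_that("adaptive flood fill recovers a uniform disk exactly", {
  img <- disk_image(60, 60, c(30, 30), 4.6)   # 69 px disk
  expect_equal(sum(img == 200), 69)
  blob <- list(row = 30, col = 30, circular_area_px = 78)
  roi <- floodfill_adaptive(img, blob, tolerance_grid = 1:149)
  expect_equal(roi$area_px, 69)
  expect_identical(roi$mask, img == 200)
  expect_equal(roi$tolerance_used, 1)         # tie toward smaller tolerance

  # tolerance 0 on a noise-free image: the constant region under the seed
  roi0 <- floodfill_adaptive(img, blob, tolerance_grid = 0)
  expect_identical(roi0$mask, img == 200)

  # seed on the background with a large tolerance floods the background
  # (the 200-valued disk stays excluded at tolerance 100)
  blob_bg <- list(row = 2, col = 2, circular_area_px = 50)
  roi_bg <- floodfill_adaptive(img, blob_bg, tolerance_grid = 100)
  expect_equal(roi_bg$area_px, 60 * 60 - 69)

  expect_error(floodfill_adaptive(img, list(row = 0, col = 5,
                                            circular_area_px = 10)),
               "outside")
})

test_that("shape filter applies the aspect and area thresholds inclusively", {
  cand <- function(aspect, area) list(mask = NULL, area_px = area,
                                      aspect_ratio = aspect,
                                      centroid = c(1, 1),
                                      tolerance_used = 1)
  out <- shape_filter(list(cand(0.9, 100), cand(0.5, 100), cand(0.9, 300),
                           cand(0.9, 10), cand(0.85, 20), cand(0.85, 200)))
  expect_length(out$kept, 3)   # boundary values 0.85, 20, 200 are kept
  expect_length(out$rejected, 3)
  expect_equal(out$reasons, c("aspect", "area", "area"))
})

test_that("filtering is monotone in its thresholds", {
  set.seed(8)
  cands <- lapply(1:40, function(i)
    list(mask = NULL, area_px = sample(1:400, 1),
         aspect_ratio = runif(1), centroid = c(1, 1), tolerance_used = 1))
  base <- length(shape_filter(cands)$kept)
  expect_lte(length(shape_filter(cands, min_aspect = 0.95)$kept), base)
  expect_lte(length(shape_filter(cands, area_range = c(40, 150))$kept),
             base)
})

test_that("median removal is local, disk-shaped and matches brute force", {
  set.seed(21)
  img <- matrix(100 + rnorm(40 * 40, 0, 0.5), 40, 40)
  spot <- disk_image(40, 40, c(20, 20), 2, bg = 0, fg = 150)
  img_sp <- img + spot
  attention <- disk_image(40, 40, c(20, 20), 6, bg = 0, fg = 1) > 0
  out <- median_remove_in_roi(img_sp, attention, kernel_radius = 3)
  # outside the attention region: bit-exact identity
  expect_identical(out[!attention], img_sp[!attention])
  # former spot pixels are levelled to near-background
  expect_true(all(abs(out[spot > 0] - 100) < 1.5))
  # brute-force disk-median oracle on a few pixels
  off <- which(EBImage::makeBrush(7, "disc") > 0, arr.ind = TRUE) - 4L
  for (p in list(c(20, 20), c(18, 22), c(22, 19))) {
    rr <- p[1] + off[, 1]; cc <- p[2] + off[, 2]
    expect_equal(out[p[1], p[2]],
                 median(img_sp[cbind(rr, cc)]))
  }
  # empty attention mask: identity everywhere
  none <- matrix(FALSE, 40, 40)
  expect_identical(median_remove_in_roi(img_sp, none), img_sp)
  expect_error(median_remove_in_roi(img_sp, attention, kernel_radius = 0),
               "kernel_radius")
})

test_that("weak-label generation keeps in-band blobs and erases the rest", {
  # 3 in-band extracellular bodies, 1 oversized artifact, 1 blob inside a
  # cell mask
  set.seed(5)
  img <- matrix(1000 + rnorm(200 * 200, 0, 10), 200, 200)
  cellm <- disk_image(200, 200, c(160, 160), 14, bg = 0, fg = 1) > 0
  img[cellm] <- 700
  centers <- list(c(40, 40), c(40, 120), c(120, 40))
  for (p in centers) img[disk_image(200, 200, p, 5, 0, 1) > 0] <- 1800
  img[disk_image(200, 200, c(120, 130), 12, 0, 1) > 0] <- 1800  # oversized
  img[disk_image(200, 200, c(160, 160), 4, 0, 1) > 0] <- 1900   # in cell

  wl <- generate_weak_labels(img, cell_masks = cellm)
  expect_equal(n_instances(wl$instances), 3)
  for (p in centers) expect_gt(wl$instances[p[1], p[2]], 0)
  # the in-cell blob never becomes a candidate
  expect_equal(wl$instances[160, 160], 0)
  # kept-instance pixels are untouched relative to the rescaled image
  img8 <- rescale_to_8bit(img)
  kept_px <- wl$instances > 0
  expect_identical(wl$filtered_image[kept_px], img8[kept_px])
  # the oversized artifact is levelled toward local background
  over <- disk_image(200, 200, c(120, 130), 12, 0, 1) > 0
  bg8 <- median(img8[1:20, 1:20])
  expect_true(all(abs(wl$filtered_image[over] - bg8) < 10))

  # a blob-free (constant) frame passes through unchanged
  flat <- matrix(500, 64, 64)
  wl0 <- generate_weak_labels(flat)
  expect_equal(n_instances(wl0$instances), 0)
  expect_identical(wl0$filtered_image, rescale_to_8bit(flat))
})
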