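#' Rescale an image to the 8-bit range
#'
#' Linear min-max mapping onto [0, 255]; a constant image maps to all
#' zeros. Values are left as floating point (not quantized).
#'
#' @param image finite numeric matrix.
#' @return Numeric matrix with values in [0, 255].
#' @export
rescale_to_8bit <- function(image) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  rng <- range(image)
  if (rng[1] == rng[2]) return(matrix(0, nrow(image), ncol(image)))
  (image - rng[1]) * (255 / (rng[2] - rng[1]))
}

# max over the 3x3 neighbourhood (including centre), edges padded with -Inf
nbhd_max3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  shift <- function(dr, dc) {
    s <- matrix(-Inf, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    s[rs, cs] <- m[rs - dr, cs - dc]
    s
  }
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0) out <- pmax(out, shift(dr, dc))
  out
}

#' Scale-normalized Laplacian-of-Gaussian blob detection
#'
#' Detects compact bright and dark spots (apoptotic bodies appear with
#' either polarity in phase contrast) as local maxima of the
#' scale-normalized LoG response \code{sigma^2 * Laplacian(G_sigma * I)}
#' over a log-spaced sigma ladder; bright spots are maxima of the negated
#' response, dark spots of the response itself. The two polarities are
#' merged and deduplicated by centre distance. Each detection carries the
#' pixel area of the circle implied by its scale, \code{pi * (sqrt(2) *
#' sigma)^2}, used downstream to pick the flood-fill tolerance.
#'
#' @param image numeric matrix, conventionally already rescaled to 8 bit.
#' @param sigma_range range of Gaussian scales in pixels (default
#'   \code{c(1.5, 6)}, matching body radii of roughly 2-8.5 px).
#' @param n_sigma number of scales on the ladder.
#' @param threshold minimum scale-normalized response (8-bit intensity
#'   units).
#' @param dedup_px detections of opposite polarity closer than this are
#'   merged, keeping the stronger (default 2).
#' @return A data.frame with one row per detection: \code{row}, \code{col},
#'   \code{sigma}, \code{response}, \code{polarity} (+1 bright, -1 dark)
#'   and \code{circular_area_px}.
#' @export
detect_blobs_log <- function(image, sigma_range = c(1.5, 6), n_sigma = 6L,
                             threshold = 30, dedup_px = 2) {
  stopifnot(is.matrix(image))
  if (length(sigma_range) < 1 || any(sigma_range <= 0))
    stop("sigma_range must contain positive scales")
  sigmas <- if (length(sigma_range) == 2L && n_sigma > 1L)
    exp(seq(log(sigma_range[1]), log(sigma_range[2]), length.out = n_sigma))
  else sort(unique(sigma_range))
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  resp <- lapply(sigmas, function(s) {
    sm <- EBImage::gblur(image, sigma = s, radius = 2 * ceiling(3 * s) + 1)
    s^2 * EBImage::filter2(sm, lap, boundary = "replicate")
  })
  hits <- list()
  for (pol in c(1, -1)) {           # +1: bright spots (negative LoG)
    r <- lapply(resp, function(m) -pol * m)
    nm <- lapply(r, nbhd_max3)
    for (si in seq_along(sigmas)) {
      cand <- r[[si]] >= nm[[si]] & r[[si]] > threshold
      if (si > 1L) cand <- cand & r[[si]] >= nm[[si - 1L]]
      if (si < length(sigmas)) cand <- cand & r[[si]] >= nm[[si + 1L]]
      idx <- which(cand, arr.ind = TRUE)
      if (nrow(idx))
        hits[[length(hits) + 1L]] <- data.frame(
          row = idx[, 1], col = idx[, 2], sigma = sigmas[si],
          response = r[[si]][idx], polarity = pol)
    }
  }
  if (!length(hits))
    return(data.frame(row = integer(), col = integer(), sigma = numeric(),
                      response = numeric(), polarity = numeric(),
                      circular_area_px = numeric()))
  out <- do.call(rbind, hits)
  out <- out[order(-out$response), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      later <- seq(i + 1L, nrow(out))
      d2 <- (out$row[later] - out$row[i])^2 + (out$col[later] - out$col[i])^2
      keep[later][d2 < dedup_px^2] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  out$circular_area_px <- pi * (sqrt(2) * out$sigma)^2
  rownames(out) <- NULL
  out
}

#' Flood fill a blob with an adaptively chosen intensity tolerance
#'
#' For each tolerance on the grid, grows the 4-connected region of pixels
#' whose intensity differs from the seed pixel by at most the tolerance,
#' and returns the candidate whose pixel area is closest to the circular
#' area implied by the blob's detection scale (ties broken toward the
#' smaller tolerance). Region area is non-decreasing in the tolerance, so
#' the search stops once the area overshoots past the best candidate.
#'
#' @param image numeric matrix.
#' @param blob one row of a \code{\link{detect_blobs_log}} result (or any
#'   list with \code{row}, \code{col}, \code{circular_area_px}).
#' @param tolerance_grid increasing non-negative tolerances (default 1:50,
#'   8-bit units).
#' @return An RoI candidate: list with \code{mask} (logical matrix),
#'   \code{area_px}, \code{aspect_ratio} (minor/major best-fit ellipse
#'   axis ratio), \code{centroid} and \code{tolerance_used}.
#' @export
floodfill_adaptive <- function(image, blob, tolerance_grid = 1:50) {
  stopifnot(is.matrix(image), length(tolerance_grid) >= 1)
  r0 <- as.integer(round(blob$row)); c0 <- as.integer(round(blob$col))
  if (r0 < 1 || r0 > nrow(image) || c0 < 1 || c0 > ncol(image))
    stop("blob seed lies outside the image")
  tolerance_grid <- sort(tolerance_grid)
  seed_val <- image[r0, c0]
  target <- blob$circular_area_px
  h <- nrow(image); w <- ncol(image)
  # flood inside a window around the seed, regrowing whenever the region
  # touches the window border so the result equals a full-frame fill
  fill_at <- function(tol, win) {
    repeat {
      rs <- max(1L, r0 - win):min(h, r0 + win)
      cs <- max(1L, c0 - win):min(w, c0 + win)
      cand <- abs(image[rs, cs, drop = FALSE] - seed_val) <= tol
      lab <- EBImage::bwlabel(cand)        # 4-connected components
      reg <- lab == lab[r0 - rs[1] + 1L, c0 - cs[1] + 1L]
      full_win <- length(rs) == h && length(cs) == w
      touches <- any(reg[1, ]) || any(reg[nrow(reg), ]) ||
        any(reg[, 1]) || any(reg[, ncol(reg)])
      if (full_win || !touches) {
        out <- matrix(FALSE, h, w)
        out[rs, cs] <- reg
        return(out)
      }
      win <- win * 4L
    }
  }
  win0 <- max(24L, as.integer(ceiling(2 * sqrt(target))))
  best <- NULL; best_diff <- Inf
  for (tol in tolerance_grid) {
    reg <- fill_at(tol, win0)
    area <- sum(reg)
    diff <- abs(area - target)
    if (diff < best_diff) {                # strict: ties keep smaller tol
      best_diff <- diff
      best <- list(mask = reg, tolerance = tol)
    }
    if (area > target && diff > best_diff) break
  }
  st <- mask_shape_stats(best$mask)
  list(mask = best$mask, area_px = st$area, aspect_ratio = st$aspect,
       centroid = st$centroid, tolerance_used = best$tolerance)
}

#' Filter RoI candidates by aspect ratio and area
#'
#' Keeps candidates that look like apoptotic bodies: best-fit-ellipse
#' minor/major axis ratio at least \code{min_aspect} (default 0.85) and
#' pixel area inside \code{area_range} (default 20-200 px, inclusive at
#' both ends). Rejection reasons are recorded.
#'
#' @param candidates list of RoI candidates from
#'   \code{\link{floodfill_adaptive}}.
#' @param min_aspect minimum aspect ratio (kept when equal).
#' @param area_range inclusive pixel-area band.
#' @return List with \code{kept}, \code{rejected} (both candidate lists)
#'   and \code{reasons} (character, one per rejected candidate).
#' @export
shape_filter <- function(candidates, min_aspect = 0.85,
                         area_range = c(20, 200)) {
  kept <- list(); rejected <- list(); reasons <- character()
  for (cand in candidates) {
    if (cand$aspect_ratio < min_aspect) {
      rejected[[length(rejected) + 1L]] <- cand
      reasons <- c(reasons, "aspect")
    } else if (cand$area_px < area_range[1] ||
               cand$area_px > area_range[2]) {
      rejected[[length(rejected) + 1L]] <- cand
      reasons <- c(reasons, "area")
    } else {
      kept[[length(kept) + 1L]] <- cand
    }
  }
  list(kept = kept, rejected = rejected, reasons = reasons)
}

# offsets (dr, dc) of a disk-shaped kernel of the given radius
disk_offsets <- function(radius) {
  b <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  idx <- which(b > 0, arr.ind = TRUE)
  cbind(idx[, 1] - (radius + 1L), idx[, 2] - (radius + 1L))
}

#' Median filter restricted to an attention region
#'
#' Replaces each pixel inside \code{attention} by the median of the
#' original image over a disk-shaped kernel centred there (out-of-bounds
#' kernel positions are dropped); pixels outside the region are returned
#' bit-exactly unchanged. Used to erase unannotated objects from
#' weak-label training images without touching the rest of the frame.
#'
#' @param image numeric matrix.
#' @param attention logical matrix of the same geometry.
#' @param kernel_radius disk radius in pixels (default 3).
#' @return Numeric matrix.
#' @export
median_remove_in_roi <- function(image, attention, kernel_radius = 3L) {
  stopifnot(is.matrix(image))
  check_binary_mask(attention, dim_ref = image)
  if (kernel_radius < 1) stop("kernel_radius must be >= 1")
  idx <- which(attention, arr.ind = TRUE)
  if (!nrow(idx)) return(image)
  off <- disk_offsets(kernel_radius)
  h <- nrow(image); w <- ncol(image)
  vals <- matrix(NA_real_, nrow(idx), nrow(off))
  for (j in seq_len(nrow(off))) {
    rr <- idx[, 1] + off[j, 1]; cc <- idx[, 2] + off[j, 2]
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    vals[ok, j] <- image[cbind(rr[ok], cc[ok])]
  }
  out <- image
  out[idx] <- apply(vals, 1, stats::median, na.rm = TRUE)
  out
}

# Replace the pixels of `region` by the disk-kernel median of the pixels
# OUTSIDE the region (the local background), growing the kernel radius
# until every pixel has support. A plain median blur preserves straight
# edges, so it cannot level objects wider than its kernel; taking the
# median over background pixels only removes objects of any size.
masked_median_fill <- function(image, region, radius = 3L) {
  idx <- which(region, arr.ind = TRUE)
  if (!nrow(idx)) return(image)
  h <- nrow(image); w <- ncol(image)
  out <- image
  todo <- rep(TRUE, nrow(idx))
  r <- radius
  while (any(todo) && r <= max(h, w)) {
    off <- disk_offsets(r)
    sub <- idx[todo, , drop = FALSE]
    vals <- matrix(NA_real_, nrow(sub), nrow(off))
    for (j in seq_len(nrow(off))) {
      rr <- sub[, 1] + off[j, 1]; cc <- sub[, 2] + off[j, 2]
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      ok[ok] <- !region[cbind(rr[ok], cc[ok])]
      vals[ok, j] <- image[cbind(rr[ok], cc[ok])]
    }
    support <- rowSums(!is.na(vals))
    done <- support >= 5L
    if (any(done)) {
      out[sub[done, , drop = FALSE]] <-
        apply(vals[done, , drop = FALSE], 1, stats::median, na.rm = TRUE)
      todo[todo] <- !done
    }
    r <- r * 2L
  }
  out
}

# Shared candidate pipeline: rescale, LoG detection, drop blobs whose
# centres fall in (a slightly dilated) cell mask, adaptive flood fill,
# shape filter. Returns the rescaled image, detections and both candidate
# sets. `params` recognises: sigma_range, n_sigma, threshold, dedup_px,
# tolerance_grid, min_aspect, area_range, cell_mask_dilate.
blob_candidates <- function(image, cell_masks = NULL, params = list()) {
  p <- utils::modifyList(list(
    sigma_range = c(1.5, 6), n_sigma = 6L, threshold = 30, dedup_px = 2,
    tolerance_grid = 1:50, min_aspect = 0.85, area_range = c(20, 200),
    cell_mask_dilate = 3L), params)
  img8 <- rescale_to_8bit(image)
  blobs <- detect_blobs_log(img8, p$sigma_range, p$n_sigma, p$threshold,
                            p$dedup_px)
  excluded <- NULL
  if (!is.null(cell_masks) && nrow(blobs)) {
    check_binary_mask(cell_masks, dim_ref = image)
    cm <- if (p$cell_mask_dilate > 0)
      EBImage::dilate(cell_masks,
                      EBImage::makeBrush(2 * p$cell_mask_dilate + 1,
                                         "disc")) > 0
    else cell_masks
    inside <- cm[cbind(blobs$row, blobs$col)]
    excluded <- blobs[inside, , drop = FALSE]
    blobs <- blobs[!inside, , drop = FALSE]
  }
  cands <- lapply(seq_len(nrow(blobs)), function(i)
    floodfill_adaptive(img8, blobs[i, ], p$tolerance_grid))
  sf <- shape_filter(cands, p$min_aspect, p$area_range)
  list(image8 = img8, blobs = blobs, excluded_blobs = excluded,
       kept = sf$kept, rejected = sf$rejected, reasons = sf$reasons,
       params = p)
}

# footprint disks of a set of blob detections, optionally dilated
blob_footprints <- function(blobs, dims, extra = 0) {
  m <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_len(nrow(blobs))) {
    r <- sqrt(2) * blobs$sigma[i] + extra
    m <- m | disk_mask(dims[1], dims[2], c(blobs$row[i], blobs$col[i]), r)
  }
  m
}

# label matrix from a list of kept candidates (first come, first claim)
instances_from_candidates <- function(kept, dims) {
  lab <- matrix(0L, dims[1], dims[2])
  nxt <- 0L
  for (cand in kept) {
    free <- cand$mask & lab == 0L
    if (any(free)) {
      nxt <- nxt + 1L
      lab[free] <- nxt
    }
  }
  instance_mask(lab)
}

#' Generate a weak-label segmentation entry from one frame
#'
#' Automates instance annotation for apoptotic bodies: the frame is
#' rescaled to 8 bit, LoG blob detection finds candidate bodies, blobs
#' centred inside the (dilated) cell mask are dropped, each remaining blob
#' is segmented by adaptive flood fill, and the aspect/area shape filter
#' splits candidates into kept instances and rejects. Rejected candidates
#' and residual blob detections without a kept mask are then erased from
#' the training image, restricted to the attention region: each pixel of
#' the erase region is replaced by the disk-kernel median of the
#' surrounding local background (a masked median, so objects wider than
#' the kernel are levelled too), followed by one plain disk-median pass
#' over the region to smooth the fill. Kept-instance pixels are never
#' modified.
#'
#' @param frame numeric matrix (phase-contrast image).
#' @param cell_masks logical matrix marking cell bodies, or NULL.
#' @param attention logical matrix marking where erasure may act; defaults
#'   to the union of all blob footprints dilated by the kernel radius (the
#'   baseline attention provider).
#' @param params list of pipeline parameters (see
#'   \code{\link{detect_blobs_log}}, \code{\link{floodfill_adaptive}},
#'   \code{\link{shape_filter}}); also \code{kernel_radius} (default 3).
#' @return List with \code{filtered_image} (8-bit scale), \code{instances}
#'   (instance label matrix), \code{kept}, \code{rejected},
#'   \code{reasons}, \code{blobs}.
#' @export
generate_weak_labels <- function(frame, cell_masks = NULL,
                                 attention = NULL, params = list()) {
  kr <- if (is.null(params$kernel_radius)) 3L else params$kernel_radius
  bc <- blob_candidates(frame, cell_masks, params)
  dims <- dim(frame)
  instances <- instances_from_candidates(bc$kept, dims)
  if (is.null(attention)) {
    # baseline attention: all blob footprints plus the rejected candidate
    # masks, dilated by the kernel radius so the eraser can reach local
    # background beyond each object
    attention <- blob_footprints(bc$blobs, dims, extra = kr)
    if (length(bc$rejected)) {
      rej <- Reduce(`|`, lapply(bc$rejected, `[[`, "mask"))
      attention <- attention |
        (EBImage::dilate(rej, EBImage::makeBrush(2 * kr + 1, "disc")) > 0)
    }
  }
  check_binary_mask(attention, dim_ref = frame)

  # erase region: rejected candidate masks plus their blob footprints,
  # clipped to attention, never touching kept instances
  erase <- matrix(FALSE, dims[1], dims[2])
  for (cand in bc$rejected) erase <- erase | cand$mask
  if (length(bc$rejected)) {
    rej_idx <- which(!vapply(seq_len(nrow(bc$blobs)), function(i) {
      any(vapply(bc$kept, function(k)
        k$mask[bc$blobs$row[i], bc$blobs$col[i]], logical(1)))
    }, logical(1)))
    if (length(rej_idx))
      erase <- erase | blob_footprints(bc$blobs[rej_idx, , drop = FALSE],
                                       dims, extra = 1)
  }
  erase <- erase & attention & instances == 0L

  filtered <- bc$image8
  if (any(erase)) {
    filtered <- masked_median_fill(filtered, erase, kr)
    filtered <- median_remove_in_roi(filtered, erase, kr)
  }
  list(filtered_image = filtered, instances = instances, kept = bc$kept,
       rejected = bc$rejected, reasons = bc$reasons, blobs = bc$blobs)
}
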