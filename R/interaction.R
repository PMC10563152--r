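#' Stand-in cell segmentation from fluorescence channels
#'
#' Otsu-binarizes each available fluorescence membrane-dye channel
#' (effector, target) and keeps 4-connected components of at least
#' \code{min_area} pixels as cell instances. A lightweight replacement for
#' a dedicated cell-detection module.
#'
#' @param frame a \code{\link{multichannel_frame}}.
#' @param min_area minimum component area in pixels (default 50).
#' @return Named list per available channel, each with \code{mask}
#'   (logical), \code{labels} (instance matrix) and \code{centroids}.
#' @export
segment_cells_standin <- function(frame, min_area = 50L) {
  stopifnot(inherits(frame, "multichannel_frame"))
  chans <- intersect(c("effector", "target"), names(frame$channels))
  if (!length(chans)) stop("no effector/target fluorescence channel present")
  out <- list()
  for (ch in chans) {
    img <- frame$channels[[ch]]
    if (length(unique(as.vector(img))) < 2L)
      stop("channel '", ch, "' is constant; cannot binarize")
    mask <- binarize_otsu(img)
    lab <- EBImage::bwlabel(mask)
    keep <- which(tabulate(lab[lab > 0]) >= min_area)
    lab2 <- matrix(0L, nrow(lab), ncol(lab))
    for (j in seq_along(keep)) lab2[lab == keep[j]] <- j
    lab2 <- instance_mask(lab2)
    cents <- if (n_instances(lab2))
      do.call(rbind, lapply(seq_len(n_instances(lab2)), function(j)
        mask_centroid(lab2 == j)))
    else matrix(numeric(), 0, 2)
    out[[ch]] <- list(mask = lab2 > 0L, labels = lab2, centroids = cents)
  }
  out
}

#' Track cells across a video by mask overlap
#'
#' Segments each frame with \code{\link{segment_cells_standin}} and links
#' instances frame-to-frame by greatest mask overlap (a simple greedy
#' tracker). Cells present in the first frame define the track set.
#'
#' @param video a \code{\link{nanowell_video}} with fluorescence channels.
#' @param min_area minimum cell area in pixels.
#' @return List of \code{\link{cell_record}}.
#' @export
track_cells <- function(video, min_area = 50L) {
  stopifnot(inherits(video, "nanowell_video"))
  n <- length(video$frames)
  segs <- lapply(video$frames, segment_cells_standin, min_area = min_area)
  records <- list()
  next_id <- 0L
  for (ch in names(segs[[1]])) {
    k0 <- n_instances(segs[[1]][[ch]]$labels)
    for (j in seq_len(k0)) {
      next_id <- next_id + 1L
      masks <- vector("list", n)
      cents <- matrix(NA_real_, n, 2)
      masks[[1]] <- segs[[1]][[ch]]$labels == j
      cents[1, ] <- segs[[1]][[ch]]$centroids[j, ]
      prev <- masks[[1]]
      for (t in 2:n) {
        lab <- segs[[t]][[ch]]$labels
        if (n_instances(lab) == 0L) { prev <- NULL; next }
        ov <- vapply(seq_len(n_instances(lab)), function(m)
          if (is.null(prev)) 0L else sum(prev & lab == m), integer(1))
        if (max(ov) > 0L) {
          m <- which.max(ov)
          masks[[t]] <- lab == m
          cents[t, ] <- segs[[t]][[ch]]$centroids[m, ]
          prev <- masks[[t]]
        } else prev <- NULL
      }
      records[[next_id]] <- cell_record(
        next_id, if (ch == "effector") "effector" else "target",
        masks, cents)
    }
  }
  records
}

#' Detect qualified effector-target contacts
#'
#' Finds maximal runs of frames in which an effector and a target mask
#' overlap by at least one pixel, and keeps runs of at least
#' \code{min_frames} frames. The default of 4 reads the qualification
#' "more than three consecutive frames" strictly (a 3-frame overlap does
#' not qualify).
#'
#' @param effector,target \code{\link{cell_record}} objects sharing frame
#'   indexing.
#' @param min_frames minimum qualifying run length (default 4).
#' @return A data.frame with columns \code{effector_id}, \code{target_id},
#'   \code{start_frame}, \code{end_frame} (0-based, inclusive); zero rows
#'   when no contact qualifies.
#' @export
detect_contacts <- function(effector, target, min_frames = 4L) {
  n <- length(effector$masks)
  stopifnot(length(target$masks) == n)
  overlap <- vapply(seq_len(n), function(t) {
    a <- effector$masks[[t]]; b <- target$masks[[t]]
    !is.null(a) && !is.null(b) && any(a & b)
  }, logical(1))
  r <- rle(overlap)
  starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  hit <- which(r$values & r$lengths >= min_frames)
  if (!length(hit))
    return(data.frame(effector_id = integer(), target_id = integer(),
                      start_frame = integer(), end_frame = integer()))
  data.frame(effector_id = effector$cell_id, target_id = target$cell_id,
             start_frame = starts[hit] - 1L,
             end_frame = starts[hit] + r$lengths[hit] - 2L)
}

#' Annexin-V validity of an apoptotic event
#'
#' Otsu-binarizes the Annexin-V channel and scores its IoU against the
#' cell-body mask; the signal is valid when the IoU is strictly above the
#' threshold (default 0.1). A constant channel (no signal at all) yields
#' IoU 0 and an invalid call.
#'
#' @param annexin_channel numeric matrix.
#' @param cell_mask logical matrix, non-empty.
#' @param threshold validity bound on the IoU (strict; default 0.1).
#' @return An assessment list: \code{iou_vs_cell}, \code{valid},
#'   \code{distribution} (NA until classified), \code{pcc_vs_cell},
#'   \code{pcc_vs_synapse} (NA until computed).
#' @export
annexin_validity <- function(annexin_channel, cell_mask, threshold = 0.1) {
  stopifnot(is.matrix(annexin_channel))
  check_binary_mask(cell_mask, dim_ref = annexin_channel)
  if (!any(cell_mask)) stop("cell mask is empty")
  iou_vs_cell <- if (length(unique(as.vector(annexin_channel))) < 2L) 0
  else iou(binarize_otsu(annexin_channel), cell_mask)
  list(iou_vs_cell = iou_vs_cell, valid = iou_vs_cell > threshold,
       distribution = NA_character_, pcc_vs_cell = NA_real_,
       pcc_vs_synapse = NA_real_)
}

#' Classify Annexin-V distribution as even or localized
#'
#' A high IoU of the Annexin mask against the cell body (strictly above
#' \code{even_threshold}, default 0.5) indicates an even distribution over
#' the membrane; a low IoU indicates staining localized to part of the
#' cell, typically toward the immune synapse.
#'
#' @param assessment an \code{\link{annexin_validity}} result.
#' @param even_threshold bound separating even from localized (strict).
#' @return The assessment with \code{distribution} filled in.
#' @export
classify_localization <- function(assessment, even_threshold = 0.5) {
  assessment$distribution <-
    if (assessment$iou_vs_cell > even_threshold) "even" else "localized"
  assessment
}

#' Delineate the immune synapse between two cells
#'
#' The synapse region is taken as the intersection of the two cell masks
#' each dilated by \code{dilation_radius} pixels: a band along the shared
#' boundary, empty when the cells are farther apart than twice the radius.
#'
#' @param effector_mask,target_mask non-empty logical matrices.
#' @param dilation_radius dilation in pixels (default 3).
#' @return Logical matrix.
#' @export
delineate_synapse <- function(effector_mask, target_mask,
                              dilation_radius = 3L) {
  check_binary_mask(effector_mask)
  check_binary_mask(target_mask, dim_ref = effector_mask)
  if (!any(effector_mask) || !any(target_mask))
    stop("both cell masks must be non-empty")
  b <- EBImage::makeBrush(2 * dilation_radius + 1, shape = "disc")
  (EBImage::dilate(effector_mask, b) > 0) &
    (EBImage::dilate(target_mask, b) > 0)
}

#' Pearson correlation of the Annexin image against cell and synapse masks
#'
#' Quantifies Annexin-V polarization: the channel is correlated against
#' the cell-body mask and the synapse mask rendered as 0/1 images over the
#' whole nanowell. A higher synapse correlation than cell correlation
#' indicates signal polarized toward the synapse.
#'
#' @param annexin_channel numeric matrix with nonzero variance.
#' @param cell_mask non-empty logical matrix.
#' @param synapse_mask logical matrix; when empty (no contact) the synapse
#'   correlation is NA.
#' @return List with \code{pcc_vs_cell} and \code{pcc_vs_synapse}.
#' @export
localization_pcc <- function(annexin_channel, cell_mask, synapse_mask) {
  pc <- pcc(annexin_channel, cell_mask + 0)
  ps <- if (any(synapse_mask) && !all(synapse_mask))
    pcc(annexin_channel, synapse_mask + 0) else NA_real_
  list(pcc_vs_cell = pc, pcc_vs_synapse = ps)
}

#' Summarize a batch of apoptotic events
#'
#' @param events list of event records, each with logical
#'   \code{annexin_valid} and \code{killing}, and optionally
#'   \code{distribution} ("even"/"localized").
#' @return List with \code{n_events}, \code{n_annexin_valid},
#'   \code{fraction_annexin_valid}, a killing/non-killing split and
#'   localization tallies; all-zero/empty summary for empty input.
#' @export
summarize_events <- function(events) {
  if (!length(events))
    return(list(n_events = 0L, n_annexin_valid = 0L,
                fraction_annexin_valid = NA_real_,
                by_killing = data.frame(), localization = table(character())))
  valid <- vapply(events, function(e) isTRUE(e$annexin_valid), logical(1))
  killing <- vapply(events, function(e) isTRUE(e$killing), logical(1))
  distr <- vapply(events, function(e)
    if (is.null(e$distribution) || is.na(e$distribution)) NA_character_
    else e$distribution, character(1))
  by_killing <- data.frame(
    killing = c(TRUE, FALSE),
    n_events = c(sum(killing), sum(!killing)),
    n_annexin_valid = c(sum(valid & killing), sum(valid & !killing)))
  list(n_events = length(events), n_annexin_valid = sum(valid),
       fraction_annexin_valid = mean(valid),
       by_killing = by_killing,
       localization = table(distr[!is.na(distr)]))
}
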