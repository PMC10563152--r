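#' Classical per-frame ApoBD-presence classifier
#'
#' A deep network screens frames in the original pipeline; this baseline
#' plugs into the same contract with no training: a frame is called
#' ApoBD-positive when at least \code{min_blobs} extracellular blob
#' detections survive the adaptive flood fill and shape filter. The score
#' is the kept-blob count divided by a saturation constant, capped at 1.
#'
#' Any replacement classifier only needs to map a frame to a list with
#' \code{label} and \code{score} to plug into the temporal stage.
#'
#' @param frame a \code{\link{multichannel_frame}} (or a bare phase
#'   matrix).
#' @param cell_masks logical matrix of cell bodies, or NULL.
#' @param params blob-pipeline parameters plus \code{min_blobs} (default 1)
#'   and \code{saturation} (default 5).
#' @return List with \code{label} ("ApoBD_positive"/"ApoBD_negative"),
#'   \code{positive} (logical), \code{score} and \code{n_kept}.
#' @export
baseline_classifier <- function(frame, cell_masks = NULL, params = list()) {
  phase <- if (inherits(frame, "multichannel_frame")) frame$phase else frame
  stopifnot(is.matrix(phase))
  if (!is.null(cell_masks)) check_binary_mask(cell_masks, dim_ref = phase)
  min_blobs <- if (is.null(params$min_blobs)) 1L else params$min_blobs
  saturation <- if (is.null(params$saturation)) 5 else params$saturation
  bc <- blob_candidates(phase, cell_masks, params)
  n_kept <- length(bc$kept)
  positive <- n_kept >= min_blobs
  list(label = if (positive) "ApoBD_positive" else "ApoBD_negative",
       positive = positive, score = min(1, n_kept / saturation),
       n_kept = n_kept)
}

#' Nanowell-grouped k-fold assignment
#'
#' Frames from the same nanowell are highly correlated, so cross-validation
#' folds are assigned at the nanowell level: nanowell ids are shuffled with
#' the given seed and dealt round-robin into k folds (sizes differing by at
#' most one nanowell), and every frame inherits its nanowell's fold.
#'
#' @param nanowell_ids character vector, one entry per item (frame).
#' @param k number of folds (default 5).
#' @param seed RNG seed for the shuffle.
#' @return Integer vector of fold numbers in 1..k, one per item.
#' @export
grouped_kfold <- function(nanowell_ids, k = 5L, seed = 1L) {
  stopifnot(length(nanowell_ids) >= 1, k >= 1)
  wells <- unique(nanowell_ids)
  if (k > length(wells))
    stop("k exceeds the number of distinct nanowells")
  with_seed(seed, {
    shuffled <- sample(wells)
    fold_of <- stats::setNames(rep_len(seq_len(k), length(shuffled)),
                               shuffled)
    unname(fold_of[nanowell_ids])
  })
}

#' Classification metrics from confusion counts
#'
#' @param tp,fp,fn,tn non-negative integer counts; alternatively pass a
#'   single list/vector with those names as \code{tp}.
#' @return List with \code{accuracy}, \code{precision}, \code{recall} and
#'   \code{f1}. Precision is NA when tp + fp = 0, recall when tp + fn = 0,
#'   and f1 when either is NA or both are zero.
#' @export
classification_metrics <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (is.list(tp) || (is.numeric(tp) && length(tp) == 4L &&
                      !is.null(names(tp)))) {
    cc <- tp
    tp <- cc[["tp"]]; fp <- cc[["fp"]]; fn <- cc[["fn"]]; tn <- cc[["tn"]]
  }
  stopifnot(all(c(tp, fp, fn, tn) >= 0))
  total <- tp + fp + fn + tn
  if (total == 0) stop("no evaluated frames")
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) ||
            (precision + recall) == 0) NA_real_
  else 2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / total, precision = precision,
       recall = recall, f1 = f1)
}

#' Baseline attention mask for a frame
#'
#' Contract: return a mask covering the regions the classifier found
#' salient (the original pipeline uses Grad-CAM on a trained network).
#' The baseline provider marks the footprints of every blob detection,
#' kept or rejected, dilated by \code{dilate_px} so the downstream median
#' erasure has room to act.
#'
#' @param frame a \code{\link{multichannel_frame}} or phase matrix.
#' @param params blob-pipeline parameters plus \code{dilate_px}
#'   (default 3).
#' @return Logical matrix.
#' @export
attention_provider <- function(frame, params = list()) {
  phase <- if (inherits(frame, "multichannel_frame")) frame$phase else frame
  dilate_px <- if (is.null(params$dilate_px)) 3 else params$dilate_px
  img8 <- rescale_to_8bit(phase)
  p <- params; p$cell_mask_dilate <- NULL
  blobs <- detect_blobs_log(
    img8,
    if (is.null(p$sigma_range)) c(1.5, 6) else p$sigma_range,
    if (is.null(p$n_sigma)) 6L else p$n_sigma,
    if (is.null(p$threshold)) 4 else p$threshold,
    if (is.null(p$dedup_px)) 2 else p$dedup_px)
  blob_footprints(blobs, dim(phase), extra = dilate_px)
}
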