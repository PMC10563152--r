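#' Multi-channel nanowell frame
#'
#' A single time point of a nanowell video: one phase-contrast intensity
#' matrix plus any subset of the named fluorescence channels
#' (\code{effector}, \code{target}, \code{annexin}). All grids must share
#' the same geometry and contain finite, non-negative intensities.
#'
#' @param phase numeric matrix of phase-contrast intensities.
#' @param channels named list of numeric matrices; allowed names are
#'   \code{"effector"}, \code{"target"}, \code{"annexin"}.
#' @param frame_index non-negative integer, 0-based position in the video.
#' @return An object of class \code{multichannel_frame}.
#' @export
multichannel_frame <- function(phase, channels = list(), frame_index = 0L) {
  stopifnot(is.matrix(phase), is.numeric(phase))
  if (!all(is.finite(phase)) || any(phase < 0))
    stop("phase intensities must be finite and >= 0")
  if (length(channels)) {
    bad <- setdiff(names(channels), c("effector", "target", "annexin"))
    if (length(bad) || is.null(names(channels)))
      stop("channel names must be a subset of {effector, target, annexin}")
    for (nm in names(channels)) {
      ch <- channels[[nm]]
      if (!is.matrix(ch) || !identical(dim(ch), dim(phase)))
        stop("channel '", nm, "' does not share the phase geometry")
      if (!all(is.finite(ch)) || any(ch < 0))
        stop("channel '", nm, "' intensities must be finite and >= 0")
    }
  }
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0)
    stop("frame_index must be a non-negative integer")
  structure(list(phase = phase, channels = channels,
                 frame_index = frame_index),
            class = "multichannel_frame")
}

#' Nanowell time-lapse video
#'
#' An ordered sequence of \code{\link{multichannel_frame}} objects for one
#' nanowell, acquired at a fixed frame interval (5 min by default, the
#' standard TIMING acquisition rate).
#'
#' @param nanowell_id character scalar identifying the well.
#' @param frames list of \code{multichannel_frame}; their \code{frame_index}
#'   values must be the consecutive run 0..n-1.
#' @param frame_interval_minutes positive number, minutes between frames.
#' @return An object of class \code{nanowell_video}.
#' @export
nanowell_video <- function(nanowell_id, frames, frame_interval_minutes = 5) {
  stopifnot(is.character(nanowell_id), length(nanowell_id) == 1L,
            length(frames) >= 1L, frame_interval_minutes > 0)
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  if (!identical(idx, seq_along(frames) - 1L))
    stop("frame_index values must be consecutive 0..n-1")
  dims <- lapply(frames, function(f) dim(f$phase))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all frames must share the same geometry")
  structure(list(nanowell_id = nanowell_id, frames = frames,
                 frame_interval_minutes = frame_interval_minutes),
            class = "nanowell_video")
}

#' @export
print.nanowell_video <- function(x, ...) {
  d <- dim(x$frames[[1]]$phase)
  cat(sprintf("<nanowell_video> %s: %d frames, %dx%d px, %.4g min/frame\n",
              x$nanowell_id, length(x$frames), d[1], d[2],
              x$frame_interval_minutes))
  cat("channels:", paste(names(x$frames[[1]]$channels), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.multichannel_frame <- function(x, ...) {
  cat(sprintf("<multichannel_frame> t=%d, %dx%d px, channels: %s\n",
              x$frame_index, nrow(x$phase), ncol(x$phase),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# Binary masks are plain logical matrices; instance masks are integer
# matrices with 0 = background and labels 1..n. These validators are the
# package-wide contract for the two mask kinds.

#' Validate a binary mask
#'
#' Binary masks throughout the package are plain logical matrices.
#'
#' @param mask logical matrix.
#' @param dim_ref optional matrix or dim vector the mask must match.
#' @return The mask, invisibly, after validation.
#' @export
check_binary_mask <- function(mask, dim_ref = NULL) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("a binary mask must be a logical matrix")
  if (!is.null(dim_ref)) {
    ref <- if (is.matrix(dim_ref)) dim(dim_ref) else as.integer(dim_ref)
    if (!identical(dim(mask), ref)) stop("mask geometry mismatch")
  }
  invisible(mask)
}

#' Construct an instance mask from a label matrix
#'
#' Relabels so that the labels used are exactly \{0\} U \{1..n\} with every
#' instance non-empty.
#'
#' @param labels integer matrix, 0 = background.
#' @return Integer matrix with consecutive labels; attribute
#'   \code{n_instances} gives the instance count.
#' @export
instance_mask <- function(labels) {
  if (!is.matrix(labels) || any(labels < 0) || any(labels != round(labels)))
    stop("labels must be a matrix of non-negative integers")
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  used <- sort(unique(labels[labels > 0L]))
  if (length(used) && !identical(used, seq_along(used))) {
    remap <- integer(max(used))
    remap[used] <- seq_along(used)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
  }
  attr(labels, "n_instances") <- length(used)
  labels
}

#' Number of instances in an instance mask
#' @param labels instance mask (integer label matrix).
#' @return integer count.
#' @export
n_instances <- function(labels) {
  n <- attr(labels, "n_instances")
  if (is.null(n)) n <- length(setdiff(unique(as.vector(labels)), 0L))
  as.integer(n)
}

#' Per-frame record of one tracked cell
#'
#' @param cell_id positive integer.
#' @param cell_type \code{"effector"} or \code{"target"}.
#' @param masks list of logical matrices (or NULL where the cell is absent),
#'   one entry per frame.
#' @param centroids n_frames x 2 numeric matrix of (row, col) centroids;
#'   NA rows where absent.
#' @return An object of class \code{cell_record}.
#' @export
cell_record <- function(cell_id, cell_type, masks, centroids) {
  stopifnot(cell_id >= 1, cell_type %in% c("effector", "target"),
            is.matrix(centroids), ncol(centroids) == 2,
            length(masks) == nrow(centroids))
  structure(list(cell_id = as.integer(cell_id), cell_type = cell_type,
                 masks = masks, centroids = centroids),
            class = "cell_record")
}

# Centroid of a binary mask: mean pixel coordinates (row, col), 1-based.
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot take the centroid of an empty mask")
  c(mean(idx[, 1]), mean(idx[, 2]))
}

# Shape statistics of a binary mask: pixel area, centroid and the
# minor/major axis ratio of the best-fit ellipse (square roots of the
# eigenvalues of the pixel-coordinate covariance). A single pixel has
# aspect 1 by convention; a perfectly collinear region has aspect 0.
mask_shape_stats <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  area <- nrow(idx)
  if (area == 0L) stop("empty mask has no shape")
  centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
  if (area == 1L) return(list(area = 1L, centroid = centroid, aspect = 1))
  cv <- stats::cov(idx)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  aspect <- if (ev[1] <= 0) 1 else sqrt(ev[2] / ev[1])
  list(area = area, centroid = centroid, aspect = aspect)
}
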