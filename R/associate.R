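#' Reference ApoBD instance segmentation for one frame
#'
#' Classical stand-in for a trained instance-segmentation model: the kept
#' candidates of the blob pipeline (LoG detection, adaptive flood fill,
#' shape filter, extracellular only) become the ApoBD instances. No image
#' filtering is applied.
#'
#' @param frame a \code{\link{multichannel_frame}} or phase matrix.
#' @param cell_masks logical matrix of cell bodies, or NULL.
#' @param params blob-pipeline parameters.
#' @return List with \code{frame_index} (if known), \code{instances}
#'   (label matrix) and \code{centroids} (n x 2 matrix of (row, col)).
#' @export
segment_apobds_reference <- function(frame, cell_masks = NULL,
                                     params = list()) {
  phase <- if (inherits(frame, "multichannel_frame")) frame$phase else frame
  bc <- blob_candidates(phase, cell_masks, params)
  instances <- instances_from_candidates(bc$kept, dim(phase))
  cent <- if (length(bc$kept))
    do.call(rbind, lapply(bc$kept, `[[`, "centroid"))
  else matrix(numeric(), 0, 2)
  list(frame_index = if (inherits(frame, "multichannel_frame"))
    frame$frame_index else NA_integer_,
    instances = instances, centroids = cent)
}

#' Mean distance from a cell to a set of ApoBD centroids
#'
#' @param cell_centroid numeric (row, col).
#' @param apobd_centroids n x 2 matrix of ApoBD centroids, n >= 1.
#' @return Arithmetic mean of the Euclidean centroid distances.
#' @export
mean_distance <- function(cell_centroid, apobd_centroids) {
  apobd_centroids <- matrix(apobd_centroids, ncol = 2)
  if (nrow(apobd_centroids) == 0L)
    stop("mean distance is undefined without ApoBDs")
  mean(sqrt((apobd_centroids[, 1] - cell_centroid[1])^2 +
            (apobd_centroids[, 2] - cell_centroid[2])^2))
}

#' Assign the apoptotic cell for one frame
#'
#' The cell with the least average centroid distance to the ApoBDs is
#' called apoptotic; exact ties go to the smaller cell id.
#'
#' @param cell_centroids named list (or n x 2 matrix with rownames) of cell
#'   centroids, names = cell ids; cells absent in the frame are skipped by
#'   passing NA centroids.
#' @param apobd_centroids n x 2 matrix of ApoBD centroids.
#' @return List with \code{cell_id} and \code{distances} (named vector of
#'   per-cell mean distances).
#' @export
assign_apoptotic_cell <- function(cell_centroids, apobd_centroids) {
  if (is.matrix(cell_centroids)) {
    ids <- as.integer(rownames(cell_centroids))
    cl <- lapply(seq_len(nrow(cell_centroids)),
                 function(i) cell_centroids[i, ])
  } else {
    ids <- as.integer(names(cell_centroids))
    cl <- cell_centroids
  }
  present <- !vapply(cl, function(p) any(is.na(p)), logical(1))
  if (!any(present)) stop("no cells present in the frame")
  d <- vapply(cl[present], mean_distance, numeric(1),
              apobd_centroids = apobd_centroids)
  names(d) <- ids[present]
  ids_p <- ids[present]
  winner <- ids_p[order(d, ids_p)[1]]  # ties -> smaller cell id
  list(cell_id = winner, distances = d)
}

#' Majority vote over per-frame apoptotic-cell winners
#'
#' A cell winning a strict majority of the voting frames is the apoptotic
#' cell; frames without ApoBDs abstain (NA winners). Without a strict
#' majority the tie-break is the cell with the smallest mean of its
#' per-frame mean distances over the frames where it was a candidate.
#'
#' @param winners integer vector of per-frame winning cell ids, NA for
#'   abstaining frames.
#' @param distances list (one per frame) of named per-cell mean-distance
#'   vectors, as returned by \code{\link{assign_apoptotic_cell}}; only
#'   needed for the tie-break.
#' @return List with \code{cell_id}, \code{votes} (table) and
#'   \code{by_majority} (logical).
#' @export
majority_vote <- function(winners, distances = NULL) {
  voting <- winners[!is.na(winners)]
  if (!length(voting)) stop("all frames abstained")
  votes <- sort(table(voting), decreasing = TRUE)
  if (votes[1] * 2 > length(voting))
    return(list(cell_id = as.integer(names(votes)[1]), votes = votes,
                by_majority = TRUE))
  if (is.null(distances))
    stop("no strict majority and no distances for the tie-break")
  all_ids <- unique(unlist(lapply(distances, names)))
  mean_d <- vapply(all_ids, function(id) {
    ds <- unlist(lapply(distances, function(dv)
      if (!is.null(dv) && id %in% names(dv)) dv[[id]] else NULL))
    mean(ds)
  }, numeric(1))
  ord <- order(mean_d, as.integer(all_ids))
  list(cell_id = as.integer(all_ids[ord[1]]), votes = votes,
       by_majority = FALSE)
}

#' Identify the apoptotic cell in a video by ApoBD association
#'
#' Runs the reference ApoBD segmentation on a window of frames starting at
#' the onset (default 3 frames, matching the majority-voting window),
#' assigns a per-frame winner by least average distance, and resolves the
#' final apoptotic cell by majority vote.
#'
#' @param video a \code{\link{nanowell_video}}.
#' @param cells list of \code{\link{cell_record}} with per-frame centroids.
#' @param onset_frame 0-based onset frame.
#' @param window number of voting frames (default 3).
#' @param params blob-pipeline parameters.
#' @return List with \code{cell_id}, \code{per_frame} (winners) and
#'   \code{votes}.
#' @export
associate_apoptotic_cell <- function(video, cells, onset_frame,
                                     window = 3L, params = list()) {
  stopifnot(inherits(video, "nanowell_video"), onset_frame >= 0)
  n <- length(video$frames)
  frames_t <- seq(onset_frame, min(onset_frame + window - 1L, n - 1L))
  winners <- rep(NA_integer_, length(frames_t))
  dists <- vector("list", length(frames_t))
  for (j in seq_along(frames_t)) {
    t <- frames_t[j]
    fr <- video$frames[[t + 1L]]
    cmask <- Reduce(`|`, lapply(cells, function(cr) {
      m <- cr$masks[[t + 1L]]
      if (is.null(m)) matrix(FALSE, nrow(fr$phase), ncol(fr$phase)) else m
    }))
    seg <- segment_apobds_reference(fr, cmask, params)
    if (nrow(seg$centroids) == 0L) next
    cents <- stats::setNames(
      lapply(cells, function(cr) cr$centroids[t + 1L, ]),
      vapply(cells, `[[`, integer(1), "cell_id"))
    a <- assign_apoptotic_cell(cents, seg$centroids)
    winners[j] <- a$cell_id
    dists[[j]] <- a$distances
  }
  mv <- majority_vote(winners, dists)
  list(cell_id = mv$cell_id, per_frame = winners, votes = mv$votes)
}
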