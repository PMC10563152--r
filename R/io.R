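#' Write a nanowell video as per-frame 16-bit TIFFs
#'
#' Layout: \code{<dir>/<nanowell_id>/frame_<t>_<channel>.tif} with channel
#' one of \code{phase}, \code{effector}, \code{target}, \code{annexin} and
#' \code{t} the 0-based frame index. Intensities are clamped to
#' [0, 65535] and rounded to integers, so integer-valued videos round-trip
#' bit-exactly.
#'
#' @param video a \code{\link{nanowell_video}}.
#' @param dir output directory; the nanowell subdirectory is created.
#' @return The nanowell directory path, invisibly.
#' @export
write_video <- function(video, dir) {
  stopifnot(inherits(video, "nanowell_video"))
  well_dir <- file.path(dir, video$nanowell_id)
  dir.create(well_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in video$frames) {
    grids <- c(list(phase = f$phase), f$channels)
    for (ch in names(grids)) {
      img <- round(pmin(pmax(grids[[ch]], 0), 65535))
      tiff::writeTIFF(img / 65535, file.path(
        well_dir, sprintf("frame_%d_%s.tif", f$frame_index, ch)),
        bits.per.sample = 16L)
    }
  }
  invisible(well_dir)
}

#' Read a nanowell video written by \code{write_video}
#'
#' @param path the nanowell directory (containing the frame TIFFs).
#' @param frame_interval_minutes minutes between frames (not stored in the
#'   TIFFs; default 5).
#' @return A \code{\link{nanowell_video}}.
#' @export
read_video <- function(path, frame_interval_minutes = 5) {
  files <- list.files(path, pattern = "^frame_[0-9]+_[a-z]+\\.tif$")
  if (!length(files)) stop("no frame TIFFs found under ", path)
  m <- regmatches(files, regexec("^frame_([0-9]+)_([a-z]+)\\.tif$", files))
  t_idx <- vapply(m, function(x) as.integer(x[2]), integer(1))
  chans <- vapply(m, function(x) x[3], character(1))
  ts <- sort(unique(t_idx))
  if (!identical(ts, seq_along(ts) - 1L))
    stop("gap in frame numbering: found frames ",
         paste(ts, collapse = ","))
  frames <- lapply(ts, function(t) {
    here <- chans[t_idx == t]
    if (!"phase" %in% here)
      stop("frame ", t, " is missing channel 'phase'")
    read1 <- function(ch) {
      img <- tiff::readTIFF(
        file.path(path, sprintf("frame_%d_%s.tif", t, ch)), as.is = TRUE)
      matrix(as.numeric(img), nrow(img), ncol(img))
    }
    ch_names <- intersect(c("effector", "target", "annexin"), here)
    multichannel_frame(read1("phase"),
                       stats::setNames(lapply(ch_names, read1), ch_names),
                       frame_index = t)
  })
  # every frame must carry the same channel set
  sets <- lapply(frames, function(f) names(f$channels))
  for (i in seq_along(frames)) {
    miss <- setdiff(union(unlist(sets), character(0)), sets[[i]])
    if (length(miss))
      stop("frame ", i - 1L, " is missing channel '", miss[1], "'")
  }
  nanowell_video(basename(path), frames, frame_interval_minutes)
}

# Run-length encoding of a mask/label matrix, column-major, for the JSON
# truth sidecar (values, lengths, dim).
rle_encode <- function(m) {
  r <- rle(as.integer(m))
  list(values = r$values, lengths = r$lengths, dim = dim(m))
}

rle_decode <- function(enc) {
  matrix(inverse.rle(list(values = as.integer(enc$values),
                          lengths = as.integer(enc$lengths))),
         nrow = enc$dim[1], ncol = enc$dim[2])
}

#' Write simulation ground truth as a JSON sidecar
#'
#' Stores the onset frame, apoptotic cell id, Annexin flags, per-cell
#' centroid tracks and run-length-encoded per-frame cell and ApoBD instance
#' masks next to the TIFF frames.
#'
#' @param truth the \code{truth} element of a \code{\link{simulate_video}}
#'   result.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- list(
    onset_frame = truth$onset_frame,
    apoptotic_cell_id = truth$apoptotic_cell_id,
    annexin_valid = truth$annexin_valid,
    annexin_localized = truth$annexin_localized,
    contact_intervals = truth$contact_intervals,
    cells = lapply(truth$cells, function(cr) list(
      cell_id = cr$cell_id, cell_type = cr$cell_type,
      centroids = cr$centroids,
      masks = lapply(cr$masks, function(m)
        if (is.null(m)) NULL else rle_encode(m)))),
    apobd_instances = lapply(truth$apobd_instances, rle_encode))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#' @param path JSON file written by \code{\link{write_truth}}.
#' @return A truth list mirroring the simulator output.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = TRUE)
  x$cells <- lapply(x$cells, function(cr) cell_record(
    cr$cell_id, cr$cell_type,
    masks = lapply(cr$masks, function(m)
      if (is.null(m)) NULL else rle_decode(m) > 0L),
    centroids = matrix(unlist(cr$centroids), ncol = 2)))
  x$apobd_instances <- lapply(x$apobd_instances,
                              function(m) instance_mask(rle_decode(m)))
  x
}
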