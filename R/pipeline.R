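#' End-to-end analysis of one nanowell video
#'
#' Chains the full label-free pipeline: cell segmentation/tracking from the
#' fluorescence channels, per-frame ApoBD-presence classification on the
#' phase channel, onset calling under the consecutive-frame constraint,
#' apoptotic-cell association by least average ApoBD distance with
#' majority voting, effector-target contact (killing) detection, and
#' Annexin-V validity/localization assessment at the onset frame.
#'
#' @param video a \code{\link{nanowell_video}} with phase plus effector,
#'   target and (optionally) annexin channels.
#' @param cells optional list of \code{\link{cell_record}}; tracked from
#'   the fluorescence channels when omitted.
#' @param params blob-pipeline/classifier parameters; also \code{min_run}
#'   (default 3), \code{vote_window} (default 3), \code{contact_min_frames}
#'   (default 4), \code{annexin_threshold} (default 0.1),
#'   \code{even_threshold} (default 0.5), \code{min_cell_area}
#'   (default 50).
#' @return List: \code{is_event}, \code{onset_frame}, \code{onset_minutes},
#'   \code{apoptotic_cell_id}, \code{killing}, \code{contacts},
#'   \code{annexin} (assessment or NULL), \code{labels} (per-frame 0/1),
#'   \code{cells}.
#' @export
analyze_video <- function(video, cells = NULL, params = list()) {
  stopifnot(inherits(video, "nanowell_video"))
  min_run <- if (is.null(params$min_run)) 3L else params$min_run
  vote_window <- if (is.null(params$vote_window)) 3L else params$vote_window
  contact_min <- if (is.null(params$contact_min_frames)) 4L else
    params$contact_min_frames
  ann_thr <- if (is.null(params$annexin_threshold)) 0.1 else
    params$annexin_threshold
  even_thr <- if (is.null(params$even_threshold)) 0.5 else
    params$even_threshold
  min_cell_area <- if (is.null(params$min_cell_area)) 50L else
    params$min_cell_area

  if (is.null(cells)) cells <- track_cells(video, min_cell_area)
  n <- length(video$frames)
  dims <- dim(video$frames[[1]]$phase)
  cmask_t <- lapply(seq_len(n), function(t) {
    ms <- lapply(cells, function(cr) cr$masks[[t]])
    ms <- ms[!vapply(ms, is.null, logical(1))]
    if (length(ms)) Reduce(`|`, ms) else matrix(FALSE, dims[1], dims[2])
  })

  labels <- vapply(seq_len(n), function(t)
    as.integer(baseline_classifier(video$frames[[t]], cmask_t[[t]],
                                   params)$positive), integer(1))
  call <- detect_onset(labels, min_run)

  apoptotic_cell_id <- NULL
  annexin <- NULL
  killing <- FALSE
  contacts <- data.frame()
  if (call$is_event) {
    assoc <- tryCatch(
      associate_apoptotic_cell(video, cells, call$onset_frame,
                               vote_window, params),
      error = function(e) NULL)
    apoptotic_cell_id <- if (is.null(assoc)) NULL else assoc$cell_id

    eff <- Filter(function(cr) cr$cell_type == "effector", cells)
    tgt <- Filter(function(cr) cr$cell_type == "target", cells)
    for (e in eff) for (g in tgt) {
      ci <- detect_contacts(e, g, contact_min)
      if (nrow(ci)) contacts <- rbind(contacts, ci)
    }
    # a killing event: qualified contact with the apoptotic cell before
    # (or spanning) onset
    if (!is.null(apoptotic_cell_id) && nrow(contacts))
      killing <- any(contacts$target_id == apoptotic_cell_id &
                     contacts$start_frame < call$onset_frame)

    if ("annexin" %in% names(video$frames[[1]]$channels) &&
        !is.null(apoptotic_cell_id)) {
      apo <- Filter(function(cr) cr$cell_id == apoptotic_cell_id,
                    cells)[[1]]
      t_assess <- min(call$onset_frame + 1L, n - 1L)
      cm <- apo$masks[[t_assess + 1L]]
      if (!is.null(cm) && any(cm)) {
        ann_ch <- video$frames[[t_assess + 1L]]$channels$annexin
        annexin <- annexin_validity(ann_ch, cm, ann_thr)
        annexin <- classify_localization(annexin, even_thr)
        if (annexin$valid && killing) {
          row <- contacts[contacts$target_id == apoptotic_cell_id, ][1, ]
          epair <- Filter(function(cr) cr$cell_id == row$effector_id,
                          cells)[[1]]
          em <- epair$masks[[t_assess + 1L]]
          if (!is.null(em) && any(em)) {
            syn <- delineate_synapse(em, cm)
            lp <- localization_pcc(ann_ch, cm, syn)
            annexin$pcc_vs_cell <- lp$pcc_vs_cell
            annexin$pcc_vs_synapse <- lp$pcc_vs_synapse
          }
        }
      }
    }
  }
  list(is_event = call$is_event, onset_frame = call$onset_frame,
       onset_minutes = if (call$is_event)
         onset_minutes(call$onset_frame, video$frame_interval_minutes)
       else NULL,
       apoptotic_cell_id = apoptotic_cell_id, killing = killing,
       contacts = contacts, annexin = annexin, labels = labels,
       cells = cells)
}
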