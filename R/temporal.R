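#' Call the onset of apoptosis from a per-frame label sequence
#'
#' Scans the sequence for \code{min_run} consecutive ApoBD-positive frames
#' (default 3, the temporal constraint that separates genuine apoptosis
#' from sporadic single-frame noise). When a qualifying run exists the
#' sequence is an event and the onset is the first frame of the first such
#' run; under \code{onset_rule = "first_positive"} the onset is instead the
#' first positive frame anywhere in an event sequence.
#'
#' @param labels binary vector (0/1 or logical), one entry per frame.
#' @param min_run qualifying run length (default 3).
#' @param onset_rule "run_start" (default) or "first_positive".
#' @return An onset call: list with \code{is_event} and \code{onset_frame}
#'   (0-based, NULL for non-events).
#' @export
detect_onset <- function(labels, min_run = 3L,
                         onset_rule = c("run_start", "first_positive")) {
  if (length(labels) == 0L) stop("empty label sequence")
  if (min_run < 1) stop("min_run must be >= 1")
  onset_rule <- match.arg(onset_rule)
  sc <- scan_runs(as.logical(labels), min_run)
  if (is.null(sc$onset)) return(list(is_event = FALSE, onset_frame = NULL))
  onset <- if (onset_rule == "first_positive")
    which(as.logical(labels))[1] - 1L else sc$onset
  list(is_event = TRUE, onset_frame = as.integer(onset))
}

#' Frame error between a true and a predicted onset call
#'
#' When both calls are events, the error is the absolute onset difference
#' in frames. A missed event or a false event costs the full penalty
#' (by convention the sequence length, 10 frames for the standard
#' protocol). Two agreeing non-events cost 0.
#'
#' @param truth,pred onset calls as returned by \code{\link{detect_onset}}.
#' @param penalty frames charged for a missed or false event (default 10).
#' @return Non-negative number of frames.
#' @export
frame_error <- function(truth, pred, penalty = 10) {
  stopifnot(penalty > 0)
  if (truth$is_event && pred$is_event)
    return(abs(pred$onset_frame - truth$onset_frame))
  if (truth$is_event != pred$is_event) return(penalty)
  0
}

#' Evaluate onset calling on synthetic label sequences
#'
#' Runs the synthetic-sequence protocol: generate event and non-event
#' label sequences, corrupt the true labels with independent per-frame
#' false-positive/false-negative flips (or apply a supplied predictor),
#' call onsets on the corrupted sequences with the consecutive-frame
#' constraint, and average the frame error per class with the
#' sequence-length penalty for missed/false events.
#'
#' @param n_per_class sequences per class (default 300).
#' @param length frames per sequence (default 10).
#' @param max_positive_fraction cap on positive frames (default 0.5).
#' @param min_run qualifying run length (default 3).
#' @param fp_rate,fn_rate per-frame label flip probabilities.
#' @param predictor optional function(labels) -> predicted binary vector;
#'   overrides the flip-noise model.
#' @param seed RNG seed for both generation and corruption.
#' @return List with \code{mean_error_event}, \code{mean_error_nonevent}
#'   and \code{table}, a data.frame with one row per sequence.
#' @export
evaluate_protocol <- function(n_per_class = 300L, length = 10L,
                              max_positive_fraction = 0.5, min_run = 3L,
                              fp_rate = 0, fn_rate = 0, predictor = NULL,
                              seed = 1L) {
  seqs <- simulate_label_sequences(n_per_class, length,
                                   max_positive_fraction, min_run,
                                   seed = seed)
  rows <- with_seed(seed + 1L, lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    pred_labels <- if (!is.null(predictor)) as.integer(predictor(s$labels))
    else {
      flips <- stats::runif(length(s$labels))
      ifelse(s$labels == 1L, as.integer(flips >= fn_rate),
             as.integer(flips < fp_rate))
    }
    truth_call <- list(is_event = s$is_event, onset_frame = s$onset)
    pred_call <- detect_onset(pred_labels, min_run)
    data.frame(sequence = i, is_event = s$is_event,
               true_onset = if (s$is_event) s$onset else NA_integer_,
               pred_event = pred_call$is_event,
               pred_onset = if (pred_call$is_event) pred_call$onset_frame
               else NA_integer_,
               error = frame_error(truth_call, pred_call,
                                   penalty = length))
  }))
  tab <- do.call(rbind, rows)
  list(mean_error_event = mean(tab$error[tab$is_event]),
       mean_error_nonevent = mean(tab$error[!tab$is_event]),
       table = tab)
}

#' Convert an onset frame to minutes
#' @param onset_frame 0-based frame index.
#' @param frame_interval_minutes minutes per frame (default 5).
#' @return Minutes since the start of the video.
#' @export
onset_minutes <- function(onset_frame, frame_interval_minutes = 5) {
  onset_frame * frame_interval_minutes
}
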