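#' Simulation configuration for synthetic nanowell videos
#'
#' Defaults describe a stylized TIMING nanowell: a 256 x 256 px crop holding
#' a few effector and target cells (disks of radius 8-14 px with a dark
#' interior and bright halo), an apoptosis event at a configurable onset
#' frame releasing 3-12 apoptotic bodies with pixel areas inside the 20-200
#' px detection band, and an Annexin-V channel that lights up for about 30%
#' of apoptotic events (the fraction observed in Mel526-TIL killing
#' assays), either evenly over the dying cell or localized toward the
#' immune synapse.
#'
#' @param image_size integer (H, W), default c(256, 256).
#' @param n_effectors,n_targets cell counts, defaults 1 and 2.
#' @param cell_radius_px range the per-cell radius is drawn from.
#' @param apobd_area_px range apoptotic-body pixel areas are drawn from.
#' @param apobd_count_at_burst range of the number of bodies released.
#' @param onset_frame 0-based frame of apoptosis onset, or NULL for a
#'   non-event video.
#' @param n_frames number of frames (5 min apart by default downstream).
#' @param annexin_positive_prob probability the event shows Annexin-V.
#' @param annexin_localized_prob probability an Annexin-positive event is
#'   synapse-localized rather than even.
#' @param motion_sigma_px per-frame random-walk step of cell centers.
#' @param noise_sigma additive Gaussian noise (16-bit intensity units).
#' @param killing simulate an effector-target contact before onset.
#' @param contact_frames length of the forced contact run (frames).
#' @param seed integer RNG seed; same seed and config give bit-identical
#'   output.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(image_size = c(256L, 256L),
                       n_effectors = 1L, n_targets = 2L,
                       cell_radius_px = c(8, 14),
                       apobd_area_px = c(20, 200),
                       apobd_count_at_burst = c(3L, 12L),
                       onset_frame = 4L, n_frames = 10L,
                       annexin_positive_prob = 0.3,
                       annexin_localized_prob = 0.5,
                       motion_sigma_px = 1, noise_sigma = 30,
                       killing = TRUE, contact_frames = 5L,
                       seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 64),
            n_effectors >= 0, n_targets >= 0,
            diff(range(cell_radius_px)) >= 0, all(cell_radius_px > 0),
            all(apobd_area_px > 0), apobd_area_px[1] <= apobd_area_px[2],
            apobd_count_at_burst[1] >= 1,
            n_frames >= 1,
            annexin_positive_prob >= 0, annexin_positive_prob <= 1,
            annexin_localized_prob >= 0, annexin_localized_prob <= 1,
            motion_sigma_px >= 0, noise_sigma >= 0, contact_frames >= 0)
  if (!is.null(onset_frame)) {
    onset_frame <- as.integer(onset_frame)
    if (onset_frame < 0 || onset_frame >= n_frames)
      stop("onset_frame must lie in [0, n_frames)")
    if (n_targets < 1) stop("an apoptosis event requires at least one target")
  }
  structure(list(image_size = as.integer(image_size),
                 n_effectors = as.integer(n_effectors),
                 n_targets = as.integer(n_targets),
                 cell_radius_px = cell_radius_px,
                 apobd_area_px = apobd_area_px,
                 apobd_count_at_burst = as.integer(apobd_count_at_burst),
                 onset_frame = onset_frame, n_frames = as.integer(n_frames),
                 annexin_positive_prob = annexin_positive_prob,
                 annexin_localized_prob = annexin_localized_prob,
                 motion_sigma_px = motion_sigma_px,
                 noise_sigma = noise_sigma,
                 killing = isTRUE(killing),
                 contact_frames = as.integer(contact_frames),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Logical disk: pixels whose center distance to `center` is <= r.
disk_mask <- function(h, w, center, r) {
  dr <- outer((seq_len(h) - center[1])^2, (seq_len(w) - center[2])^2, "+")
  dr <= r^2
}

# run a block with a private RNG stream, restoring global state afterwards
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate one nanowell video with full ground truth
#'
#' Renders a stylized phase-contrast channel (cells as dark textured disks
#' with a bright halo; apoptotic bodies as small bright or dark disks
#' released around the dying cell from the onset frame on), fluorescence
#' channels consistent with the cell masks, and an Annexin-V channel that
#' is nonzero only for Annexin-valid events. When a killing event is
#' simulated the first effector's mask overlaps the apoptotic target's for
#' a run of \code{contact_frames} frames ending just before onset.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with elements \code{video} (a
#'   \code{\link{nanowell_video}}) and \code{truth} (onset frame, apoptotic
#'   cell id, Annexin flags, per-frame ApoBD instance masks, cell records
#'   and contact intervals).
#' @export
simulate_video <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_video_impl(config))
}

simulate_video_impl <- function(config) {
  h <- config$image_size[1]; w <- config$image_size[2]
  n_cells <- config$n_effectors + config$n_targets
  if (n_cells < 1) stop("at least one cell is required")
  types <- c(rep("effector", config$n_effectors),
             rep("target", config$n_targets))
  radii <- stats::runif(n_cells, config$cell_radius_px[1],
                        config$cell_radius_px[2])

  # initial non-overlapping placement, bounded retries
  centers <- matrix(NA_real_, n_cells, 2)
  for (i in seq_len(n_cells)) {
    ok <- FALSE
    for (try in seq_len(200)) {
      p <- c(stats::runif(1, radii[i] + 3, h - radii[i] - 2),
             stats::runif(1, radii[i] + 3, w - radii[i] - 2))
      if (i == 1L ||
          all(sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE],
                                 2, p)^2)) >
              radii[seq_len(i - 1)] + radii[i] + 2)) {
        centers[i, ] <- p; ok <- TRUE; break
      }
    }
    if (!ok) stop("cells cannot be placed without overlap")
  }

  onset <- config$onset_frame
  apo_id <- if (!is.null(onset))
    config$n_effectors + sample.int(config$n_targets, 1) else NULL

  # forced effector-target contact run ending just before onset
  contact <- NULL
  eff_id <- if (config$n_effectors >= 1) 1L else NULL
  if (config$killing && !is.null(onset) && !is.null(eff_id) &&
      config$contact_frames > 0) {
    ce <- onset - 1L
    cs <- max(0L, ce - config$contact_frames + 1L)
    if (ce >= cs)
      contact <- list(effector_id = eff_id, target_id = apo_id,
                      start_frame = cs, end_frame = ce,
                      angle = stats::runif(1, 0, 2 * pi))
  }

  # per-frame cell trajectories (random walk, overlap-rejecting)
  traj <- array(NA_real_, c(config$n_frames, n_cells, 2))
  traj[1, , ] <- centers
  pos <- centers
  step_frame <- function(pos, t) {
    for (i in seq_len(n_cells)) {
      forced <- !is.null(contact) && i == contact$effector_id &&
        t >= contact$start_frame && t <= contact$end_frame
      if (forced) {
        tc <- pos[contact$target_id, ]
        d <- radii[contact$effector_id] + radii[contact$target_id] - 3
        p <- tc + d * c(cos(contact$angle), sin(contact$angle))
        p[1] <- min(max(p[1], radii[i] + 1), h - radii[i])
        p[2] <- min(max(p[2], radii[i] + 1), w - radii[i])
        pos[i, ] <- p
        next
      }
      p <- pos[i, ] + stats::rnorm(2, 0, config$motion_sigma_px)
      in_b <- p[1] > radii[i] + 1 && p[1] < h - radii[i] &&
        p[2] > radii[i] + 1 && p[2] < w - radii[i]
      others <- setdiff(seq_len(n_cells), i)
      # during a forced contact the pair is allowed to overlap
      pairs_ok <- all(vapply(others, function(j) {
        allow <- !is.null(contact) && t >= contact$start_frame &&
          t <= contact$end_frame &&
          setequal(c(i, j), c(contact$effector_id, contact$target_id))
        allow || sqrt(sum((p - pos[j, ])^2)) > radii[i] + radii[j] + 1
      }, logical(1)))
      if (in_b && pairs_ok) pos[i, ] <- p
    }
    pos
  }
  force_contact <- function(pos, t) {
    if (!is.null(contact) && t >= contact$start_frame &&
        t <= contact$end_frame) {
      tc <- pos[contact$target_id, ]
      i <- contact$effector_id
      d <- radii[i] + radii[contact$target_id] - 3
      p <- tc + d * c(cos(contact$angle), sin(contact$angle))
      p[1] <- min(max(p[1], radii[i] + 1), h - radii[i])
      p[2] <- min(max(p[2], radii[i] + 1), w - radii[i])
      pos[i, ] <- p
    }
    pos
  }
  for (t in seq_len(config$n_frames) - 1L) {
    if (t > 0) pos <- step_frame(pos, t)
    pos <- force_contact(pos, t)
    traj[t + 1L, , ] <- pos
  }

  # apoptotic bodies: sizes/polarities drawn at burst, jittered positions
  apobds <- NULL
  if (!is.null(onset)) {
    k <- sample(seq(config$apobd_count_at_burst[1],
                    config$apobd_count_at_burst[2]), 1)
    areas <- stats::runif(k, config$apobd_area_px[1],
                          config$apobd_area_px[2])
    # a disk of radius r holds ~pi r^2 pixels; aim the rendered pixel area
    # at the drawn value
    ar <- sqrt(areas / pi)
    pol <- sample(c(-1, 1), k, replace = TRUE)
    apobds <- list(k = k, r = ar, polarity = pol,
                   pos = array(NA_real_, c(config$n_frames, k, 2)))
    place_ok <- function(p, r, placed, cell_pos) {
      if (p[1] < r + 2 || p[1] > h - r - 1 ||
          p[2] < r + 2 || p[2] > w - r - 1) return(FALSE)
      for (j in seq_len(n_cells))
        if (sqrt(sum((p - cell_pos[j, ])^2)) < radii[j] + r + 6)
          return(FALSE)
      if (length(placed))
        for (q in placed)
          if (sqrt(sum((p - q$p)^2)) < r + q$r + 3) return(FALSE)
      TRUE
    }
    for (t in seq(onset, config$n_frames - 1L)) {
      cell_pos <- matrix(traj[t + 1L, , ], n_cells, 2)
      placed <- list()
      for (i in seq_len(k)) {
        found <- FALSE
        if (t > onset) {  # jitter last position first
          for (try in seq_len(30)) {
            p <- apobds$pos[t, i, ] + stats::rnorm(2, 0, 1)
            if (place_ok(p, ar[i], placed, cell_pos)) {
              found <- TRUE; break
            }
          }
        }
        if (!found) {  # ring around the apoptotic cell, widening
          ac <- cell_pos[apo_id, ]
          for (try in seq_len(300)) {
            ang <- stats::runif(1, 0, 2 * pi)
            d <- radii[apo_id] + ar[i] +
              stats::runif(1, 6, 20 + try / 5)
            p <- ac + d * c(cos(ang), sin(ang))
            if (place_ok(p, ar[i], placed, cell_pos)) {
              found <- TRUE; break
            }
          }
        }
        if (!found) stop("could not place apoptotic bodies in the well")
        apobds$pos[t + 1L, i, ] <- p
        placed[[length(placed) + 1L]] <- list(p = p, r = ar[i])
      }
    }
  }

  annexin_valid <- if (!is.null(onset))
    stats::runif(1) < config$annexin_positive_prob else FALSE
  annexin_localized <- if (annexin_valid)
    stats::runif(1) < config$annexin_localized_prob else FALSE
  annexin_angle <- stats::runif(1, 0, 2 * pi)
  if (!is.null(contact)) annexin_angle <- contact$angle + pi

  frames <- vector("list", config$n_frames)
  apobd_instances <- vector("list", config$n_frames)
  cell_masks_t <- vector("list", config$n_frames)
  ns <- config$noise_sigma
  for (t in seq_len(config$n_frames) - 1L) {
    cell_pos <- matrix(traj[t + 1L, , ], n_cells, 2)
    cmasks <- lapply(seq_len(n_cells), function(i)
      disk_mask(h, w, cell_pos[i, ], radii[i]))
    cell_masks_t[[t + 1L]] <- cmasks

    phase <- matrix(2000 + stats::rnorm(h * w, 0, ns), h, w)
    for (i in seq_len(n_cells)) {
      halo <- disk_mask(h, w, cell_pos[i, ], radii[i] + 2) & !cmasks[[i]]
      phase[halo] <- 3400 + stats::rnorm(sum(halo), 0, ns)
      phase[cmasks[[i]]] <-
        1400 + stats::rnorm(sum(cmasks[[i]]), 0, ns + 60)
    }

    lab <- matrix(0L, h, w)
    if (!is.null(apobds) && t >= onset) {
      for (i in seq_len(apobds$k)) {
        m <- disk_mask(h, w, apobds$pos[t + 1L, i, ], apobds$r[i])
        lab[m] <- i
        amp <- 2000 + apobds$polarity[i] * 1300
        phase[m] <- amp + stats::rnorm(sum(m), 0, ns)
      }
    }
    apobd_instances[[t + 1L]] <- instance_mask(lab)

    mk_fluor <- function(type) {
      ch <- matrix(150 + stats::rnorm(h * w, 0, max(ns / 2, 5)), h, w)
      for (i in which(types == type))
        ch[cmasks[[i]]] <- 8000 + stats::rnorm(sum(cmasks[[i]]), 0, 150)
      pmax(ch, 0)
    }
    annexin <- matrix(0, h, w)
    if (annexin_valid && t >= onset) {
      ac <- cell_pos[apo_id, ]; rc <- radii[apo_id]
      sig_mask <- if (annexin_localized) {
        disk_mask(h, w, ac + 0.7 * rc * c(cos(annexin_angle),
                                          sin(annexin_angle)), 0.55 * rc)
      } else cmasks[[apo_id]]
      annexin[sig_mask] <- 6000 + stats::rnorm(sum(sig_mask), 0, 150)
      annexin <- pmax(annexin, 0)
    }

    frames[[t + 1L]] <- multichannel_frame(
      pmax(phase, 0),
      list(effector = mk_fluor("effector"), target = mk_fluor("target"),
           annexin = annexin),
      frame_index = t)
  }

  cells <- lapply(seq_len(n_cells), function(i) cell_record(
    i, types[i],
    masks = lapply(cell_masks_t, `[[`, i),
    centroids = matrix(traj[, i, ], config$n_frames, 2)))

  truth <- list(
    onset_frame = onset, apoptotic_cell_id = apo_id,
    annexin_valid = annexin_valid, annexin_localized = annexin_localized,
    cells = cells, apobd_instances = apobd_instances,
    contact_intervals = if (is.null(contact)) list() else
      list(contact[c("effector_id", "target_id", "start_frame",
                     "end_frame")]))
  structure(list(video = nanowell_video("sim", frames), truth = truth),
            class = "sim_output")
}

# longest run of TRUE and the 0-based start of the first run >= min_run
scan_runs <- function(labels, min_run) {
  r <- rle(as.logical(labels))
  starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  hit <- which(r$values & r$lengths >= min_run)
  list(longest = if (any(r$values)) max(r$lengths[r$values]) else 0L,
       onset = if (length(hit)) starts[hit[1]] - 1L else NULL)
}

#' Simulate binary ApoBD-presence label sequences
#'
#' Generates the synthetic evaluation protocol for onset calling: equal
#' numbers of event and non-event sequences of a fixed length (default
#' protocol: 300 + 300 sequences of 10 frames), in which at most
#' \code{ceiling(max_positive_fraction * length)} frames are positive.
#' Event sequences contain at least one run of \code{min_run} consecutive
#' positives; non-event sequences contain none. Positive positions are
#' rejection-sampled uniformly over the feasible arrangements, with the
#' positive count drawn uniformly over its feasible range.
#'
#' @param n_per_class sequences per class.
#' @param length frames per sequence.
#' @param max_positive_fraction cap on the positive fraction (default 1/2).
#' @param min_run qualifying run length (default 3 frames).
#' @param seed RNG seed.
#' @return A list of \code{2 * n_per_class} entries, each a list with
#'   \code{labels} (integer 0/1 vector), \code{is_event} and \code{onset}
#'   (0-based first frame of the first qualifying run, or NULL).
#' @export
simulate_label_sequences <- function(n_per_class, length = 10L,
                                     max_positive_fraction = 0.5,
                                     min_run = 3L, seed = 1L) {
  stopifnot(n_per_class >= 1, length >= 1, min_run >= 1,
            max_positive_fraction > 0, max_positive_fraction <= 1)
  if (length < min_run)
    stop("length must be >= min_run")
  max_pos <- as.integer(ceiling(max_positive_fraction * length))
  if (min_run > max_pos)
    stop("infeasible: min_run exceeds the allowed number of positives")
  # largest positive count arrangeable with every run < min_run
  max_nonevent <- length - floor(length / min_run)
  with_seed(seed, {
    draw <- function(is_event) {
      ks <- if (is_event) seq(min_run, max_pos) else
        seq(0L, min(max_pos, max_nonevent))
      for (try in seq_len(10000L)) {
        k <- if (length(ks) == 1L) ks else sample(ks, 1)
        labels <- integer(length)
        if (k > 0) labels[sample.int(length, k)] <- 1L
        sc <- scan_runs(labels, min_run)
        if (is_event == (sc$longest >= min_run))
          return(list(labels = labels, is_event = is_event,
                      onset = sc$onset))
      }
      stop("rejection sampling failed; constraints look infeasible")
    }
    c(lapply(seq_len(n_per_class), function(i) draw(TRUE)),
      lapply(seq_len(n_per_class), function(i) draw(FALSE)))
  })
}
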