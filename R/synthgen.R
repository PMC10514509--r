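# Synthetic organoid time-lapse generator. The organoid is modelled as a 2D
# ring of nuclei (the equatorial cross-section of a nearly centrosymmetric
# shell) rendered into 3D z-stacks; cells move tangentially within the shell.

# fraction of the mean angular spacing used as angular placement jitter
ANGLE_JITTER_FRAC <- 0.05

frame_times_h <- function(spec) {
  (seq_len(spec$n_frames) - 1L) * spec$frame_interval_min / 60
}

#' Create the frame-0 ground truth of a synthetic organoid
#'
#' Places `n_cells` nuclei at approximately equally spaced angles (small
#' angular jitter, Gaussian radial jitter) on a ring of radius `radius_um`.
#' The circle centre is placed so that the organoid fits the rendered field
#' of view at all frames, including growth.
#'
#' @param spec an [organoid_spec()].
#' @return An object of class `synthetic_truth`: a list with `cells`
#'   (data.frame: frame, cell_id, x_um, y_um, angle_rad, radius_offset_um,
#'   edu_label, ablated), `circle_center_xy_um`, `circle_radius_um_per_frame`,
#'   `fov_um`, `ablation` (NULL until [apply_ablation()]), and `spec`.
#' @export
make_organoid <- function(spec) {
  validate_organoid_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_cells
  t_h <- frame_times_h(spec)
  r_frames <- spec$radius_um * (1 + spec$growth_rate_per_h * t_h)
  # pad: growth + jitter + nucleus footprint + safety margin
  pad <- 4 * spec$radial_jitter_um + 6 * spec$nucleus_sigma_um + 10
  half <- max(r_frames) + pad
  center <- c(half, half)

  spacing <- 2 * pi / n
  angles <- (seq_len(n) - 1L) * spacing +
    stats::rnorm(n, 0, ANGLE_JITTER_FRAC * spacing)
  angles <- wrap_angle(angles)
  r_off <- stats::rnorm(n, 0, spec$radial_jitter_um)
  r0 <- spec$radius_um + r_off

  cells <- data.frame(
    frame = 0L, cell_id = seq_len(n),
    x_um = center[1] + r0 * cos(angles),
    y_um = center[2] + r0 * sin(angles),
    angle_rad = angles, radius_offset_um = r_off,
    edu_label = FALSE, ablated = FALSE)

  structure(list(cells = cells, circle_center_xy_um = center,
                 circle_radius_um_per_frame = r_frames, fov_um = 2 * half,
                 ablation = NULL, spec = spec),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  nf <- length(unique(x$cells$frame))
  cat("synthetic_truth:", length(unique(x$cells$cell_id)), "cells,", nf,
      "frame(s), radius", round(x$circle_radius_um_per_frame[1], 1), "um",
      if (!is.null(x$ablation))
        paste0(", ", x$ablation$k, " cell(s) ablated at frame ",
               x$ablation$frame), "\n")
  invisible(x)
}

# wrap angles to [-pi, pi)
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out >= pi] <- -pi
  out
}

#' Ablate a contiguous group of cells
#'
#' Marks `k` angularly contiguous cells as ablated. Ablated cells keep their
#' position up to and including the ablation frame and are removed from all
#' later frames. The ablation site is the circular mean of the ablated cells'
#' angles, projected onto the shell circle.
#'
#' @param truth a `synthetic_truth`.
#' @param k number of cells to ablate (1 <= k < n_cells).
#' @param frame ablation frame index (default 0).
#' @param seed seed selecting the first ablated cell; default derives from the
#'   organoid spec seed.
#' @return The modified `synthetic_truth` with an `ablation` element
#'   (`k`, `frame`, `cell_ids`, `theta_rad`, `center_xy_um`).
#' @export
apply_ablation <- function(truth, k, frame = 0L,
                           seed = truth$spec$seed + 10000019L) {
  n <- truth$spec$n_cells
  if (!is.numeric(k) || k < 1 || k >= n)
    stop("k must satisfy 1 <= k < n_cells (", n, ")", call. = FALSE)
  k <- as.integer(k)
  set.seed(seed)
  f0 <- truth$cells[truth$cells$frame == 0L, ]
  ord <- order(f0$angle_rad)
  start <- sample.int(n, 1L)
  idx <- ord[((start - 1L + seq_len(k) - 1L) %% n) + 1L]
  ids <- f0$cell_id[idx]

  theta <- atan2(mean(sin(f0$angle_rad[idx])), mean(cos(f0$angle_rad[idx])))
  theta <- wrap_angle(theta)
  r <- truth$circle_radius_um_per_frame[min(frame + 1L,
                                            length(truth$circle_radius_um_per_frame))]
  center_xy <- truth$circle_center_xy_um + r * c(cos(theta), sin(theta))

  truth$cells$ablated[truth$cells$cell_id %in% ids] <- TRUE
  truth$cells <- truth$cells[!(truth$cells$ablated & truth$cells$frame > frame), ]
  truth$ablation <- list(k = k, frame = as.integer(frame), cell_ids = ids,
                         theta_rad = theta, center_xy_um = center_xy)
  truth
}

#' Simulate cell motion over all frames
#'
#' Starting from the frame-0 truth, each surviving cell's angle advances per
#' frame by a tangential Gaussian step of SD `sigma_tangential_um` (expressed
#' in radians as sigma/R). If an ablation exists and the cell lies within
#' `drift_range_um` arc distance of the wound, it additionally steps
#' `drift_speed_um_per_frame` toward the wound angle (never overshooting).
#' The shell radius follows the growth law R(t) = R0 (1 + g t).
#'
#' @param truth a `synthetic_truth` holding frame 0 (ablation optional).
#' @param motion a [motion_spec()].
#' @param seed seed for the motion random walk.
#' @return The `synthetic_truth` with `cells` covering all frames.
#' @export
simulate_timelapse <- function(truth, motion = motion_spec(),
                               seed = truth$spec$seed + 20000003L) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(motion, "motion_spec"))
  spec <- truth$spec
  set.seed(seed)
  f0 <- truth$cells[truth$cells$frame == 0L, ]
  abl <- truth$ablation
  frames <- list(f0)
  cur <- f0
  for (f in seq_len(spec$n_frames - 1L)) {
    r_shell <- truth$circle_radius_um_per_frame[f + 1L]
    growth_fac <- r_shell / spec$radius_um
    alive <- cur
    if (!is.null(abl) && f > abl$frame)
      alive <- alive[!alive$ablated, ]
    m <- nrow(alive)
    if (m > 0) {
      dtheta <- stats::rnorm(m, 0, motion$sigma_tangential_um / r_shell)
      if (!is.null(abl) && motion$drift_speed_um_per_frame > 0 &&
          motion$drift_range_um > 0 && f > abl$frame) {
        dth_w <- wrap_angle(abl$theta_rad - alive$angle_rad)
        arc <- r_shell * abs(dth_w)
        in_range <- arc > 0 & arc <= motion$drift_range_um
        step <- pmin(motion$drift_speed_um_per_frame / r_shell, abs(dth_w))
        dtheta[in_range] <- dtheta[in_range] +
          sign(dth_w[in_range]) * step[in_range]
      }
      alive$angle_rad <- wrap_angle(alive$angle_rad + dtheta)
      r_cell <- (spec$radius_um + alive$radius_offset_um) * growth_fac
      alive$x_um <- truth$circle_center_xy_um[1] + r_cell * cos(alive$angle_rad)
      alive$y_um <- truth$circle_center_xy_um[2] + r_cell * sin(alive$angle_rad)
    }
    alive$frame <- f
    frames[[f + 1L]] <- alive
    cur <- alive
  }
  truth$cells <- do.call(rbind, frames)
  rownames(truth$cells) <- NULL
  truth
}

#' Assign ground-truth EdU labels
#'
#' Each cell is independently labelled with probability
#' `baseline_rate + boost(bin)`, where the bin is the 30-um arc-distance bin
#' of the cell at the organoid's last simulated frame (the fixed, imaged
#' timepoint of an EdU assay). Labels are constant across frames.
#'
#' @param truth a `synthetic_truth`.
#' @param labels a [label_spec()].
#' @param bin_width_um distance-bin width (default 30 um).
#' @param seed seed for the Bernoulli draws.
#' @return The `synthetic_truth` with `edu_label` filled in.
#' @export
assign_edu_labels <- function(truth, labels = label_spec(), bin_width_um = 30,
                              seed = truth$spec$seed + 30000001L) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(labels, "label_spec"))
  if (length(labels$bin_boosts) && is.null(truth$ablation))
    stop("bin_boosts require an ablation site; call apply_ablation() first",
         call. = FALSE)
  set.seed(seed)
  last <- max(truth$cells$frame)
  ref <- truth$cells[truth$cells$frame == last, ]
  p <- rep(labels$baseline_rate, nrow(ref))
  if (length(labels$bin_boosts)) {
    r_shell <- truth$circle_radius_um_per_frame[last + 1L]
    dth <- wrap_angle(ref$angle_rad - truth$ablation$theta_rad)
    arc <- r_shell * pmin(abs(dth), 2 * pi - abs(dth))
    bin <- floor(arc / bin_width_um)
    boost <- labels$bin_boosts[as.character(bin)]
    boost[is.na(boost)] <- 0
    p <- p + boost
  }
  if (any(p < 0 | p > 1))
    stop("labelling probability outside [0, 1]; check label_spec", call. = FALSE)
  lab <- stats::runif(nrow(ref)) < p
  names(lab) <- ref$cell_id
  truth$cells$edu_label <- unname(lab[as.character(truth$cells$cell_id)])
  truth$cells$edu_label[is.na(truth$cells$edu_label)] <- FALSE
  truth
}

#' Render a synthetic truth into image z-stacks
#'
#' Channel 1 is the nuclear label: each nucleus is a 3D Gaussian (lateral SD
#' `nucleus_sigma_um`, axial Gaussian attenuation) on a dark background.
#' Channel 2 is EdU: same positions, amplitude multiplied by
#' `channel_contrast` for labelled cells. Optional shot (Poisson) and Gaussian
#' read noise; the ablation scar is rendered as a bright static blob for
#' `scar_frames` frames after ablation and is absent from the ground truth.
#'
#' @param truth a `synthetic_truth` covering the requested frames.
#' @param labels a [label_spec()] (used for channel contrast) or NULL to
#'   render only the nuclear channel.
#' @param frames integer vector of frame indices to render (default: all).
#' @param noise logical; apply Poisson shot noise and Gaussian read noise.
#' @param read_noise_sd SD of the additive Gaussian read noise (counts).
#' @param background background level (counts).
#' @param amplitude peak nuclear amplitude (counts).
#' @param edu_base unlabelled-cell amplitude in the EdU channel (counts).
#' @param axial_sigma_um axial Gaussian attenuation SD (um).
#' @param scar_frames number of frames after ablation with a rendered scar.
#' @param scar_amplitude peak scar amplitude (counts).
#' @param seed seed for the rendering noise.
#' @return An object of class `organoid_stack`: list with `data` (numeric
#'   array \[y, x, z, channel, frame\]), `frames`, `z_um`, `pixel_size_um`,
#'   `channels`.
#' @export
render_stack <- function(truth, labels = label_spec(), frames = NULL,
                         noise = TRUE, read_noise_sd = 2, background = 5,
                         amplitude = 120, edu_base = 25, axial_sigma_um = 4,
                         scar_frames = 3L, scar_amplitude = 200,
                         seed = truth$spec$seed + 40000003L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  spec <- truth$spec
  if (is.null(frames)) frames <- sort(unique(truth$cells$frame))
  if (length(frames) == 0) frames <- 0L
  if (!all(frames %in% 0:(spec$n_frames - 1L)))
    stop("truth does not cover requested frames", call. = FALSE)
  px <- spec$pixel_size_um
  npx <- as.integer(ceiling(truth$fov_um / px))
  z_um <- seq(-spec$z_range_um, spec$z_range_um, by = spec$z_step_um)
  nz <- length(z_um)
  nch <- if (is.null(labels)) 1L else 2L
  sig <- spec$nucleus_sigma_um

  # reject fields of view that cannot contain the rendered organoid
  lim <- c(3 * sig, truth$fov_um - 3 * sig)
  pos_all <- truth$cells[truth$cells$frame %in% frames, ]
  if (nrow(pos_all) && (min(pos_all$x_um, pos_all$y_um) < lim[1] ||
                        max(pos_all$x_um, pos_all$y_um) > lim[2]))
    stop("field of view smaller than organoid", call. = FALSE)

  set.seed(seed)
  zatt <- exp(-z_um^2 / (2 * axial_sigma_um^2))
  w <- ceiling(4 * sig / px)  # half-width of the per-nucleus patch, px
  arr <- array(background, dim = c(npx, npx, nz, nch, length(frames)))

  add_blob <- function(slab, x_um, y_um, amp, sigma_um) {
    # slab: [y, x] matrix; returns slab with Gaussian added at (x_um, y_um)
    cx <- x_um / px + 0.5  # pixel-centre coordinates (pixel i spans (i-1, i]*px)
    cy <- y_um / px + 0.5
    wp <- ceiling(4 * sigma_um / px)
    xs <- max(1L, floor(cx) - wp):min(npx, floor(cx) + wp)
    ys <- max(1L, floor(cy) - wp):min(npx, floor(cy) + wp)
    gx <- exp(-((xs - cx) * px)^2 / (2 * sigma_um^2))
    gy <- exp(-((ys - cy) * px)^2 / (2 * sigma_um^2))
    slab[ys, xs] <- slab[ys, xs] + amp * (gy %o% gx)
    slab
  }

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    cells <- truth$cells[truth$cells$frame == f, ]
    scar <- !is.null(truth$ablation) && f >= truth$ablation$frame &&
      f < truth$ablation$frame + scar_frames
    for (ch in seq_len(nch)) {
      # lateral pattern is z-independent; render once, scale by z attenuation
      base <- matrix(0, npx, npx)
      if (nrow(cells)) {
        amp <- if (ch == 1L) rep(amplitude, nrow(cells)) else
          edu_base * ifelse(cells$edu_label, labels$channel_contrast, 1)
        for (i in seq_len(nrow(cells)))
          base <- add_blob(base, cells$x_um[i], cells$y_um[i], amp[i], sig)
      }
      if (scar)
        base <- add_blob(base, truth$ablation$center_xy_um[1],
                         truth$ablation$center_xy_um[2],
                         scar_amplitude, 2.5 * sig)
      for (zi in seq_len(nz))
        arr[, , zi, ch, fi] <- background + zatt[zi] * base
    }
  }
  if (noise) {
    n_el <- length(arr)
    arr[] <- stats::rpois(n_el, lambda = as.vector(arr)) +
      stats::rnorm(n_el, 0, read_noise_sd)
    arr[arr < 0] <- 0
  }
  structure(list(data = arr, frames = as.integer(frames), z_um = z_um,
                 pixel_size_um = px, channels = nch),
            class = "organoid_stack")
}

#' @export
print.organoid_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("organoid_stack:", d[5], "frame(s) x", d[3], "z x", d[4], "channel(s) x",
      d[1], "x", d[2], "px @", x$pixel_size_um, "um/px\n")
  invisible(x)
}

#' Write / read a synthetic ground-truth table as CSV
#'
#' Columns: frame, cell_id, x_um, y_um, angle_rad, edu_label, ablated.
#' Coordinates are micrometres with the origin at the image top-left corner
#' and y increasing downward; bins are half-open \[lo, hi); frame 0 is the
#' first (pre-ablation) frame. These conventions are stated in `#` header
#' comments.
#'
#' @param truth a `synthetic_truth`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# synthetic organoid ground truth",
               "# units: um; origin top-left; y increases downward; frame 0 = pre-ablation"),
             con)
  utils::write.table(
    truth$cells[, c("frame", "cell_id", "x_um", "y_um", "angle_rad",
                    "edu_label", "ablated")],
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @param path path of a CSV written by [write_truth_csv()].
#' @return `read_truth_csv`: the truth data.frame.
#' @export
read_truth_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write an image stack as multi-page TIFF with a JSON metadata sidecar
#'
#' Pages are ordered frame-major, then z, then channel ("TZCYX"). Intensities
#' are stored as 32-bit float scaled by `scale`; the sidecar (`<path>.json`)
#' records axis order, dimensions, pixel size, z positions, frame indices and
#' the intensity scale, so the stack round-trips exactly.
#'
#' @param stack an `organoid_stack`.
#' @param path output TIFF path.
#' @param scale intensity divisor applied before writing (counts per unit).
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, scale = 65535) {
  stopifnot(inherits(stack, "organoid_stack"))
  d <- dim(stack$data)
  pages <- vector("list", d[5] * d[3] * d[4])
  k <- 1L
  for (fi in seq_len(d[5])) for (zi in seq_len(d[3])) for (ch in seq_len(d[4])) {
    pages[[k]] <- stack$data[, , zi, ch, fi] / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(axes = "TZCYX", n_frames = d[5], n_z = d[3], n_channels = d[4],
               height_px = d[1], width_px = d[2],
               pixel_size_um = stack$pixel_size_um, z_um = stack$z_um,
               frames = stack$frames, intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @return `read_stack_tiff`: the `organoid_stack`.
#' @export
read_stack_tiff <- function(path) {
  meta_path <- paste0(path, ".json")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    # fallback: single frame, single channel, all pages are z-slices
    meta <- list(n_frames = 1L, n_z = length(pages), n_channels = 1L,
                 pixel_size_um = 1, z_um = seq_along(pages), frames = 0L,
                 intensity_scale = 1)
  }
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(d[1], d[2], meta$n_z, meta$n_channels, meta$n_frames))
  k <- 1L
  for (fi in seq_len(meta$n_frames)) for (zi in seq_len(meta$n_z))
    for (ch in seq_len(meta$n_channels)) {
      arr[, , zi, ch, fi] <- pages[[k]] * meta$intensity_scale
      k <- k + 1L
    }
  structure(list(data = arr, frames = as.integer(meta$frames),
                 z_um = as.numeric(meta$z_um),
                 pixel_size_um = meta$pixel_size_um,
                 channels = as.integer(meta$n_channels)),
            class = "organoid_stack")
}
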