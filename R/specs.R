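#' Specification of a synthetic airway organoid
#'
#' Describes the geometry, optics and timing of one simulated organoid
#' time-lapse. Defaults emulate the experimental design the package targets:
#' a ~150-um organoid (equatorial ring of nuclei), two-photon z-stacks at
#' 2-um steps, frames every 30 min.
#'
#' @param n_cells number of cells on the equatorial ring (>= 3).
#' @param radius_um mean shell radius in um (default 74, i.e. 148 um diameter).
#' @param radial_jitter_um SD of per-cell radial offset from the shell (um).
#' @param nucleus_sigma_um lateral Gaussian half-width of a rendered nucleus (um).
#' @param growth_rate_per_h relative diameter increase per hour
#'   (0.0025 = 0.25 %/h, about 6 % over 24 h).
#' @param frame_interval_min time between frames in minutes.
#' @param n_frames number of frames (frame 0 is pre-ablation).
#' @param z_range_um half-range of the z-stack around the equatorial plane (um).
#' @param z_step_um z-slice spacing (um).
#' @param pixel_size_um lateral pixel size (um/px).
#' @param seed integer seed controlling cell placement.
#' @return An object of class `organoid_spec`.
#' @export
organoid_spec <- function(n_cells = 80L, radius_um = 74, radial_jitter_um = 1.5,
                          nucleus_sigma_um = 1.2, growth_rate_per_h = 0.0025,
                          frame_interval_min = 30, n_frames = 13L,
                          z_range_um = 8, z_step_um = 2, pixel_size_um = 0.5,
                          seed = 1L) {
  spec <- list(n_cells = as.integer(n_cells), radius_um = radius_um,
               radial_jitter_um = radial_jitter_um,
               nucleus_sigma_um = nucleus_sigma_um,
               growth_rate_per_h = growth_rate_per_h,
               frame_interval_min = frame_interval_min,
               n_frames = as.integer(n_frames),
               z_range_um = z_range_um, z_step_um = z_step_um,
               pixel_size_um = pixel_size_um, seed = as.integer(seed))
  class(spec) <- "organoid_spec"
  validate_organoid_spec(spec)
  spec
}

validate_organoid_spec <- function(spec) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid organoid_spec field '", field, "': ", msg, call. = FALSE)
  }
  chk(is.numeric(spec$n_cells) && spec$n_cells >= 3, "n_cells", "must be >= 3")
  chk(spec$radius_um > 0, "radius_um", "must be > 0")
  chk(spec$radial_jitter_um >= 0, "radial_jitter_um", "must be >= 0")
  chk(spec$nucleus_sigma_um > 0, "nucleus_sigma_um", "must be > 0")
  chk(spec$frame_interval_min > 0, "frame_interval_min", "must be > 0")
  chk(spec$n_frames >= 1, "n_frames", "must be >= 1")
  chk(spec$z_range_um >= 0, "z_range_um", "must be >= 0")
  chk(spec$z_step_um > 0, "z_step_um", "must be > 0")
  chk(spec$pixel_size_um > 0, "pixel_size_um", "must be > 0")
  invisible(spec)
}

#' @export
print.organoid_spec <- function(x, ...) {
  cat("organoid_spec:", x$n_cells, "cells, radius", x$radius_um, "um,",
      x$n_frames, "frames @", x$frame_interval_min, "min,",
      "z +/-", x$z_range_um, "um @", x$z_step_um, "um, px",
      x$pixel_size_um, "um\n")
  invisible(x)
}

#' Specification of cell motility
#'
#' Cells perform a tangential random walk within the epithelial shell;
#' optionally, cells within a given arc distance of the wound drift toward it.
#'
#' @param sigma_tangential_um per-frame SD of the tangential random-walk step (um).
#' @param drift_speed_um_per_frame directed speed toward the wound (um/frame).
#' @param drift_range_um arc distance (um) within which the drift applies.
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(sigma_tangential_um = 0.75,
                        drift_speed_um_per_frame = 0,
                        drift_range_um = 0) {
  m <- list(sigma_tangential_um = sigma_tangential_um,
            drift_speed_um_per_frame = drift_speed_um_per_frame,
            drift_range_um = drift_range_um)
  for (f in names(m)) {
    if (!is.numeric(m[[f]]) || m[[f]] < 0)
      stop("invalid motion_spec field '", f, "': must be >= 0", call. = FALSE)
  }
  class(m) <- "motion_spec"
  m
}

#' Specification of EdU labelling probabilities
#'
#' Each cell is labelled EdU-positive independently with probability
#' `baseline_rate` plus an additive boost for its arc-distance bin.
#'
#' @param baseline_rate baseline labelling probability in \[0, 1\].
#' @param bin_boosts named numeric vector: names are 0-based bin indices,
#'   values additive probability boosts (may be empty).
#' @param channel_contrast EdU-channel mean-intensity ratio of labelled to
#'   unlabelled nuclei (> 1 for a separable positive population).
#' @return An object of class `label_spec`.
#' @export
label_spec <- function(baseline_rate = 0.13, bin_boosts = numeric(0),
                       channel_contrast = 5) {
  if (!is.numeric(baseline_rate) || baseline_rate < 0 || baseline_rate > 1)
    stop("invalid label_spec field 'baseline_rate': must be in [0, 1]", call. = FALSE)
  bin_boosts <- unlist(bin_boosts)
  if (length(bin_boosts) && is.null(names(bin_boosts)))
    stop("invalid label_spec field 'bin_boosts': must be named by bin index",
         call. = FALSE)
  if (any(baseline_rate + c(0, bin_boosts) > 1) ||
      any(baseline_rate + c(0, bin_boosts) < 0))
    stop("invalid label_spec field 'bin_boosts': resulting probability outside [0, 1]",
         call. = FALSE)
  if (!is.numeric(channel_contrast) || channel_contrast <= 0)
    stop("invalid label_spec field 'channel_contrast': must be > 0", call. = FALSE)
  l <- list(baseline_rate = baseline_rate, bin_boosts = bin_boosts,
            channel_contrast = channel_contrast)
  class(l) <- "label_spec"
  l
}
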