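# The three organoid readouts: normalized diameter time series, distance-
# binned EdU proliferation rate, and distance-binned migration distance,
# plus aggregation across organoids (mean +/- SEM, n = organoids).

#' Minor/major axes of a binary mask via its second-moment ellipse
#'
#' Axes of the ellipse whose second central moments match the mask's
#' (full axes = 4 sqrt(eigenvalues of the pixel covariance)).
#'
#' @param mask logical matrix \[y, x\].
#' @param pixel_size_um um per pixel.
#' @return c(minor_um, major_um).
#' @export
mask_axes <- function(mask, pixel_size_um) {
  ij <- which(mask, arr.ind = TRUE)
  if (nrow(ij) == 0) stop("empty mask", call. = FALSE)
  y <- ij[, 1]; x <- ij[, 2]
  cov_xy <- stats::cov(cbind(x, y)) * (length(x) - 1) / length(x)
  ev <- eigen(cov_xy, symmetric = TRUE)$values
  ev[ev < 0] <- 0
  axes <- 4 * sqrt(ev) * pixel_size_um
  c(minor_um = min(axes), major_um = max(axes))
}

#' Mean organoid diameter over time, normalized to the first timepoint
#'
#' Per z-slice, the organoid is segmented and the minor and major axes of the
#' second-moment ellipse are averaged; the per-timepoint diameter is the mean
#' over slices, and the series is normalized to timepoint 0 (= 100 %).
#'
#' @param stacks an `organoid_stack` covering the timepoints, or a list of
#'   single-frame `organoid_stack`s.
#' @param channel channel used for segmentation (default 1, nuclear).
#' @param smooth_sigma_um passed to [segment_organoid()].
#' @param frame_interval_min minutes between consecutive frame indices; fills
#'   the `time_h` column (NA if not given).
#' @return data.frame of class `diameter_series`: frame, time_h, n_slices,
#'   mean_diameter_um, rel_diameter_pct.
#' @export
diameter_series <- function(stacks, channel = 1L, smooth_sigma_um = 2,
                            frame_interval_min = NULL) {
  if (inherits(stacks, "organoid_stack")) {
    frames <- stacks$frames
    get_slice <- function(fi, zi)
      projected_image(stacks$data[, , zi, channel, fi],
                      stacks$pixel_size_um, channel = channel,
                      mode = "max", frame = frames[fi])
    nz <- length(stacks$z_um)
    n_t <- length(frames)
    slice_idx <- function(fi) seq_len(nz)
  } else {
    frames <- vapply(stacks, function(s) s$frames[1], numeric(1))
    get_slice <- function(fi, zi)
      projected_image(stacks[[fi]]$data[, , zi, channel, 1],
                      stacks[[fi]]$pixel_size_um, channel = channel,
                      mode = "max", frame = frames[fi])
    n_t <- length(stacks)
    slice_idx <- function(fi) seq_along(stacks[[fi]]$z_um)
  }
  out <- data.frame(frame = frames, time_h = NA_real_, n_slices = 0L,
                    mean_diameter_um = NA_real_, rel_diameter_pct = NA_real_)
  for (fi in seq_len(n_t)) {
    diams <- c()
    for (zi in slice_idx(fi)) {
      d <- tryCatch({
        m <- segment_organoid(get_slice(fi, zi), smooth_sigma_um)
        mean(mask_axes(m$mask, m$pixel_size_um))
      }, error = function(e) {
        warning("slice ", zi, " of frame ", frames[fi], " skipped: ",
                conditionMessage(e), call. = FALSE)
        NA_real_
      })
      diams <- c(diams, d)
    }
    diams <- diams[!is.na(diams)]
    if (length(diams) == 0)
      stop("all slices failed at frame ", frames[fi], call. = FALSE)
    out$n_slices[fi] <- length(diams)
    out$mean_diameter_um[fi] <- mean(diams)
  }
  if (!is.null(frame_interval_min))
    out$time_h <- out$frame * frame_interval_min / 60
  out$rel_diameter_pct <- 100 * out$mean_diameter_um / out$mean_diameter_um[1]
  out$rel_diameter_pct[1] <- 100  # exact by construction
  class(out) <- c("diameter_series", "data.frame")
  out
}

# 1D Otsu threshold on a numeric vector (256-bin histogram): the positivity
# cut that maximizes between-class variance, assuming a bimodal intensity mix
otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (diff(rng) < 1e-12) return(rng[1])
  h <- graphics::hist(values, breaks = seq(rng[1], rng[2],
                                           length.out = n_bins + 1L),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  # the maximum is a plateau across any empty gap between the classes;
  # split at its midpoint
  plateau <- which(sb >= max(sb) - 1e-12 * max(sb))
  mids[round(mean(range(plateau)))]
}

#' EdU positivity calls from per-nucleus intensities
#'
#' @param intensities numeric vector of per-nucleus mean EdU intensities.
#' @param strategy `"otsu"` (default; per-organoid Otsu split assuming a
#'   bimodal positive/negative mix), `"fixed"` (absolute cut at `value`), or
#'   `"mad"` (`value` MADs above the median).
#' @param value threshold parameter for `"fixed"` / `"mad"` (default 3 MADs).
#' @return logical vector of positivity calls.
#' @export
edu_positive <- function(intensities, strategy = c("otsu", "fixed", "mad"),
                         value = NULL) {
  strategy <- match.arg(strategy)
  thr <- switch(strategy,
    otsu = otsu_threshold(intensities),
    fixed = {
      if (is.null(value)) stop("strategy 'fixed' needs a threshold value",
                               call. = FALSE)
      value
    },
    mad = stats::median(intensities) +
      (if (is.null(value)) 3 else value) * stats::mad(intensities))
  intensities > thr
}

#' Distance-binned proliferation rate
#'
#' The relative proliferation rate is the ratio of EdU-positive to all cells,
#' reported overall and per 30-um arc-distance bin from the ablation site.
#' Empty bins are absent from the result, never zero.
#'
#' @param detections data.frame with `x_um`, `y_um` and either an EdU
#'   intensity column or explicit labels (see `labels`).
#' @param circle a `circle_fit` (fit to all detected cells).
#' @param site an `ablation_site`.
#' @param labels optional logical vector of positivity calls (bypass mode,
#'   e.g. ground truth); if NULL, calls are made from `edu_column` via
#'   [edu_positive()].
#' @param edu_column name of the EdU intensity column (default
#'   `"mean_intensity_ch2"`).
#' @param threshold_strategy,threshold_value passed to [edu_positive()].
#' @param bin_width_um bin width (um).
#' @param metric distance metric, see [arc_distance()].
#' @return Object of class `proliferation_result`: list with `overall_rate`,
#'   `overall_counts` (edu_pos, total), `per_bin` (data.frame: bin_index,
#'   lo_um, hi_um, n_total, n_pos, rate).
#' @export
proliferation_map <- function(detections, circle, site, labels = NULL,
                              edu_column = "mean_intensity_ch2",
                              threshold_strategy = "otsu",
                              threshold_value = NULL, bin_width_um = 30,
                              metric = c("arc", "chord")) {
  if (nrow(detections) == 0) stop("no detections", call. = FALSE)
  if (is.null(labels)) {
    if (!edu_column %in% names(detections))
      stop("EdU intensity column '", edu_column, "' not found", call. = FALSE)
    labels <- edu_positive(detections[[edu_column]], threshold_strategy,
                           threshold_value)
  }
  stopifnot(length(labels) == nrow(detections))
  d <- cell_distances(detections, circle, site, bin_width_um, metric)
  per_bin <- do.call(rbind, lapply(split(seq_len(nrow(d)), d$bin_index),
    function(i) data.frame(bin_index = d$bin_index[i[1]],
                           lo_um = d$bin_lo_um[i[1]], hi_um = d$bin_hi_um[i[1]],
                           n_total = length(i), n_pos = sum(labels[i]),
                           rate = mean(labels[i]))))
  per_bin <- per_bin[order(per_bin$bin_index), ]
  rownames(per_bin) <- NULL
  structure(list(overall_rate = mean(labels),
                 overall_counts = c(edu_pos = sum(labels),
                                    total = length(labels)),
                 per_bin = per_bin, bin_width_um = bin_width_um),
            class = "proliferation_result")
}

#' @export
print.proliferation_result <- function(x, ...) {
  cat(sprintf("proliferation_result: overall %.1f%% (%d/%d), %d bins\n",
              100 * x$overall_rate, x$overall_counts["edu_pos"],
              x$overall_counts["total"], nrow(x$per_bin)))
  invisible(x)
}

#' Distance-binned migration distance
#'
#' Each retained track is binned by its arc distance from the ablation site
#' at the reference frame; the chosen motion metric is averaged per bin and
#' overall. Tracks shorter than `min_duration_frac` of the covered frame
#' range, or absent at the reference frame, are excluded.
#'
#' @param tracks an `organoid_tracks`.
#' @param circle a `circle_fit`.
#' @param site an `ablation_site`.
#' @param metric one of `"path_length"` (default headline metric),
#'   `"net_displacement"`, `"max_excursion"`.
#' @param reference_frame frame at which tracks are binned (default: the
#'   earliest tracked frame).
#' @param min_duration_frac minimum track duration as a fraction of the
#'   tracked frame range (default 0.5).
#' @param bin_width_um bin width (um).
#' @param distance_metric see [arc_distance()].
#' @return Object of class `migration_result`: list with `overall_mean_um`,
#'   `n_tracks`, `per_bin` (data.frame: bin_index, lo_um, hi_um, n, mean_um),
#'   `metric`.
#' @export
migration_map <- function(tracks, circle, site,
                          metric = c("path_length", "net_displacement",
                                     "max_excursion"),
                          reference_frame = NULL, min_duration_frac = 0.5,
                          bin_width_um = 30,
                          distance_metric = c("arc", "chord")) {
  metric <- match.arg(metric)
  pts <- tracks$points
  met <- tracks$metrics
  if (nrow(met) == 0) stop("no tracks", call. = FALSE)
  all_frames <- sort(unique(pts$frame))
  if (is.null(reference_frame)) reference_frame <- all_frames[1]
  span <- met$last_frame - met$first_frame
  keep <- span >= min_duration_frac * (max(all_frames) - min(all_frames))
  ref <- pts[pts$frame == reference_frame, ]
  keep <- keep & met$track_id %in% ref$track_id
  met <- met[keep, ]
  if (nrow(met) == 0) stop("no retained tracks", call. = FALSE)
  ref <- ref[match(met$track_id, ref$track_id), ]
  d <- cell_distances(ref, circle, site, bin_width_um, distance_metric)
  value <- met[[paste0(metric, "_um")]]
  per_bin <- do.call(rbind, lapply(split(seq_len(nrow(d)), d$bin_index),
    function(i) data.frame(bin_index = d$bin_index[i[1]],
                           lo_um = d$bin_lo_um[i[1]], hi_um = d$bin_hi_um[i[1]],
                           n = length(i), mean_um = mean(value[i]))))
  per_bin <- per_bin[order(per_bin$bin_index), ]
  rownames(per_bin) <- NULL
  structure(list(overall_mean_um = mean(value), n_tracks = nrow(met),
                 per_bin = per_bin, metric = metric,
                 reference_frame = reference_frame,
                 bin_width_um = bin_width_um),
            class = "migration_result")
}

#' @export
print.migration_result <- function(x, ...) {
  cat(sprintf("migration_result (%s): overall %.1f um over %d tracks, %d bins\n",
              x$metric, x$overall_mean_um, x$n_tracks, nrow(x$per_bin)))
  invisible(x)
}

#' Aggregate per-organoid results across a condition
#'
#' Mean and SEM are computed across organoids: each organoid contributes one
#' value per bin (its rate or mean distance) and one overall value; organoids
#' lacking a bin are excluded from that bin, never counted as zero.
#'
#' @param results list of `proliferation_result` or `migration_result`
#'   objects (>= 2, one per organoid, same type).
#' @return data.frame of class `condition_summary`: bin (`"overall"` or the
#'   bin index), lo_um, hi_um, mean, sem, n_organoids.
#' @export
aggregate_condition <- function(results) {
  if (length(results) < 2)
    stop("need >= 2 organoids to compute a SEM", call. = FALSE)
  is_prolif <- inherits(results[[1]], "proliferation_result")
  value_col <- if (is_prolif) "rate" else "mean_um"
  overall <- vapply(results, function(r)
    if (is_prolif) r$overall_rate else r$overall_mean_um, numeric(1))
  rows <- list(data.frame(bin = "overall", lo_um = NA_real_, hi_um = NA_real_,
                          mean = mean(overall), sem = sem(overall),
                          n_organoids = length(overall)))
  bins <- sort(unique(unlist(lapply(results, function(r) r$per_bin$bin_index))))
  for (b in bins) {
    vals <- unlist(lapply(results, function(r) {
      i <- match(b, r$per_bin$bin_index)
      if (is.na(i)) NULL else r$per_bin[[value_col]][i]
    }))
    if (length(vals) < 2) next
    w <- results[[1]]$bin_width_um
    rows[[length(rows) + 1]] <- data.frame(
      bin = as.character(b), lo_um = b * w, hi_um = (b + 1) * w,
      mean = mean(vals), sem = sem(vals), n_organoids = length(vals))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("condition_summary", "data.frame")
  out
}
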