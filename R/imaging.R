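# Projection, nucleus detection and whole-organoid segmentation.
#
# Pixel/micrometre convention (used throughout the package): pixel (row, col)
# covers ((col-1)*px, col*px] x ((row-1)*px, row*px] um; its centre is at
# x_um = (col - 0.5) * px, y_um = (row - 0.5) * px. Origin is the image
# top-left corner, y increases downward.

#' Project a z-stack to 2D
#'
#' Pixelwise maximum or sum over the selected z-slices of one channel and
#' frame.
#'
#' @param stack an `organoid_stack` (see [render_stack()] /
#'   [read_stack_tiff()]).
#' @param channel channel index (1-based).
#' @param mode `"max"` (maximum-intensity projection) or `"sum"` (sum slices).
#' @param z_window optional numeric length-2, z-range in um (inclusive);
#'   default: all slices.
#' @param frame frame index as stored in `stack$frames` (default: first).
#' @return An object of class `projected_image`: list with `pixels`
#'   (matrix \[y, x\]), `channel`, `mode`, `pixel_size_um`, `frame`.
#' @export
project <- function(stack, channel = 1L, mode = c("max", "sum"),
                    z_window = NULL, frame = stack$frames[1]) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "organoid_stack"))
  fi <- match(frame, stack$frames)
  if (is.na(fi)) stop("frame ", frame, " not in stack", call. = FALSE)
  if (channel < 1 || channel > stack$channels)
    stop("channel ", channel, " not in stack", call. = FALSE)
  zi <- if (is.null(z_window)) seq_along(stack$z_um) else
    which(stack$z_um >= z_window[1] & stack$z_um <= z_window[2])
  if (length(zi) == 0) stop("empty z_window", call. = FALSE)
  slab <- stack$data[, , zi, channel, fi, drop = FALSE]
  dim(slab) <- dim(slab)[1:3]
  slices <- lapply(seq_along(zi), function(i) slab[, , i])
  px <- Reduce(if (mode == "max") pmax else `+`, slices)
  projected_image(px, stack$pixel_size_um, channel = channel, mode = mode,
                  frame = frame)
}

#' Construct a projected image from a plain matrix
#'
#' Entry point for detection-only workflows that start from 2D images rather
#' than stacks.
#'
#' @param pixels numeric matrix \[y, x\].
#' @param pixel_size_um um per pixel.
#' @param channel,mode,frame metadata carried along.
#' @return A `projected_image`.
#' @export
projected_image <- function(pixels, pixel_size_um, channel = 1L, mode = "max",
                            frame = 0L) {
  stopifnot(is.matrix(pixels), pixel_size_um > 0)
  structure(list(pixels = pixels, channel = channel, mode = mode,
                 pixel_size_um = pixel_size_um, frame = frame),
            class = "projected_image")
}

#' @export
print.projected_image <- function(x, ...) {
  cat("projected_image:", nrow(x$pixels), "x", ncol(x$pixels), "px (",
      x$mode, "), channel", x$channel, ", frame", x$frame, "\n")
  invisible(x)
}

# difference-of-Gaussians blob response at scale sigma (px); approximates the
# scale-normalized Laplacian of Gaussian
dog_response <- function(pixels, sigma_px, k = 1.6) {
  g1 <- EBImage::gblur(pixels, sigma = sigma_px)
  g2 <- EBImage::gblur(pixels, sigma = k * sigma_px)
  (g1 - g2) / (k - 1)
}

#' Detect nuclei as scale-space blobs
#'
#' Local maxima of a difference-of-Gaussians response at scale `sigma_um`,
#' kept if they exceed `rel_threshold` of the response range and are separated
#' by at least `min_separation_um` (non-maximum suppression, strongest first).
#' Positions are refined to subpixel precision by the intensity-weighted
#' centroid of the positive response in a 2-sigma window.
#'
#' @param img a `projected_image`.
#' @param sigma_um blob scale in um (approximately the nucleus Gaussian SD).
#' @param min_separation_um minimum distance between detections (um).
#' @param rel_threshold response threshold as a fraction of the response
#'   range above its minimum.
#' @param exclusion_center_um optional c(x, y) um: centre of an exclusion
#'   disc (e.g. the ablation scar's autofluorescent site).
#' @param exclusion_radius_um radius of the exclusion disc (um, default 0).
#' @return data.frame of class `nucleus_detections`: cell_index, x_um, y_um,
#'   radius_um (detection scale, sqrt(2) * sigma), response.
#' @export
detect_nuclei <- function(img, sigma_um = 1.2, min_separation_um = 3,
                          rel_threshold = 0.1, exclusion_center_um = NULL,
                          exclusion_radius_um = 0) {
  stopifnot(inherits(img, "projected_image"), sigma_um > 0)
  px <- img$pixel_size_um
  s <- sigma_um / px
  resp <- dog_response(img$pixels, s)
  rng <- range(resp)
  empty <- data.frame(cell_index = integer(0), x_um = numeric(0),
                      y_um = numeric(0), radius_um = numeric(0),
                      response = numeric(0))
  class(empty) <- c("nucleus_detections", "data.frame")
  if (!is.finite(diff(rng)) || diff(rng) < 1e-12) return(empty)
  thr <- rel_threshold * diff(rng)

  # strict local maxima over the 8-neighbourhood (1-px border excluded)
  nr <- nrow(resp); nc <- ncol(resp)
  if (nr < 3 || nc < 3) return(empty)
  ctr <- resp[2:(nr - 1), 2:(nc - 1)]
  is_max <- ctr > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- resp[(2 + dy):(nr - 1 + dy), (2 + dx):(nc - 1 + dx)]
    is_max <- is_max & (ctr >= nb) & (ctr > nb | (dy < 0 | (dy == 0 & dx < 0)))
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  rows <- idx[, 1] + 1L; cols <- idx[, 2] + 1L
  vals <- resp[cbind(rows, cols)]

  # non-maximum suppression at min_separation_um, strongest first
  ord <- order(vals, decreasing = TRUE)
  rows <- rows[ord]; cols <- cols[ord]; vals <- vals[ord]
  min_sep_px2 <- (min_separation_um / px)^2
  keep <- logical(length(vals))
  for (i in seq_along(vals)) {
    ki <- which(keep)
    if (!length(ki) ||
        all((rows[ki] - rows[i])^2 + (cols[ki] - cols[i])^2 >= min_sep_px2))
      keep[i] <- TRUE
  }
  rows <- rows[keep]; cols <- cols[keep]; vals <- vals[keep]

  # subpixel refinement: positive-response-weighted centroid, 2-sigma window
  w <- max(1L, ceiling(2 * s))
  x_um <- y_um <- numeric(length(vals))
  for (i in seq_along(vals)) {
    rs <- max(1L, rows[i] - w):min(nr, rows[i] + w)
    cs <- max(1L, cols[i] - w):min(nc, cols[i] + w)
    wts <- pmax(resp[rs, cs, drop = FALSE], 0)
    sw <- sum(wts)
    if (sw > 0) {
      y_px <- sum(rowSums(wts) * rs) / sw
      x_px <- sum(colSums(wts) * cs) / sw
    } else {
      y_px <- rows[i]; x_px <- cols[i]
    }
    x_um[i] <- (x_px - 0.5) * px
    y_um[i] <- (y_px - 0.5) * px
  }

  det <- data.frame(cell_index = seq_along(vals), x_um = x_um, y_um = y_um,
                    radius_um = sqrt(2) * sigma_um, response = vals)
  if (!is.null(exclusion_center_um) && exclusion_radius_um > 0) {
    d2 <- (det$x_um - exclusion_center_um[1])^2 +
      (det$y_um - exclusion_center_um[2])^2
    det <- det[d2 >= exclusion_radius_um^2, , drop = FALSE]
    det$cell_index <- seq_len(nrow(det))
    rownames(det) <- NULL
  }
  class(det) <- c("nucleus_detections", "data.frame")
  det
}

#' Measure per-nucleus mean intensities
#'
#' Mean pixel intensity in a disc of radius `aperture_um` around each
#' detection, for each supplied channel image. Detections whose aperture is
#' clipped by the image border are measured on the clipped disc and flagged.
#'
#' @param detections a `nucleus_detections` data.frame (needs x_um, y_um).
#' @param images a `projected_image` or a named list of them (one per
#'   channel); the names become intensity column suffixes
#'   (`mean_intensity_<name>`), unnamed lists use ch1, ch2, ...
#' @param aperture_um disc radius (um); default: the detections' radius_um
#'   (the nucleus footprint).
#' @return `detections` with one `mean_intensity_*` column per channel and a
#'   logical `clipped` column.
#' @export
measure_intensity <- function(detections, images, aperture_um = NULL) {
  if (inherits(images, "projected_image")) images <- list(ch1 = images)
  if (is.null(names(images)) || any(names(images) == ""))
    names(images) <- paste0("ch", seq_along(images))
  if (is.null(aperture_um)) {
    if (!is.null(detections$radius_um)) aperture_um <- detections$radius_um
    else stop("aperture_um required when detections carry no radius_um",
              call. = FALSE)
  }
  if (any(aperture_um <= 0)) stop("aperture_um must be > 0", call. = FALSE)
  ap <- rep_len(aperture_um, nrow(detections))
  clipped <- rep(FALSE, nrow(detections))
  for (nm in names(images)) {
    img <- images[[nm]]
    stopifnot(inherits(img, "projected_image"))
    pxs <- img$pixels
    px <- img$pixel_size_um
    nr <- nrow(pxs); nc <- ncol(pxs)
    vals <- numeric(nrow(detections))
    for (i in seq_len(nrow(detections))) {
      cx <- detections$x_um[i] / px + 0.5
      cy <- detections$y_um[i] / px + 0.5
      r_px <- ap[i] / px
      cs <- max(1L, floor(cx - r_px)):min(nc, ceiling(cx + r_px))
      rs <- max(1L, floor(cy - r_px)):min(nr, ceiling(cy + r_px))
      inside <- outer((rs - cy)^2, (cs - cx)^2, "+") <= r_px^2
      if (cx - r_px < 0.5 || cx + r_px > nc + 0.5 ||
          cy - r_px < 0.5 || cy + r_px > nr + 0.5) clipped[i] <- TRUE
      vals[i] <- if (any(inside)) mean(pxs[rs, cs, drop = FALSE][inside]) else NA_real_
    }
    detections[[paste0("mean_intensity_", nm)]] <- vals
  }
  detections$clipped <- clipped
  detections
}

#' Segment the whole organoid
#'
#' Gaussian smoothing, Otsu threshold, morphological closing at the
#' inter-nuclear spacing scale (so a shell of discrete nuclei becomes a
#' closed outline), largest connected component, hole filling. Yields the
#' organoid's filled outline for morphometry.
#'
#' @param img a `projected_image`.
#' @param smooth_sigma_um smoothing SD before thresholding (um).
#' @param close_radius_um disc radius of the morphological closing (um);
#'   should be a few nucleus-to-nucleus spacings so a shell of discrete
#'   nuclei closes into one outline. 0 disables closing.
#' @param min_component_um2 foreground components smaller than this (um^2,
#'   sub-nucleus scale) are discarded as noise before the closing.
#' @param min_contrast minimum foreground/background mean-intensity ratio on
#'   the smoothed image; below it the slice is treated as signal-free
#'   ("no organoid found"), so callers can skip it.
#' @return An object of class `organoid_mask`: list with `mask` (logical
#'   matrix \[y, x\]), `area_um2`, `centroid_xy_um`, `pixel_size_um`.
#' @export
segment_organoid <- function(img, smooth_sigma_um = 2, close_radius_um = 20,
                             min_component_um2 = 3,
                             min_contrast = 1.5) {
  stopifnot(inherits(img, "projected_image"))
  px <- img$pixel_size_um
  pxs <- img$pixels
  if (length(pxs) == 0) stop("no organoid found", call. = FALSE)
  sm <- EBImage::gblur(pxs, sigma = smooth_sigma_um / px)
  rng <- range(sm)
  if (diff(rng) < 1e-12) stop("no organoid found", call. = FALSE)
  norm <- (sm - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > thr
  if (!any(bw)) stop("no organoid found", call. = FALSE)
  if (min_component_um2 > 0) {
    lab0 <- EBImage::bwlabel(EBImage::Image(bw * 1))
    sizes <- tabulate(as.integer(lab0))
    small <- which(sizes * px^2 < min_component_um2)
    if (length(small)) bw[as.matrix(lab0) %in% small] <- FALSE
    if (!any(bw)) stop("no organoid found", call. = FALSE)
  }
  if (close_radius_um > 0) {
    r_px <- max(1L, round(close_radius_um / px))
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    bw <- EBImage::closing(EBImage::Image(bw * 1), brush) > 0
  }
  fg <- mean(sm[bw]); bg <- mean(sm[!bw])
  if (!any(!bw) || !is.finite(fg / bg) || fg / bg < min_contrast)
    stop("no organoid found (insufficient contrast)", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  tab <- tabulate(as.integer(lab))
  biggest <- which.max(tab)
  comp <- (lab == biggest)
  filled <- EBImage::fillHull(comp)
  mask <- as.matrix(filled) > 0
  ij <- which(mask, arr.ind = TRUE)
  centroid <- c((mean(ij[, 2]) - 0.5) * px, (mean(ij[, 1]) - 0.5) * px)
  structure(list(mask = mask, area_um2 = sum(mask) * px^2,
                 centroid_xy_um = centroid, pixel_size_um = px),
            class = "organoid_mask")
}

#' @export
print.organoid_mask <- function(x, ...) {
  cat("organoid_mask: area", round(x$area_um2), "um^2, centroid (",
      round(x$centroid_xy_um[1], 1), ",", round(x$centroid_xy_um[2], 1), ") um\n")
  invisible(x)
}

#' Write / read a nucleus-detection table as CSV
#'
#' @param detections a `nucleus_detections` data.frame (optionally with
#'   intensity columns and a `frame` column).
#' @param path CSV path.
#' @return `path` invisibly; `read_detections_csv` returns the data.frame.
#' @export
write_detections_csv <- function(detections, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# nucleus detections",
               "# units: um; origin top-left; y increases downward"), con)
  utils::write.table(detections, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  det <- utils::read.csv(path, comment.char = "#")
  class(det) <- c("nucleus_detections", "data.frame")
  det
}

#' Greedy one-to-one matching of detections to reference points
#'
#' Pairs are formed in order of increasing distance; each point is used at
#' most once and pairs farther than `radius_um` are not formed. Recall is
#' matched / reference points, precision matched / detections.
#'
#' @param detections,reference data.frames with `x_um`, `y_um`.
#' @param radius_um maximum match distance (um).
#' @return list: `pairs` (data.frame det_row, ref_row, dist_um), `recall`,
#'   `precision`.
#' @export
match_points <- function(detections, reference, radius_um = 3) {
  n <- nrow(detections); m <- nrow(reference)
  if (n == 0 || m == 0)
    return(list(pairs = data.frame(det_row = integer(0), ref_row = integer(0),
                                   dist_um = numeric(0)),
                recall = if (m == 0) NA_real_ else 0,
                precision = if (n == 0) NA_real_ else 0))
  d <- sqrt(outer(detections$x_um, reference$x_um, "-")^2 +
            outer(detections$y_um, reference$y_um, "-")^2)
  ord <- order(d)
  used_d <- logical(n); used_r <- logical(m)
  pairs <- list()
  for (k in ord) {
    if (d[k] > radius_um) break
    i <- (k - 1) %% n + 1; j <- (k - 1) %/% n + 1
    if (used_d[i] || used_r[j]) next
    used_d[i] <- used_r[j] <- TRUE
    pairs[[length(pairs) + 1]] <- data.frame(det_row = i, ref_row = j,
                                             dist_um = d[k])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(det_row = integer(0), ref_row = integer(0),
               dist_um = numeric(0))
  list(pairs = pairs, recall = nrow(pairs) / m, precision = nrow(pairs) / n)
}
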