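make_stack <- function(seed = 1, n_cells = 40, radius = 40, noise = FALSE,
                       n_frames = 1, ...) {
  spec <- organoid_spec(n_cells = n_cells, radius_um = radius, seed = seed,
                        n_frames = n_frames, ...)
  tr <- make_organoid(spec)
  list(truth = tr, stack = render_stack(tr, noise = noise))
}

test_that("projection reduces correctly and commutes with slice structure", {
  fx <- make_stack(seed = 2, n_cells = 10, radius = 15)
  st <- fx$stack
  # one-slice window: identity for both modes
  z0 <- st$z_um[5]
  for (mode in c("max", "sum")) {
    p <- project(st, 1, mode, z_window = c(z0, z0))
    expect_equal(p$pixels, st$data[, , 5, 1, 1])
  }
  # sum over the full stack equals the sum of disjoint sub-window sums
  s_all <- project(st, 1, "sum")$pixels
  s_lo <- project(st, 1, "sum", z_window = c(min(st$z_um), 0))$pixels
  s_hi <- project(st, 1, "sum", z_window = c(st$z_um[6], max(st$z_um)))$pixels
  expect_equal(s_all, s_lo + s_hi, tolerance = 1e-12)
  # max is invariant under slice permutation
  st2 <- st
  st2$data <- st$data[, , rev(seq_along(st$z_um)), , , drop = FALSE]
  expect_equal(project(st2, 1, "max")$pixels, project(st, 1, "max")$pixels)
  # single bright voxel lands at its (x, y) in the max projection
  arr <- array(0, dim = c(8, 8, 3, 1, 1))
  arr[3, 6, 2, 1, 1] <- 7
  stv <- structure(list(data = arr, frames = 0L, z_um = c(-2, 0, 2),
                        pixel_size_um = 1, channels = 1L),
                   class = "organoid_stack")
  mp <- project(stv, 1, "max")$pixels
  expect_equal(which(mp == 7, arr.ind = TRUE)[1, ], c(row = 3, col = 6))
  expect_error(project(st, 1, "max", z_window = c(99, 100)), "empty z_window")
})

test_that("blank images yield zero detections", {
  img <- projected_image(matrix(0, 64, 64), 0.5)
  expect_equal(nrow(detect_nuclei(img)), 0)
  imgc <- projected_image(matrix(3.2, 64, 64), 0.5)
  expect_equal(nrow(detect_nuclei(imgc)), 0)
})

test_that("two well-separated blobs are each localized within one pixel", {
  px <- 0.5
  n <- 128
  xs <- ((1:n) - 0.5) * px
  blob <- function(cx, cy, s) {
    outer(exp(-(xs - cy)^2 / (2 * s^2)), exp(-(xs - cx)^2 / (2 * s^2)))
  }
  img <- projected_image(100 * blob(20, 30, 4) + 100 * blob(50, 30, 4), px)
  det <- detect_nuclei(img, sigma_um = 4, min_separation_um = 10)
  expect_equal(nrow(det), 2)
  det <- det[order(det$x_um), ]
  expect_lt(abs(det$x_um[1] - 20), px)
  expect_lt(abs(det$y_um[1] - 30), px)
  expect_lt(abs(det$x_um[2] - 50), px)
})

test_that("detection on noiseless organoids is perfect at 4-sigma spacing", {
  for (seed in 1:3) {
    fx <- make_stack(seed = seed, n_cells = 100, radius = 74)
    mip <- project(fx$stack, 1, "max", z_window = c(-6, 6))
    det <- detect_nuclei(mip)
    m <- match_points(det, fx$truth$cells, radius_um = 3)
    expect_equal(m$recall, 1.0)
    expect_equal(m$precision, 1.0)
  }
})

test_that("detected positions are equivariant under whole-pixel translation", {
  fx <- make_stack(seed = 5, n_cells = 20, radius = 20)
  mip <- project(fx$stack, 1, "max")
  det <- detect_nuclei(mip)
  shift <- 7L
  pxs <- mip$pixels
  shifted <- matrix(0, nrow(pxs), ncol(pxs))
  shifted[, (shift + 1):ncol(pxs)] <- pxs[, 1:(ncol(pxs) - shift)]
  det2 <- detect_nuclei(projected_image(shifted, mip$pixel_size_um))
  det2 <- det2[match_points(det2, det, 10)$pairs$det_row, ]
  ord <- order(det$x_um, det$y_um); ord2 <- order(det2$x_um, det2$y_um)
  expect_equal(det2$x_um[ord2], det$x_um[ord] + shift * mip$pixel_size_um,
               tolerance = 1e-6)
  expect_equal(det2$y_um[ord2], det$y_um[ord], tolerance = 1e-6)
})

test_that("an exclusion disc suppresses detections at the declared site", {
  fx <- make_stack(seed = 6, n_cells = 30, radius = 30)
  mip <- project(fx$stack, 1, "max")
  det_all <- detect_nuclei(mip)
  target <- c(det_all$x_um[1], det_all$y_um[1])
  det_ex <- detect_nuclei(mip, exclusion_center_um = target,
                          exclusion_radius_um = 5)
  expect_equal(nrow(det_ex), nrow(det_all) - 1)
  d2 <- (det_ex$x_um - target[1])^2 + (det_ex$y_um - target[2])^2
  expect_true(all(d2 >= 25))
})

test_that("intensity measurement averages the aperture disc", {
  img <- projected_image(matrix(7.5, 80, 80), 1)
  det <- data.frame(x_um = c(20, 40), y_um = c(20, 40), radius_um = 3)
  out <- measure_intensity(det, img)
  expect_equal(out$mean_intensity_ch1, c(7.5, 7.5))
  expect_false(any(out$clipped))
  # zero region stays zero
  z <- matrix(0, 40, 40); z[1:10, 1:10] <- 5
  out0 <- measure_intensity(data.frame(x_um = 30, y_um = 30, radius_um = 4),
                            projected_image(z, 1))
  expect_equal(out0$mean_intensity_ch1, 0)
  # border detections are measured on the clipped disc and flagged
  outb <- measure_intensity(data.frame(x_um = 1, y_um = 1, radius_um = 4),
                            projected_image(matrix(2, 40, 40), 1))
  expect_true(outb$clipped)
  expect_equal(outb$mean_intensity_ch1, 2)
})

test_that("EdU channel contrast survives rendering and measurement", {
  spec <- organoid_spec(n_cells = 40, radius_um = 40, seed = 9, n_frames = 1)
  tr <- make_organoid(spec)
  tr <- apply_ablation(tr, 2)
  tr <- assign_edu_labels(tr, label_spec(0.4, channel_contrast = 5))
  st <- render_stack(tr, scar_frames = 0, noise = FALSE, background = 0)
  mip <- project(st, 1, "max", z_window = c(-6, 6))
  edu <- project(st, 2, "sum")
  det <- detect_nuclei(mip)
  det <- measure_intensity(det, list(ch1 = mip, ch2 = edu))
  m <- match_points(det, tr$cells, 3)
  lab <- tr$cells$edu_label[m$pairs$ref_row]
  iv <- det$mean_intensity_ch2[m$pairs$det_row]
  ratio <- mean(iv[lab]) / mean(iv[!lab])
  expect_lt(abs(ratio - 5) / 5, 0.1)
})

test_that("organoid segmentation yields a filled disc near the true centre", {
  fx <- make_stack(seed = 10, n_cells = 60, radius = 40)
  img <- projected_image(fx$stack$data[, , 5, 1, 1], 0.5)
  m <- segment_organoid(img)
  expect_lt(sqrt(sum((m$centroid_xy_um - fx$truth$circle_center_xy_um)^2)), 1)
  # mask is one filled component whose area is close to the disc through the ring
  expect_gt(m$area_um2, 0.8 * pi * 40^2)
  lab <- EBImage::bwlabel(EBImage::Image(m$mask * 1))
  expect_equal(max(lab), 1)
  expect_error(segment_organoid(projected_image(matrix(0, 50, 50), 1)),
               "no organoid")
})

test_that("segmentation keeps only the largest of two organoids", {
  spec_big <- organoid_spec(n_cells = 60, radius_um = 40, seed = 11,
                            n_frames = 1)
  big <- render_stack(make_organoid(spec_big), labels = NULL, noise = FALSE)
  spec_small <- organoid_spec(n_cells = 15, radius_um = 10,
                              radial_jitter_um = 0.5, seed = 12, n_frames = 1)
  small <- render_stack(make_organoid(spec_small), labels = NULL,
                        noise = FALSE)
  # place both in one canvas, far apart
  nb <- dim(big$data)[1]; ns <- dim(small$data)[1]
  canvas <- matrix(0, nb + ns + 100, nb + ns + 100)
  canvas[1:nb, 1:nb] <- big$data[, , 5, 1, 1]
  canvas[(nb + 100) + 1:ns, (nb + 100) + 1:ns] <- small$data[, , 5, 1, 1]
  m <- segment_organoid(projected_image(canvas, 0.5))
  # mask confined to the big organoid's corner
  ij <- which(m$mask, arr.ind = TRUE)
  expect_true(all(ij <= nb + 40))
})

test_that("detection tables round-trip through CSV", {
  fx <- make_stack(seed = 13, n_cells = 15, radius = 15)
  mip <- project(fx$stack, 1, "max")
  det <- measure_intensity(detect_nuclei(mip), mip)
  det$frame <- 0L
  p <- file.path(withr::local_tempdir(), "det.csv")
  write_detections_csv(det, p)
  back <- read_detections_csv(p)
  expect_equal(back$x_um, det$x_um, tolerance = 1e-9)
  expect_equal(back$mean_intensity_ch1, det$mean_intensity_ch1,
               tolerance = 1e-9)
})
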