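test_that("jitter-free ring places every cell exactly on the shell circle", {
  spec <- organoid_spec(n_cells = 100, radius_um = 74, radial_jitter_um = 0,
                        seed = 7)
  tr <- make_organoid(spec)
  r <- sqrt((tr$cells$x_um - tr$circle_center_xy_um[1])^2 +
            (tr$cells$y_um - tr$circle_center_xy_um[2])^2)
  expect_equal(r, rep(74, 100), tolerance = 1e-12)
  expect_equal(2 * tr$circle_radius_um_per_frame[1], 148)
})

test_that("generation is seed-deterministic, including rendering", {
  spec <- organoid_spec(n_cells = 20, radius_um = 20, seed = 11, n_frames = 3)
  make <- function() {
    tr <- simulate_timelapse(apply_ablation(make_organoid(spec), 3))
    tr <- assign_edu_labels(tr)
    list(tr = tr, st = render_stack(tr))
  }
  a <- make(); b <- make()
  expect_identical(a$tr$cells, b$tr$cells)
  expect_identical(a$st$data, b$st$data)
})

test_that("invalid specs fail naming the offending field", {
  expect_error(organoid_spec(n_cells = 2), "n_cells")
  expect_error(organoid_spec(radius_um = 0), "radius_um")
  expect_error(organoid_spec(z_step_um = 0), "z_step_um")
  expect_error(organoid_spec(pixel_size_um = -1), "pixel_size_um")
  expect_error(motion_spec(sigma_tangential_um = -1), "sigma_tangential_um")
  expect_error(label_spec(baseline_rate = 1.2), "baseline_rate")
  expect_error(label_spec(0.9, c("1" = 0.2)), "bin_boosts")
})

test_that("ablation removes k contiguous cells from later frames only", {
  spec <- organoid_spec(n_cells = 100, seed = 3, n_frames = 4)
  tr <- simulate_timelapse(apply_ablation(make_organoid(spec), 10))
  counts <- table(tr$cells$frame)
  expect_equal(unname(counts[["0"]]), 100)
  expect_equal(unname(counts[["1"]]), 90)
  expect_equal(unname(counts[["3"]]), 90)
  # contiguity: ablated cells occupy consecutive rank positions on the ring
  f0 <- tr$cells[tr$cells$frame == 0, ]
  ranks <- sort(match(tr$ablation$cell_ids, f0$cell_id[order(f0$angle_rad)]))
  gaps <- diff(ranks)
  expect_true(sum(gaps != 1) <= 1)  # at most one wrap-around jump
  expect_error(apply_ablation(make_organoid(spec), 100), "k must")
})

test_that("ablation centre is the circular mean of the ablated cells", {
  spec <- organoid_spec(n_cells = 12, radial_jitter_um = 0, seed = 5)
  tr <- make_organoid(spec)
  # single cell: centre at that cell's projected position
  tr1 <- apply_ablation(tr, 1)
  f0 <- tr$cells
  cell <- f0[f0$cell_id == tr1$ablation$cell_ids, ]
  expect_equal(tr1$ablation$theta_rad, cell$angle_rad, tolerance = 1e-12)
  # two cells at theta and theta + delta: centre at theta + delta/2
  tr2 <- apply_ablation(tr, 2)
  th <- sort(f0$angle_rad[f0$cell_id %in% tr2$ablation$cell_ids])
  expect_equal(tr2$ablation$theta_rad, mean(th), tolerance = 1e-12)
})

test_that("frozen dynamics yield constant trajectories", {
  spec <- organoid_spec(n_cells = 30, radius_um = 40, growth_rate_per_h = 0,
                        seed = 2, n_frames = 6)
  tr <- simulate_timelapse(make_organoid(spec), motion_spec(0, 0, 0))
  for (f in 1:5) {
    ff <- tr$cells[tr$cells$frame == f, ]
    f0 <- tr$cells[tr$cells$frame == 0, ]
    expect_equal(ff$x_um[order(ff$cell_id)], f0$x_um[order(f0$cell_id)])
  }
})

test_that("pure wound-directed advection shrinks arc distance monotonically", {
  spec <- organoid_spec(n_cells = 40, radius_um = 74, radial_jitter_um = 0,
                        growth_rate_per_h = 0, seed = 9, n_frames = 20)
  tr <- apply_ablation(make_organoid(spec), 1)
  tr <- simulate_timelapse(tr, motion_spec(0, 1.0, 60))
  th0 <- tr$ablation$theta_rad
  r <- 74
  # pick a surviving cell starting 30-55 um from the wound
  f1 <- tr$cells[tr$cells$frame == 1 & !tr$cells$ablated, ]
  d1 <- r * abs(sapply(f1$angle_rad - th0, function(d) min(abs(d), 2 * pi - abs(d))))
  id <- f1$cell_id[which(d1 > 10 & d1 < 18)[1]]
  traj <- tr$cells[tr$cells$cell_id == id, ]
  traj <- traj[order(traj$frame), ]
  d <- sapply(traj$angle_rad - th0, function(x) {
    x <- abs(x); r * min(x, 2 * pi - x)
  })
  expect_true(all(diff(d) <= 1e-9))
  expect_lt(min(d), 1)  # reaches the wound and stays
})

test_that("diffusive path length matches the half-normal expectation", {
  # E path = n_steps * sigma * sqrt(2/pi) for tangential N(0, sigma^2) steps
  spec <- organoid_spec(n_cells = 200, radius_um = 74, growth_rate_per_h = 0,
                        seed = 21, n_frames = 49)
  tr <- simulate_timelapse(make_organoid(spec), motion_spec(1.0, 0, 0))
  paths <- sapply(split(tr$cells, tr$cells$cell_id), function(p) {
    p <- p[order(p$frame), ]
    sum(sqrt(diff(p$x_um)^2 + diff(p$y_um)^2))
  })
  n_steps <- 48
  expected <- n_steps * 1.0 * sqrt(2 / pi)
  se <- sqrt(n_steps * (1 - 2 / pi)) / sqrt(length(paths))
  expect_lt(abs(mean(paths) - expected), 3 * se)
})

test_that("labelling frequencies track the specified probabilities", {
  # 1000 cells x 50 seeds; empirical rates inside a 99% binomial envelope
  pos_base <- 0; n_base <- 0; pos_b1 <- 0; n_b1 <- 0
  for (s in 1:50) {
    spec <- organoid_spec(n_cells = 1000, radius_um = 74, seed = 3000 + s,
                          n_frames = 1)
    tr <- apply_ablation(make_organoid(spec), 5)
    tr <- assign_edu_labels(tr, label_spec(0.13, c("1" = 0.14)))
    cells <- tr$cells
    th <- cells$angle_rad - tr$ablation$theta_rad
    arc <- 74 * pmin(abs(th), 2 * pi - abs(th))
    b1 <- arc >= 30 & arc < 60
    pos_b1 <- pos_b1 + sum(cells$edu_label[b1]); n_b1 <- n_b1 + sum(b1)
    pos_base <- pos_base + sum(cells$edu_label[!b1]); n_base <- n_base + sum(!b1)
  }
  z99 <- qnorm(0.995)
  expect_lt(abs(pos_base / n_base - 0.13),
            z99 * sqrt(0.13 * 0.87 / n_base))
  expect_lt(abs(pos_b1 / n_b1 - 0.27), z99 * sqrt(0.27 * 0.73 / n_b1))
  # degenerate rates
  tr0 <- assign_edu_labels(make_organoid(organoid_spec(seed = 1, n_frames = 1)),
                           label_spec(0))
  expect_false(any(tr0$cells$edu_label))
  tr1 <- assign_edu_labels(make_organoid(organoid_spec(seed = 2, n_frames = 1)),
                           label_spec(1))
  expect_true(all(tr1$cells$edu_label))
})

test_that("rendering places nuclei where the truth says", {
  spec <- organoid_spec(n_cells = 3, radius_um = 8, radial_jitter_um = 0,
                        seed = 4, n_frames = 1)
  tr <- make_organoid(spec)
  # keep one cell only
  tr$cells <- tr$cells[1, ]
  st <- render_stack(tr, labels = NULL, noise = FALSE)
  mp <- Reduce(pmax, lapply(seq_along(st$z_um), function(z) st$data[, , z, 1, 1]))
  ij <- which(mp == max(mp), arr.ind = TRUE)[1, ]
  px <- spec$pixel_size_um
  expect_lt(abs((ij[2] - 0.5) * px - tr$cells$x_um), px)
  expect_lt(abs((ij[1] - 0.5) * px - tr$cells$y_um), px)
  # zero cells: flat background
  tr0 <- tr; tr0$cells <- tr0$cells[0, ]
  st0 <- render_stack(tr0, labels = NULL, frames = 0, noise = FALSE)
  expect_equal(diff(range(st0$data)), 0)
})

test_that("noiseless rendering gives every nucleus the same integrated signal", {
  spec <- organoid_spec(n_cells = 20, radius_um = 74, radial_jitter_um = 0,
                        seed = 6, n_frames = 1)
  tr <- make_organoid(spec)
  st <- render_stack(tr, labels = NULL, noise = FALSE, background = 0)
  slab <- st$data[, , 5, 1, 1]
  px <- spec$pixel_size_um
  ints <- sapply(seq_len(nrow(tr$cells)), function(i) {
    cx <- tr$cells$x_um[i] / px + 0.5; cy <- tr$cells$y_um[i] / px + 0.5
    w <- 8
    sum(slab[round(cy - w):round(cy + w), round(cx - w):round(cx + w)])
  })
  expect_lt(diff(range(ints)) / mean(ints), 0.01)
})

test_that("field of view smaller than the organoid is an error", {
  spec <- organoid_spec(n_cells = 10, radius_um = 20, seed = 1, n_frames = 1)
  tr <- make_organoid(spec)
  tr$fov_um <- 30  # shrink below the organoid footprint
  expect_error(render_stack(tr, labels = NULL), "field of view")
})

test_that("truth tables and stacks round-trip through their file formats", {
  spec <- organoid_spec(n_cells = 12, radius_um = 15, seed = 8, n_frames = 2)
  tr <- simulate_timelapse(apply_ablation(make_organoid(spec), 2))
  tr <- assign_edu_labels(tr)
  tdir <- withr::local_tempdir()
  p <- file.path(tdir, "truth.csv")
  write_truth_csv(tr, p)
  back <- read_truth_csv(p)
  expect_equal(back$x_um, tr$cells$x_um, tolerance = 1e-9)
  expect_equal(back$edu_label, tr$cells$edu_label)
  st <- render_stack(tr)
  tf <- file.path(tdir, "stack.tif")
  write_stack_tiff(st, tf)
  st2 <- read_stack_tiff(tf)
  expect_equal(dim(st2$data), dim(st$data))
  expect_equal(st2$z_um, st$z_um)
  expect_lt(max(abs(st2$data - st$data)), 1e-2)
})
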