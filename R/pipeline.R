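# Configuration and end-to-end orchestration. Every run writes its fully
# resolved config next to its outputs; unknown config keys are rejected
# before any computation.

#' Default pipeline configuration
#'
#' Nested list with one section per stage (`synth`, `detect`, `track`,
#' `geometry`, `quantify`, `stats`, `experiment`) plus `seed` and `out_dir`.
#' All lengths are micrometres, times minutes, as stated in field names.
#'
#' @return the configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "orgrepair-out",
    experiment = list(
      n_organoids = 2L,
      # named conditions: number of ablated cells (0 = unablated control)
      conditions = list(control = 0L, ablate10 = 10L)),
    synth = list(
      n_cells = 80L, radius_um = 74, radial_jitter_um = 1.5,
      nucleus_sigma_um = 1.2, growth_rate_per_h = 0.0025,
      frame_interval_min = 30, n_frames = 13L, z_range_um = 8, z_step_um = 2,
      pixel_size_um = 0.5, ablation_frame = 0L,
      motion = list(sigma_tangential_um = 0.75, drift_speed_um_per_frame = 0,
                    drift_range_um = 0),
      labels = list(baseline_rate = 0.13, bin_boosts = list(),
                    channel_contrast = 5),
      render = list(noise = TRUE, read_noise_sd = 2, background = 5,
                    amplitude = 120, edu_base = 25, axial_sigma_um = 4,
                    scar_frames = 3L, scar_amplitude = 200)),
    detect = list(sigma_um = 1.2, min_separation_um = 3, rel_threshold = 0.1,
                  z_window_um = 6, exclusion_radius_um = 0),
    track = list(max_link_um = 15, max_gap_frames = 2L),
    geometry = list(bin_width_um = 30, metric = "arc", refine_circle = FALSE),
    quantify = list(migration_metric = "path_length", min_duration_frac = 0.5,
                    threshold_strategy = "otsu", segmentation_channel = 1L),
    stats = list(alpha = 0.05, holm = FALSE))
}

# recursive merge of user config onto defaults; unknown keys rejected
merge_config <- function(default, user, path = character()) {
  if (!is.list(user)) return(user)
  extra <- setdiff(names(user), names(default))
  # leaf maps whose keys are data, not schema (e.g. bin_boosts, conditions)
  open_maps <- c("bin_boosts", "conditions")
  if (length(extra) && !(length(path) && path[length(path)] %in% open_maps))
    stop("unknown config key(s): ",
         paste(paste(c(path, ""), collapse = "."), extra, sep = "",
               collapse = ", "), call. = FALSE)
  if (length(path) && path[length(path)] %in% open_maps) return(user)
  out <- default
  for (k in names(user))
    out[[k]] <- merge_config(default[[k]], user[[k]], c(path, k))
  out
}

#' Read and validate a pipeline config file
#'
#' YAML keys mirror [default_config()]; unknown keys are rejected, missing
#' keys take their defaults.
#'
#' @param path YAML file path.
#' @return the fully resolved configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

config_spec <- function(config, seed) {
  s <- config$synth
  organoid_spec(n_cells = s$n_cells, radius_um = s$radius_um,
                radial_jitter_um = s$radial_jitter_um,
                nucleus_sigma_um = s$nucleus_sigma_um,
                growth_rate_per_h = s$growth_rate_per_h,
                frame_interval_min = s$frame_interval_min,
                n_frames = s$n_frames, z_range_um = s$z_range_um,
                z_step_um = s$z_step_um, pixel_size_um = s$pixel_size_um,
                seed = seed)
}

config_labels <- function(config) {
  l <- config$synth$labels
  label_spec(baseline_rate = l$baseline_rate,
             bin_boosts = unlist(l$bin_boosts),
             channel_contrast = l$channel_contrast)
}

organoid_dir <- function(config, condition, i) {
  file.path(config$out_dir, condition, sprintf("org%02d", i))
}

require_artifact <- function(path) {
  if (!file.exists(path))
    stop("missing artifact: ", path, " (run the producing stage first)",
         call. = FALSE)
  path
}

#' Run pipeline stages
#'
#' Subcommands: `simulate` (synthetic stacks + ground truth), `detect`,
#' `track`, `geometry`, `prolif`, `migrate`, `morph`, `stats`, `report`, and
#' `e2e` chaining all stages. Each stage writes its CSV/TIFF/PNG artifacts
#' under `out_dir/<condition>/orgNN/`; summaries, the stats table and figures
#' go to `out_dir`. The resolved config is written to
#' `out_dir/resolved_config.yaml` before any computation.
#'
#' @param config a configuration list (see [default_config()]) or the path of
#'   a YAML config file.
#' @param stage one of the subcommands above.
#' @param quiet suppress progress messages.
#' @return For quantification stages, the aggregated results (invisibly for
#'   the others).
#' @export
run_pipeline <- function(config = default_config(),
                         stage = c("e2e", "simulate", "detect", "track",
                                   "geometry", "prolif", "migrate", "morph",
                                   "stats", "report"),
                         quiet = FALSE) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- merge_config(default_config(), config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(config$out_dir, "resolved_config.yaml"))
  say <- function(...) if (!quiet) message(...)

  stages <- if (stage == "e2e")
    c("simulate", "detect", "track", "geometry", "prolif", "migrate",
      "morph", "stats", "report") else stage
  out <- NULL
  for (st in stages) {
    say("[orgrepair] stage: ", st)
    out <- switch(st,
      simulate = stage_simulate(config),
      detect = stage_detect(config),
      track = stage_track(config),
      geometry = stage_geometry(config),
      prolif = stage_prolif(config),
      migrate = stage_migrate(config),
      morph = stage_morph(config),
      stats = stage_stats(config),
      report = stage_report(config))
  }
  invisible(out)
}

for_each_organoid <- function(config, fn) {
  conds <- config$experiment$conditions
  res <- list()
  for (ci in seq_along(conds)) {
    cond <- names(conds)[ci]
    for (i in seq_len(config$experiment$n_organoids)) {
      dir <- organoid_dir(config, cond, i)
      seed <- config$seed * 10000L + ci * 100L + i
      res[[cond]][[i]] <- fn(cond, conds[[ci]], i, dir, seed)
    }
  }
  res
}

stage_simulate <- function(config) {
  for_each_organoid(config, function(cond, k, i, dir, seed) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    spec <- config_spec(config, seed)
    labels <- config_labels(config)
    truth <- make_organoid(spec)
    if (k > 0)
      truth <- apply_ablation(truth, k, frame = config$synth$ablation_frame)
    m <- config$synth$motion
    truth <- simulate_timelapse(truth, motion_spec(
      m$sigma_tangential_um, m$drift_speed_um_per_frame, m$drift_range_um))
    boosts <- labels$bin_boosts
    lab_here <- if (k > 0 || !length(boosts)) labels else
      label_spec(labels$baseline_rate, numeric(0), labels$channel_contrast)
    truth <- assign_edu_labels(truth, lab_here,
                               bin_width_um = config$geometry$bin_width_um)
    r <- config$synth$render
    stack <- render_stack(truth, labels, noise = r$noise,
                          read_noise_sd = r$read_noise_sd,
                          background = r$background, amplitude = r$amplitude,
                          edu_base = r$edu_base,
                          axial_sigma_um = r$axial_sigma_um,
                          scar_frames = r$scar_frames,
                          scar_amplitude = r$scar_amplitude)
    write_stack_tiff(stack, file.path(dir, "stack.tif"))
    write_truth_csv(truth, file.path(dir, "truth.csv"))
    meta <- list(condition = cond, ablate_k = k, organoid = i, seed = seed,
                 fov_um = truth$fov_um,
                 circle_center_xy_um = truth$circle_center_xy_um,
                 ablation_center_xy_um =
                   if (k > 0) truth$ablation$center_xy_um else NULL,
                 ablation_frame = if (k > 0) truth$ablation$frame else NULL)
    meta <- Filter(Negate(is.null), meta)
    jsonlite::write_json(meta, file.path(dir, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
  })
}

stage_detect <- function(config) {
  d <- config$detect
  for_each_organoid(config, function(cond, k, i, dir, seed) {
    stack <- read_stack_tiff(require_artifact(file.path(dir, "stack.tif")))
    meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                                simplifyVector = TRUE)
    excl <- if (d$exclusion_radius_um > 0 && !is.null(meta$ablation_center_xy_um))
      meta$ablation_center_xy_um else NULL
    dets <- lapply(stack$frames, function(f) {
      mip <- project(stack, channel = 1L, mode = "max",
                     z_window = c(-d$z_window_um, d$z_window_um), frame = f)
      det <- detect_nuclei(mip, sigma_um = d$sigma_um,
                           min_separation_um = d$min_separation_um,
                           rel_threshold = d$rel_threshold,
                           exclusion_center_um = excl,
                           exclusion_radius_um = d$exclusion_radius_um)
      imgs <- list(ch1 = mip)
      if (stack$channels >= 2)
        imgs$ch2 <- project(stack, channel = 2L, mode = "sum", frame = f)
      det <- measure_intensity(det, imgs)
      det$frame <- f
      det
    })
    write_detections_csv(do.call(rbind, dets), file.path(dir, "detections.csv"))
    invisible(dir)
  })
}

stage_track <- function(config) {
  for_each_organoid(config, function(cond, k, i, dir, seed) {
    det <- read_detections_csv(require_artifact(file.path(dir, "detections.csv")))
    tracks <- build_tracks(det, max_link_um = config$track$max_link_um,
                           max_gap_frames = config$track$max_gap_frames)
    write_tracks_csv(tracks, file.path(dir, "tracks.csv"),
                     file.path(dir, "track_metrics.csv"))
    invisible(dir)
  })
}

# per-frame circle fit + site angle; returns the geometry table
organoid_geometry <- function(det, meta, refine = FALSE) {
  site_xy <- meta$ablation_center_xy_um
  if (length(site_xy) != 2) site_xy <- NULL
  rows <- lapply(sort(unique(det$frame)), function(f) {
    d <- det[det$frame == f, ]
    fit <- fit_circle(d, refine = refine)
    xy <- if (is.null(site_xy))  # sham site for unablated controls: theta = 0
      c(fit$cx_um + fit$r_um, fit$cy_um) else site_xy
    site <- ablation_site(xy[1], xy[2], fit)
    data.frame(frame = f, cx_um = fit$cx_um, cy_um = fit$cy_um,
               r_um = fit$r_um, rms_residual_um = fit$rms_residual_um,
               theta0_rad = site$theta0_rad, site_x_um = xy[1],
               site_y_um = xy[2])
  })
  do.call(rbind, rows)
}

stage_geometry <- function(config) {
  for_each_organoid(config, function(cond, k, i, dir, seed) {
    det <- read_detections_csv(require_artifact(file.path(dir, "detections.csv")))
    meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                                simplifyVector = TRUE)
    geo <- organoid_geometry(det, meta, config$geometry$refine_circle)
    con <- file(file.path(dir, "geometry.csv"), "w")
    writeLines("# per-frame circle fit and ablation-site angle (um, rad)", con)
    utils::write.table(geo, con, sep = ",", row.names = FALSE, quote = FALSE)
    close(con)
    invisible(dir)
  })
}

geometry_at <- function(dir, frame) {
  geo <- utils::read.csv(require_artifact(file.path(dir, "geometry.csv")),
                         comment.char = "#")
  row <- geo[which.min(abs(geo$frame - frame)), ]
  circle <- structure(list(cx_um = row$cx_um, cy_um = row$cy_um,
                           r_um = row$r_um,
                           rms_residual_um = row$rms_residual_um,
                           n = NA_integer_, refined = FALSE),
                      class = "circle_fit")
  list(circle = circle,
       site = ablation_site(row$site_x_um, row$site_y_um, circle))
}

stage_prolif <- function(config) {
  res <- for_each_organoid(config, function(cond, k, i, dir, seed) {
    det <- read_detections_csv(require_artifact(file.path(dir, "detections.csv")))
    last <- max(det$frame)
    det <- det[det$frame == last, ]
    g <- geometry_at(dir, last)
    pr <- proliferation_map(det, g$circle, g$site,
                            threshold_strategy = config$quantify$threshold_strategy,
                            bin_width_um = config$geometry$bin_width_um,
                            metric = config$geometry$metric)
    con <- file(file.path(dir, "prolif.csv"), "w")
    writeLines(c("# EdU-positive fraction per half-open 30-um arc-distance bin",
                 sprintf("# overall_rate,%g", pr$overall_rate)), con)
    utils::write.table(pr$per_bin, con, sep = ",", row.names = FALSE,
                       quote = FALSE)
    close(con)
    pr
  })
  summaries <- lapply(names(res), function(cond) {
    s <- aggregate_condition(res[[cond]])
    s$condition <- cond
    s
  })
  summary <- do.call(rbind, summaries)
  utils::write.csv(summary, file.path(config$out_dir, "summary_prolif.csv"),
                   row.names = FALSE)
  invisible(list(per_organoid = res, summary = summary))
}

stage_migrate <- function(config) {
  res <- for_each_organoid(config, function(cond, k, i, dir, seed) {
    tracks <- read_tracks_csv(require_artifact(file.path(dir, "tracks.csv")))
    meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                                simplifyVector = TRUE)
    ref_frame <- if (!is.null(meta$ablation_frame))
      meta$ablation_frame + 1L else min(tracks$points$frame)
    if (!ref_frame %in% tracks$points$frame)
      ref_frame <- min(tracks$points$frame)
    g <- geometry_at(dir, ref_frame)
    mg <- migration_map(tracks, g$circle, g$site,
                        metric = config$quantify$migration_metric,
                        reference_frame = ref_frame,
                        min_duration_frac = config$quantify$min_duration_frac,
                        bin_width_um = config$geometry$bin_width_um,
                        distance_metric = config$geometry$metric)
    con <- file(file.path(dir, "migration.csv"), "w")
    writeLines(c(sprintf("# per-bin mean %s (um), half-open 30-um arc bins",
                         mg$metric),
                 sprintf("# overall_mean_um,%g", mg$overall_mean_um)), con)
    utils::write.table(mg$per_bin, con, sep = ",", row.names = FALSE,
                       quote = FALSE)
    close(con)
    mg
  })
  summaries <- lapply(names(res), function(cond) {
    s <- aggregate_condition(res[[cond]])
    s$condition <- cond
    s
  })
  summary <- do.call(rbind, summaries)
  utils::write.csv(summary, file.path(config$out_dir, "summary_migration.csv"),
                   row.names = FALSE)
  invisible(list(per_organoid = res, summary = summary))
}

stage_morph <- function(config) {
  res <- for_each_organoid(config, function(cond, k, i, dir, seed) {
    stack <- read_stack_tiff(require_artifact(file.path(dir, "stack.tif")))
    ds <- diameter_series(stack, channel = config$quantify$segmentation_channel,
                          frame_interval_min = config$synth$frame_interval_min)
    utils::write.csv(ds, file.path(dir, "diameter.csv"), row.names = FALSE)
    ds
  })
  rows <- list()
  for (cond in names(res)) {
    rel_last <- vapply(res[[cond]], function(d)
      d$rel_diameter_pct[nrow(d)], numeric(1))
    rows[[cond]] <- data.frame(condition = cond,
                               rel_diameter_last_mean = mean(rel_last),
                               rel_diameter_last_sem = sem(rel_last),
                               n_organoids = length(rel_last))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  utils::write.csv(summary, file.path(config$out_dir, "summary_diameter.csv"),
                   row.names = FALSE)
  invisible(list(per_organoid = res, summary = summary))
}

read_overall <- function(path, key) {
  lines <- readLines(path, n = 5)
  hit <- grep(paste0("^# ", key, ","), lines, value = TRUE)
  as.numeric(sub(paste0("^# ", key, ","), "", hit[1]))
}

stage_stats <- function(config) {
  conds <- names(config$experiment$conditions)
  collect <- function(file, key) {
    vals <- lapply(conds, function(cond) {
      vapply(seq_len(config$experiment$n_organoids), function(i)
        read_overall(require_artifact(
          file.path(organoid_dir(config, cond, i), file)), key), numeric(1))
    })
    names(vals) <- conds
    vals
  }
  tabs <- list(
    compare_groups(collect("prolif.csv", "overall_rate"),
                   "overall proliferation rate", config$stats$alpha,
                   config$stats$holm),
    compare_groups(collect("migration.csv", "overall_mean_um"),
                   "overall migration distance (um)", config$stats$alpha,
                   config$stats$holm))
  stats_table <- do.call(rbind, tabs)
  utils::write.csv(stats_table, file.path(config$out_dir, "stats.csv"),
                   row.names = FALSE)
  invisible(stats_table)
}

bar_with_sem <- function(summary, value_lab, file) {
  grDevices::png(file, width = 900, height = 500)
  on.exit(grDevices::dev.off())
  conds <- unique(summary$condition)
  bins <- summary[summary$bin != "overall", ]
  labs <- sort(unique(paste0("[", bins$lo_um, ",", bins$hi_um, ")")))
  mat <- matrix(NA_real_, length(conds), length(labs),
                dimnames = list(conds, labs))
  sems <- mat
  for (r in seq_len(nrow(bins))) {
    lab <- paste0("[", bins$lo_um[r], ",", bins$hi_um[r], ")")
    mat[bins$condition[r], lab] <- bins$mean[r]
    sems[bins$condition[r], lab] <- bins$sem[r]
  }
  bp <- graphics::barplot(mat, beside = TRUE, legend.text = conds,
                          ylab = value_lab, xlab = "distance from ablation site (um)",
                          ylim = c(0, max(mat + sems, na.rm = TRUE) * 1.2))
  graphics::arrows(bp, mat - sems, bp, mat + sems, angle = 90, code = 3,
                   length = 0.03)
  invisible(file)
}

stage_report <- function(config) {
  pr <- file.path(config$out_dir, "summary_prolif.csv")
  mg <- file.path(config$out_dir, "summary_migration.csv")
  if (file.exists(pr))
    bar_with_sem(utils::read.csv(pr), "EdU-positive fraction",
                 file.path(config$out_dir, "report_prolif.png"))
  if (file.exists(mg))
    bar_with_sem(utils::read.csv(mg), "mean migration distance (um)",
                 file.path(config$out_dir, "report_migration.png"))
  invisible(config$out_dir)
}
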