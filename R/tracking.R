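# LAP-style cell tracking: frame-to-frame linear assignment with birth/death
# alternatives, gap closing across short disappearances, per-track metrics.

# Solve the Jaqaman-style augmented assignment between two point sets.
# Returns integer vector a of length n (rows of det_t): a[i] = j if i links to
# detection j in det_t1, NA if track i terminates.
lap_assign <- function(xy0, xy1, max_cost, cost_fun) {
  n <- nrow(xy0); m <- nrow(xy1)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  C <- cost_fun(xy0, xy1)
  feasible <- C <= max_cost
  big <- max_cost * (n + m + 2)
  M <- matrix(big, n + m, n + m)
  M[seq_len(n), seq_len(m)] <- ifelse(feasible, C, big)
  M[cbind(seq_len(n), m + seq_len(n))] <- max_cost  # death
  M[cbind(n + seq_len(m), seq_len(m))] <- max_cost  # birth
  M[n + seq_len(m), m + seq_len(n)] <- ifelse(t(feasible), 0, big)
  sol <- as.integer(clue::solve_LSAP(M))
  a <- rep(NA_integer_, n)
  hit <- sol[seq_len(n)] <= m & feasible[cbind(seq_len(n),
                                               pmin(sol[seq_len(n)], m))]
  a[hit] <- sol[seq_len(n)][hit]
  a
}

sqdist_matrix <- function(xy0, xy1) {
  outer(xy0[, 1], xy1[, 1], "-")^2 + outer(xy0[, 2], xy1[, 2], "-")^2
}

#' Link detections of two consecutive frames
#'
#' Globally optimal one-to-one assignment minimizing the summed squared
#' Euclidean distances, with links longer than `max_link_um` forbidden.
#' Unmatched detections terminate (frame t) or open (frame t+1) tracks.
#'
#' @param det_t,det_t1 data.frames with `x_um`, `y_um` (frames t, t+1).
#' @param max_link_um maximum link length (um).
#' @return list: `links` (data.frame i, j, dist_um), `unmatched_t`,
#'   `unmatched_t1` (row indices), `cost` (summed squared distance of links).
#' @export
link_frames <- function(det_t, det_t1, max_link_um = 15) {
  stopifnot(max_link_um > 0)
  xy0 <- cbind(det_t$x_um, det_t$y_um)
  xy1 <- cbind(det_t1$x_um, det_t1$y_um)
  a <- lap_assign(xy0, xy1, max_link_um^2, sqdist_matrix)
  i <- which(!is.na(a))
  j <- a[i]
  d <- if (length(i)) sqrt((xy0[i, 1] - xy1[j, 1])^2 +
                           (xy0[i, 2] - xy1[j, 2])^2) else numeric(0)
  list(links = data.frame(i = i, j = j, dist_um = d),
       unmatched_t = setdiff(seq_len(nrow(det_t)), i),
       unmatched_t1 = setdiff(seq_len(nrow(det_t1)), j),
       cost = sum(d^2))
}

#' Build cell trajectories from per-frame detections
#'
#' Chains frame-to-frame LAP assignments into track segments, then closes
#' gaps: a track ending at frame t may continue as one starting at frame
#' t + g + 1 (g <= `max_gap_frames`) if the jump is within
#' `max_link_um * (g + 1)`; gap closing is itself solved as a LAP.
#'
#' @param detections data.frame with `frame`, `x_um`, `y_um` (all frames), or
#'   a list of per-frame data.frames.
#' @param max_link_um maximum per-frame link length (um, default 15 um per
#'   30-min frame).
#' @param max_gap_frames maximum number of missed frames bridged (default 2).
#' @return Object of class `organoid_tracks`: list with `points`
#'   (data.frame: track_id, frame, x_um, y_um, det_row) and `metrics`
#'   (data.frame: track_id, n_points, first_frame, last_frame,
#'   path_length_um, net_displacement_um, max_excursion_um).
#' @export
build_tracks <- function(detections, max_link_um = 15, max_gap_frames = 2) {
  if (!is.data.frame(detections)) detections <- do.call(rbind, detections)
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(detections)))
  # enumerate the full frame range so frame-number gaps are respected even
  # when whole frames are missing from the table
  frames <- if (nrow(detections)) seq(min(detections$frame),
                                      max(detections$frame)) else numeric(0)
  by_frame <- lapply(frames, function(f)
    detections[detections$frame == f, , drop = FALSE])
  nf <- length(by_frame)
  # seg id per detection, per frame
  seg_of <- lapply(by_frame, function(d) rep(NA_integer_, nrow(d)))
  next_seg <- 0L
  new_segs <- function(k) {
    ids <- next_seg + seq_len(k)
    next_seg <<- next_seg + k
    ids
  }
  if (nf > 0 && nrow(by_frame[[1]]) > 0)
    seg_of[[1]] <- new_segs(nrow(by_frame[[1]]))
  if (nf > 1) for (f in seq_len(nf - 1)) {
    asg <- link_frames(by_frame[[f]], by_frame[[f + 1]], max_link_um)
    s <- rep(NA_integer_, nrow(by_frame[[f + 1]]))
    s[asg$links$j] <- seg_of[[f]][asg$links$i]
    if (length(asg$unmatched_t1))
      s[asg$unmatched_t1] <- new_segs(length(asg$unmatched_t1))
    seg_of[[f + 1]] <- s
  }
  pts <- do.call(rbind, lapply(seq_len(nf), function(f) {
    d <- by_frame[[f]]
    if (nrow(d) == 0) return(NULL)
    data.frame(seg = seg_of[[f]], frame = frames[f], x_um = d$x_um,
               y_um = d$y_um, det_row = seq_len(nrow(d)))
  }))
  if (is.null(pts) || nrow(pts) == 0) {
    empty <- data.frame(track_id = integer(0), frame = numeric(0),
                        x_um = numeric(0), y_um = numeric(0),
                        det_row = integer(0))
    return(structure(list(points = empty, metrics = track_metrics(empty)),
                     class = "organoid_tracks"))
  }

  # gap closing: track-end to track-start LAP
  if (max_gap_frames > 0) {
    seg_split <- split(pts, pts$seg)
    ends <- do.call(rbind, lapply(seg_split, function(p)
      p[which.max(p$frame), , drop = FALSE]))
    starts <- do.call(rbind, lapply(seg_split, function(p)
      p[which.min(p$frame), , drop = FALSE]))
    # [end, start] frame gap in frame positions (gap of 2 = one missed frame)
    gaps <- outer(match(ends$frame, frames), match(starts$frame, frames),
                  function(e, s) s - e)
    d2 <- sqdist_matrix(cbind(ends$x_um, ends$y_um),
                        cbind(starts$x_um, starts$y_um))
    allowed <- gaps >= 2 & gaps <= (max_gap_frames + 1) &
      outer(ends$seg, starts$seg, "!=") &
      d2 <= (max_link_um * gaps)^2  # jump limit scales with frame gap
    maxc <- (max_link_um * (max_gap_frames + 1))^2
    C <- ifelse(allowed, d2, maxc * 10)
    if (any(allowed)) {
      a <- lap_assign(cbind(ends$x_um, ends$y_um),
                      cbind(starts$x_um, starts$y_um), maxc,
                      function(a1, a2) C)
      # merge: start segment inherits end segment's id (iteratively resolve)
      relabel <- seq_len(next_seg)
      for (i in which(!is.na(a))) {
        if (!allowed[i, a[i]]) next
        relabel[starts$seg[a[i]]] <- ends$seg[i]
      }
      # resolve chains end-to-start-to-end
      repeat {
        r2 <- relabel[relabel]
        if (identical(r2, relabel)) break
        relabel <- r2
      }
      pts$seg <- relabel[pts$seg]
    }
  }
  pts <- pts[order(pts$seg, pts$frame), ]
  pts$track_id <- match(pts$seg, unique(pts$seg))
  pts <- pts[, c("track_id", "frame", "x_um", "y_um", "det_row")]
  rownames(pts) <- NULL
  structure(list(points = pts, metrics = track_metrics(pts)),
            class = "organoid_tracks")
}

#' Per-track motion metrics
#'
#' @param points data.frame with `track_id`, `frame`, `x_um`, `y_um`.
#' @return data.frame: track_id, n_points, first_frame, last_frame,
#'   path_length_um (sum of consecutive step lengths), net_displacement_um
#'   (start-to-end), max_excursion_um (max distance from start).
#' @export
track_metrics <- function(points) {
  if (nrow(points) == 0)
    return(data.frame(track_id = integer(0), n_points = integer(0),
                      first_frame = numeric(0), last_frame = numeric(0),
                      path_length_um = numeric(0),
                      net_displacement_um = numeric(0),
                      max_excursion_um = numeric(0)))
  m <- do.call(rbind, lapply(split(points, points$track_id), function(p) {
    p <- p[order(p$frame), ]
    dx <- diff(p$x_um); dy <- diff(p$y_um)
    ex <- sqrt((p$x_um - p$x_um[1])^2 + (p$y_um - p$y_um[1])^2)
    data.frame(track_id = p$track_id[1], n_points = nrow(p),
               first_frame = p$frame[1], last_frame = p$frame[nrow(p)],
               path_length_um = sum(sqrt(dx^2 + dy^2)),
               net_displacement_um = ex[length(ex)],
               max_excursion_um = max(ex))
  }))
  rownames(m) <- NULL
  m
}

#' @export
print.organoid_tracks <- function(x, ...) {
  cat("organoid_tracks:", nrow(x$metrics), "tracks,",
      nrow(x$points), "points; median path length",
      round(stats::median(x$metrics$path_length_um), 1), "um\n")
  invisible(x)
}

#' Write / read track tables as CSV
#'
#' `write_tracks_csv` writes the point table (track_id, frame, x_um, y_um)
#' and, when `metrics_path` is given, the per-track metrics table.
#'
#' @param tracks an `organoid_tracks`.
#' @param path point-table CSV path.
#' @param metrics_path optional metrics CSV path.
#' @return `path` invisibly; `read_tracks_csv` rebuilds the
#'   `organoid_tracks` (metrics recomputed from the points).
#' @export
write_tracks_csv <- function(tracks, path, metrics_path = NULL) {
  con <- file(path, "w")
  writeLines(c("# cell trajectories",
               "# units: um; origin top-left; y increases downward"), con)
  utils::write.table(tracks$points[, c("track_id", "frame", "x_um", "y_um")],
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
  if (!is.null(metrics_path)) {
    con <- file(metrics_path, "w")
    writeLines("# per-track motion metrics (um)", con)
    utils::write.table(tracks$metrics, con, sep = ",", row.names = FALSE,
                       quote = FALSE)
    close(con)
  }
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  pts <- utils::read.csv(path, comment.char = "#")
  pts$det_row <- NA_integer_
  structure(list(points = pts, metrics = track_metrics(pts)),
            class = "organoid_tracks")
}
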