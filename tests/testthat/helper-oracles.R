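# Independent oracles and fixture builders shared across tests.

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# brute-force optimal full assignment cost (squared distances), links > max
# forbidden; Inf if no feasible full assignment
brute_force_assignment_cost <- function(a, b, max_link_um) {
  n <- nrow(a)
  p <- perms(n)
  costs <- apply(p, 1, function(idx) {
    d2 <- (a$x_um - b$x_um[idx])^2 + (a$y_um - b$y_um[idx])^2
    if (all(d2 <= max_link_um^2)) sum(d2) else Inf
  })
  min(costs)
}

# geometric circle fit by coarse-to-fine grid search over the centre, radius
# closed-form (mean distance); independent of the Kasa solver
grid_circle_fit <- function(x, y, half_width = 20, steps = 4) {
  cx <- mean(x); cy <- mean(y)
  h <- half_width
  for (s in seq_len(steps)) {
    gx <- seq(cx - h, cx + h, length.out = 41)
    gy <- seq(cy - h, cy + h, length.out = 41)
    best <- c(Inf, cx, cy)
    for (xx in gx) {
      for (yy in gy) {
        d <- sqrt((x - xx)^2 + (y - yy)^2)
        ss <- sum((d - mean(d))^2)
        if (ss < best[1]) best <- c(ss, xx, yy)
      }
    }
    cx <- best[2]; cy <- best[3]
    h <- h / 10
  }
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  list(cx = cx, cy = cy, r = mean(d))
}

# geodesic distance on a circle by enumeration over winding offsets
enum_arc <- function(theta, theta0, r) {
  r * min(abs(theta - theta0 + 2 * pi * (-2:2)))
}

# quick single-frame organoid with k ablated cells and EdU labels
edu_fixture <- function(seed, n_cells = 100, k = 5,
                        labels = label_spec(0.13, c("1" = 0.14))) {
  spec <- organoid_spec(n_cells = n_cells, seed = seed, n_frames = 1)
  tr <- apply_ablation(make_organoid(spec), k)
  assign_edu_labels(tr, labels)
}

# truth positions formatted as a detection table
truth_as_detections <- function(truth, frames = NULL) {
  d <- truth$cells
  if (!is.null(frames)) d <- d[d$frame %in% frames, ]
  data.frame(frame = d$frame, x_um = d$x_um, y_um = d$y_um,
             cell_id = d$cell_id, edu_label = d$edu_label)
}

wrap_angle_for_test <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  if (out >= pi) out <- -pi
  out
}
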