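#' Receptive-field grid of the local motion-energy layer
#'
#' 1116 local motion-energy detectors arranged as a 36-row by 31-column grid
#' of small (about 0.4 degree) receptive fields tiling the stimulus area with
#' some overlap.  Each detector signals motion in the four cardinal
#' directions.  Row 1 is the bottom of the grid (world y-up convention).
#'
#' Field size is derived from the grid pitch and the overlap fraction:
#' `size = pitch / (1 - overlap)`, so `overlap = 0` partitions the area
#' exactly.
#'
#' @param rows,cols grid dimensions (defaults 36 x 31).
#' @param width_deg,height_deg extent of the tiled stimulus area in degrees.
#' @param center_deg world (x, y) of the grid centre.
#' @param overlap linear overlap fraction between neighbouring fields, in
#'   `[0, 1)`.  The default 1/6 yields 0.4-degree fields at the default
#'   extent.
#' @return object of class `motion_grid` with field centres and half-sizes.
#' @export
motion_grid <- function(rows = 36L, cols = 31L, width_deg = 10 + 1 / 3,
                        height_deg = 12, center_deg = c(0, 6),
                        overlap = 1 / 6) {
  stopifnot(rows >= 2, cols >= 2, overlap >= 0, overlap < 1)
  pitch_x <- width_deg / cols
  pitch_y <- height_deg / rows
  size_x <- pitch_x / (1 - overlap)
  size_y <- pitch_y / (1 - overlap)
  cx <- center_deg[1] + (seq_len(cols) - (cols + 1) / 2) * pitch_x
  cy <- center_deg[2] + (seq_len(rows) - (rows + 1) / 2) * pitch_y
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 cx = cx, cy = cy, half_x = size_x / 2, half_y = size_y / 2,
                 overlap = overlap, n_fields = as.integer(rows * cols)),
            class = "motion_grid")
}

#' @export
print.motion_grid <- function(x, ...) {
  cat(sprintf("Motion-energy grid: %d x %d = %d receptive fields (%.2f x %.2f deg, overlap %.2f)\n",
              x$rows, x$cols, x$n_fields, 2 * x$half_x, 2 * x$half_y, x$overlap))
  invisible(x)
}

direction_labels <- function() c("right", "left", "up", "down")

#' Optical flow between two frames
#'
#' Two modes are supported.  `"exact"` takes a `plseq` plus a frame index and
#' returns the ground-truth joint velocities (projected, degrees per frame) at
#' the joints' positions, bypassing estimation error; this is the mode used by
#' the simulation pipeline.  `"lk"` is a classic dense Lucas-Kanade estimator
#' on a pair of rendered frames.
#'
#' @param frame_a,frame_b same-shape intensity matrices (`"lk"` mode).
#' @param method `"lk"` (dense) -- for ground truth use [flow_exact()].
#' @param window odd window size for the local least squares (pixels).
#' @param px_per_deg pixel scale used to convert to degrees.
#' @return a `flow_field`: either dense (`vx`, `vy` matrices, world y-up
#'   already applied) or joint-based (`px`, `py`, `vx`, `vy` vectors).
#' @export
compute_flow <- function(frame_a, frame_b, method = "lk", window = 9L,
                         px_per_deg = 8) {
  if (!all(dim(frame_a) == dim(frame_b))) stop("frame shapes differ")
  method <- match.arg(method, "lk")
  lucas_kanade(frame_a, frame_b, window = window, px_per_deg = px_per_deg)
}

# dense Lucas-Kanade: local least-squares on spatial/temporal gradients
lucas_kanade <- function(a, b, window = 9L, px_per_deg = 8, eps = 1e-4) {
  sm <- function(m) box_filter(m, 3L)
  a <- sm(a); b <- sm(b)
  Ix <- shift_m(a + b, 0, 1) - shift_m(a + b, 0, -1)
  Iy <- shift_m(a + b, 1, 0) - shift_m(a + b, -1, 0)
  Ix <- Ix / 4; Iy <- Iy / 4          # average of the two frames, central diff
  It <- b - a
  Sxx <- box_filter(Ix * Ix, window); Sxy <- box_filter(Ix * Iy, window)
  Syy <- box_filter(Iy * Iy, window)
  Sxt <- box_filter(Ix * It, window); Syt <- box_filter(Iy * It, window)
  det <- (Sxx + eps) * (Syy + eps) - Sxy^2
  vx <- (-(Syy + eps) * Sxt + Sxy * Syt) / det
  vy <- (Sxy * Sxt - (Sxx + eps) * Syt) / det
  # image rows grow downward; world v_y is the negation
  structure(list(type = "dense", vx = vx / px_per_deg, vy = -vy / px_per_deg,
                 px_per_deg = px_per_deg),
            class = "flow_field")
}

shift_m <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(seq_len(nr) + dr, 1), nr)
  c <- pmin(pmax(seq_len(nc) + dc, 1), nc)
  m[r, c, drop = FALSE]
}

box_filter <- function(m, k) {
  if (k <= 1) return(m)
  h <- (k - 1) %/% 2
  out <- m * 0
  cnt <- m * 0
  for (dr in -h:h) for (dc in -h:h) {
    out <- out + shift_m(m, dr, dc)
    cnt <- cnt + 1
  }
  out / cnt
}

#' Ground-truth flow from joint kinematics
#'
#' @param seq a `plseq`.
#' @param frame_index index `i` in `2:n_frames`; the flow is the displacement
#'   from frame `i - 1` to frame `i` of each joint's orthographic projection,
#'   in degrees per frame.
#' @export
flow_exact <- function(seq, frame_index) {
  stopifnot(inherits(seq, "plseq"), frame_index >= 2,
            frame_index <= dim(seq$frames)[1])
  p1 <- seq$frames[frame_index - 1, , c("x", "y"), drop = TRUE]
  p2 <- seq$frames[frame_index, , c("x", "y"), drop = TRUE]
  structure(list(type = "joint",
                 px = p2[, "x"], py = p2[, "y"],
                 vx = p2[, "x"] - p1[, "x"], vy = p2[, "y"] - p1[, "y"],
                 frame_index = frame_index),
            class = "flow_field")
}

#' Local motion-energy responses on the receptive-field grid
#'
#' For each grid cell the flow vectors falling inside the receptive field are
#' averaged and the mean is projected onto the four cardinal directions with
#' half-wave rectification, so opposite channels are mutually exclusive.
#'
#' @param flow a `flow_field` (dense or joint-based).
#' @param grid a [motion_grid()].
#' @return `direction_maps`: array `rows x cols x 4` with direction order
#'   (right, left, up, down).
#' @export
local_response <- function(flow, grid) {
  stopifnot(inherits(flow, "flow_field"), inherits(grid, "motion_grid"))
  mvx <- matrix(0, grid$rows, grid$cols)
  mvy <- matrix(0, grid$rows, grid$cols)
  if (flow$type == "joint") {
    # loop over joints (few) rather than cells (1116); overlapping fields may
    # share a joint, so accumulate sums and counts per cell
    sx <- mvx; sy <- mvx; cnt <- mvx
    for (j in seq_along(flow$px)) {
      rs <- which(abs(grid$cy - flow$py[j]) <= grid$half_y)
      cs <- which(abs(grid$cx - flow$px[j]) <= grid$half_x)
      if (!length(rs) || !length(cs)) next
      sx[rs, cs] <- sx[rs, cs] + flow$vx[j]
      sy[rs, cs] <- sy[rs, cs] + flow$vy[j]
      cnt[rs, cs] <- cnt[rs, cs] + 1
    }
    nz <- cnt > 0
    mvx[nz] <- sx[nz] / cnt[nz]
    mvy[nz] <- sy[nz] / cnt[nz]
  } else {
    nrp <- nrow(flow$vx); ncp <- ncol(flow$vx)
    # pixel world coordinates (image centred on the grid centre)
    px <- (seq_len(ncp) - (ncp + 1) / 2) / flow$px_per_deg + mean(grid$cx)
    py <- ((nrp + 1) / 2 - seq_len(nrp)) / flow$px_per_deg + mean(grid$cy)
    for (r in seq_len(grid$rows)) {
      ry <- which(abs(py - grid$cy[r]) <= grid$half_y)
      if (!length(ry)) next
      for (c in seq_len(grid$cols)) {
        rx <- which(abs(px - grid$cx[c]) <= grid$half_x)
        if (!length(rx)) next
        mvx[r, c] <- mean(flow$vx[ry, rx])
        mvy[r, c] <- mean(flow$vy[ry, rx])
      }
    }
  }
  maps <- array(0, dim = c(grid$rows, grid$cols, 4L),
                dimnames = list(NULL, NULL, direction_labels()))
  maps[, , "right"] <- pmax(mvx, 0)
  maps[, , "left"] <- pmax(-mvx, 0)
  maps[, , "up"] <- pmax(mvy, 0)
  maps[, , "down"] <- pmax(-mvy, 0)
  structure(maps, class = "direction_maps")
}

#' Direction maps for every consecutive frame pair of a sequence
#'
#' Ground-truth (joint-velocity) mode; returns a list indexed by frame pair,
#' element `p` holding the maps for the flow from frame `p` to `p + 1`.
#'
#' @param seq a `plseq`.
#' @param grid a [motion_grid()].
#' @export
sequence_direction_maps <- function(seq, grid) {
  nf <- dim(seq$frames)[1]
  lapply(2:nf, function(i) local_response(flow_exact(seq, i), grid))
}
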