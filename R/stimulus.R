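#' Stimulus generator configuration
#'
#' The synthetic point-light kicker is a keyframed two-legged skeleton with 14
#' joints (head, shoulders, elbows, wrists, mid-hip, knees, ankles, toes).
#' Coordinates are expressed directly in degrees of visual angle, with the
#' whole figure subtending roughly 12 degrees vertically; `x` points rightward,
#' `y` upward, and `z` toward the viewer (the depth axis about which the
#' deviation rotation is applied).
#'
#' @param n_frames number of animation frames (default 90).
#' @param frame_rate frames per second (default 20, so 90 frames last 4.5 s).
#' @param figure_height_deg vertical extent of the figure in degrees of visual
#'   angle (default 12).
#' @param windup_fraction fraction of the sequence spent in the preparatory
#'   wind-up before the ballistic leg swing (default 0.6).
#' @param hold_fraction fraction of the sequence spent in the initial static
#'   stance before any movement (default 0.1); a real kicker stands quietly
#'   before the run-up, and the stance carries no direction information.
#' @return a list of class `stimulus_config`.
#' @export
stimulus_config <- function(n_frames = 90L, frame_rate = 20,
                            figure_height_deg = 12, windup_fraction = 0.6,
                            hold_fraction = 0.1) {
  stopifnot(n_frames >= 2, frame_rate > 0, figure_height_deg > 0,
            windup_fraction > 0, windup_fraction < 1,
            hold_fraction >= 0, hold_fraction < windup_fraction)
  structure(list(n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 figure_height_deg = figure_height_deg,
                 windup_fraction = windup_fraction,
                 hold_fraction = hold_fraction),
            class = "stimulus_config")
}

kick_joint_labels <- function() {
  c("head", "l_shoulder", "r_shoulder", "l_elbow", "r_elbow",
    "l_wrist", "r_wrist", "hip", "l_knee", "r_knee",
    "l_ankle", "r_ankle", "l_toe", "r_toe")
}

# smoothstep ramp on [0, 1]
.sstep <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  v * v * (3 - 2 * v)
}

# Base kick at zero deviation: a bilaterally symmetric two-legged ballistic
# kick (crouching wind-up, then both legs swing forward and up while the
# raised arms drop).  Returns n_frames x 14 x 3 array in world coordinates
# (degrees), hip root at (0, hip_y, 0).
#
# Bilateral symmetry is deliberate: the left and right test classes are pure
# rotations of one base movement, so at zero deviation the two classes
# coincide and the only left/right information is the rotation sign carried
# by the late-phase limb trajectories.  An asymmetric (one-legged) kicker
# would leak a deviation-independent identity cue into the feature level.
# The symmetric strike still provides the opposed motion the opponent level
# feeds on: legs spread and rise while hip, head and arms drop.
.base_kick_frames <- function(config) {
  n <- config$n_frames
  u <- (seq_len(n) - 1) / (n - 1)
  u0 <- config$windup_fraction
  s <- config$figure_height_deg / 12   # joint layout drawn for a 12-deg figure

  lab <- kick_joint_labels()
  fr <- array(0, dim = c(n, length(lab), 3L), dimnames = list(NULL, lab, c("x", "y", "z")))

  u1 <- config$hold_fraction
  ua <- pmax((u - u1) / (1 - u1), 0)                     # time since movement onset
  w0 <- (u0 - u1) / (1 - u1)
  wind <- ifelse(ua < w0, sin(pi * ua / (2 * w0)), 1)    # 0 -> 1 over wind-up
  v <- pmax((ua - w0) / (1 - w0), 0)                     # strike phase ramp
  swing <- .sstep(v)                                     # 0 -> 1 ballistic swing

  bob <- 0.15 * sin(2 * pi * ua) * s
  arm_z <- 0.8 * sin(1.5 * pi * ua) * s                  # both arms together
  crouch <- 0.6 * wind * s
  dip <- 0.35 * swing * s
  arm_y <- 1.0 * wind * s - 1.7 * swing * s              # raise, then drop

  fr[, "head", ] <- cbind(0, 11.5 * s + bob - 0.5 * crouch - dip, 0)
  fr[, "l_shoulder", ] <- cbind(-1.5 * s, 9.5 * s + bob - 0.7 * crouch - dip, 0)
  fr[, "r_shoulder", ] <- cbind(+1.5 * s, 9.5 * s + bob - 0.7 * crouch - dip, 0)
  fr[, "l_elbow", ] <- cbind(-1.7 * s, 7.8 * s + bob + 0.5 * arm_y, 0.5 * arm_z)
  fr[, "r_elbow", ] <- cbind(+1.7 * s, 7.8 * s + bob + 0.5 * arm_y, 0.5 * arm_z)
  fr[, "l_wrist", ] <- cbind(-1.8 * s, 6.3 * s + bob + arm_y, arm_z)
  fr[, "r_wrist", ] <- cbind(+1.8 * s, 6.3 * s + bob + arm_y, arm_z)
  fr[, "hip", ] <- cbind(0, 6.5 * s + bob - crouch - dip, 0.3 * swing * s)

  # legs: draw back and crouch during wind-up, then ballistic forward/upward
  # swing with a slight symmetric spread; the late-phase foot trajectory is
  # the direction carrier once the figure is rotated
  z_leg <- (-2.0 * wind + 5.2 * swing) * s
  y_lift <- 3.2 * .sstep(v) * s
  spread <- swing * s
  fr[, "l_knee", ] <- cbind(-0.8 * s - 0.4 * spread,
                            3.5 * s - 0.5 * crouch + 0.8 * swing * s, 0.5 * z_leg)
  fr[, "r_knee", ] <- cbind(+0.8 * s + 0.4 * spread,
                            3.5 * s - 0.5 * crouch + 0.8 * swing * s, 0.5 * z_leg)
  fr[, "l_ankle", ] <- cbind(-0.9 * s - 0.9 * spread,
                             (0.5 + 0.4 * wind) * s + y_lift, z_leg)
  fr[, "r_ankle", ] <- cbind(+0.9 * s + 0.9 * spread,
                             (0.5 + 0.4 * wind) * s + y_lift, z_leg)
  fr[, "l_toe", ] <- cbind(-1.0 * s - spread,
                           (0.1 + 0.5 * wind) * s + 1.1 * y_lift, 0.4 * s + 1.1 * z_leg)
  fr[, "r_toe", ] <- cbind(+1.0 * s + spread,
                           (0.1 + 0.5 * wind) * s + 1.1 * y_lift, 0.4 * s + 1.1 * z_leg)
  fr
}

new_plseq <- function(frames, frame_rate, deviation_deg, side) {
  structure(list(joints = dimnames(frames)[[2]], frames = frames,
                 frame_rate = frame_rate, deviation_deg = deviation_deg,
                 side = side),
            class = "plseq")
}

#' Generate a synthetic point-light kick
#'
#' Produces one point-light kicking sequence whose left/right direction signal
#' is carried by the late-phase trajectory of the kicking foot.  Leftward and
#' rightward kicks at a given deviation are exact mirror images about the
#' vertical midplane; the deviation is a rigid rotation about the depth (z)
#' axis through the skeleton's hip root.  The generator is fully
#' deterministic.
#'
#' Sign convention: positive stored `deviation_deg` means a rightward kick;
#' positive rotation angles rotate the figure clockwise as seen by the viewer,
#' so a positive deviation tips the upward follow-through of the foot to the
#' right in the image.
#'
#' @param side `"left"` or `"right"`.
#' @param deviation_deg unsigned deviation angle in degrees; values above 20
#'   are outside the validated range and raise a warning.
#' @param config a [stimulus_config()].
#' @return an object of class `plseq` with fields `joints`, `frames`
#'   (`n_frames x n_joints x 3`), `frame_rate`, `deviation_deg` (signed,
#'   positive = rightward) and `side`.
#' @examples
#' seq <- generate_kick("right", 8)
#' dim(seq$frames)
#' @export
generate_kick <- function(side = c("right", "left"), deviation_deg = 0,
                          config = stimulus_config()) {
  side <- match.arg(side)
  if (!is.finite(deviation_deg)) stop("deviation_deg must be finite")
  if (deviation_deg < 0) stop("deviation_deg is unsigned; use `side` for direction")
  if (deviation_deg > 20)
    warning("deviation above 20 degrees is outside the validated range")
  base <- new_plseq(.base_kick_frames(config), config$frame_rate, 0, "right")
  out <- rotate_z(base, deviation_deg)
  if (side == "left") out <- mirror_x(out)
  out
}

#' Rotate a point-light sequence about the depth axis
#'
#' Rigid rotation of every joint in every frame about the z (depth) axis
#' through the skeleton's hip root.  Positive angles rotate clockwise in the
#' image (viewer's perspective), matching the sign convention under which a
#' positive deviation is a rightward kick.  The stored `deviation_deg` is
#' incremented by `angle_deg`.
#'
#' @param seq a `plseq`.
#' @param angle_deg signed rotation angle in degrees.
#' @export
rotate_z <- function(seq, angle_deg) {
  stopifnot(inherits(seq, "plseq"))
  if (!is.finite(angle_deg)) stop("angle_deg must be finite")
  th <- angle_deg * pi / 180
  root <- seq$frames[1, "hip", c("x", "y")]
  x <- seq$frames[, , "x"] - root[1]
  y <- seq$frames[, , "y"] - root[2]
  # clockwise in the image for positive angle
  seq$frames[, , "x"] <- root[1] + cos(th) * x + sin(th) * y
  seq$frames[, , "y"] <- root[2] - sin(th) * x + cos(th) * y
  seq$deviation_deg <- seq$deviation_deg + angle_deg
  seq
}

#' Mirror a sequence about the vertical midplane
#'
#' Negates the x coordinate of every joint (anatomical labels are kept, so the
#' mirrored kicker uses the other leg).  The stored deviation and side flip
#' sign accordingly.
#'
#' @param seq a `plseq`.
#' @export
mirror_x <- function(seq) {
  stopifnot(inherits(seq, "plseq"))
  seq$frames[, , "x"] <- -seq$frames[, , "x"]
  seq$deviation_deg <- -seq$deviation_deg
  seq$side <- if (identical(seq$side, "right")) "left" else "right"
  seq
}

#' Rendering configuration
#'
#' @param px_per_deg pixels per degree of visual angle (default 8).
#' @param width_deg,height_deg rendered field of view in degrees.
#' @param center_deg x/y world coordinates mapped to the image centre.
#' @param point_sigma_px Gaussian blob radius (standard deviation) in pixels.
#' @export
render_config <- function(px_per_deg = 8, width_deg = 10 + 1 / 3,
                          height_deg = 12, center_deg = c(0, 6),
                          point_sigma_px = 1.2) {
  stopifnot(px_per_deg > 0, width_deg > 0, height_deg > 0, point_sigma_px > 0)
  structure(list(px_per_deg = px_per_deg, width_deg = width_deg,
                 height_deg = height_deg, center_deg = center_deg,
                 point_sigma_px = point_sigma_px),
            class = "render_config")
}

#' Render a point-light sequence to an intensity frame stack
#'
#' Orthographic projection (z is dropped) of each joint as a Gaussian blob of
#' bright intensity on a dark background.  Row 1 of each image is the top of
#' the field of view; world y increases upward, so the row index carries the
#' sign flip (documented once here; all world-space code is y-up).
#'
#' @param seq a `plseq`.
#' @param config a [render_config()].
#' @return list of class `frame_stack`: `frames` (array
#'   `n_frames x height_px x width_px`, intensities in `[0, 1]`),
#'   `px_per_deg`, and the world extent of the image.
#' @export
render_frames <- function(seq, config = render_config()) {
  stopifnot(inherits(seq, "plseq"))
  w <- max(2L, round(config$width_deg * config$px_per_deg))
  h <- max(2L, round(config$height_deg * config$px_per_deg))
  nf <- dim(seq$frames)[1]
  out <- array(0, dim = c(nf, h, w))
  sig <- config$point_sigma_px
  # pixel centre world coordinates
  px_x <- config$center_deg[1] + (seq_len(w) - (w + 1) / 2) / config$px_per_deg
  px_y <- config$center_deg[2] + ((h + 1) / 2 - seq_len(h)) / config$px_per_deg
  clipped <- FALSE
  for (f in seq_len(nf)) {
    img <- matrix(0, h, w)
    for (j in seq_along(seq$joints)) {
      cx <- (seq$frames[f, j, "x"] - config$center_deg[1]) * config$px_per_deg + (w + 1) / 2
      cy <- (h + 1) / 2 - (seq$frames[f, j, "y"] - config$center_deg[2]) * config$px_per_deg
      if (cx < 1 || cx > w || cy < 1 || cy > h) clipped <- TRUE
      dx2 <- (seq_len(w) - cx)^2
      dy2 <- (seq_len(h) - cy)^2
      blob <- exp(-outer(dy2, dx2, "+") / (2 * sig^2))
      img <- pmax(img, blob)
    }
    out[f, , ] <- img
  }
  if (clipped) warning("some joints project outside the frame and were clipped")
  structure(list(frames = out, px_per_deg = config$px_per_deg,
                 world_x = px_x, world_y = px_y),
            class = "frame_stack")
}

#' Build a randomized stimulus set for the forced-choice protocol
#'
#' @param angles unsigned deviation angles in degrees.
#' @param sides subset of `c("left", "right")`.
#' @param reps repetitions per (side, angle) cell.
#' @param config a [stimulus_config()].
#' @param seed integer seed governing the randomized presentation order.
#' @return a list of `plseq` objects of length
#'   `length(angles) * length(sides) * reps`, in randomized order.
#' @export
make_stimulus_set <- function(angles, sides = c("left", "right"), reps = 1L,
                              config = stimulus_config(), seed = 1L) {
  stopifnot(length(angles) > 0, length(sides) > 0, reps >= 1)
  cells <- expand.grid(angle = angles, side = sides,
                       rep = seq_len(reps), stringsAsFactors = FALSE)
  ord <- withr_seed_sample(nrow(cells), seed)
  cells <- cells[ord, , drop = FALSE]
  # one prototype per (side, angle); the generator is deterministic
  proto <- list()
  lapply(seq_len(nrow(cells)), function(i) {
    key <- paste(cells$side[i], cells$angle[i])
    if (is.null(proto[[key]]))
      proto[[key]] <<- generate_kick(cells$side[i], cells$angle[i], config)
    proto[[key]]
  })
}

# sample a permutation under a local seed without disturbing the global RNG
withr_seed_sample <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(n)
}

#' @export
print.plseq <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Point-light sequence: %d frames x %d joints, %.1f fps (%.2f s)\n",
              d[1], d[2], x$frame_rate, d[1] / x$frame_rate))
  cat(sprintf("  side: %s, deviation: %+.2f deg\n", x$side, x$deviation_deg))
  invisible(x)
}

#' @export
as.data.frame.plseq <- function(x, ...) {
  d <- dim(x$frames)
  data.frame(frame = rep(seq_len(d[1]), d[2]),
             joint = rep(x$joints, each = d[1]),
             x = as.vector(x$frames[, , "x"]),
             y = as.vector(x$frames[, , "y"]),
             z = as.vector(x$frames[, , "z"]))
}

#' @export
plot.plseq <- function(x, frames = NULL, ...) {
  if (is.null(frames)) frames <- unique(round(seq(1, dim(x$frames)[1], length.out = 6)))
  xs <- x$frames[frames, , "x"]; ys <- x$frames[frames, , "y"]
  graphics::plot(range(xs), range(ys), type = "n", asp = 1,
                 xlab = "x (deg)", ylab = "y (deg)",
                 main = sprintf("%s kick, %+.1f deg", x$side, x$deviation_deg))
  cols <- grDevices::hcl.colors(length(frames), "viridis")
  for (i in seq_along(frames)) graphics::points(xs[i, ], ys[i, ], pch = 16, col = cols[i])
  invisible(x)
}

#' Write / read a point-light sequence as CSV
#'
#' Long format with columns `frame, joint, x, y, z`; frame rate, side and
#' deviation are stored in `#`-prefixed header comments.
#'
#' @param seq a `plseq`.
#' @param path file path.
#' @export
write_sequence_csv <- function(seq, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# frame_rate: %g", seq$frame_rate),
               sprintf("# deviation_deg: %g", seq$deviation_deg),
               sprintf("# side: %s", seq$side)), con)
  utils::write.table(as.data.frame(seq), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_sequence_csv
#' @param path file path.
#' @export
read_sequence_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  getv <- function(key) sub(sprintf("^# %s: *", key), "", hdr[grepl(key, hdr)][1])
  df <- utils::read.csv(path, comment.char = "#")
  joints <- unique(df$joint)
  nf <- max(df$frame)
  fr <- array(NA_real_, dim = c(nf, length(joints), 3L),
              dimnames = list(NULL, joints, c("x", "y", "z")))
  for (j in seq_along(joints)) {
    sub <- df[df$joint == joints[j], ]
    sub <- sub[order(sub$frame), ]
    fr[, j, ] <- as.matrix(sub[, c("x", "y", "z")])
  }
  new_plseq(fr, as.numeric(getv("frame_rate")),
            as.numeric(getv("deviation_deg")), getv("side"))
}
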