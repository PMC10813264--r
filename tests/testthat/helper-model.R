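# Shared fixtures.  The calibrated model is expensive (trains templates on 28
# synthetic kicks and runs three calibration probes), so it is built once per
# test run and reused; everything it contains is deterministic.

.fixture_env <- new.env(parent = emptyenv())

shared_model <- function() {
  if (is.null(.fixture_env$model)) .fixture_env$model <- bm_model()
  .fixture_env$model
}

# small synthetic feature sets for template tests: two well-separated classes
# with the window structure of the real pipeline
synthetic_features <- function(n_per_class = 4, n_pairs = 89, D = 12,
                               sep = 3, noise = 0.1, seed = 42) {
  set.seed(seed)
  base_r <- matrix(stats::runif(n_pairs * D), n_pairs, D)
  base_l <- base_r + sep / sqrt(D)
  feats <- list(); dirs <- character(0)
  for (i in seq_len(n_per_class)) {
    feats[[length(feats) + 1]] <- abs(base_r + matrix(stats::rnorm(n_pairs * D, 0, noise), n_pairs, D))
    dirs <- c(dirs, "right")
    feats[[length(feats) + 1]] <- abs(base_l + matrix(stats::rnorm(n_pairs * D, 0, noise), n_pairs, D))
    dirs <- c(dirs, "left")
  }
  list(features = feats, directions = dirs)
}

# hand-built point-light sequence (bypasses the kick generator)
manual_plseq <- function(frames, frame_rate = 20, deviation = 0,
                         side = "right") {
  structure(list(joints = dimnames(frames)[[2]], frames = frames,
                 frame_rate = frame_rate, deviation_deg = deviation,
                 side = side),
            class = "plseq")
}

# uniform dense flow field covering a grid, in world units (deg/frame)
uniform_dense_flow <- function(vx, vy, grid, px_per_deg = 4) {
  h <- round(2 * max(abs(grid$cy - mean(grid$cy)) + grid$half_y) * px_per_deg) + 8
  w <- round(2 * max(abs(grid$cx - mean(grid$cx)) + grid$half_x) * px_per_deg) + 8
  structure(list(type = "dense",
                 vx = matrix(vx, h, w), vy = matrix(vy, h, w),
                 px_per_deg = px_per_deg),
            class = "flow_field")
}
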