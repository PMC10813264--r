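test_that("the default grid instantiates 1116 ordered receptive fields", {
  g <- motion_grid()
  expect_equal(g$n_fields, 1116L)
  expect_equal(c(g$rows, g$cols), c(36L, 31L))
  expect_true(all(diff(g$cx) > 0))
  expect_true(all(diff(g$cy) > 0))
  expect_equal(2 * g$half_x, 0.4, tolerance = 1e-12)
  # zero overlap partitions the area exactly: field size equals the pitch
  g0 <- motion_grid(overlap = 0)
  expect_equal(2 * g0$half_x, diff(g0$cx)[1], tolerance = 1e-12)
  expect_equal(2 * g0$half_y, diff(g0$cy)[1], tolerance = 1e-12)
})

test_that("dense Lucas-Kanade recovers a global translation", {
  set.seed(1)
  base <- matrix(0, 48, 48)
  for (i in 1:12) {
    cx <- runif(1, 10, 38); cy <- runif(1, 10, 38)
    base <- pmax(base, exp(-(outer((1:48 - cy)^2, (1:48 - cx)^2, "+")) / 8))
  }
  shifted <- cbind(base[, 1], base[, -48])   # 1 px rightward
  fl <- compute_flow(base, shifted, px_per_deg = 1)
  sel <- base > 0.2                           # where there is texture
  expect_equal(stats::median(fl$vx[sel]), 1, tolerance = 0.1)
  expect_equal(stats::median(abs(fl$vy[sel])), 0, tolerance = 0.1)
  # identical frames give zero flow
  f0 <- compute_flow(base, base, px_per_deg = 1)
  expect_true(all(abs(f0$vx) < 1e-9) && all(abs(f0$vy) < 1e-9))
  expect_error(compute_flow(base, base[1:10, 1:10]), "differ")
})

test_that("exact flow reproduces known joint displacements", {
  fr <- array(0, dim = c(3, 2, 3),
              dimnames = list(NULL, c("a", "b"), c("x", "y", "z")))
  fr[, "a", "x"] <- c(0, 0.3, 0.6); fr[, "a", "y"] <- 5
  fr[, "b", "y"] <- c(8, 7.8, 7.6)
  fl <- flow_exact(manual_plseq(fr), 2)
  expect_equal(unname(fl$vx), c(0.3, 0))
  expect_equal(unname(fl$vy), c(0, -0.2))
})

test_that("local responses rectify the mean flow onto four channels", {
  g <- motion_grid(rows = 8, cols = 8, width_deg = 4, height_deg = 4,
                   center_deg = c(0, 0))
  zero <- local_response(uniform_dense_flow(0, 0, g), g)
  expect_true(all(zero == 0))

  v <- 0.7
  right <- local_response(uniform_dense_flow(v, 0, g), g)
  expect_equal(max(abs(right[, , "right"] - v)), 0, tolerance = 1e-9)
  expect_true(all(right[, , c("left", "up", "down")] == 0))

  diag <- local_response(uniform_dense_flow(v, v, g), g)
  expect_equal(max(abs(diag[, , "right"] - v)), 0, tolerance = 1e-9)
  expect_equal(max(abs(diag[, , "up"] - v)), 0, tolerance = 1e-9)
  expect_true(all(diag[, , c("left", "down")] == 0))
})

test_that("responses are linear in flow magnitude and opposite-exclusive", {
  g <- motion_grid(rows = 6, cols = 5, width_deg = 3, height_deg = 3,
                   center_deg = c(0, 0))
  set.seed(7)
  for (i in 1:5) {
    vx <- runif(1, -1, 1); vy <- runif(1, -1, 1); c0 <- runif(1, 0, 3)
    m1 <- local_response(uniform_dense_flow(vx, vy, g), g)
    m2 <- local_response(uniform_dense_flow(c0 * vx, c0 * vy, g), g)
    expect_equal(unclass(m2), unclass(m1) * c0, tolerance = 1e-9)
    expect_true(all(m1[, , "right"] * m1[, , "left"] == 0))
    expect_true(all(m1[, , "up"] * m1[, , "down"] == 0))
  }
})

test_that("rotating the flow vectors by 90 degrees permutes the channels", {
  g <- motion_grid(rows = 6, cols = 6, width_deg = 3, height_deg = 3,
                   center_deg = c(0, 0))
  vx <- 0.4; vy <- -0.2
  m <- local_response(uniform_dense_flow(vx, vy, g), g)
  mr <- local_response(uniform_dense_flow(-vy, vx, g), g)  # +90 deg (ccw)
  # right -> up -> left -> down -> right
  expect_equal(mr[, , "up"], m[, , "right"])
  expect_equal(mr[, , "left"], m[, , "up"])
  expect_equal(mr[, , "down"], m[, , "left"])
  expect_equal(mr[, , "right"], m[, , "down"])
})

test_that("joint-mode grid pooling averages joints sharing a field", {
  g <- motion_grid(rows = 4, cols = 4, width_deg = 4, height_deg = 4,
                   center_deg = c(0, 0), overlap = 0)
  fl <- structure(list(type = "joint", px = c(-1.5, -1.4, 1.5),
                       py = c(-1.5, -1.5, 1.5),
                       vx = c(0.2, 0.4, -0.3), vy = c(0, 0, 0)),
                  class = "flow_field")
  m <- local_response(fl, g)
  expect_equal(as.numeric(m[1, 1, "right"]), 0.3)   # mean of the two co-located joints
  expect_equal(as.numeric(m[4, 4, "left"]), 0.3)
  expect_equal(sum(m > 0), 2)
})
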