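test_that("detector counts match the stated configurations", {
  g <- motion_grid()
  lay <- opponent_layout(g)
  expect_equal(lay$n_detectors, 100L)
  expect_equal(sum(lay$kinds %in% c("cw", "ccw")), 20L)
  expect_equal(opponent_layout(g, rotation = FALSE)$n_detectors, 80L)
  expect_equal(opponent_layout(g, n_rotation = 40L)$n_detectors, 120L)
  expect_equal(sum(opponent_layout(g, n_rotation = 40L)$kinds == "cw"), 20L)
  # 5 x 4 assembly per expansion/contraction kind
  for (kd in c("h_expand", "h_contract", "v_expand", "v_contract"))
    expect_equal(sum(lay$kinds == kd), 20L)
  expect_error(opponent_layout(g, n_rotation = 30L), "20 or 40")
})

test_that("every subfield is non-empty and within the grid", {
  g <- motion_grid()
  lay <- opponent_layout(g)
  for (d in lay$detectors) {
    for (sf in d$subfields) {
      expect_gt(length(sf), 0)
      expect_true(all(sf >= 1 & sf <= g$n_fields))
    }
    if (d$kind %in% c("cw", "ccw")) expect_length(d$subfields, 4L)
    else expect_length(d$subfields, 2L)
  }
})

test_that("the first 80 components are unchanged by enabling rotation", {
  g <- motion_grid()
  lay_on <- opponent_layout(g)
  lay_off <- opponent_layout(g, rotation = FALSE)
  set.seed(2)
  maps <- array(runif(g$rows * g$cols * 4), dim = c(g$rows, g$cols, 4),
                dimnames = list(NULL, NULL, c("right", "left", "up", "down")))
  # enforce opposite-channel exclusivity as the lower level guarantees it
  keep <- maps[, , "right"] >= maps[, , "left"]
  maps[, , "right"][!keep] <- 0; maps[, , "left"][keep] <- 0
  keepv <- maps[, , "up"] >= maps[, , "down"]
  maps[, , "up"][!keepv] <- 0; maps[, , "down"][keepv] <- 0
  f_on <- opponent_response(maps, lay_on)
  f_off <- opponent_response(maps, lay_off)
  expect_equal(f_on[seq_len(80)], f_off)
  expect_length(f_on, 100)
  expect_true(all(f_on >= 0))
  expect_true(all(opponent_response(maps * 0, lay_on) == 0))
})

test_that("opposed subfield motion drives expansion, not contraction", {
  g <- motion_grid()
  lay <- opponent_layout(g)
  d1 <- which(lay$kinds == "h_expand")[7]      # an interior detector
  det <- lay$detectors[[d1]]
  maps <- array(0, dim = c(g$rows, g$cols, 4))
  left_ch <- matrix(0, g$rows, g$cols); right_ch <- left_ch
  left_ch[det$subfields$a] <- 0.5              # left half moves leftward
  right_ch[det$subfields$b] <- 0.5             # right half moves rightward
  maps[, , 1] <- right_ch; maps[, , 2] <- left_ch
  feats <- opponent_response(maps, lay)
  expect_gt(feats[d1], 0)
  expect_true(all(feats[lay$kinds == "h_contract"] == 0))
})

test_that("rotation conditions follow the two-trigger rule", {
  sub0 <- matrix(0, 4, 4)
  # uniform rightward motion: no opponency, neither sense responds
  subr <- sub0; subr[, 1] <- 1
  expect_equal(rotation_condition(subr, "cw"), 0)
  expect_equal(rotation_condition(subr, "ccw"), 0)
  # condition A (cw): upper subfields rightward, lower subfields leftward
  subA <- sub0; subA[1:2, 1] <- c(0.8, 0.3); subA[3:4, 2] <- c(0.2, 0.6)
  expect_equal(rotation_condition(subA, "cw"), min(0.8, 0.6))
  expect_equal(rotation_condition(subA, "ccw"), 0)
  # condition B (cw): left subfields up, right subfields down
  subB <- sub0; subB[c(1, 3), 3] <- 0.5; subB[c(2, 4), 4] <- 0.4
  expect_equal(rotation_condition(subB, "cw"), 0.4)
  # disjunction across conditions takes the max
  both <- pmax(subA, subB)
  expect_equal(rotation_condition(both, "cw"), max(min(0.8, 0.6), 0.4))
  # product conjunction is available
  expect_equal(rotation_condition(subA, "cw", conjunction = "product"),
               0.8 * 0.6)
})

test_that("analytic rigid rotation activates only the matching sense", {
  g <- motion_grid()
  lay <- opponent_layout(g)
  cw_ids <- which(lay$kinds == "cw")
  det <- lay$detectors[[cw_ids[5]]]
  cells <- sort(unique(unlist(det$subfields)))
  rr <- ((cells - 1) %% g$rows) + 1
  cc <- ((cells - 1) %/% g$rows) + 1
  # rotation centred exactly on the detector centre
  x0 <- g$cx[1] + (det$center[2] - 1) * diff(g$cx)[1]
  y0 <- g$cy[1] + (det$center[1] - 1) * diff(g$cy)[1]
  # clockwise field (y up): v = (omega * (y - y0), -omega * (x - x0))
  omega <- 0.3
  maps <- array(0, dim = c(g$rows, g$cols, 4))
  for (i in seq_along(cells)) {
    vx <- omega * (g$cy[rr[i]] - y0)
    vy <- -omega * (g$cx[cc[i]] - x0)
    maps[rr[i], cc[i], ] <- c(max(vx, 0), max(-vx, 0), max(vy, 0), max(-vy, 0))
  }
  feats <- opponent_response(maps, lay)
  expect_gt(feats[cw_ids[5]], 0)
  # the ccw detector at the same position is exactly silent
  ccw_same <- which(lay$kinds == "ccw")[5]
  expect_equal(feats[ccw_same], 0)
  expect_gt(max(feats[lay$kinds == "cw"]), 4 * max(feats[lay$kinds == "ccw"]))
})

test_that("x-mirroring permutes the features and swaps cw with ccw", {
  g <- motion_grid()
  lay <- opponent_layout(g)
  p <- mirror_permutation(lay)
  expect_true(all(sort(p) == seq_len(lay$n_detectors)))
  expect_true(all(lay$kinds[p[lay$kinds == "cw"]] == "ccw"))

  set.seed(5)
  maps <- array(runif(g$rows * g$cols * 4, 0, 0.5),
                dim = c(g$rows, g$cols, 4))
  keep <- maps[, , 1] >= maps[, , 2]
  maps[, , 1][!keep] <- 0; maps[, , 2][keep] <- 0
  keepv <- maps[, , 3] >= maps[, , 4]
  maps[, , 3][!keepv] <- 0; maps[, , 4][keepv] <- 0
  # mirror: reverse columns, swap the left and right channels
  mir <- maps[, rev(seq_len(g$cols)), ]
  tmp <- mir[, , 1]; mir[, , 1] <- mir[, , 2]; mir[, , 2] <- tmp
  f <- opponent_response(maps, lay)
  fm <- opponent_response(mir, lay)
  expect_equal(fm, f[p], tolerance = 1e-12)
})

test_that("max-pooling ignores sub-maximal perturbations within a subfield", {
  g <- motion_grid()
  lay <- opponent_layout(g)
  d1 <- which(lay$kinds == "v_expand")[3]
  det <- lay$detectors[[d1]]
  maps <- array(0, dim = c(g$rows, g$cols, 4))
  up_ch <- matrix(0, g$rows, g$cols); dn_ch <- up_ch
  up_ch[det$subfields$a] <- 0.9
  dn_ch[det$subfields$b] <- 0.7
  maps[, , 3] <- up_ch; maps[, , 4] <- dn_ch
  base <- opponent_response(maps, lay)[d1]
  # raising one cell below the subfield maximum changes nothing
  maps2 <- maps
  maps2[, , 3][det$subfields$a[1]] <- 0.5
  expect_equal(opponent_response(maps2, lay)[d1], base)
})

test_that("whole-sequence features have the documented shape", {
  lay <- opponent_layout(motion_grid())
  f <- sequence_features(generate_kick("right", 10), lay)
  expect_equal(dim(f), c(89L, 100L))
  expect_true(all(f >= 0))
})
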