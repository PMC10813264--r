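#' Opponent-motion detector layout
#'
#' Builds the second-level detector bank: horizontal/vertical expansion and
#' contraction detectors (a 5 x 4 assembly of each of the four kinds, 80
#' detectors) plus clockwise and counterclockwise rotation detectors.  With
#' the default `n_rotation = 20` (10 per sense) the bank totals 100 detectors;
#' `n_rotation = 40` instantiates a full 5 x 4 assembly per sense instead.
#'
#' Expansion/contraction detectors pool two opposed subfields (left/right
#' halves of the receptive field for the horizontal kinds, upper/lower for the
#' vertical ones).  Rotation detectors pool four contiguous quadrant
#' subfields (upper-left, upper-right, lower-left, lower-right), each
#' roughly a 4 x 5 block of grid cells; quadrants of neighbouring detectors
#' overlap.  All placements are symmetric
#' under reflection about the grid's vertical midline, so mirroring a stimulus
#' permutes detectors within kind and swaps cw with ccw exactly.
#'
#' @param grid a [motion_grid()].
#' @param rotation logical; include rotation detectors (default `TRUE`).
#' @param n_rotation total rotation detectors when enabled: 20 or 40.
#' @param conjunction how opposed subfield signals are combined: `"min"`
#'   (soft AND, default) or `"product"`.
#' @return object of class `opponent_layout`; one descriptor per detector
#'   with kind, assembly position, and subfield cell-index sets (linear
#'   indices into the `rows x cols` grid, column-major).
#' @export
opponent_layout <- function(grid = motion_grid(), rotation = TRUE,
                            n_rotation = 20L, conjunction = c("min", "product")) {
  conjunction <- match.arg(conjunction)
  if (rotation && !n_rotation %in% c(20L, 40L))
    stop("n_rotation must be 20 or 40")
  nr <- grid$rows; nc <- grid$cols
  # assembly centres, symmetric about the grid midlines
  rc5 <- (nr + 1) / 2 + (-2:2) * nr / 5
  cc4 <- (nc + 1) / 2 + c(-1.5, -0.5, 0.5, 1.5) * nc / 4
  cc2 <- (nc + 1) / 2 + c(-1, 1) * nc / 6

  rf_cells <- function(r0, c0, rh, ch) {
    rs <- which(abs(seq_len(nr) - r0) <= rh)
    cs <- which(abs(seq_len(nc) - c0) <= ch)
    list(rs = rs, cs = cs)
  }
  lin <- function(rs, cs) as.vector(outer(rs, (cs - 1) * nr, "+"))

  det <- list()
  add <- function(kind, arow, acol, center, subfields) {
    if (any(!vapply(subfields, length, 1L))) stop("empty subfield")
    det[[length(det) + 1]] <<- list(kind = kind, arow = arow, acol = acol,
                                    center = center, subfields = subfields)
  }

  rh <- nr / 8; ch <- nc / 7    # RF half-extents (cells); neighbours overlap
  for (kind in c("h_expand", "h_contract", "v_expand", "v_contract")) {
    for (i in seq_along(rc5)) for (j in seq_along(cc4)) {
      f <- rf_cells(rc5[i], cc4[j], rh, ch)
      if (!length(f$rs) || !length(f$cs))
        stop("assembly exceeds grid bounds")
      if (startsWith(kind, "h")) {
        sf <- list(a = lin(f$rs, f$cs[f$cs <= cc4[j]]),
                   b = lin(f$rs, f$cs[f$cs >= cc4[j]]))   # a = left, b = right
      } else {
        sf <- list(a = lin(f$rs[f$rs >= rc5[i]], f$cs),
                   b = lin(f$rs[f$rs <= rc5[i]], f$cs))   # a = upper, b = lower
      }
      add(kind, i, j, c(rc5[i], cc4[j]), sf)
    }
  }
  if (rotation) {
    ccr <- if (n_rotation == 20L) cc2 else cc4
    rrh <- nr / 9; rch <- nc / 6  # quadrants come out near 4 x 5 cells
    for (kind in c("cw", "ccw")) {
      for (i in seq_along(rc5)) for (j in seq_along(ccr)) {
        # fractional centres split the quadrants cleanly; each quadrant is a
        # contiguous block of about 4 x 5 cells, and the quadrant blocks of
        # neighbouring detectors overlap
        r0 <- rc5[i]; c0 <- ccr[j]
        up <- which(seq_len(nr) > r0 & seq_len(nr) <= r0 + rrh)
        lo <- which(seq_len(nr) < r0 & seq_len(nr) >= r0 - rrh)
        le <- which(seq_len(nc) < c0 & seq_len(nc) >= c0 - rch)
        ri <- which(seq_len(nc) > c0 & seq_len(nc) <= c0 + rch)
        add(kind, i, j, c(r0, c0), list(ul = lin(up, le), ur = lin(up, ri),
                                        ll = lin(lo, le), lr = lin(lo, ri)))
      }
    }
  }
  kinds <- vapply(det, `[[`, "", "kind")
  structure(list(detectors = det, kinds = kinds, rotation = rotation,
                 n_detectors = length(det), grid = grid,
                 conjunction = conjunction),
            class = "opponent_layout")
}

#' @export
print.opponent_layout <- function(x, ...) {
  cat(sprintf("Opponent-motion layout: %d detectors (%s)\n", x$n_detectors,
              paste(sprintf("%s: %d", names(table(x$kinds)), table(x$kinds)),
                    collapse = ", ")))
  invisible(x)
}

conj2 <- function(a, b, how) if (how == "min") min(a, b) else a * b

#' Rotation-detector trigger conditions
#'
#' A rotation can only be signalled by the four-direction lower level under
#' two flow configurations; either triggers the detector.  For a clockwise
#' detector (world y-up): (A) the upper subfields move rightward while the
#' lower ones move leftward, or (B) the left subfields move upward while the
#' right ones move downward.  Counterclockwise mirrors the directions.  The
#' activation is conjunctive within a condition (default `min`) and
#' disjunctive (`max`) across the two conditions.
#'
#' @param sub a 4 x 4 matrix of subfield direction signals; rows `ul, ur, ll,
#'   lr`, columns `right, left, up, down`.
#' @param sense `"cw"` or `"ccw"`.
#' @param conjunction `"min"` or `"product"`.
#' @export
rotation_condition <- function(sub, sense = c("cw", "ccw"),
                               conjunction = "min") {
  sense <- match.arg(sense)
  stopifnot(is.matrix(sub), all(sub >= 0))
  rownames(sub) <- c("ul", "ur", "ll", "lr")
  colnames(sub) <- direction_labels()
  if (sense == "cw") {
    a <- conj2(max(sub["ul", "right"], sub["ur", "right"]),
               max(sub["ll", "left"], sub["lr", "left"]), conjunction)
    b <- conj2(max(sub["ul", "up"], sub["ll", "up"]),
               max(sub["ur", "down"], sub["lr", "down"]), conjunction)
  } else {
    a <- conj2(max(sub["ul", "left"], sub["ur", "left"]),
               max(sub["ll", "right"], sub["lr", "right"]), conjunction)
    b <- conj2(max(sub["ul", "down"], sub["ll", "down"]),
               max(sub["ur", "up"], sub["lr", "up"]), conjunction)
  }
  max(a, b)
}

#' Opponent-motion feature vector for one frame pair
#'
#' Each subfield's signal is the maximum of the relevant direction channel
#' over its cells (max-pooling confers positional invariance inside the
#' receptive field); a detector combines its subfield signals according to its
#' opponency rule.
#'
#' @param maps a `direction_maps` array from [local_response()].
#' @param layout an [opponent_layout()].
#' @return numeric vector of non-negative activations, one per detector,
#'   ordered by (kind, assembly row, assembly column).
#' @export
opponent_response <- function(maps, layout) {
  g <- layout$grid
  m <- matrix(maps, g$rows * g$cols, 4L)
  colnames(m) <- direction_labels()
  how <- layout$conjunction
  out <- numeric(layout$n_detectors)
  for (d in seq_len(layout$n_detectors)) {
    dd <- layout$detectors[[d]]
    sf <- dd$subfields
    out[d] <- switch(dd$kind,
      h_expand = conj2(max(m[sf$a, "left"]), max(m[sf$b, "right"]), how),
      h_contract = conj2(max(m[sf$a, "right"]), max(m[sf$b, "left"]), how),
      v_expand = conj2(max(m[sf$a, "up"]), max(m[sf$b, "down"]), how),
      v_contract = conj2(max(m[sf$a, "down"]), max(m[sf$b, "up"]), how),
      cw = ,
      ccw = {
        sub <- rbind(ul = c(max(m[sf$ul, 1]), max(m[sf$ul, 2]), max(m[sf$ul, 3]), max(m[sf$ul, 4])),
                     ur = c(max(m[sf$ur, 1]), max(m[sf$ur, 2]), max(m[sf$ur, 3]), max(m[sf$ur, 4])),
                     ll = c(max(m[sf$ll, 1]), max(m[sf$ll, 2]), max(m[sf$ll, 3]), max(m[sf$ll, 4])),
                     lr = c(max(m[sf$lr, 1]), max(m[sf$lr, 2]), max(m[sf$lr, 3]), max(m[sf$lr, 4])))
        rotation_condition(sub, dd$kind, how)
      })
  }
  out
}

#' Detector permutation induced by mirroring the stimulus
#'
#' Horizontal reflection of the stimulus maps each detector onto the detector
#' of the mirror-equivalent kind (cw and ccw swap; the other kinds map onto
#' themselves) at the column-mirrored assembly position.  Returns the index
#' permutation `p` such that `features(mirrored stimulus) =
#' features(stimulus)[p]`.
#'
#' @param layout an [opponent_layout()].
#' @export
mirror_permutation <- function(layout) {
  kinds <- layout$kinds
  arow <- vapply(layout$detectors, `[[`, 1, "arow")
  acol <- vapply(layout$detectors, `[[`, 1, "acol")
  swap <- c(h_expand = "h_expand", h_contract = "h_contract",
            v_expand = "v_expand", v_contract = "v_contract",
            cw = "ccw", ccw = "cw")
  ncols_of <- ave(acol, kinds, FUN = max)
  target_kind <- swap[kinds]
  target_col <- ncols_of - acol + 1
  p <- integer(layout$n_detectors)
  for (d in seq_len(layout$n_detectors)) {
    hit <- which(kinds == target_kind[d] & arow == arow[d] &
                   acol == target_col[d])
    if (length(hit) != 1) stop("layout is not mirror-symmetric")
    p[d] <- hit
  }
  p
}

#' Opponent-motion features for a whole sequence
#'
#' Convenience wrapper: ground-truth flow, grid pooling, and opponent
#' responses for every consecutive frame pair.
#'
#' @param seq a `plseq`.
#' @param layout an [opponent_layout()].
#' @return matrix `n_pairs x n_detectors`; row `p` corresponds to the flow
#'   from frame `p` to `p + 1`.
#' @export
sequence_features <- function(seq, layout) {
  maps <- sequence_direction_maps(seq, layout$grid)
  t(vapply(maps, opponent_response, numeric(layout$n_detectors),
           layout = layout))
}
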