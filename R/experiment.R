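#' Default forced-choice protocol
#'
#' 2AFC direction judgements at deviations of 2, 4, 8 and 15 degrees for
#' each side, 120 trials per (side, angle) cell: 960 trials per block.
#'
#' @param angles unsigned deviation angles.
#' @param sides stimulus sides.
#' @param reps trials per cell.
#' @export
default_protocol <- function(angles = c(2, 4, 8, 15),
                             sides = c("left", "right"), reps = 120L) {
  stopifnot(length(angles) > 0, length(sides) > 0, reps >= 1)
  list(angles = angles, sides = sides, reps = as.integer(reps))
}

#' Run one forced-choice block
#'
#' Simulates a full block of the 2AFC protocol: for every trial the stimulus
#' is generated, passed through flow, opponent features, template evidence
#' and the optic-flow-pattern dynamics (all deterministic and cached per
#' condition), and the noisy outputs race through the decision stage to a
#' choice and reaction time.  Trial order is randomized under the seed.
#'
#' @param model a calibrated [bm_model()].
#' @param params observer parameters: list with any of `delta`, `tau`, `k`,
#'   `tau_a` (missing entries fall back to the model's decision defaults).
#' @param protocol a [default_protocol()].
#' @param seed integer seed for trial order and internal noise.
#' @return a response table: data frame with one row per trial
#'   (`trial`, `side`, `deviation_deg` signed, `choice`, `correct`, `rt`,
#'   `decided`) plus the parameters used as attributes.
#' @export
run_block <- function(model, params = list(), protocol = default_protocol(),
                      seed = 1L) {
  stopifnot(inherits(model, "bm_model"))
  if (is.null(model$calibration))
    stop("model is not calibrated; run calibrate_model() first")
  par <- do.call(within_params, c(list(model$decision), params))
  stopifnot(par$dt == model$ofp$dt)
  cells <- expand.grid(angle = protocol$angles, side = protocol$sides,
                       stringsAsFactors = FALSE)
  set.seed(seed)
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- model_cell(model, cells$side[i], cells$angle[i])
    n_steps <- nrow(cell$hbar) - 1
    own <- if (cells$side[i] == "right") "right" else "left"
    other <- setdiff(c("right", "left"), own)
    b <- run_decision_batch(cell$H[seq_len(n_steps), ], cell$idx[[own]],
                            cell$idx[[other]], par,
                            n_trials = protocol$reps)
    choice <- ifelse(b$winner == "T", own,
                     ifelse(b$winner == "D", other, NA))
    res[[i]] <- data.frame(
      side = cells$side[i],
      deviation_deg = ifelse(cells$side[i] == "right", 1, -1) * cells$angle[i],
      choice = choice,
      correct = ifelse(is.na(choice), NA, choice == cells$side[i]),
      rt = b$rt,
      decided = b$winner != "none")
  }
  tab <- do.call(rbind, res)
  ord <- sample.int(nrow(tab))
  tab <- tab[ord, ]
  tab$trial <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab <- tab[, c("trial", "side", "deviation_deg", "choice", "correct",
                 "rt", "decided")]
  attr(tab, "params") <- par[c("delta", "tau", "k", "tau_a")]
  attr(tab, "seed") <- seed
  tab
}

#' Observer summary over repeated blocks
#'
#' Runs `n_blocks` independent blocks, fits a psychometric function to each
#' and summarises the 75% threshold, slope and mean reaction time (decided
#' trials only; undecided trials are excluded and counted) as mean +/-
#' standard error across blocks.
#'
#' @param model a calibrated `bm_model`.
#' @param params observer parameters (see [run_block()]).
#' @param n_blocks number of blocks.
#' @param protocol a [default_protocol()].
#' @param seed base seed; block `b` uses `seed + b - 1`.
#' @param family psychometric family.
#' @return object of class `observer_summary`.
#' @export
summarize_observer <- function(model, params = list(), n_blocks = 2L,
                               protocol = default_protocol(), seed = 1L,
                               family = "logistic") {
  thr <- slp <- rts <- numeric(0)
  undecided <- 0L; total <- 0L; conv <- logical(0)
  for (b in seq_len(n_blocks)) {
    tab <- run_block(model, params, protocol, seed = seed + b - 1L)
    fit <- fit_psychometric(tab, family = family)
    conv <- c(conv, fit$converged)
    thr <- c(thr, fit$threshold75)
    slp <- c(slp, fit$slope)
    rts <- c(rts, mean(tab$rt[tab$decided], na.rm = TRUE))
    undecided <- undecided + sum(!tab$decided)
    total <- total + nrow(tab)
  }
  if (undecided == total) stop("all trials undecided")
  se <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  }
  structure(list(
    params = utils::modifyList(model$decision[c("delta", "tau", "k", "tau_a")],
                               params),
    threshold75 = mean(thr, na.rm = TRUE), threshold75_se = se(thr),
    slope = mean(slp, na.rm = TRUE), slope_se = se(slp),
    rt = mean(rts, na.rm = TRUE), rt_se = se(rts),
    n_blocks = n_blocks, converged = conv,
    undecided = undecided, total = total),
    class = "observer_summary")
}

#' @export
print.observer_summary <- function(x, ...) {
  p <- x$params
  cat(sprintf("Observer summary (delta=%g, tau=%g, k=%g, tau_a=%g; %d block%s):\n",
              p$delta, p$tau, p$k, p$tau_a, x$n_blocks,
              if (x$n_blocks > 1) "s" else ""))
  cat(sprintf("  threshold75: %.3f deg (se %s)\n", x$threshold75,
              format(x$threshold75_se, digits = 3)))
  cat(sprintf("  slope:       %.4f /deg (se %s)\n", x$slope,
              format(x$slope_se, digits = 3)))
  cat(sprintf("  mean rt:     %.3f s (se %s); undecided %d/%d\n", x$rt,
              format(x$rt_se, digits = 3), x$undecided, x$total))
  invisible(x)
}

#' Grid-search tuning of the four observer parameters
#'
#' Exhaustively evaluates a grid over (`delta`, `tau`, `k`, `tau_a`),
#' summarising each candidate with [summarize_observer()] and scoring it by
#' the weighted relative error against the target triple (threshold, slope,
#' mean reaction time).  Every candidate is evaluated under the same seeds,
#' so the leaderboard is invariant to grid row order.
#'
#' @param model a calibrated `bm_model`.
#' @param target named vector or list with `threshold75`, `slope`, `rt`.
#' @param grid data frame with columns `delta`, `tau`, `k`, `tau_a`.
#' @param weights relative-error weights for the three targets.
#' @param n_blocks,protocol,seed passed to [summarize_observer()].
#' @return list with `best` (parameter row), `best_summary`, and
#'   `leaderboard` (grid plus simulated values and loss, sorted by loss).
#' @export
grid_search <- function(model, target, grid, weights = c(1, 1, 1),
                        n_blocks = 1L, protocol = default_protocol(),
                        seed = 1L) {
  stopifnot(nrow(grid) > 0,
            all(c("delta", "tau", "k", "tau_a") %in% names(grid)))
  target <- as.list(target)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- summarize_observer(model,
                            params = as.list(grid[i, c("delta", "tau", "k", "tau_a")]),
                            n_blocks = n_blocks, protocol = protocol,
                            seed = seed)
    rel <- c(abs(s$threshold75 - target$threshold75) / target$threshold75,
             abs(s$slope - target$slope) / target$slope,
             abs(s$rt - target$rt) / target$rt)
    loss <- sum(weights * rel) / sum(weights)
    cbind(grid[i, c("delta", "tau", "k", "tau_a")],
          sim_threshold75 = s$threshold75, sim_slope = s$slope,
          sim_rt = s$rt, loss = if (is.finite(loss)) loss else Inf)
  })
  lb <- do.call(rbind, rows)
  lb <- lb[order(lb$loss, lb$delta, lb$tau, lb$k, lb$tau_a), ]
  rownames(lb) <- NULL
  best <- lb[1, ]
  list(best = best[, c("delta", "tau", "k", "tau_a")],
       best_summary = best, leaderboard = lb)
}
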