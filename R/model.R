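#' Build (and train) the biological-motion perception model
#'
#' Assembles the four-level hierarchy: stimulus generator, motion-energy
#' grid, opponent-motion layout, template bank (trained on synthetic kicks
#' over the training angle range, both sides), optic-flow-pattern dynamics
#' and decision stage defaults.  After training the model is calibrated (see
#' [calibrate_model()]); per-stimulus feature, evidence and latent
#' optic-flow-pattern trajectories are cached, since all levels below the
#' decision stage are deterministic and noise-free.
#'
#' @param stim_config a [stimulus_config()].
#' @param grid a [motion_grid()].
#' @param rotation include rotation detectors (default `TRUE`).
#' @param n_rotation 20 (default) or 40.
#' @param conjunction subfield conjunction rule, `"min"` or `"product"`.
#' @param train_angles unsigned training angles in degrees (default `7:20`,
#'   used for both sides).
#' @param lambda risk-aversion coefficient of the template match.
#' @param var_floor template variance floor (`NULL` = relative default).
#' @param ofp an [ofp_params()] (threshold and kernel are rescaled during
#'   calibration).
#' @param decision a [decision_params()] holding the fixed decision-stage
#'   constants; observer-level parameters are supplied per run.
#' @param calibrate run [calibrate_model()] (default `TRUE`).
#' @return object of class `bm_model`.
#' @export
bm_model <- function(stim_config = stimulus_config(), grid = motion_grid(),
                     rotation = TRUE, n_rotation = 20L,
                     conjunction = "min", train_angles = 7:20,
                     lambda = 0.1, var_floor = NULL,
                     ofp = ofp_params(), decision = decision_params(),
                     calibrate = TRUE) {
  layout <- opponent_layout(grid, rotation = rotation,
                            n_rotation = n_rotation,
                            conjunction = conjunction)
  train <- expand.grid(angle = train_angles, side = c("left", "right"),
                       stringsAsFactors = FALSE)
  feats <- lapply(seq_len(nrow(train)), function(i)
    sequence_features(generate_kick(train$side[i], train$angle[i], stim_config),
                      layout))
  bank <- fit_templates(feats, train$side, lambda = lambda,
                        var_floor = var_floor)
  m <- structure(list(stim_config = stim_config, grid = grid,
                      layout = layout, bank = bank, ofp = ofp,
                      decision = decision, train_angles = train_angles,
                      calibration = NULL, cache = new.env(parent = emptyenv())),
                 class = "bm_model")
  if (calibrate) m <- calibrate_model(m)
  m
}

#' @export
print.bm_model <- function(x, ...) {
  cat("Biological-motion perception model\n")
  cat(sprintf("  level 1: %d motion-energy fields (%d x %d)\n",
              x$grid$n_fields, x$grid$rows, x$grid$cols))
  cat(sprintf("  level 2: %d opponent-motion detectors (rotation %s)\n",
              x$layout$n_detectors,
              if (x$layout$rotation) "on" else "off"))
  cat(sprintf("  level 3: %d optic-flow-pattern neurons, tau = %g s\n",
              x$bank$n_windows * 2, x$ofp$tau))
  cat(sprintf("  level 4: 2 decision neurons, criterion = %.3g\n",
              x$decision$criterion))
  cat(sprintf("  trained on |angles| %s (both sides)%s\n",
              paste(range(x$train_angles), collapse = "-"),
              if (is.null(x$calibration)) " [uncalibrated]" else ""))
  invisible(x)
}

# cached deterministic pipeline products for one (side, angle) stimulus
model_cell <- function(model, side, angle) {
  key <- sprintf("%s:%g", side, angle)
  hit <- model$cache[[key]]
  if (!is.null(hit)) return(hit)
  seq <- generate_kick(side, angle, model$stim_config)
  feats <- sequence_features(seq, model$layout)
  G <- evidence_stream(feats, model$bank)
  run <- ofp_run(G, model$ofp, frame_rate = model$stim_config$frame_rate)
  nh <- model$bank$n_windows
  # noise-free per-direction drives: rectified outputs pooled per chain
  pool <- function(m) {
    if (model$decision$drive_pool == "max") Reduce(pmax, asplit(m, 2))
    else rowMeans(m)
  }
  hbar <- cbind(right = pool(pmax(run$H[, seq_len(nh), drop = FALSE], 0)),
                left = pool(pmax(run$H[, nh + seq_len(nh), drop = FALSE], 0)))
  out <- list(features = feats, G = G, times = run$times, H = run$H,
              hbar = hbar, idx = list(right = seq_len(nh),
                                      left = nh + seq_len(nh)))
  model$cache[[key]] <- out
  out
}

#' Deterministic pipeline products for one stimulus condition
#'
#' Returns the cached opponent-motion features, evidence stream and latent
#' optic-flow-pattern trajectories for a given side and unsigned angle.
#'
#' @param model a [bm_model()].
#' @param side `"left"` or `"right"`.
#' @param angle unsigned deviation (degrees).
#' @export
model_pipeline <- function(model, side, angle) model_cell(model, side, angle)

#' Calibrate the model's operating constants
#'
#' Three constants tie the hierarchy's stages together; all are fixed model
#' constants (not observer parameters) and are set by deterministic rules:
#'
#' * evidence scale: all evidence-unit quantities (template evidence, lateral
#'   kernel, threshold `theta_f`) are rescaled so that the mean left-right
#'   drive asymmetry evoked by a reference stimulus (`ref_angle`, default 8
#'   degrees) equals `snr_ref` times the per-sample output noise at the
#'   reference noise level `delta_ref`.  This puts the paper's noise range on
#'   the scale where it produces gradual psychometric functions over the
#'   tested angles.
#' * `theta_f`: the step-function threshold is set to `theta_frac` of the
#'   mean per-window peak activity of a clean zero-deviation stimulus, so
#'   each window's neuron activates in sequence.
#' * drive gain and criterion: the drive gain normalises the maximal clean
#'   15-degree drive to 1, and the decision criterion is `crit_frac` of the
#'   winner's plateau under a clean (noise-free) 15-degree stimulus, so a
#'   clean large-deviation trial is always decided before the stimulus ends.
#'
#' @param model a `bm_model`.
#' @param ref_angle reference angle (deg) for the noise-comparability rule.
#' @param delta_ref reference internal-noise level.
#' @param snr_ref target ratio of drive asymmetry to per-sample noise sd.
#' @param theta_frac fraction defining `theta_f`.
#' @param crit_frac fraction defining the decision criterion.
#' @return the calibrated model.
#' @export
calibrate_model <- function(model, ref_angle = 8, delta_ref = 0.030,
                            snr_ref = 0.9, theta_frac = 0.5,
                            crit_frac = 0.7) {
  # stage 1: theta_f in the bank's raw evidence units, from a clean 0-deg run
  cell0 <- model_cell(model, "right", 0)
  nh <- model$bank$n_windows
  t_win <- ceiling(cell0$times / (4.5 / nh) - 1e-9)
  peaks <- vapply(seq_len(nh), function(w) {
    rows <- which(t_win == w)
    max(cell0$H[rows, c(w, nh + w)])
  }, 1)
  theta_f <- theta_frac * mean(peaks)
  model$ofp$theta_f <- theta_f
  model$cache <- new.env(parent = emptyenv())   # H depends on theta_f

  # stage 2: evidence rescaling against the reference noise level
  cellr <- model_cell(model, "right", ref_angle)
  late <- cellr$times >= 0.25 * max(cellr$times)
  asym <- mean(pmax(cellr$hbar[late, "right"] - cellr$hbar[late, "left"], 0))
  if (asym <= 0) stop("calibration failed: no drive asymmetry at the reference angle")
  sd_dir <- sqrt(model$decision$dt) * delta_ref / sqrt(nh)
  sc <- sd_dir * snr_ref / asym
  model$bank$scale$gain <- model$bank$scale$gain * sc
  model$bank$scale$offset <- model$bank$scale$offset * sc
  model$ofp$theta_f <- model$ofp$theta_f * sc
  model$ofp$w_plus <- model$ofp$w_plus * sc
  model$ofp$w_minus <- model$ofp$w_minus * sc
  model$cache <- new.env(parent = emptyenv())

  # stage 3: drive gain and decision criterion from a clean 15-deg stimulus
  cell15 <- model_cell(model, "right", 15)
  model$decision$drive_gain <- 1 / max(cell15$hbar)
  n_steps <- nrow(cell15$hbar) - 1
  probe <- run_decision_batch(cell15$H[seq_len(n_steps), ],
                              cell15$idx$right, cell15$idx$left,
                              within_params(model$decision, delta = 0,
                                            criterion = Inf),
                              n_trials = 1)
  plateau <- max(probe$T)
  model$decision$criterion <- crit_frac * plateau
  model$calibration <- list(ref_angle = ref_angle, delta_ref = delta_ref,
                            snr_ref = snr_ref, theta_frac = theta_frac,
                            crit_frac = crit_frac, evidence_scale = sc,
                            theta_f = model$ofp$theta_f,
                            drive_gain = model$decision$drive_gain,
                            criterion = model$decision$criterion,
                            clean_plateau = plateau)
  model
}

# decision_params copy with fields overridden
within_params <- function(par, ...) {
  mod <- list(...)
  par[names(mod)] <- mod
  par
}

#' Simulate trials from the model
#'
#' `simulate()` method: runs `nsim` forced-choice blocks under the default
#' protocol and returns the stacked response tables (see [run_block()]).
#'
#' @param object a `bm_model`.
#' @param nsim number of blocks.
#' @param seed integer seed.
#' @param params observer parameters (list with any of `delta`, `tau`, `k`,
#'   `tau_a`).
#' @param protocol protocol description passed to [run_block()].
#' @param ... unused.
#' @export
simulate.bm_model <- function(object, nsim = 1, seed = 1L, params = list(),
                              protocol = default_protocol(), ...) {
  out <- lapply(seq_len(nsim), function(b)
    cbind(block = b,
          run_block(object, params, protocol, seed = seed + b - 1L)))
  do.call(rbind, out)
}
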