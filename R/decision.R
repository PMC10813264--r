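#' Modified Michaelis-Menten gain function
#'
#' `S(x) = beta * max(x, 0) / (gamma + max(x, 0))`: zero at and below zero,
#' monotone non-decreasing, saturating at `beta`, with half-saturation at
#' `x = gamma`.
#'
#' @param x input (any shape; negative inputs are treated as zero, which
#'   also switches the lateral connection off when the information threshold
#'   is negative).
#' @param beta saturation level.
#' @param gamma half-saturation constant.
#' @export
mm_S <- function(x, beta = 1.5, gamma = 0.3) {
  xp <- pmax(x, 0)
  beta * xp / (gamma + xp)
}

#' Decision-stage parameters
#'
#' Two decision neurons race under robust mutual inhibition with neural
#' adaptation ("disremembering").  Each neuron obeys
#' \deqn{\tau \dot T = -T + S(P_T(D)) + DiS_T}
#' with information threshold `P_T(D) = g_T - theta_i - k D - a T` (evidence
#' drive minus the baseline `theta_i`, the mutual inhibition with gain `k`
#' and the auto-inhibition `a`) and the
#' adaptation input
#' \deqn{DiS_T = u(t - \tau_a)\,[T - S(P_T(D)) - k_a T],}
#' switched on by the unit step at the adaptation onset `tau_a`, after which
#' the dynamic reduces to a pure exponential decline `\tau \dot T = -k_a T`
#' that drives the winner out of excitation.  Negative activities are clamped
#' to zero after each integration step (robust rule).
#'
#' The four observer-level parameters are `delta` (internal noise, applied to
#' the optic-flow-pattern outputs that form the drives), `tau`, `k` and
#' `tau_a`; the remaining constants are fixed model constants.
#'
#' @param tau neuron time constant (s).
#' @param theta_i information-threshold baseline (drive units): the evidence
#'   drive must exceed this level before a neuron engages; below it the
#'   information threshold is negative, the lateral connection is off and the
#'   rectified output stays silent.
#' @param k inhibitory feedback gain (dimensionless).
#' @param tau_a adaptation onset time (s).
#' @param delta internal-noise standard deviation (evidence units).
#' @param k_adapt adaptation weighting coefficient `k_a` (fixed, default 1).
#' @param a_auto auto-inhibition gain `a`.
#' @param beta,gamma constants of [mm_S()].
#' @param criterion decision criterion on the winner's activity; calibrated
#'   by [calibrate_model()] in the full pipeline.
#' @param drive_gain scale applied to the pooled noisy optic-flow-pattern
#'   outputs to form the evidence drives.
#' @param drive_pool how a direction's nine rectified outputs are pooled
#'   into its drive: `"mean"` (default) or `"max"` (the direction's most
#'   active template neuron; with internal noise the max of nine rectified
#'   units acquires an upward bias that favours whichever chain has more
#'   near-zero activities, so the mean is the safer default).
#' @param ff_inhib feed-forward opponent inhibition: each neuron's drive is
#'   its direction's pooled evidence minus `ff_inhib` times the opponent
#'   direction's (default 1, full opponent subtraction).  Evidence shared by
#'   both directions then cancels, so the race stays quiescent until the
#'   stimulus actually discriminates.
#' @param dt integration step (s); must be at most `tau / 10`.
#' @param eps_plateau relative tolerance defining the reaction-time plateau.
#' @export
decision_params <- function(tau = 0.025, k = 4, tau_a = 1.22, delta = 0.030,
                            theta_i = 0.3, k_adapt = 1, a_auto = 0.5,
                            beta = 1.5, gamma = 0.3, criterion = 0.55,
                            drive_gain = 1, drive_pool = c("mean", "max"),
                            ff_inhib = 1, dt = 0.001, eps_plateau = 1e-6) {
  stopifnot(tau > 0, tau_a >= 0, dt > 0, dt <= tau / 10, criterion > 0,
            delta >= 0, k >= 0, k_adapt > 0)
  drive_pool <- match.arg(drive_pool)
  structure(list(tau = tau, k = k, tau_a = tau_a, delta = delta,
                 theta_i = theta_i, k_adapt = k_adapt, a_auto = a_auto, beta = beta,
                 gamma = gamma, criterion = criterion,
                 drive_gain = drive_gain, drive_pool = drive_pool,
                 ff_inhib = ff_inhib, dt = dt,
                 eps_plateau = eps_plateau),
            class = "decision_params")
}

#' Time derivatives of the two decision neurons
#'
#' @param state numeric vector `c(T, D)` (or a 2-row matrix for a batch of
#'   trials).
#' @param t current time (s).
#' @param drives numeric vector `c(g_T, g_D)` (or 2-row matrix).
#' @param par a [decision_params()].
#' @param adaptation logical; set `FALSE` to disable the disremembering
#'   input entirely.
#' @export
decision_derivs <- function(state, t, drives, par, adaptation = TRUE) {
  if (any(!is.finite(state))) stop("non-finite state")
  Tn <- state[1]; Dn <- state[2]
  gT <- drives[1]; gD <- drives[2]
  sT <- mm_S(gT - par$theta_i - par$k * Dn - par$a_auto * Tn, par$beta, par$gamma)
  sD <- mm_S(gD - par$theta_i - par$k * Tn - par$a_auto * Dn, par$beta, par$gamma)
  dT <- -Tn + sT
  dD <- -Dn + sD
  if (adaptation && t >= par$tau_a) {
    dT <- dT + (Tn - sT - par$k_adapt * Tn)
    dD <- dD + (Dn - sD - par$k_adapt * Dn)
  }
  c(dT, dD) / par$tau
}

#' Classical 4th-order Runge-Kutta step
#'
#' @param f derivative function `f(y, t, ...)` returning an object shaped
#'   like `y`.
#' @param y state.
#' @param t time.
#' @param dt step size.
#' @param ... passed to `f`.
#' @export
rk4_step <- function(f, y, t, dt, ...) {
  k1 <- f(y, t, ...)
  k2 <- f(y + dt / 2 * k1, t + dt / 2, ...)
  k3 <- f(y + dt / 2 * k2, t + dt / 2, ...)
  k4 <- f(y + dt * k3, t + dt, ...)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Run one decision trial
#'
#' Integrates the two decision neurons (RK4, clamping applied after each full
#' step) against the supplied per-direction drive time series.  The winner is
#' the first neuron whose activity exceeds the criterion; simultaneous
#' crossings within one step leave the trial undecided.
#'
#' @param drive_T,drive_D numeric vectors: evidence drives on the integration
#'   grid (drive during step `s` is element `s`); both must cover the full
#'   horizon.
#' @param par a [decision_params()].
#' @param t_end simulation horizon (s), default 4.5.
#' @param adaptation logical.
#' @return object of class `decision_trace`: `times`, `T`, `D`, `winner`
#'   (`"T"`, `"D"` or `"none"`), `rt` (s, `NA` if undecided),
#'   `crossing_time`.
#' @export
run_decision <- function(drive_T, drive_D, par = decision_params(),
                         t_end = 4.5, adaptation = TRUE) {
  n_steps <- round(t_end / par$dt)
  if (length(drive_T) < n_steps || length(drive_D) < n_steps)
    stop("evidence drives shorter than the simulation horizon")
  Tt <- numeric(n_steps + 1); Dt <- numeric(n_steps + 1)
  times <- (0:n_steps) * par$dt
  for (s in seq_len(n_steps)) {
    # the adaptation gate is held fixed within a step so the discrete flow
    # switches exactly at the grid point reached by tau_a
    st <- rk4_step(decision_derivs, c(Tt[s], Dt[s]), times[s], par$dt,
                   drives = c(drive_T[s], drive_D[s]), par = par,
                   adaptation = adaptation && times[s] >= par$tau_a + 0)
    Tt[s + 1] <- max(st[1], 0)
    Dt[s + 1] <- max(st[2], 0)
  }
  crossT <- which(Tt > par$criterion)[1]
  crossD <- which(Dt > par$criterion)[1]
  winner <- "none"; cross <- NA_real_
  if (!is.na(crossT) && (is.na(crossD) || crossT < crossD)) {
    winner <- "T"; cross <- times[crossT]
  } else if (!is.na(crossD) && (is.na(crossT) || crossD < crossT)) {
    winner <- "D"; cross <- times[crossD]
  }
  tr <- structure(list(times = times, T = Tt, D = Dt, winner = winner,
                       rt = NA_real_, crossing_time = cross),
                  class = "decision_trace")
  if (winner != "none") tr$rt <- extract_rt(tr, par$eps_plateau)
  tr
}

#' Reaction time of a decided trial
#'
#' The reaction time is the mean of all time points at which the winning
#' signal lies within a relative tolerance of its global maximum (motor time
#' is treated as zero).
#'
#' @param trace a `decision_trace`.
#' @param eps_plateau relative tolerance defining the plateau.
#' @export
extract_rt <- function(trace, eps_plateau = 1e-6) {
  if (trace$winner == "none") return(NA_real_)
  w <- if (trace$winner == "T") trace$T else trace$D
  m <- max(w)
  mean(trace$times[w >= m * (1 - eps_plateau)])
}

#' @export
print.decision_trace <- function(x, ...) {
  cat(sprintf("Decision trace: winner = %s, crossing = %s s, rt = %s s\n",
              x$winner,
              ifelse(is.na(x$crossing_time), "NA", sprintf("%.3f", x$crossing_time)),
              ifelse(is.na(x$rt), "NA", sprintf("%.3f", x$rt))))
  invisible(x)
}

#' @export
plot.decision_trace <- function(x, ...) {
  graphics::matplot(x$times, cbind(x$T, x$D), type = "l", lty = 1,
                    col = c("firebrick", "navy"), xlab = "time (s)",
                    ylab = "activity", ...)
  graphics::legend("topright", c("T", "D"), lty = 1,
                   col = c("firebrick", "navy"), bty = "n")
  invisible(x)
}

# Vectorised race over a batch of trials sharing one latent OFP trajectory.
#
# hmat: n_steps x n matrix of noise-free optic-flow-pattern activities;
# idx_T / idx_D: columns forming the drive of neuron "T" (the neuron
# matching the stimulus side under test) and of the other neuron.  Each
# neuron's output is drawn from N(H_i, dt * delta^2), rectified, and the
# per-direction mean (times drive_gain) forms the evidence drive; drives are
# sampled once per step and held constant within the RK4 stages.
run_decision_batch <- function(hmat, idx_T, idx_D, par, n_trials,
                               adaptation = TRUE) {
  n_steps <- nrow(hmat)
  dt <- par$dt
  sd1 <- sqrt(dt) * par$delta
  Tm <- matrix(0, n_steps + 1, n_trials)
  Dm <- matrix(0, n_steps + 1, n_trials)
  Tc <- numeric(n_trials); Dc <- numeric(n_trials)
  times <- (0:n_steps) * dt
  k <- par$k; a <- par$a_auto; beta <- par$beta; gam <- par$gamma
  th_i <- par$theta_i
  g_gain <- par$drive_gain
  nT <- length(idx_T); nD <- length(idx_D)
  pool <- function(m) {
    if (par$drive_pool == "mean") return(rowMeans(m))
    mx <- m[, 1]
    for (j in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, j])
    mx
  }
  pool1 <- function(v) if (par$drive_pool == "max") max(v) else mean(v)
  deriv <- function(Tn, Dn, gT, gD, adapt_on) {
    sT <- mm_S(gT - th_i - k * Dn - a * Tn, beta, gam)
    sD <- mm_S(gD - th_i - k * Tn - a * Dn, beta, gam)
    dT <- -Tn + sT
    dD <- -Dn + sD
    if (adapt_on) {
      dT <- dT + (Tn - sT - par$k_adapt * Tn)
      dD <- dD + (Dn - sD - par$k_adapt * Dn)
    }
    list(dT = dT / par$tau, dD = dD / par$tau)
  }
  for (s in seq_len(n_steps)) {
    if (par$delta > 0) {
      outT <- pmax(matrix(stats::rnorm(n_trials * nT, 0, sd1), n_trials, nT) +
                     rep(hmat[s, idx_T], each = n_trials), 0)
      outD <- pmax(matrix(stats::rnorm(n_trials * nD, 0, sd1), n_trials, nD) +
                     rep(hmat[s, idx_D], each = n_trials), 0)
      eT <- pool(outT); eD <- pool(outD)
    } else {
      eT <- pool1(pmax(hmat[s, idx_T], 0))
      eD <- pool1(pmax(hmat[s, idx_D], 0))
    }
    gT <- g_gain * (eT - par$ff_inhib * eD)
    gD <- g_gain * (eD - par$ff_inhib * eT)
    Tn <- Tc; Dn <- Dc
    # RK4 with drives and the adaptation gate held constant within the step
    a_on <- adaptation && times[s] >= par$tau_a
    k1 <- deriv(Tn, Dn, gT, gD, a_on)
    k2 <- deriv(Tn + dt / 2 * k1$dT, Dn + dt / 2 * k1$dD, gT, gD, a_on)
    k3 <- deriv(Tn + dt / 2 * k2$dT, Dn + dt / 2 * k2$dD, gT, gD, a_on)
    k4 <- deriv(Tn + dt * k3$dT, Dn + dt * k3$dD, gT, gD, a_on)
    Tc <- pmax(Tn + dt / 6 * (k1$dT + 2 * k2$dT + 2 * k3$dT + k4$dT), 0)
    Dc <- pmax(Dn + dt / 6 * (k1$dD + 2 * k2$dD + 2 * k3$dD + k4$dD), 0)
    Tm[s + 1, ] <- Tc
    Dm[s + 1, ] <- Dc
  }
  crit <- par$criterion
  winner <- character(n_trials); rt <- rep(NA_real_, n_trials)
  for (i in seq_len(n_trials)) {
    cT <- which(Tm[, i] > crit)[1]
    cD <- which(Dm[, i] > crit)[1]
    if (!is.na(cT) && (is.na(cD) || cT < cD)) {
      winner[i] <- "T"
      w <- Tm[, i]
    } else if (!is.na(cD) && (is.na(cT) || cD < cT)) {
      winner[i] <- "D"
      w <- Dm[, i]
    } else {
      winner[i] <- "none"
      next
    }
    m <- max(w)
    rt[i] <- mean(times[w >= m * (1 - par$eps_plateau)])
  }
  list(winner = winner, rt = rt, times = times, T = Tm, D = Dm)
}
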