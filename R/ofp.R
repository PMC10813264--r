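#' Parameters of the optic-flow-pattern layer dynamics
#'
#' The 18 optic-flow-pattern neurons follow a laterally connected neural-field
#' dynamic
#' \deqn{\tau \dot H_i = -H_i + G_i(t) + \sum_m w(i-m)\, f(H_m)}
#' with time constant `tau = 0.150` s, a step threshold `f(H) = 1(H >
#' theta_f)`, and an asymmetric kernel of compact support: `w(+1) = w_plus >
#' 0` (the active neuron excites the neuron tuned to the next temporal
#' window) and `w(-1) = -w_minus < 0` (it inhibits the previous one).
#' Lateral coupling runs within each direction's chain of nine neurons only.
#'
#' @param tau time constant in seconds (default 0.150).
#' @param dt integration step in seconds (default 0.001; must be at most
#'   `tau / 10`).
#' @param w_plus,w_minus kernel magnitudes (evidence units).
#' @param theta_f threshold of the step function `f`, in evidence units;
#'   calibrated by [calibrate_model()] in the full pipeline.
#' @param f_arg `"source"` applies `f` to the emitting neuron `H_m`
#'   (canonical neural-field form, default); `"self"` applies it to the
#'   receiving neuron `H_i`.
#' @param n number of neurons (default 18: two chains of nine).
#' @export
ofp_params <- function(tau = 0.150, dt = 0.001, w_plus = 0.05, w_minus = 0.05,
                       theta_f = 0.5, f_arg = c("source", "self"), n = 18L) {
  f_arg <- match.arg(f_arg)
  stopifnot(tau > 0, dt > 0, dt <= tau / 10, w_plus >= 0, w_minus >= 0,
            n >= 2, n %% 2 == 0)
  structure(list(tau = tau, dt = dt, w_plus = w_plus, w_minus = w_minus,
                 theta_f = theta_f, f_arg = f_arg, n = as.integer(n)),
            class = "ofp_params")
}

#' Lateral input of the optic-flow-pattern layer
#'
#' @param H numeric vector of activities (length `par$n`); the first half is
#'   one direction's chain in temporal-window order, the second half the
#'   other's.
#' @param par an [ofp_params()].
#' @return numeric vector of lateral inputs, one per neuron.
#' @export
lateral_input <- function(H, par) {
  f <- as.numeric(H > par$theta_f)
  half <- par$n %/% 2
  out <- numeric(par$n)
  for (chain in list(seq_len(half), half + seq_len(half))) {
    fc <- if (par$f_arg == "source") f[chain] else NULL
    n <- length(chain)
    inp <- numeric(n)
    if (par$f_arg == "source") {
      inp[2:n] <- inp[2:n] + par$w_plus * fc[1:(n - 1)]       # excite future
      inp[1:(n - 1)] <- inp[1:(n - 1)] - par$w_minus * fc[2:n] # inhibit past
    } else {
      fi <- f[chain]
      w_in <- c(-par$w_minus, rep(par$w_plus - par$w_minus, n - 2), par$w_plus)
      inp <- w_in * fi
    }
    out[chain] <- inp
  }
  out
}

ofp_deriv <- function(H, G, par) {
  (-H + G + lateral_input(H, par)) / par$tau
}

#' One RK4 step of the optic-flow-pattern dynamics
#'
#' @param H activities at time `t`.
#' @param G feed-forward evidence input held constant over the step.
#' @param par an [ofp_params()].
#' @param dt step size (defaults to `par$dt`).
#' @export
ofp_step <- function(H, G, par, dt = par$dt) {
  if (any(!is.finite(G))) stop("non-finite evidence input")
  rk4_step(function(y, t) ofp_deriv(y, G, par), H, 0, dt)
}

#' Integrate the optic-flow-pattern layer over a stimulus
#'
#' The evidence stream is piecewise constant: frame pair `p` (flow from frame
#' `p` to `p + 1`) drives the layer during `t` in `((p-1) dt_f, p dt_f]`,
#' where `dt_f` is the frame interval.  The latent trajectory is
#' deterministic; internal noise applies to the layer's outputs only (see
#' [noisy_output()]).
#'
#' @param G `n_pairs x n` evidence matrix from [evidence_stream()].
#' @param par an [ofp_params()].
#' @param frame_rate stimulus frame rate in Hz (default 20).
#' @param H0 initial activities (default 0).
#' @return list with `times` (length `n_steps + 1`), `H` (matrix
#'   `(n_steps + 1) x n`), and the parameters used.
#' @export
ofp_run <- function(G, par = ofp_params(), frame_rate = 20, H0 = NULL) {
  stopifnot(ncol(G) == par$n)
  if (any(!is.finite(G))) stop("non-finite evidence input")
  dt_f <- 1 / frame_rate
  t_end <- (nrow(G) + 1) * dt_f             # n_frames / frame_rate
  n_steps <- round(t_end / par$dt)
  H <- matrix(0, n_steps + 1, par$n)
  if (!is.null(H0)) H[1, ] <- H0
  times <- (0:n_steps) * par$dt
  for (s in seq_len(n_steps)) {
    p <- min(nrow(G), max(1L, ceiling((times[s] + par$dt / 2) / dt_f)))
    H[s + 1, ] <- ofp_step(H[s, ], G[p, ], par)
  }
  list(times = times, H = H, par = par)
}

#' Noisy output of optic-flow-pattern neurons
#'
#' The output of each neuron is drawn from a Gaussian with mean equal to its
#' noise-free activity and variance `dt * delta^2`; with `delta = 0` the
#' output equals the activity exactly.  Noise enters the model only here (the
#' two lower levels are noise-free).
#'
#' @param H activities (any shape).
#' @param dt sampling interval in seconds.
#' @param delta internal-noise standard-deviation parameter.
#' @export
noisy_output <- function(H, dt, delta) {
  stopifnot(delta >= 0, dt > 0)
  if (delta == 0) return(H)
  H + stats::rnorm(length(H), 0, sqrt(dt) * delta)
}
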