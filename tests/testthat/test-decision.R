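test_that("the gain function has the Michaelis-Menten identities", {
  expect_equal(mm_S(0), 0)
  expect_equal(mm_S(-3), 0)
  expect_equal(mm_S(0.3, beta = 1.5, gamma = 0.3), 0.75)   # S(gamma) = beta/2
  xs <- seq(-1, 5, by = 0.01)
  expect_true(all(diff(mm_S(xs)) >= 0))
  expect_true(all(mm_S(xs) <= 1.5))
})

test_that("one RK4 step of exponential decay matches the closed form", {
  f <- function(y, t) -y
  expect_equal(rk4_step(f, 1, 0, 0.01), exp(-0.01), tolerance = 1e-10)
  expect_identical(rk4_step(function(y, t) 0 * y, c(2, 3), 0, 0.1), c(2, 3))
})

test_that("adaptation is inert before onset and an exact decay after", {
  par <- decision_params(tau_a = 1.0, k_adapt = 1.3)
  st <- c(0.4, 0.2); dr <- c(0.9, 0.6)
  expect_identical(decision_derivs(st, 0.5, dr, par, adaptation = TRUE),
                   decision_derivs(st, 0.5, dr, par, adaptation = FALSE))
  # at and after onset the S terms cancel: tau * dT/dt = -k_a * T
  d_on <- decision_derivs(st, 1.5, dr, par, adaptation = TRUE)
  expect_equal(d_on, -par$k_adapt * st / par$tau, tolerance = 1e-12)
  # quiescent fixed point
  expect_equal(decision_derivs(c(0, 0), 0, c(0, 0), par), c(0, 0))
  expect_error(decision_derivs(c(NaN, 0), 0, dr, par), "non-finite")
})

test_that("the race picks the driven neuron and symmetry ties are preserved", {
  par <- decision_params(delta = 0, criterion = 0.5, tau_a = 1.2)
  n <- 4500
  strong <- rep(0.95, n); weak <- rep(0.55, n)
  tr <- run_decision(strong, weak, par)
  expect_equal(tr$winner, "T")
  expect_true(is.finite(tr$rt))
  # adaptation returns the winner below criterion by the end
  expect_lt(tr$T[length(tr$T)], par$criterion)
  # swapping the drives swaps the winner at identical reaction time
  tr2 <- run_decision(weak, strong, par)
  expect_equal(tr2$winner, "D")
  expect_equal(tr2$rt, tr$rt)
  expect_equal(tr2$D, tr$T)
  # exactly symmetric evidence stays tied: no winner
  tr3 <- run_decision(strong, strong, par)
  expect_equal(tr3$winner, "none")
  expect_true(is.na(tr3$rt))
  expect_error(run_decision(strong[1:10], weak, par), "shorter")
})

test_that("activities stay non-negative under arbitrary bounded evidence", {
  set.seed(12)
  for (i in 1:6) {
    par <- decision_params(tau = runif(1, 0.02, 0.05), k = sample(c(1, 4, 16), 1),
                           tau_a = runif(1, 0.5, 1.4), delta = 0,
                           criterion = 0.5)
    n <- 2000
    gT <- pmax(stats::filter(rnorm(n, 0.5, 0.5), rep(1 / 50, 50), circular = TRUE), -1)
    gD <- pmax(stats::filter(rnorm(n, 0.5, 0.5), rep(1 / 50, 50), circular = TRUE), -1)
    tr <- run_decision(as.numeric(gT), as.numeric(gD), par, t_end = 2)
    expect_true(all(tr$T >= 0))
    expect_true(all(tr$D >= 0))
  }
})

test_that("reaction time is the mean of the plateau at the maximum", {
  mk_trace <- function(w) {
    structure(list(times = seq(0, 4.5, by = 0.001),
                   T = w, D = 0 * w, winner = "T",
                   rt = NA_real_, crossing_time = 0.5),
              class = "decision_trace")
  }
  ts <- seq(0, 4.5, by = 0.001)
  # single sharp peak at t = 1
  expect_equal(extract_rt(mk_trace(exp(-(ts - 1)^2 / 0.01))), 1, tolerance = 1e-3)
  # flat plateau over [0.9, 1.1] averages to its centre
  w <- pmin(1, pmax(0, 1 - (abs(ts - 1) - 0.1) * 10))
  expect_equal(extract_rt(mk_trace(w)), 1, tolerance = 1e-3)
  # asymmetric plateau over [1.0, 1.4] averages to 1.2
  w2 <- pmin(1, pmax(0, 1 - (pmax(abs(ts - 1.2) - 0.2, 0)) * 10))
  expect_equal(extract_rt(mk_trace(w2)), 1.2, tolerance = 1e-3)
})

test_that("the batch integrator reproduces the single-trial path exactly", {
  set.seed(3)
  H <- matrix(runif(1000 * 18, 0, 0.8), 1000, 18)
  par <- decision_params(delta = 0, criterion = 0.6, drive_gain = 1.2,
                         tau_a = 0.7)
  b <- kinemotion:::run_decision_batch(H, 1:9, 10:18, par, n_trials = 1)
  eT <- rowMeans(pmax(H[, 1:9], 0))
  eD <- rowMeans(pmax(H[, 10:18], 0))
  gT <- par$drive_gain * (eT - par$ff_inhib * eD)
  gD <- par$drive_gain * (eD - par$ff_inhib * eT)
  tr <- run_decision(gT, gD, par, t_end = 1)
  expect_equal(b$T[, 1], tr$T, tolerance = 1e-12)
  expect_equal(b$D[, 1], tr$D, tolerance = 1e-12)
  expect_equal(b$winner[1], tr$winner)
})

test_that("RK4 decision trajectories match an adaptive reference integrator", {
  skip_if_not_installed("deSolve")
  set.seed(21)
  for (i in 1:20) {
    par <- decision_params(tau = runif(1, 0.02, 0.06),
                           k = runif(1, 1, 16),
                           tau_a = 0.3,
                           delta = 0, criterion = 10,
                           theta_i = runif(1, 0, 0.3),
                           a_auto = runif(1, 0.1, 0.6),
                           k_adapt = runif(1, 0.5, 2), dt = 1e-4)
    gT <- runif(1, 0.4, 1); gD <- runif(1, 0.2, 1)
    n <- 6000
    tr <- run_decision(rep(gT, n), rep(gD, n), par, t_end = 0.6)
    rhs <- function(t, y, p)
      list(decision_derivs(y, t, c(gT, gD), par))
    # integrate the two smooth pieces around the adaptation onset separately
    t1 <- c(0, 0.3); t2 <- c(0.3, 0.6)
    ref1 <- deSolve::ode(c(T = 0, D = 0), t1, rhs, NULL,
                         method = "lsoda", rtol = 1e-10, atol = 1e-12)
    ref2 <- deSolve::ode(ref1[nrow(ref1), c("T", "D")], t2, rhs, NULL,
                         method = "lsoda", rtol = 1e-10, atol = 1e-12)
    ref <- rbind(ref1, ref2[-1, ])
    idx <- round(ref[, "time"] / par$dt) + 1
    scale <- max(abs(ref[, c("T", "D")]))
    err <- max(abs(tr$T[idx] - ref[, "T"]), abs(tr$D[idx] - ref[, "D"]))
    expect_lt(err / scale, 1e-6)
  }
})
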