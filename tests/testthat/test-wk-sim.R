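# 0D Windkessel simulator: stepper accuracy, flow conservation, mean-split
# behaviour, convergence detection and the synthetic inflow generator.

const_wf <- function(period, q, n = 64) {
  waveform(period, seq(0, period, length.out = n + 1)[1:n], rep(q, n))
}

test_that("constant inflow settles to the closed-form steady pressure", {
  bc <- windkessel_bc(4.8e6, 3.79e-14, 5.89e7, distal_pressure = 1200)
  q0 <- 5.35e-6
  tr <- rcr_outlet_pressure(const_wf(0.55, q0), bc, max_cycles = 7)
  expect_true(tr$converged)
  expect_equal(tail(tr$pressure, 1), 1200 + q0 * (4.8e6 + 5.89e7),
               tolerance = 1e-12)
})

test_that("zero inflow decays exponentially with time constant Rd*C", {
  Rd <- 5e7; C <- 4e-9  # Rd*C = 0.2 s
  bc <- windkessel_bc(1e7, C, Rd, distal_pressure = 500)
  p0 <- 4000
  tr <- rcr_outlet_pressure(const_wf(0.55, 0), bc, dt = 0.55 / 2000,
                            max_cycles = 1, initial_pressure = p0)
  expected <- 500 + (p0 - 500) * exp(-tr$time / (Rd * C))
  expect_lt(max(abs(tr$pressure - expected) / (p0 - 500)), 0.005)
})

test_that("the stepper matches the analytic sinusoidal solution", {
  T <- 0.753; w <- 2 * pi / T
  bc <- windkessel_bc(1e7, 2e-9, 5e7, distal_pressure = 800)
  Q0 <- 5e-6; A <- 2.5e-6
  t <- seq(0, T, length.out = 129)[1:128]
  wf <- waveform(T, t, Q0 + A * sin(w * t))
  tr <- rcr_outlet_pressure(wf, bc, dt = T / 8192, max_cycles = 30,
                            tol = 1e-8)
  expect_true(tr$converged)
  last <- tr$time > (tr$cycles_run - 1) * T
  pan <- analytic_rcr_sinusoid(tr$time[last], Q0, A, w, bc)
  expect_lt(max(abs(tr$pressure[last] - pan)) / diff(range(pan)), 0.005)
})

test_that("halving the step halves the error (first-order stepper)", {
  T <- 0.55; w <- 2 * pi / T
  bc <- windkessel_bc(8e6, 1e-8, 4e7)  # Rd*C = 0.4 s
  Q0 <- 6e-6; A <- 3e-6
  t <- seq(0, T, length.out = 129)[1:128]
  wf <- waveform(T, t, Q0 + A * sin(w * t))
  err <- vapply(c(256, 512, 1024), function(n) {
    tr <- rcr_outlet_pressure(wf, bc, dt = T / n, max_cycles = 60,
                              tol = 1e-9)
    last <- tr$time > (tr$cycles_run - 1) * T
    max(abs(tr$pressure[last] -
              analytic_rcr_sinusoid(tr$time[last], Q0, A, w, bc)))
  }, numeric(1))
  expect_gt(err[1] / err[2], 1.6)
  expect_lt(err[1] / err[2], 2.4)
  expect_gt(err[2] / err[3], 1.6)
  expect_lt(err[2] / err[3], 2.4)
})

test_that("the stepper agrees with an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  T <- 0.55
  bc <- windkessel_bc(1.1e7, 3.9e-10, 3.2e7, distal_pressure = 0)
  wf <- synth_inflow(period = T)
  sp <- carotidwk:::waveform_splines(wf)
  rhs <- function(t, y, parms) {
    with(as.list(parms), list(
      (sp$q(t) * (1 + Rp / Rd) + C * Rp * sp$dq(t) - (y - Pd) / Rd) / C))
  }
  parms <- c(Rp = bc$proximal_resistance, Rd = bc$distal_resistance,
             C = bc$compliance, Pd = bc$distal_pressure)
  times <- seq(0, 5 * T, by = T / 1000)
  ode <- deSolve::lsoda(c(P = 0), times, rhs, parms,
                        rtol = 1e-9, atol = 1e-6)
  tr <- rcr_outlet_pressure(wf, bc, dt = T / 1000, max_cycles = 5,
                            tol = 1e-12)
  ## the BE run may stop once periodic; compare the overlapping cycles
  n <- length(tr$pressure)
  ref <- ode[-1, "P"][seq_len(n)]
  expect_lt(max(abs(tr$pressure - ref)) / diff(range(ref)), 0.01)
})

test_that("multi-outlet junction conserves flow to round-off", {
  ica <- windkessel_bc(4.8e6, 3.79e-14, 5.89e7)
  eca <- windkessel_bc(1.11e7, 3.89e-13, 3.19e7)
  sim <- multi_outlet_split(synth_inflow(), list(ICA = ica, ECA = eca),
                            max_cycles = 7)
  expect_lt(max(abs(rowSums(sim$flows) - sim$inflow)),
            1e-12 * max(sim$inflow))
  expect_equal(unname(rowSums(sim$cycle_mean_splits)),
               rep(1, nrow(sim$cycle_mean_splits)))
  expect_true(all(is.finite(sim$pressure)))
})

test_that("converged mean splits follow the inverse total-resistance divider", {
  # the published ICA/ECA totals give ~40.3% ICA at the 0D junction
  ica <- windkessel_bc(4.8e6, 3.79e-14, 5.89e7)
  eca <- windkessel_bc(1.11e7, 3.89e-13, 3.19e7)
  sim <- multi_outlet_split(synth_inflow(), list(ICA = ica, ECA = eca),
                            max_cycles = 10, tol = 1e-6)
  expect_true(sim$converged)
  div <- resistive_divider_split(list(ICA = ica, ECA = eca))
  expect_equal(unname(sim$mean_splits), unname(div), tolerance = 0.005)
  expect_equal(unname(sim$mean_splits[["ICA"]]), 0.403, tolerance = 0.005)

  # randomized RCR pairs with physiological time constants
  set.seed(42)
  for (i in 1:5) {
    bcs <- lapply(1:2, function(j) {
      Rp <- 10^stats::runif(1, 6.5, 7.5)
      Rd <- 10^stats::runif(1, 7, 8)
      C <- stats::runif(1, 0.01, 0.1) / Rd  # Rd*C in 0.01-0.1 s
      windkessel_bc(Rp, C, Rd)
    })
    sim <- multi_outlet_split(synth_inflow(), bcs, max_cycles = 30,
                              tol = 1e-6)
    expect_true(sim$converged)
    expect_equal(unname(sim$mean_splits),
                 unname(resistive_divider_split(bcs)), tolerance = 0.005)
  }
})

test_that("compliance shapes the waveform but not the cycle-mean split", {
  base <- list(windkessel_bc(5e6, 2e-9, 6e7),
               windkessel_bc(1.2e7, 8e-10, 3e7))
  tenx <- lapply(base, function(b)
    windkessel_bc(b$proximal_resistance, 10 * b$compliance,
                  b$distal_resistance))
  wf <- synth_inflow()
  s1 <- multi_outlet_split(wf, base, max_cycles = 30, tol = 1e-6)
  s2 <- multi_outlet_split(wf, tenx, max_cycles = 30, tol = 1e-6)
  expect_true(s1$converged && s2$converged)
  expect_lt(max(abs(s1$mean_splits - s2$mean_splits)), 0.005)
  # but the instantaneous flow traces differ (the capacitor matters)
  expect_gt(max(abs(s1$flows[, 1] - s2$flows[seq_len(nrow(s1$flows)), 1])) /
              max(s1$flows[, 1]), 0.001)
})

test_that("synthetic inflow has the exact prescribed mean and stays positive", {
  wf <- synth_inflow(period = 0.55, mean_flow = 5.35e-6)
  expect_equal(waveform_mean(wf), 5.35e-6, tolerance = 1e-12)
  expect_true(all(wf$flow > 0))
  wf2 <- synth_inflow(period = 0.753, mean_flow = 4e-6)
  expect_equal(waveform_mean(wf2), 4e-6, tolerance = 1e-12)
  # zero harmonics give a constant waveform
  flat <- synth_inflow(amplitudes = numeric(0), phases = numeric(0))
  expect_true(all(flat$flow == 5.35e-6))
  # negative-crossing parameter sets are rejected unless allowed
  expect_error(synth_inflow(amplitudes = c(2), phases = c(0)),
               "crosses zero")
  neg <- synth_inflow(amplitudes = c(2), phases = c(0),
                      allow_negative = TRUE)
  expect_lt(min(neg$flow), 0)
})

test_that("periodic convergence detection finds the first settled cycle", {
  # identical repeated cycles converge at index 2
  m <- matrix(rep(c(100, 2, 3), 4), nrow = 4, byrow = TRUE)
  expect_equal(periodic_convergence(m, tol = 1e-4), 2L)
  # a decaying transient converges once the change drops below tol
  x <- 100 + 10 * exp(-(1:8))
  # first index i with |x_i - x_{i-1}| / x_{i-1} < tol, computed directly
  first <- min(which(abs(diff(x)) / head(x, -1) < 1e-3)) + 1L
  expect_equal(periodic_convergence(cbind(x), tol = 1e-3), first)
  expect_warning(idx <- periodic_convergence(cbind(1:5), tol = 1e-6),
                 "no periodic steady state")
  expect_true(is.na(idx))
  expect_error(periodic_convergence(cbind(1), tol = 1e-4), "at least 2")
  # a pulsatile RCR with Rd*C << T converges within 7 cycles at tol 1e-3
  bc <- windkessel_bc(1e7, 1e-10, 5e7)  # Rd*C = 5e-3 s
  tr <- rcr_outlet_pressure(synth_inflow(), bc, max_cycles = 7, tol = 1e-3)
  expect_true(tr$converged)
  expect_lte(tr$converged_cycle, 7L)
})

test_that("waveform validation rejects malformed grids", {
  expect_error(waveform(0.5, c(0, 0.1, 0.1), c(1, 2, 3)),
               "strictly increasing")
  expect_error(waveform(0.5, seq(0, 0.6, length.out = 20), rep(1, 20)),
               "within")
  expect_error(waveform(0.5, seq(0, 0.5, length.out = 10), rep(1, 10)),
               "16 samples")
  # closed grid with mismatched endpoints is not periodic
  t <- seq(0, 0.5, length.out = 33)
  q <- sin(2 * pi * t / 0.5) + 2
  q[33] <- q[33] + 0.5
  expect_error(waveform(0.5, t, q), "not periodic")
  # dt restrictions
  wf <- synth_inflow()
  bc <- windkessel_bc(1e7, 1e-9, 5e7)
  expect_error(rcr_outlet_pressure(wf, bc, dt = wf$period / 10), "dt")
})
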