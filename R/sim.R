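## 0D transient simulation of three-element Windkessel outlets: implicit
## (backward) Euler on the linear pressure/flow state equations, with the
## shared junction pressure of a multi-outlet run closed exactly each step.

#' Periodic flow waveform
#'
#' One cardiac cycle of a volumetric flow record.  The grid must lie in
#' `[0, T]`, be strictly increasing and carry at least 16 samples; if both
#' endpoints are present their flow values must agree (periodicity), and
#' the duplicate endpoint is dropped internally.
#'
#' @param period Cycle period T in seconds.
#' @param time Sample times in seconds.
#' @param flow Volumetric flow in m^3 s^-1, one value per time.
#' @return An object of class `waveform`.
#' @export
waveform <- function(period, time, flow) {
  check_positive_scalar(period, "period")
  if (!is.numeric(time) || !is.numeric(flow) || length(time) != length(flow))
    stop("`time` and `flow` must be numeric vectors of equal length",
         call. = FALSE)
  if (any(!is.finite(time)) || any(!is.finite(flow)))
    stop("`time` and `flow` must be finite", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("`time` must be strictly increasing", call. = FALSE)
  if (min(time) < 0 || max(time) > period * (1 + 1e-12))
    stop("`time` must lie within [0, period]", call. = FALSE)
  n <- length(time)
  if (abs(time[n] - period) < 1e-12 * period) {
    if (abs(flow[n] - flow[1]) >
        1e-9 * max(abs(flow[1]), abs(flow[n]), 1e-300))
      stop("waveform is not periodic: flow at t = 0 and t = T differ",
           call. = FALSE)
    time <- time[-n]
    flow <- flow[-n]
  }
  if (length(time) < 16L)
    stop("waveform needs at least 16 samples per period", call. = FALSE)
  structure(list(period = period, time = time, flow = flow),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> T = %g s, %d samples, mean Q = %.4g m^3/s\n",
              x$period, length(x$time), waveform_mean(x)))
  invisible(x)
}

#' Cycle-mean flow of a waveform (periodic trapezoid rule)
#'
#' @param wf A [waveform()].
#' @return Mean flow over one period, m^3 s^-1.
#' @export
waveform_mean <- function(wf) {
  stopifnot(inherits(wf, "waveform"))
  t <- c(wf$time, wf$time[1] + wf$period)
  q <- c(wf$flow, wf$flow[1])
  sum(diff(t) * (q[-1] + q[-length(q)]) / 2) / wf$period
}

## Periodic cubic-spline interpolants of Q(t) and dQ/dt for a waveform.
waveform_splines <- function(wf) {
  t <- c(wf$time, wf$time[1] + wf$period)
  q <- c(wf$flow, wf$flow[1])
  f <- stats::splinefun(t, q, method = "periodic")
  t0 <- wf$time[1]
  T <- wf$period
  list(q = function(tt) f(t0 + (tt - t0) %% T),
       dq = function(tt) f(t0 + (tt - t0) %% T, deriv = 1))
}

#' Synthetic pulsatile inflow waveform
#'
#' Deterministic truncated-Fourier pulse
#' \deqn{Q(t) = \bar Q \left(1 + \sum_k a_k \cos(2\pi k t / T - \phi_k)\right)}
#' with an exactly prescribed cycle mean.  The default harmonic set gives a
#' carotid-like pulse (sharp systolic upstroke, diastolic decay) whose
#' relative amplitudes sum to less than one, so the flow stays strictly
#' positive.  Presets exist for cardiac periods of 0.55 s and 0.753 s; any
#' period is accepted.
#'
#' @param period Cycle period in s (default 0.55).
#' @param mean_flow Cycle-mean flow in m^3 s^-1 (default 5.35e-6, i.e.
#'   5.35 cm^3/s at the common carotid).
#' @param amplitudes Relative harmonic amplitudes a_k.
#' @param phases Harmonic phases in radians, same length as `amplitudes`.
#' @param samples Number of grid points per period (default 256).
#' @param allow_negative Permit waveforms that cross zero (default FALSE:
#'   such parameter sets are rejected).
#' @return A [waveform()].
#' @export
synth_inflow <- function(period = 0.55, mean_flow = 5.35e-6,
                         amplitudes = c(0.45, 0.22, 0.08, 0.03),
                         phases = c(0, 0.8, 1.6, 2.4),
                         samples = 256, allow_negative = FALSE) {
  check_positive_scalar(period, "period")
  check_positive_scalar(mean_flow, "mean_flow")
  if (length(amplitudes) != length(phases))
    stop("`amplitudes` and `phases` must have equal length", call. = FALSE)
  if (samples < 16L) stop_field("samples", "must be >= 16")
  t <- seq(0, period, length.out = samples + 1L)[seq_len(samples)]
  q <- rep(1, samples)
  for (k in seq_along(amplitudes))
    q <- q + amplitudes[k] * cos(2 * pi * k * t / period - phases[k])
  q <- mean_flow * q
  if (!allow_negative && any(q <= 0))
    stop("generated inflow crosses zero; reduce the harmonic amplitudes or ",
         "set allow_negative = TRUE", call. = FALSE)
  waveform(period, t, q)
}

#' Detect the first periodically converged cycle
#'
#' Given per-cycle summary metrics (e.g. mean pressure and per-outlet mean
#' flows, one row per completed cycle), returns the index of the first
#' cycle whose maximum relative change against the previous cycle falls
#' below `tol`.  Returns `NA` with a warning when no cycle converges.
#'
#' @param cycle_summary Numeric matrix or data frame, one row per cycle.
#' @param tol Relative per-cycle tolerance (default 1e-4).
#' @return Integer cycle index (>= 2), or `NA_integer_`.
#' @export
periodic_convergence <- function(cycle_summary, tol = 1e-4) {
  m <- as.matrix(cycle_summary)
  if (nrow(m) < 2L)
    stop("need at least 2 completed cycles to assess convergence",
         call. = FALSE)
  check_positive_scalar(tol, "tol")
  scale <- pmax(abs(m[-nrow(m), , drop = FALSE]), .Machine$double.xmin)
  rel <- abs(diff(m)) / scale
  worst <- apply(rel, 1L, max)
  idx <- which(worst < tol)
  if (!length(idx)) {
    warning("no periodic steady state within ", nrow(m), " cycles (worst ",
            "per-cycle change ", signif(min(worst), 3), ")", call. = FALSE)
    return(NA_integer_)
  }
  idx[1] + 1L
}

check_dt <- function(dt, period) {
  check_positive_scalar(dt, "dt")
  if (dt > period / 64)
    stop_field("dt", sprintf("must be <= T/64 = %g s", period / 64))
  dt
}

#' Outlet pressure of a single RCR Windkessel under prescribed flow
#'
#' Integrates the three-element Windkessel pressure equation
#' \deqn{C\frac{dP}{dt} = Q\left(1+\frac{R_p}{R_d}\right) + C R_p
#'   \frac{dQ}{dt} - \frac{P - P_d}{R_d}}
#' for a prescribed periodic flow, cycling the waveform until the pressure
#' trace reaches a periodic steady state or `max_cycles` is exhausted.
#' Time stepping is implicit (backward) Euler, unconditionally stable for
#' the stiff resistance/compliance ratios of distal cerebral beds; dQ/dt
#' comes from the periodic cubic spline of the waveform.
#'
#' @param wf Inflow [waveform()] (one period).
#' @param bc A [windkessel_bc()].
#' @param dt Time step in s, at most T/64 (default T/1000).
#' @param max_cycles Maximum cardiac cycles to run (default 7).
#' @param tol Per-cycle relative convergence tolerance (default 1e-4).
#' @param initial_pressure Starting pressure; defaults to the distal
#'   reference (the initial transient is discarded by the convergence
#'   detector).
#' @return List of class `rcr_trace`: `time`, `pressure`, `flow`,
#'   `cycles_run`, `converged_cycle`, `converged`.
#' @export
rcr_outlet_pressure <- function(wf, bc, dt = wf$period / 1000,
                                max_cycles = 7, tol = 1e-4,
                                initial_pressure = bc$distal_pressure) {
  stopifnot(inherits(wf, "waveform"), inherits(bc, "windkessel_bc"))
  check_dt(dt, wf$period)
  n <- max(64L, as.integer(round(wf$period / dt)))
  dt <- wf$period / n
  sp <- waveform_splines(wf)
  tg <- seq_len(n) * dt        # step endpoints within one cycle
  qs <- sp$q(tg)
  dqs <- sp$dq(tg)
  Rp <- bc$proximal_resistance; Rd <- bc$distal_resistance
  C <- bc$compliance; Pd <- bc$distal_pressure
  ## backward Euler: P_{k+1} = a * (P_k + dt * s_{k+1}), with
  ## s = (Q (1 + Rp/Rd) + C Rp dQ/dt + Pd/Rd) / C
  a <- 1 / (1 + dt / (Rd * C))
  s <- (qs * (1 + Rp / Rd) + C * Rp * dqs + Pd / Rd) / C
  b <- a * dt * s
  pressure <- numeric(0)
  p0 <- initial_pressure
  summaries <- NULL
  cycles <- 0L
  converged_cycle <- NA_integer_
  for (cyc in seq_len(max_cycles)) {
    p <- stats::filter(b, a, method = "recursive", init = p0)
    p <- as.numeric(p)
    if (any(!is.finite(p)))
      stop("pressure diverged (non-finite values) at dt = ", dt,
           "; reduce the time step", call. = FALSE)
    pressure <- c(pressure, p)
    p0 <- p[n]
    cycles <- cyc
    summaries <- rbind(summaries, c(mean = mean(p), max = max(p)))
    if (cyc >= 2L) {
      converged_cycle <- suppressWarnings(periodic_convergence(summaries, tol))
      if (!is.na(converged_cycle)) break
    }
  }
  time <- seq_len(cycles * n) * dt
  structure(list(time = time, pressure = pressure,
                 flow = rep(qs, cycles), dt = dt,
                 cycles_run = cycles,
                 converged_cycle = converged_cycle,
                 converged = !is.na(converged_cycle)),
            class = "rcr_trace")
}

#' Multi-outlet flow split through Windkessel boundary conditions
#'
#' Couples two or more RCR outlets to a single junction fed by a prescribed
#' inflow.  Each outlet carries a capacitor-node pressure state
#' \eqn{P_{c,i}} with
#' \deqn{Q_i = (P_{node} - P_{c,i})/R_{p,i}, \qquad
#'   C_i \frac{dP_{c,i}}{dt} = Q_i - (P_{c,i} - P_{d,i})/R_{d,i},}
#' and the junction pressure is closed exactly at every step so that the
#' outlet flows sum to the prescribed inflow:
#' \deqn{P_{node} = \frac{Q_{in} + \sum_i P_{c,i}/R_{p,i}}
#'   {\sum_i 1/R_{p,i}}.}
#' The coupled linear system is advanced by backward Euler with a single
#' pre-factorised matrix.  Flow conservation holds to round-off at every
#' accepted step, and the per-cycle mean split fractions sum to one.
#'
#' @param inflow Shared inflow [waveform()].
#' @param bcs List of two or more [windkessel_bc()] objects (named; names
#'   become outlet names).
#' @param dt Time step in s, at most T/64 (default T/1000).
#' @param max_cycles Maximum cycles (default 7).
#' @param tol Per-cycle relative convergence tolerance (default 1e-4).
#' @return List of class `wk_sim`: `time`, `pressure` (junction), `flows`
#'   (matrix, one column per outlet), `cycle_mean_flows`,
#'   `cycle_mean_splits`, `mean_splits` (last cycle), `cycles_run`,
#'   `converged_cycle`, `converged`.
#' @export
multi_outlet_split <- function(inflow, bcs, dt = inflow$period / 1000,
                               max_cycles = 7, tol = 1e-4) {
  stopifnot(inherits(inflow, "waveform"))
  if (!is.list(bcs) || length(bcs) < 2L)
    stop("need at least 2 outlets", call. = FALSE)
  if (!all(vapply(bcs, inherits, logical(1), "windkessel_bc")))
    stop("every entry of `bcs` must be a windkessel_bc", call. = FALSE)
  if (is.null(names(bcs)) || any(!nzchar(names(bcs))))
    names(bcs) <- paste0("outlet", seq_along(bcs))
  check_dt(dt, inflow$period)
  n <- max(64L, as.integer(round(inflow$period / dt)))
  dt <- inflow$period / n
  m <- length(bcs)
  Rp <- vapply(bcs, `[[`, numeric(1), "proximal_resistance")
  Rd <- vapply(bcs, `[[`, numeric(1), "distal_resistance")
  C <- vapply(bcs, `[[`, numeric(1), "compliance")
  Pd <- vapply(bcs, `[[`, numeric(1), "distal_pressure")
  if (any(Rp <= 0))
    stop("zero proximal resistance: junction closure undefined", call. = FALSE)
  S <- sum(1 / Rp)
  ## dPc/dt = A Pc + f(t):
  ## A[i,j] = ((1/(Rp_j S) - delta_ij)/Rp_i - delta_ij/Rd_i) / C_i
  A <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    A[i, j] <- ((1 / (Rp[j] * S) - (i == j)) / Rp[i] -
                  (i == j) / Rd[i]) / C[i]
  }
  M <- diag(m) - dt * A
  Minv <- solve(M)
  sp <- waveform_splines(inflow)
  tg <- seq_len(n) * dt
  qin <- sp$q(tg)
  fconst <- Pd / (Rd * C)
  fq <- 1 / (S * Rp * C)       # coefficient of Q_in(t) in f_i
  pc <- Pd                      # initial capacitor pressures
  pressure <- numeric(0)
  flows <- NULL
  cyc_means <- NULL
  summaries <- NULL
  cycles <- 0L
  converged_cycle <- NA_integer_
  for (cyc in seq_len(max_cycles)) {
    pcyc <- numeric(n)
    qcyc <- matrix(0, n, m)
    for (k in seq_len(n)) {
      rhs <- pc + dt * (fq * qin[k] + fconst)
      pc <- as.numeric(Minv %*% rhs)
      pnode <- (qin[k] + sum(pc / Rp)) / S
      pcyc[k] <- pnode
      qcyc[k, ] <- (pnode - pc) / Rp
    }
    if (any(!is.finite(pcyc)))
      stop("junction pressure diverged at dt = ", dt, call. = FALSE)
    pressure <- c(pressure, pcyc)
    flows <- rbind(flows, qcyc)
    cycles <- cyc
    mean_q <- colMeans(qcyc)
    cyc_means <- rbind(cyc_means, mean_q)
    summaries <- rbind(summaries, c(mean(pcyc), mean_q))
    if (cyc >= 2L) {
      converged_cycle <- suppressWarnings(periodic_convergence(summaries, tol))
      if (!is.na(converged_cycle)) break
    }
  }
  colnames(flows) <- names(bcs)
  rownames(cyc_means) <- NULL
  colnames(cyc_means) <- names(bcs)
  splits <- cyc_means / rowSums(cyc_means)
  structure(list(time = seq_len(cycles * n) * dt,
                 pressure = pressure, flows = flows,
                 inflow = rep(qin, cycles), dt = dt,
                 cycle_mean_flows = cyc_means,
                 cycle_mean_splits = splits,
                 mean_splits = splits[nrow(splits), ],
                 cycles_run = cycles,
                 converged_cycle = converged_cycle,
                 converged = !is.na(converged_cycle)),
            class = "wk_sim")
}

#' @export
print.wk_sim <- function(x, ...) {
  cat(sprintf("<wk_sim> %d outlet(s), %d cycle(s), converged: %s\n",
              ncol(x$flows), x$cycles_run, x$converged))
  cat("  mean splits:",
      paste(sprintf("%s = %.2f%%", colnames(x$flows), 100 * x$mean_splits),
            collapse = ", "), "\n")
  invisible(x)
}

#' Cycle-mean flow split implied by total resistances
#'
#' For equal distal pressures and any positive periodic inflow, the
#' converged cycle-mean split of a multi-outlet Windkessel junction is the
#' inverse total-resistance divider: compliances carry no mean current, so
#' \deqn{\mathrm{share}_i = \frac{1/(R_{p,i}+R_{d,i})}
#'   {\sum_j 1/(R_{p,j}+R_{d,j})}.}
#' Useful as a closed-form check on [multi_outlet_split()].
#'
#' @param bcs List of [windkessel_bc()] objects.
#' @return Named numeric vector of mean split fractions (sums to 1).
#' @export
resistive_divider_split <- function(bcs) {
  g <- vapply(bcs, function(b)
    1 / (b$proximal_resistance + b$distal_resistance), numeric(1))
  g / sum(g)
}
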