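# Model core: the 11-state ODE right-hand side and piecewise integration
# under a square-wave temperature schedule.
#
# The production path integrates a compiled C right-hand side (src/) through
# deSolve, restarting at every schedule discontinuity. A plain-R right-hand
# side is exported as the readable reference form of the equations and is
# used in the tests as an independent route through deSolve.

#' Thermosensing cascade derivatives
#'
#' Time derivatives of the four cascade components: TS1 integrates the
#' magnitude (cycle average) and the deviation of the temperature input;
#' TS2 is the Hill-saturated effector of TS1; active HSF1 is produced from
#' the free pool under TS2 stimulation and 1/indHSP inhibition; induced HSP
#' is produced by active HSF1 and inhibits its own production.
#'
#' @param state Named numeric state (needs TS1, TS2, actHSF1, indHSP), nM.
#' @param temp Instantaneous temperature, degC.
#' @param temp_mean Cycle-average temperature of the active pattern, degC.
#' @param params Parameter set (one-row data frame or named vector).
#' @return Named numeric derivatives, nM/h.
#' @export
#' @examples
#' # at the constant-37 fixed point TS1 is stationary
#' cascade_rhs(c(default_init(), TS1 = 7.4)[state_names()], 37, 37)["TS1"]
cascade_rhs <- function(state, temp, temp_mean, params = default_params()) {
  pv <- as_param_vector(params)
  if (state[["indHSP"]] <= 0) {
    stop("indHSP must be > 0 (it appears in denominators)", call. = FALSE)
  }
  with(as.list(c(state, pv)), {
    ts1n <- max(TS1, 0)^n
    c(TS1 = vact0_ts1 * temp_mean + vact1_ts1 * (temp - temp_mean) -
        vina_ts1 * TS1,
      TS2 = vb_ts2 * ts1n / (kb_ts2^n + ts1n) - vd_ts2 * TS2,
      actHSF1 = vact_hsf1 * (HSF1tot - actHSF1) / indHSP *
        (1 + kT * TS2 / (KT + TS2)) - vina_hsf1 * actHSF1,
      indHSP = vb_hsp * actHSF1 / indHSP - vd_hsp * indHSP)
  })
}

#' Clock gene network derivatives
#'
#' Time derivatives of the seven clock components. Per/Cry transcription is
#' driven by CLOCK/BMAL1 (plus a constitutive activator c) under
#' nuclear-PER/CRY Hill inhibition, multiplied by the HSF1 entrainment
#' factor `1 + khsf1*actHSF1/(Khsf1 + actHSF1 + khsf1_ci*indHSP/CLOCKBMAL1)`
#' in which induced HSP competes against the CLOCK/BMAL1-stabilised HSF1
#' binding. Setting `khsf1 = 0` decouples the clock from the cascade.
#'
#' @param state Named numeric state (all 11 components), nM.
#' @inheritParams cascade_rhs
#' @return Named numeric derivatives for the 7 clock components, nM/h.
#' @export
clock_rhs <- function(state, params = default_params()) {
  pv <- as_param_vector(params)
  if (state[["CLOCKBMAL1"]] <= 0) {
    stop("CLOCKBMAL1 must be > 0 (competitive-inhibition denominator)",
         call. = FALSE)
  }
  with(as.list(c(state, pv)), {
    ent <- 1 + khsf1 * actHSF1 /
      (Khsf1 + actHSF1 + khsf1_ci * indHSP / CLOCKBMAL1)
    c(PerCry_mRNA = v1b * (CLOCKBMAL1 + c) /
        (k1b * (1 + (max(nucPERCRY, 0) / k1i)^p) + CLOCKBMAL1 + c) * ent -
        k1d * PerCry_mRNA,
      PERCRY = k2b * max(PerCry_mRNA, 0)^q - k2d * PERCRY - k2t * PERCRY +
        k3t * nucPERCRY,
      nucPERCRY = k2t * PERCRY - k3t * nucPERCRY - k3d * nucPERCRY,
      Bmal1_mRNA = v4b * max(nucPERCRY, 0)^r /
        (k4b^r + max(nucPERCRY, 0)^r) - k4d * Bmal1_mRNA,
      BMAL1 = k5b * Bmal1_mRNA - k5d * BMAL1 - k5t * BMAL1 + k6t * nucBMAL1,
      nucBMAL1 = k5t * BMAL1 - k6t * nucBMAL1 - k6d * nucBMAL1 +
        k7a * CLOCKBMAL1 - k6a * nucBMAL1,
      CLOCKBMAL1 = k6a * nucBMAL1 - k7a * CLOCKBMAL1 - k7d * CLOCKBMAL1)
  })
}

#' Full model derivatives (plain R)
#'
#' The cascade and clock derivatives combined: the readable reference form
#' of the model, suitable for passing to [deSolve::ode()] directly.
#'
#' @param t Time, h (unused; the square wave enters via `temp`).
#' @param state Named numeric state of length 11.
#' @param params Named parameter vector.
#' @param temp,temp_mean Temperature and active-pattern average, degC.
#' @return List of derivatives, deSolve-style.
#' @export
model_rhs <- function(t, state, params, temp, temp_mean) {
  list(c(cascade_rhs(state, temp, temp_mean, params),
         clock_rhs(state, params)))
}

# shared piecewise driver.
# params_mat: ncell x 41; returns matrix time x (1 + 11*ncell)
.integrate_piecewise <- function(params_mat, schedule, t_end, dt, init,
                                 rtol, atol, method, t_start = 0) {
  ncell <- nrow(params_mat)
  y0 <- rep(as.numeric(init[.state_names]), ncell)
  grid <- round(seq(t_start, t_end, by = dt), 9)
  breaks <- sort(unique(round(
    c(t_start, discontinuities(schedule, c(t_start, t_end)), t_end), 9)))
  all_t <- sort(unique(round(c(grid, breaks), 9)))
  out <- matrix(NA_real_, length(all_t), 1 + 11 * ncell)
  out[1, ] <- c(t_start, y0)
  row <- 1L
  y <- y0
  for (k in seq_len(length(breaks) - 1L)) {
    a <- breaks[k]; b <- breaks[k + 1]
    seg_t <- all_t[all_t >= a - 1e-9 & all_t <= b + 1e-9]
    tw <- temperature_at(schedule, a + 1e-6)
    parms <- c(ncell, tw$temp_c, tw$temp_mean_c, as.vector(t(params_mat)))
    o <- deSolve::ode(y = y, times = seg_t, func = "clock_derivs",
                      parms = parms, dllname = "thermoclock",
                      initfunc = "clock_init", method = method,
                      rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(o, "istate")[1] < 0) {
      stop(sprintf("integration failed in segment [%g, %g] h", a, b),
           call. = FALSE)
    }
    ov <- o[, -1, drop = FALSE]
    if (!all(is.finite(ov)) || min(ov) <= 0) {
      bad <- which(!is.finite(ov) | ov <= 0, arr.ind = TRUE)[1, ]
      comp <- .state_names[(bad[2] - 1L) %% 11L + 1L]
      cell <- (bad[2] - 1L) %/% 11L + 1L
      stop(sprintf(
        "state non-positive or non-finite: %s (cell %d) at t = %g h",
        comp, cell, o[bad[1], 1]), call. = FALSE)
    }
    nseg <- nrow(o)
    out[row + seq_len(nseg - 1L), ] <- o[-1, , drop = FALSE]
    row <- row + nseg - 1L
    y <- o[nseg, -1]
  }
  # keep only the requested output grid
  keep <- all_t %in% round(grid, 9)
  out[keep, , drop = FALSE]
}

#' Simulate a single cell
#'
#' Integrates the 11-state model under a temperature schedule, restarting
#' the integrator at every square-wave edge so the discontinuous forcing is
#' honored exactly.
#'
#' @param params Parameter set (one-row data frame or named vector);
#'   defaults to the nominal values.
#' @param schedule A [temp_schedule][pattern_schedule] (default: the
#'   nominal W12/C12 37 +/- 1.5 degC pattern).
#' @param t_end Simulation horizon, h.
#' @param dt Output grid spacing, h.
#' @param init Named initial state, nM (strictly positive).
#' @param rtol,atol Solver tolerances; the tight defaults support period
#'   estimates to 0.01 h.
#' @param method deSolve method; `"lsoda"` by default.
#' @return A tibble (class `clock_trajectory`) with `time_h` and one column
#'   per state component; the schedule and parameters are attached as
#'   attributes.
#' @export
#' @examples
#' \donttest{
#' traj <- simulate_cell(t_end = 240)
#' period_of(traj$PerCry_mRNA, traj$time_h, burn_in = 120)
#' }
simulate_cell <- function(params = default_params(),
                          schedule = pattern_schedule(),
                          t_end = 1200, dt = 0.1, init = default_init(),
                          rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stopifnot(t_end > 0, dt > 0, all(init > 0))
  pm <- as_param_matrix(params)
  stopifnot(nrow(pm) == 1L)
  out <- .integrate_piecewise(pm, schedule, t_end, dt, init,
                              rtol, atol, method)
  traj <- tibble::as_tibble(as.data.frame(out))
  names(traj) <- c("time_h", .state_names)
  attr(traj, "schedule") <- schedule
  attr(traj, "params") <- tibble::as_tibble(as.list(pm[1, ]))
  class(traj) <- c("clock_trajectory", class(traj))
  traj
}

#' Algebraic steady state of the cascade at constant temperature
#'
#' TS1 and TS2 have closed-form fixed points; the activated-HSF1 /
#' induced-HSP pair is solved by a 1-D root find (indHSP is eliminated via
#' its own balance, indHSP = sqrt(vb_hsp * actHSF1 / vd_hsp)). Used as an
#' analytic oracle against long constant-temperature integrations.
#'
#' @param params Parameter set.
#' @param temp_const Constant temperature, degC (> 0).
#' @return Named numeric vector: TS1, TS2, actHSF1, indHSP at equilibrium.
#' @export
#' @examples
#' cascade_fixed_point()["TS1"]  # 7.4 nM at 37 degC
cascade_fixed_point <- function(params = default_params(), temp_const = 37) {
  stopifnot(temp_const > 0)
  pv <- as_param_vector(params)
  ts1 <- pv[["vact0_ts1"]] * temp_const / pv[["vina_ts1"]]
  ts2 <- pv[["vb_ts2"]] / pv[["vd_ts2"]] * ts1^pv[["n"]] /
    (pv[["kb_ts2"]]^pv[["n"]] + ts1^pv[["n"]])
  stim <- 1 + pv[["kT"]] * ts2 / (pv[["KT"]] + ts2)
  if (ts1 == 0) {
    # no production anywhere upstream
    return(c(TS1 = 0, TS2 = 0, actHSF1 = NA_real_, indHSP = NA_real_))
  }
  # residual of the actHSF1 balance after eliminating indHSP
  resid <- function(a) {
    h <- sqrt(pv[["vb_hsp"]] * a / pv[["vd_hsp"]])
    pv[["vact_hsf1"]] * (pv[["HSF1tot"]] - a) / h * stim -
      pv[["vina_hsf1"]] * a
  }
  upper <- pv[["HSF1tot"]]
  if (resid(upper * (1 - 1e-12)) > 0 || resid(1e-12) < 0) {
    stop("no positive cascade fixed point for these parameters",
         call. = FALSE)
  }
  a <- stats::uniroot(resid, c(1e-12, upper * (1 - 1e-12)),
                      tol = 1e-14)$root
  h <- sqrt(pv[["vb_hsp"]] * a / pv[["vd_hsp"]])
  c(TS1 = unname(ts1), TS2 = unname(ts2), actHSF1 = a, indHSP = h)
}
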