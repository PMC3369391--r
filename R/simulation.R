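# ODE integration, terminal-profile detection and summary metrics.
#
# Internal computation is in mEq/mL on the {mEq, mL, min} unit system of the
# parameter tables; all reported concentrations are multiplied by 1000 and
# labelled mEq/L, the scale on which plasma levels around 1 are therapeutic.
# Integration is restarted at every absorption-window boundary so that the
# discontinuous zero-order input is never smoothed across a step.

.DEFAULT_RTOL <- 1e-8
.DEFAULT_ATOL <- 1e-12

# Integrate dC/dt = A C + G(t)/V_G e_gi over [t0, t1] from state y0 (mEq/mL),
# splitting at absorption breakpoints; output grid spacing <= grid_dt plus all
# segment boundaries. Returns list(times, states [matrix], final).
.integrate_piecewise <- function(A, v_gi, profile, t0, t1, y0,
                                 grid_dt = 1, rtol = .DEFAULT_RTOL,
                                 atol = .DEFAULT_ATOL) {
  gi <- match("gi_tract", .state_names)
  bks <- sort(unique(c(t0, t1,
                       profile$breakpoints[profile$breakpoints > t0 &
                                           profile$breakpoints < t1])))
  times <- NULL
  states <- NULL
  y <- stats::setNames(as.numeric(y0), .state_names)
  for (k in seq_len(length(bks) - 1L)) {
    a <- bks[k]; b <- bks[k + 1L]
    g_const <- absorption_rate(profile, (a + b) / 2)  # constant within segment
    deriv <- function(t, state, parms) {
      d <- as.vector(A %*% state)
      d[gi] <- d[gi] + g_const / v_gi
      list(d)
    }
    tt <- unique(c(seq(a, b, by = grid_dt), b))
    out <- deSolve::lsoda(y, tt, deriv, parms = NULL, rtol = rtol, atol = atol)
    if (attr(out, "istate")[1L] < 0 || anyNA(out)) {
      stop(structure(class = c("li_solver_error", "error", "condition"),
                     list(message = sprintf(
                            "ODE solver failed on interval [%g, %g] min", a, b),
                          call = NULL)))
    }
    y <- stats::setNames(as.numeric(out[nrow(out), -1L]), .state_names)
    keep <- if (is.null(times)) seq_len(nrow(out)) else seq_len(nrow(out))[-1L]
    times <- c(times, out[keep, 1L])
    states <- rbind(states, out[keep, -1L, drop = FALSE])
  }
  list(times = times, states = states, final = y)
}

#' Simulate a dosing regimen
#'
#' Integrates the full mass-balance system from an all-zero initial state
#' (or a supplied one) under the regimen's repeating dose schedule, restarting
#' the adaptive integrator at every absorption-window edge.
#'
#' @param params A validated [li_physiology()].
#' @param regimen An [li_regimen()].
#' @param n_cycles Number of dosing cycles whose dose events are scheduled.
#' @param t_end End of integration, minutes; defaults to
#'   `n_cycles * cycle_length_min`. May exceed the dosed span (washout).
#' @param init Optional named initial state, mEq/mL; default all zero.
#' @param grid_dt Output grid spacing, minutes (default 1).
#' @param rtol,atol Relative/absolute solver tolerances.
#' @return An object of class `li_trajectory`: a data frame with `time_min`
#'   and one column per compartment in mEq/L, carrying attributes
#'   `final_state` (mEq/mL), `regimen` and `units`.
#' @examples
#' \donttest{
#' traj <- simulate_regimen(default_physiology(), regimen_preset("single-900"),
#'                          t_end = 48 * 60)
#' traj$time_min[which.max(traj$plasma)]  # plasma peaks at the end of release
#' }
#' @export
simulate_regimen <- function(params, regimen, n_cycles = 1L, t_end = NULL,
                             init = NULL, grid_dt = 1,
                             rtol = .DEFAULT_RTOL, atol = .DEFAULT_ATOL) {
  stopifnot(inherits(regimen, "li_regimen"))
  if (is.null(t_end)) t_end <- n_cycles * regimen$cycle_length_min
  events <- expand_regimen(regimen, n_cycles)
  profile <- absorption_profile(events, params$li_per_mg)
  A <- system_matrix(params)
  y0 <- if (is.null(init)) rep(0, 8) else as.numeric(init[.state_names])
  res <- .integrate_piecewise(A, params$compartments$gi_tract$volume, profile,
                              0, t_end, y0, grid_dt, rtol, atol)
  conc <- as.data.frame(res$states * 1000)  # mEq/mL -> mEq/L
  names(conc) <- .state_names
  traj <- cbind(data.frame(time_min = res$times), conc)
  structure(traj, class = c("li_trajectory", "data.frame"),
            final_state = res$final, regimen = regimen$label, units = "mEq/L")
}

# trapezoidal mean of y over (possibly non-uniform) grid t
.trapz_mean <- function(t, y) {
  dt <- diff(t)
  sum(dt * (y[-1L] + y[-length(y)]) / 2) / (t[length(t)] - t[1L])
}

# grid maximum refined by a local quadratic through the three nearest points
.refined_peak <- function(t, y) {
  i <- which.max(y)
  if (i == 1L || i == length(y)) {
    return(c(peak = y[i], time = t[i]))
  }
  t3 <- t[(i - 1L):(i + 1L)]; y3 <- y[(i - 1L):(i + 1L)]
  fit <- try(solve(cbind(1, t3, t3^2), y3), silent = TRUE)
  if (inherits(fit, "try-error") || fit[3L] >= 0) {
    return(c(peak = y[i], time = t[i]))
  }
  tv <- unname(-fit[2L] / (2 * fit[3L]))
  if (tv < t3[1L] || tv > t3[3L]) return(c(peak = y[i], time = t[i]))
  c(peak = unname(fit[1L] + fit[2L] * tv + fit[3L] * tv^2), time = tv)
}

# peak / peak time / average for every compartment of one cycle (mEq/mL in,
# same units out); t is local cycle time
.cycle_metrics <- function(t, states) {
  out <- lapply(.state_names, function(nm) {
    y <- states[, nm]
    pk <- .refined_peak(t, y)
    data.frame(compartment = nm, peak = unname(pk["peak"]),
               peak_time_min = unname(pk["time"]),
               average = .trapz_mean(t, y))
  })
  do.call(rbind, out)
}

#' Run a regimen to its terminal (periodic steady-state) profile
#'
#' Integrates cycle after cycle, carrying the end state forward, until for
#' every compartment the relative change of both the within-cycle peak and
#' the within-cycle average between consecutive cycles falls below
#' `tolerance`, or `max_cycles` is reached. The last cycle is the terminal
#' profile; its per-compartment peak, peak time and time-average (trapezoidal)
#' are returned.
#'
#' @param params A validated [li_physiology()].
#' @param regimen A periodic [li_regimen()].
#' @param tolerance Relative cycle-to-cycle drift below which the profile is
#'   declared terminal (default 1e-6).
#' @param max_cycles Cycle budget (default 60); non-convergence is reported
#'   via the `converged` flag, not an error.
#' @param grid_dt,rtol,atol Passed to the integrator.
#' @return An object of class `li_cycle_summary`: a data frame with one row
#'   per compartment (`compartment`, `peak`, `peak_time_min`, `average`, all
#'   concentrations in mEq/L, peak time in minutes from cycle start) with
#'   attributes `converged`, `n_cycles_run`, `tolerance`, `regimen` and
#'   `trajectory` (the terminal-cycle [li_trajectory]).
#' @examples
#' \donttest{
#' cs <- find_terminal_cycle(default_physiology(), regimen_preset("450/900"))
#' subset(cs, compartment == "fetus")
#' }
#' @export
find_terminal_cycle <- function(params, regimen, tolerance = 1e-6,
                                max_cycles = 60L, grid_dt = 1,
                                rtol = .DEFAULT_RTOL, atol = .DEFAULT_ATOL) {
  stopifnot(inherits(regimen, "li_regimen"))
  A <- system_matrix(params)
  v_gi <- params$compartments$gi_tract$volume
  cyc <- regimen$cycle_length_min
  profile <- absorption_profile(expand_regimen(regimen, 1L), params$li_per_mg)
  y <- rep(0, 8)
  prev <- NULL
  converged <- FALSE
  n_run <- 0L
  res <- NULL
  metrics <- NULL
  rel <- function(a, b) {
    den <- pmax(abs(a), abs(b))
    ifelse(den == 0, 0, abs(a - b) / den)
  }
  for (k in seq_len(max_cycles)) {
    res <- .integrate_piecewise(A, v_gi, profile, 0, cyc, y,
                                grid_dt, rtol, atol)
    y <- res$final
    n_run <- k
    metrics <- .cycle_metrics(res$times, res$states)
    if (!is.null(prev)) {
      drift <- max(rel(metrics$peak, prev$peak),
                   rel(metrics$average, prev$average))
      if (drift < tolerance) { converged <- TRUE; break }
    }
    prev <- metrics
  }
  summary <- metrics
  summary$peak <- summary$peak * 1000      # mEq/mL -> mEq/L
  summary$average <- summary$average * 1000
  conc <- as.data.frame(res$states * 1000)
  names(conc) <- .state_names
  traj <- structure(cbind(data.frame(time_min = res$times), conc),
                    class = c("li_trajectory", "data.frame"),
                    final_state = res$final, regimen = regimen$label,
                    units = "mEq/L")
  structure(summary, class = c("li_cycle_summary", "data.frame"),
            converged = converged, n_cycles_run = n_run,
            tolerance = tolerance, regimen = regimen$label,
            trajectory = traj)
}

#' Closed-form cycle-averaged concentrations at periodic steady state
#'
#' At the terminal profile, the cycle-average of every net exchange flux is
#' zero, so the flow balances collapse to algebra: the average plasma level
#' is the dosing rate divided by the effective renal clearance,
#' `avg C_P = (cycle dose / cycle length) / CL_eff`; every tissue that only
#' exchanges with plasma averages `R_i * avg C_P`; the kidney is depressed by
#' elimination, `avg C_K = R_K * Q_K/(Q_K + kk) * avg C_P`; and the fetal
#' balance forces `avg C_F / R_F = avg C_U / R_U = avg C_P`. This is an
#' exact property of the linear system and serves as an independent check on
#' the integrated terminal profile.
#'
#' @param params A validated [li_physiology()] with `renal_clearance > 0`.
#' @param regimen A periodic [li_regimen()].
#' @return Named vector of cycle-averaged concentrations, mEq/L.
#' @export
steady_state_average <- function(params, regimen) {
  stopifnot(inherits(regimen, "li_regimen"))
  cl <- effective_clearance(params)
  if (cl <= 0) {
    stop("renal clearance is zero: the system has no periodic steady state",
         call. = FALSE)
  }
  rate <- cycle_dose_meq(regimen, params$li_per_mg) / regimen$cycle_length_min
  avg_p <- rate / cl                       # mEq/mL
  R <- .partitions(params)
  kk <- params$renal_clearance
  qk <- params$compartments$kidney$flow
  avg <- c(plasma = avg_p, R * avg_p)
  avg["kidney"] <- R["kidney"] * qk / (qk + kk) * avg_p
  avg[.state_names] * 1000                 # mEq/L
}

#' Plasma half-life from a single dose
#'
#' Simulates one dose well past its absorption window, locates the plasma
#' maximum, and returns the elapsed time until the plasma concentration first
#' falls to half that maximum (linear interpolation on the dense grid).
#'
#' @param params A validated [li_physiology()].
#' @param regimen A single-dose [li_regimen()] (exactly one dose event).
#' @param t_end_hours Simulation horizon, hours (default 72).
#' @param ... Passed to [simulate_regimen()].
#' @return Half-life in hours.
#' @examples
#' \donttest{
#' estimate_half_life(default_physiology(), regimen_preset("single-900"))
#' }
#' @export
estimate_half_life <- function(params, regimen, t_end_hours = 72, ...) {
  stopifnot(inherits(regimen, "li_regimen"))
  if (length(regimen$doses_mg) != 1L || regimen$doses_mg[1L] <= 0) {
    stop("half-life estimation needs a regimen with exactly one positive dose",
         call. = FALSE)
  }
  traj <- simulate_regimen(params, regimen, n_cycles = 1L,
                           t_end = t_end_hours * 60, ...)
  pk <- .refined_peak(traj$time_min, traj$plasma)
  half <- pk["peak"] / 2
  after <- traj$time_min > pk["time"]
  below <- which(after & traj$plasma <= half)
  if (length(below) == 0L) {
    stop("plasma never fell to half its maximum within ", t_end_hours,
         " h; increase t_end_hours", call. = FALSE)
  }
  j <- below[1L]
  t_half <- stats::approx(traj$plasma[(j - 1L):j], traj$time_min[(j - 1L):j],
                          xout = half)$y
  unname((t_half - pk["time"]) / 60)
}

#' @export
print.li_cycle_summary <- function(x, ...) {
  cat(sprintf("Terminal-cycle summary for '%s' (%s after %d cycles, tol %g)\n",
              attr(x, "regimen"),
              if (attr(x, "converged")) "converged" else "NOT converged",
              attr(x, "n_cycles_run"), attr(x, "tolerance")))
  cat("Concentrations in mEq/L; peak time in min from cycle start\n")
  print.data.frame(x, row.names = FALSE, digits = 4, ...)
  invisible(x)
}
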