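#' Solver settings for the trajectory integrator
#'
#' @param rtol,atol Relative and absolute tolerances of the adaptive
#'   Runge-Kutta 4(5) stepper.
#' @param max_step Maximum step size in months (`Inf` leaves the stepper
#'   unrestricted).
#' @param dt_out Spacing of the dense output grid in months. The default
#'   0.001 is fine enough that quadratic refinement of the sampled extrema
#'   recovers peak times well below the reporting precision.
#' @param extinction_threshold Density (No./m^3) below which a population is
#'   operationally treated as extinct; the continuum model never reaches
#'   exactly zero in finite time.
#' @return A list of class `mp_solver_settings`.
#' @export
solver_settings <- function(rtol = 1e-8, atol = 1e-10, max_step = Inf,
                            dt_out = 0.001, extinction_threshold = 1e-3) {
  stopifnot(rtol > 0, atol > 0, max_step > 0, dt_out > 0,
            extinction_threshold >= 0)
  structure(
    list(rtol = rtol, atol = atol, max_step = max_step, dt_out = dt_out,
         extinction_threshold = extinction_threshold),
    class = "mp_solver_settings"
  )
}

#' Nonnegativity projection of the raw rates
#'
#' The model constrains all four state components to stay nonnegative, but
#' the raw vector field can point outward at the boundary (at the reference
#' rates the predator burden has a negative raw rate at zero). The minimal
#' rule enforcing the constraint sets a component's rate to zero exactly
#' while that component is at (or numerically below) zero and its raw rate
#' is negative, and leaves every other rate untouched.
#'
#' @param state Numeric vector `(x1, x2, C1, C2)` (nonnegative).
#' @param raw_rates Numeric vector of the same length, the raw derivatives.
#' @return The projected rate vector.
#' @examples
#' project_rates(c(100, 10, 0, 0), c(350, 10, 0.06, -0.13))
#' @export
project_rates <- function(state, raw_rates) {
  out <- as.double(raw_rates)
  out[state <= 0 & out < 0] <- 0
  out
}

#' Integrate the modified Lotka-Volterra system
#'
#' Runs the four-equation model forward with an adaptive Dormand-Prince
#' Runge-Kutta 4(5) pair (via \pkg{deSolve}), applying the nonnegativity
#' projection of [project_rates()] inside the right-hand side and clipping
#' sub-tolerance negative excursions in the reported states. Integration
#' always runs to `t_end`; crossing the extinction threshold is recorded as
#' an event but does not stop the run (prey can still rebound after the
#' predator collapses).
#'
#' @inheritParams mp_derivatives
#' @param init Initial state: named numeric vector or one-row data frame
#'   with `x1`, `x2`, `C1`, `C2`, all nonnegative.
#' @param t_end End of the integration window in months.
#' @param settings A [solver_settings()] list.
#' @param freeze_toxin If `TRUE`, hold both internal burdens exactly at
#'   their initial values (used for the toxin-free reference condition,
#'   where all four microplastic quantities are zero).
#' @return A tibble of class `mp_trajectory` with columns
#'   `t`, `x1`, `x2`, `C1`, `C2`, one row per dense-grid point. Attributes:
#'   `params`, `settings`, `freeze_toxin`, and `events`, a tibble of
#'   first-crossing records (`component`, `time`, `kind`).
#' @examples
#' traj <- simulate_mp(mp_params(), t_end = 2,
#'                     settings = solver_settings(rtol = 1e-6, dt_out = 0.01))
#' tail(traj)
#' @export
simulate_mp <- function(params, init = c(x1 = 100, x2 = 10, C1 = 0, C2 = 0),
                        t_end = 10, settings = solver_settings(),
                        freeze_toxin = FALSE) {
  p <- assert_valid_params(params)
  stopifnot(inherits(settings, "mp_solver_settings"), t_end > 0)
  y0 <- unlist(as_state_tbl(init)[1, ])
  if (any(y0 < 0)) abort("initial state must be nonnegative")

  pv <- unlist(as.list(p)[param_fields()])
  rhs <- function(t, y, parms) {
    raw <- c(
      y[1] * ((parms[["r10"]] - parms[["d1"]]) - parms[["r11"]] * y[3] -
                (parms[["a1"]] - parms[["d3"]]) * y[2]),
      y[2] * (-parms[["r20"]] - parms[["r21"]] * y[4] +
                (parms[["a2"]] - parms[["d2"]]) * y[1]),
      parms[["S1"]] * parms[["CE"]] - parms[["g1"]],
      parms[["S2"]] * parms[["CE"]] + parms[["k"]] * y[3] - parms[["g2"]]
    )
    if (freeze_toxin) raw[3:4] <- 0
    list(project_rates(y, raw))
  }

  times <- seq(0, t_end, by = settings$dt_out)
  if (tail(times, 1) < t_end) times <- c(times, t_end)
  sol <- deSolve::ode(
    y = y0, times = times, func = rhs, parms = pv,
    method = "ode45", rtol = settings$rtol, atol = settings$atol,
    hmax = if (is.finite(settings$max_step)) settings$max_step else NULL
  )
  m <- unclass(sol)
  if (anyNA(m) || !all(is.finite(m))) {
    bad <- which(!stats::complete.cases(m))[1]
    abort(paste0("integration failed; last valid time t = ",
                 signif(m[max(bad - 1, 1), 1], 6)))
  }
  states <- m[, state_fields(), drop = FALSE]
  min_preclip <- min(states)
  states[states < 0] <- 0

  out <- tibble(t = m[, "time"],
                x1 = states[, "x1"], x2 = states[, "x2"],
                C1 = states[, "C1"], C2 = states[, "C2"])
  eps <- settings$extinction_threshold
  ev <- list()
  for (sp in c("x1", "x2")) {
    tc <- first_crossing(out$t, out[[sp]], eps)
    if (!is.na(tc)) {
      ev[[sp]] <- tibble(component = sp, time = tc,
                         kind = "extinction_threshold")
    }
  }
  events <- if (length(ev) > 0) list_rbind(ev) else {
    tibble(component = character(), time = double(), kind = character())
  }

  structure(
    out,
    params = p, settings = settings, freeze_toxin = freeze_toxin,
    events = events, min_preclip = min_preclip,
    class = c("mp_trajectory", class(out))
  )
}

# first time a series falls below `threshold` (linear interpolation), NA if never
first_crossing <- function(t, v, threshold) {
  below <- v < threshold
  if (!any(below)) return(NA_real_)
  i <- which(below)[1]
  if (i == 1L) return(t[1])
  # interpolate between the last point at/above and the first below
  t[i - 1] + (v[i - 1] - threshold) / (v[i - 1] - v[i]) * (t[i] - t[i - 1])
}

#' @export
print.mp_trajectory <- function(x, ...) {
  cat(sprintf("<mp_trajectory> %d grid points over t = [%g, %g] months\n",
              nrow(x), x$t[1], x$t[nrow(x)]))
  ev <- attr(x, "events")
  if (!is.null(ev) && nrow(ev) > 0) {
    cat(sprintf("  threshold crossings: %s\n",
                paste(sprintf("%s at t = %.3f", ev$component, ev$time),
                      collapse = ", ")))
  }
  NextMethod()
}
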