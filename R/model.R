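#' Raw right-hand side of the modified Lotka-Volterra system
#'
#' Evaluates the instantaneous rates of change of the four state components
#' (prey density, predator density, internal particle concentration of prey
#' and of predator) at one or more states. This is the *raw* vector field:
#' the nonnegativity projection that the integrator applies near the state
#' boundary (see [project_rates()]) is deliberately not applied here.
#'
#' @param state A data frame with columns `x1`, `x2`, `C1`, `C2` (any number
#'   of rows), or a named numeric vector with those elements.
#' @param params An [mp_params()] parameter set.
#' @return A tibble with columns `dx1`, `dx2`, `dC1`, `dC2`, one row per
#'   input state.
#' @examples
#' mp_derivatives(c(x1 = 100, x2 = 10, C1 = 0, C2 = 0), mp_params())
#' @export
mp_derivatives <- function(state, params) {
  p <- assert_valid_params(params)
  s <- as_state_tbl(state)
  if (any(s$x1 < 0 | s$x2 < 0 | s$C1 < 0 | s$C2 < 0)) {
    abort("state components must be nonnegative")
  }
  tibble(
    dx1 = s$x1 * ((p$r10 - p$d1) - p$r11 * s$C1 - (p$a1 - p$d3) * s$x2),
    dx2 = s$x2 * (-p$r20 - p$r21 * s$C2 + (p$a2 - p$d2) * s$x1),
    dC1 = rep((p$S1 * p$CE - p$g1), nrow(s)),
    dC2 = p$S2 * p$CE + p$k * s$C1 - p$g2
  )
}

state_fields <- function() c("x1", "x2", "C1", "C2")

as_state_tbl <- function(state) {
  if (is.numeric(state) && !is.null(names(state))) {
    state <- as.list(state)
  }
  s <- as_tibble(as.data.frame(as.list(state))[state_fields()])
  if (anyNA(s)) abort("state must supply x1, x2, C1, C2")
  s
}

#' Coexistence equilibrium of the toxin-free system
#'
#' With both internal burdens held at zero the model reduces to a classical
#' Lotka-Volterra pair with effective rates `r10 - d1`, `a1 - d3`, `a2 - d2`,
#' whose interior fixed point is
#' `x1* = r20 / (a2 - d2)`, `x2* = (r10 - d1) / (a1 - d3)`.
#' Used as an analytic oracle for the integrator.
#'
#' @inheritParams mp_derivatives
#' @return A one-row tibble with columns `x1`, `x2`.
#' @examples
#' lv_equilibrium(mp_params()) # (80, 80) at the reference rates
#' @export
lv_equilibrium <- function(params) {
  p <- assert_valid_params(params)
  tibble(x1 = p$r20 / (p$a2 - p$d2), x2 = (p$r10 - p$d1) / (p$a1 - p$d3))
}

#' First integral of the toxin-free system
#'
#' The classical Lotka-Volterra conserved quantity, written with the model's
#' effective rates:
#' \deqn{H(x_1,x_2) = (a_2-d_2) x_1 - r_{20}\log x_1 +
#'                    (a_1-d_3) x_2 - (r_{10}-d_1)\log x_2.}
#' `H` is constant along exact toxin-free orbits and attains its minimum at
#' the coexistence equilibrium. It is exposed purely as an
#' integration-accuracy diagnostic (see [invariant_drift()]); with nonzero
#' response intensities it is not conserved.
#'
#' @param x1,x2 Strictly positive prey and predator densities (vectorised).
#' @inheritParams mp_derivatives
#' @return A numeric vector of `H` values.
#' @examples
#' lv_invariant(100, 10, mp_params())
#' @export
lv_invariant <- function(x1, x2, params) {
  p <- assert_valid_params(params)
  if (any(x1 <= 0) || any(x2 <= 0)) {
    abort("lv_invariant requires strictly positive densities")
  }
  (p$a2 - p$d2) * x1 - p$r20 * log(x1) +
    (p$a1 - p$d3) * x2 - (p$r10 - p$d1) * log(x2)
}

#' Analytic solution of the toxin subsystem
#'
#' The internal-burden equations are decoupled from the populations and
#' solvable in closed form from `C1(0) = C2(0) = 0`. The prey burden grows
#' linearly at rate `S1*CE - g1`; the predator burden integrates
#' `S2*CE + k*C1 - g2`. With `clamped = TRUE` (the default, matching the
#' integrator's nonnegativity projection) a component is held at zero while
#' its raw rate is negative -- for the reference rates the predator burden
#' stays at zero until the prey burden has grown enough to turn its net rate
#' positive, then follows a quadratic branch.
#'
#' @param t Nonnegative times in months (vectorised).
#' @inheritParams mp_derivatives
#' @param clamped Apply the nonnegativity clamp (default `TRUE`); with
#'   `FALSE` the raw linear/quadratic solution is returned, which may go
#'   negative.
#' @return A tibble with columns `t`, `C1`, `C2`.
#' @examples
#' toxin_closed_form(c(0, 1, 2), mp_params())
#' @export
toxin_closed_form <- function(t, params, clamped = TRUE) {
  p <- assert_valid_params(params)
  if (any(t < 0)) abort("t must be nonnegative")
  a_raw <- p$S1 * p$CE - p$g1       # constant prey-burden rate
  b0 <- p$S2 * p$CE - p$g2          # predator-burden rate at C1 = 0
  if (!clamped) {
    C1 <- a_raw * t
    C2 <- b0 * t + p$k * a_raw * t^2 / 2
    return(tibble(t = t, C1 = C1, C2 = C2))
  }
  a <- max(a_raw, 0)
  C1 <- a * t
  slope2 <- p$k * a                 # d(dC2/dt)/dt once C1 feeds in
  if (b0 >= 0) {
    C2 <- b0 * t + slope2 * t^2 / 2
  } else if (slope2 > 0) {
    t_on <- -b0 / slope2            # clamp releases when raw rate hits zero
    C2 <- ifelse(t <= t_on, 0,
                 b0 * (t - t_on) + slope2 * (t^2 - t_on^2) / 2)
  } else {
    C2 <- rep(0, length(t))
  }
  tibble(t = t, C1 = C1, C2 = C2)
}
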