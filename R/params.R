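#' Model parameters for the microplastic predator-prey system
#'
#' Bundles every rate constant of the modified Lotka-Volterra model into a
#' one-row tibble. The defaults are the reference parameterisation for a
#' freshwater system exposed to a constant surface-water concentration of
#' 30 particles/m^3; the response intensities `r11`, `r21` default to zero
#' (no toxicological response) and are the knobs the scenario machinery
#' varies.
#'
#' The population equations read
#' \deqn{dx_1/dt = x_1[(r_{10}-d_1) - r_{11} C_1 - (a_1-d_3) x_2]}
#' \deqn{dx_2/dt = x_2[-r_{20} - r_{21} C_2 + (a_2-d_2) x_1]}
#' and the internal-burden (toxin) equations
#' \deqn{dC_1/dt = S_1 C_E - g_1, \quad dC_2/dt = S_2 C_E + k C_1 - g_2,}
#' all four state components constrained to stay nonnegative.
#'
#' @param r10 Intrinsic prey growth rate without toxicity (per month).
#' @param r20 Natural predator mortality rate (per month).
#' @param r11,r21 Toxicological response intensities of prey and predator:
#'   per-capita growth-rate loss per unit of internal particle concentration.
#' @param a1 Predation loss coefficient on the prey (per month per predator).
#' @param a2 Predator gain coefficient from feeding (per month per prey).
#' @param d1 Decline in prey feeding ability; reduces `r10` (per month).
#' @param d2 Decline in predatory performance; reduces `a2`.
#' @param d3 Decline in predation pressure on prey; reduces `a1`.
#' @param S1,S2 Particle-selection/uptake coefficients of prey and predator
#'   (per month).
#' @param g1,g2 Microplastic egestion rates of prey and predator
#'   (concentration units per month), independent of the internal burden.
#' @param k Bioaccumulation transfer coefficient prey to predator (per month).
#' @param CE Environmental microplastic concentration (particles/m^3),
#'   treated as constant.
#'
#' @return A one-row tibble of class `mp_params`.
#' @seealso [validate_params()], [baseline_parameters()]
#' @examples
#' p <- mp_params(r11 = 1, r21 = 10)
#' validate_params(p)
#' @export
mp_params <- function(r10 = 4.1, r20 = 4.0, r11 = 0, r21 = 0,
                      a1 = 0.052, a2 = 0.052,
                      d1 = 0.1, d2 = 0.002, d3 = 0.002,
                      S1 = 0.042, S2 = 0.039, g1 = 1.2, g2 = 1.3,
                      k = 2.0, CE = 30) {
  out <- tibble(
    r10 = as.double(r10), r20 = as.double(r20),
    r11 = as.double(r11), r21 = as.double(r21),
    a1 = as.double(a1), a2 = as.double(a2),
    d1 = as.double(d1), d2 = as.double(d2), d3 = as.double(d3),
    S1 = as.double(S1), S2 = as.double(S2),
    g1 = as.double(g1), g2 = as.double(g2),
    k = as.double(k), CE = as.double(CE)
  )
  if (nrow(out) != 1L) {
    abort("all parameter arguments must be scalar")
  }
  class(out) <- c("mp_params", class(out))
  out
}

param_fields <- function() {
  c("r10", "r20", "r11", "r21", "a1", "a2", "d1", "d2", "d3",
    "S1", "S2", "g1", "g2", "k", "CE")
}

as_mp_params <- function(x) {
  if (inherits(x, "mp_params")) return(x)
  x <- as.list(x)
  missing <- setdiff(param_fields(), names(x))
  if (length(missing) > 0) {
    abort(paste0("missing parameter fields: ", paste(missing, collapse = ", ")))
  }
  do.call(mp_params, x[param_fields()])
}

#' Validate a parameter set
#'
#' Checks every structural constraint the model needs to keep its ecological
#' sign structure: `r10`, `r20`, `a1`, `a2` strictly positive; all toxicity,
#' feeding-decline, uptake, egestion and transfer rates nonnegative; and the
#' effective rates `r10 - d1`, `a1 - d3`, `a2 - d2` strictly positive (a
#' feeding decline large enough to flip one of these would invert prey growth
#' or turn predation into a subsidy).
#'
#' @param params An [mp_params()] row (or coercible named list/vector).
#' @return A tibble with one row per violated constraint and columns
#'   `field`, `constraint`, `value`. Zero rows means the set is valid.
#' @examples
#' validate_params(mp_params())                 # 0 rows
#' validate_params(mp_params(d3 = 0.12))        # a1 - d3 must be positive
#' @export
validate_params <- function(params) {
  p <- as.list(as_mp_params(params))
  v <- list()
  add <- function(field, constraint, value) {
    v[[length(v) + 1L]] <<- tibble(field = field, constraint = constraint,
                                   value = as.double(value))
  }
  for (f in param_fields()) {
    if (!is.finite(p[[f]])) add(f, paste(f, "must be finite"), p[[f]])
  }
  for (f in c("r10", "r20", "a1", "a2")) {
    if (is.finite(p[[f]]) && p[[f]] <= 0) {
      add(f, paste(f, "must be positive"), p[[f]])
    }
  }
  for (f in c("r11", "r21", "d1", "d2", "d3", "S1", "S2", "g1", "g2", "k", "CE")) {
    if (is.finite(p[[f]]) && p[[f]] < 0) {
      add(f, paste(f, "must be nonnegative"), p[[f]])
    }
  }
  eff <- list(
    list("d1", "r10 - d1 must be positive", p$r10 - p$d1),
    list("d3", "a1 - d3 must be positive", p$a1 - p$d3),
    list("d2", "a2 - d2 must be positive", p$a2 - p$d2)
  )
  for (e in eff) {
    if (is.finite(e[[3]]) && e[[3]] <= 0) add(e[[1]], e[[2]], e[[3]])
  }
  if (length(v) == 0) {
    return(tibble(field = character(), constraint = character(),
                  value = double()))
  }
  list_rbind(v)
}

assert_valid_params <- function(params) {
  viol <- validate_params(params)
  if (nrow(viol) > 0) {
    abort(paste0("invalid model parameters: ",
                 paste(viol$constraint, collapse = "; ")))
  }
  invisible(as_mp_params(params))
}

#' @export
print.mp_params <- function(x, ...) {
  cat("<mp_params> modified Lotka-Volterra rate constants\n")
  NextMethod()
}
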