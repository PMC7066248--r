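#' Reference parameterisation and initial state
#'
#' The canonical rate constants and initial conditions of the study system:
#' a prey density of 100 and predator density of 10 No./m^3, both species
#' initially free of internal particles, and a constant environmental
#' concentration of 30 particles/m^3. Response intensities are zero here;
#' scenarios set them.
#'
#' @return A list with elements `params` (an [mp_params()] row) and `init`
#'   (named numeric state vector).
#' @examples
#' baseline_parameters()$params$k
#' @export
baseline_parameters <- function() {
  list(params = mp_params(),
       init = c(x1 = 100, x2 = 10, C1 = 0, C2 = 0))
}

#' Build one response-intensity condition
#'
#' The scenario grid is organised by the ratio `delta = r11 / r21` of the
#' two response intensities, with levels drawn from \{0.1, 1.0, 10.0\}:
#' \describe{
#'   \item{a}{no microplastic influence: `r11 = r21 = 0` and both internal
#'     burdens frozen at zero;}
#'   \item{b}{equal response strength, `delta = 1`;}
#'   \item{c}{predator responds much more strongly, `delta = 0.1`;}
#'   \item{d}{predator responds much less strongly, `delta = 10`.}
#' }
#'
#' @param label One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param r11,r21 Response intensities; must be consistent with the label's
#'   ratio (ignored and forced to zero for `"a"`).
#' @param t_end Integration horizon in months.
#' @param name Optional scenario name; a descriptive default is derived.
#' @return A one-row scenario tibble (class `mp_scenario`) with list-columns
#'   `params` and `init`.
#' @examples
#' make_condition("c", r11 = 1, r21 = 10)
#' @export
make_condition <- function(label, r11 = 0, r21 = 0, t_end = 10, name = NULL) {
  label <- match.arg(label, c("a", "b", "c", "d"))
  if (label == "a") {
    r11 <- 0; r21 <- 0
  } else {
    lv <- c(0.1, 1.0, 10.0)
    near <- function(x, y) abs(x - y) < 1e-12
    if (!any(vapply(lv, near, TRUE, x = r11)) ||
        !any(vapply(lv, near, TRUE, x = r21))) {
      abort("r11 and r21 must come from the level set {0.1, 1.0, 10.0}")
    }
    want <- c(b = 1.0, c = 0.1, d = 10.0)[[label]]
    if (!near(r11 / r21, want)) {
      abort(sprintf("condition %s requires r11/r21 = %g, got %g",
                    label, want, r11 / r21))
    }
  }
  base <- baseline_parameters()
  params <- mp_params(r11 = r11, r21 = r21)
  if (is.null(name)) {
    name <- if (label == "a") "condition_a" else {
      sprintf("condition_%s_r11_%g_r21_%g", label, r11, r21)
    }
  }
  new_scenario(name = name, label = label, r11 = r11, r21 = r21,
               params = params, init = base$init, t_end = t_end,
               freeze_toxin = (label == "a"), feeding_decline = FALSE,
               provenance = paste0("condition_", label))
}

new_scenario <- function(name, label, r11, r21, params, init, t_end,
                         freeze_toxin, feeding_decline, provenance) {
  delta <- if (r21 > 0) r11 / r21 else NA_real_
  out <- tibble(
    name = name, label = label, r11 = r11, r21 = r21, delta = delta,
    feeding_decline = feeding_decline, freeze_toxin = freeze_toxin,
    t_end = t_end, provenance = provenance,
    params = list(params), init = list(init)
  )
  class(out) <- c("mp_scenario", class(out))
  out
}

#' Feeding-decline parameter variant
#'
#' Returns a copy of a parameter set with the feeding-decline rates raised
#' to `d1 = 0.6`, `d2 = 0.012`, `d3 = 0.012` (impaired prey feeding and
#' predatory performance under heavy particle exposure); all other fields
#' are untouched and the effective rates stay positive
#' (`a1 - d3 = 0.04 > 0`). Idempotent.
#'
#' @inheritParams mp_derivatives
#' @return An [mp_params()] row.
#' @export
feeding_decline_variant <- function(params) {
  p <- as.list(as_mp_params(params))
  p$d1 <- 0.6; p$d2 <- 0.012; p$d3 <- 0.012
  do.call(mp_params, p[param_fields()])
}

#' The full scenario registry
#'
#' All eleven scenarios of the study design: the toxin-free reference
#' condition; equal-response condition b at levels (0.1, 0.1), (1, 1) and
#' (10, 10); predator-dominated-response condition c at (0.1, 1) and
#' (1, 10); prey-dominated-response condition d at (1, 0.1) and (10, 1);
#' and the three feeding-decline variants at the condition-b levels.
#'
#' @param t_end Integration horizon shared by all members (months).
#' @return A scenario tibble with 11 rows.
#' @export
campaign_scenarios <- function(t_end = 10) {
  grid <- list(
    make_condition("a", t_end = t_end),
    make_condition("b", 0.1, 0.1, t_end),
    make_condition("b", 1.0, 1.0, t_end),
    make_condition("b", 10.0, 10.0, t_end),
    make_condition("c", 0.1, 1.0, t_end),
    make_condition("c", 1.0, 10.0, t_end),
    make_condition("d", 1.0, 0.1, t_end),
    make_condition("d", 10.0, 1.0, t_end)
  )
  fd <- map(c(0.1, 1.0, 10.0), function(lev) {
    sc <- make_condition("b", lev, lev, t_end)
    sc$params[[1]] <- feeding_decline_variant(sc$params[[1]])
    sc$feeding_decline <- TRUE
    sc$name <- sprintf("feeding_decline_r11_%g_r21_%g", lev, lev)
    sc$provenance <- "feeding_decline_variant"
    sc
  })
  out <- list_rbind(c(grid, fd))
  class(out) <- c("mp_scenario", class(out))
  out
}

#' Seeded synthetic scenario ensemble
#'
#' Draws reproducible random parameter sets around the reference values:
#' response intensities log-uniform on `intensity_range` (spanning the three
#' decades the scenario grid uses), every other rate jittered uniformly by
#' `jitter` (a ±20% band by default, inside which all validation
#' constraints provably hold). The environmental concentration is jittered
#' too; initial densities are kept at the reference state.
#'
#' @param n Number of scenarios (>= 1).
#' @param seed Integer seed; the same seed reproduces the ensemble exactly.
#' @param intensity_range Length-2 positive range for the log-uniform draw
#'   of `r11` and `r21`.
#' @param jitter Half-width of the relative jitter band on the other rates
#'   (in \[0, 0.2\]; larger bands could flip the sign of an effective rate).
#' @param t_end Integration horizon (months).
#' @return A scenario tibble with `n` rows; every member passes
#'   [validate_params()].
#' @export
random_ensemble <- function(n, seed, intensity_range = c(0.01, 20),
                            jitter = 0.2, t_end = 10) {
  if (!is.numeric(n) || n < 1) abort("n must be at least 1")
  if (length(intensity_range) != 2 || any(intensity_range <= 0) ||
      diff(intensity_range) < 0) {
    abort("intensity_range must be a positive increasing pair")
  }
  if (jitter < 0 || jitter > 0.2) {
    abort("jitter must lie in [0, 0.2] to respect the validation constraints")
  }
  n <- as.integer(n)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))

  base <- as.list(baseline_parameters()$params)
  jit_fields <- c("r10", "r20", "a1", "a2", "d1", "d2", "d3",
                  "S1", "S2", "g1", "g2", "k", "CE")
  rows <- map(seq_len(n), function(i) {
    p <- base
    p$r11 <- exp(runif(1, log(intensity_range[1]), log(intensity_range[2])))
    p$r21 <- exp(runif(1, log(intensity_range[1]), log(intensity_range[2])))
    for (f in jit_fields) {
      p[[f]] <- base[[f]] * runif(1, 1 - jitter, 1 + jitter)
    }
    params <- do.call(mp_params, p[param_fields()])
    assert_valid_params(params)
    new_scenario(
      name = sprintf("ensemble_%03d", i), label = "ensemble",
      r11 = p$r11, r21 = p$r21, params = params,
      init = baseline_parameters()$init, t_end = t_end,
      freeze_toxin = FALSE, feeding_decline = FALSE,
      provenance = sprintf("seed_%d", as.integer(seed))
    )
  })
  out <- list_rbind(rows)
  class(out) <- c("mp_scenario", class(out))
  out
}

#' Simulate one scenario row
#'
#' @param scenario A one-row scenario tibble.
#' @param settings A [solver_settings()] list.
#' @return An `mp_trajectory`.
#' @export
simulate_scenario <- function(scenario, settings = solver_settings()) {
  stopifnot(nrow(scenario) == 1)
  simulate_mp(scenario$params[[1]], init = scenario$init[[1]],
              t_end = scenario$t_end, settings = settings,
              freeze_toxin = scenario$freeze_toxin)
}

#' Run a scenario campaign
#'
#' Integrates every scenario and summarises each trajectory. Deterministic
#' given the solver settings.
#'
#' @param scenarios A scenario tibble ([campaign_scenarios()],
#'   [random_ensemble()] or hand-built rows).
#' @param settings A [solver_settings()] list.
#' @param keep_trajectories Keep the full trajectories in a list-column
#'   (off by default; the dense grids are large).
#' @return A tibble of class `mp_sweep`: one row per scenario carrying its
#'   design columns, the outcome label, period, extinction times, first and
#'   global peaks, and a `summary` list-column with the full
#'   [summarize_trajectory()] row (plus `trajectory` when kept).
#' @export
run_campaign <- function(scenarios, settings = solver_settings(),
                         keep_trajectories = FALSE) {
  if (nrow(scenarios) == 0) abort("no scenarios to run")
  rows <- map(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    traj <- tryCatch(
      simulate_scenario(sc, settings),
      error = function(e) {
        abort(paste0("scenario '", sc$name, "': ", conditionMessage(e)))
      }
    )
    sm <- summarize_trajectory(traj)
    out <- tibble(
      name = sc$name, label = sc$label, r11 = sc$r11, r21 = sc$r21,
      delta = sc$delta, feeding_decline = sc$feeding_decline,
      outcome = sm$outcome, period = sm$period,
      extinction_x1 = sm$extinction_x1, extinction_x2 = sm$extinction_x2,
      first_max_x1 = sm$first_max_x1, first_max_x2 = sm$first_max_x2,
      max_x1 = sm$max_x1, max_x2 = sm$max_x2,
      t_global_max_x1 = sm$t_global_max_x1,
      provenance = sc$provenance,
      params = sc$params,
      summary = list(sm)
    )
    if (keep_trajectories) out$trajectory <- list(traj)
    out
  })
  out <- list_rbind(rows)
  attr(out, "settings") <- settings
  class(out) <- c("mp_sweep", class(out))
  out
}
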