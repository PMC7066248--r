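#' Tidy a trajectory into long form
#'
#' @param x An `mp_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `t`, `series`, `value` (all four state
#'   components).
#' @method tidy mp_trajectory
#' @export
tidy.mp_trajectory <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(as.data.frame(x)),
                      cols = -"t", names_to = "series", values_to = "value")
}

#' One-row overview of a trajectory
#'
#' @param x An `mp_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: grid size, horizon, final state, number of
#'   threshold-crossing events.
#' @method glance mp_trajectory
#' @export
glance.mp_trajectory <- function(x, ...) {
  n <- nrow(x)
  ev <- attr(x, "events")
  tibble(
    n_grid = n, t_end = x$t[n],
    x1_final = x$x1[n], x2_final = x$x2[n],
    C1_final = x$C1[n], C2_final = x$C2[n],
    n_events = if (is.null(ev)) 0L else nrow(ev)
  )
}

#' Extrema table of a trajectory summary
#'
#' @param x An `mp_summary`.
#' @param ... Unused.
#' @return The `extrema` tibble (`series`, `time`, `value`, `kind`).
#' @method tidy mp_summary
#' @export
tidy.mp_summary <- function(x, ...) {
  x$extrema[[1]]
}

#' One-row overview of a trajectory summary
#'
#' @param x An `mp_summary`.
#' @param ... Unused.
#' @return The scalar summary columns (no list-columns).
#' @method glance mp_summary
#' @export
glance.mp_summary <- function(x, ...) {
  out <- as_tibble(as.data.frame(x[setdiff(names(x), "extrema")]))
  out
}

#' Per-scenario table of a sweep result
#'
#' @param x An `mp_sweep`.
#' @param ... Unused.
#' @return The scalar per-scenario columns (no list-columns).
#' @method tidy mp_sweep
#' @export
tidy.mp_sweep <- function(x, ...) {
  keep <- setdiff(names(x), c("summary", "trajectory", "params"))
  as_tibble(as.data.frame(x[keep]))
}

#' Outcome counts of a sweep result
#'
#' @param x An `mp_sweep`.
#' @param ... Unused.
#' @return A one-row tibble with scenario and outcome counts.
#' @method glance mp_sweep
#' @export
glance.mp_sweep <- function(x, ...) {
  tibble(
    n_scenarios = nrow(x),
    n_coexistence = sum(x$outcome == "coexistence"),
    n_predator_extinct = sum(x$outcome == "predator_extinct"),
    n_both_extinct = sum(x$outcome == "both_extinct")
  )
}
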