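# Independent oracles used across the suite.

# Prey-density extremes of the toxin-free closed orbit, from the conserved
# quantity: x1 is extremal where the orbit crosses x2 = x2*, so the extremes
# are the two roots of (a2-d2) x - r20 log(x) = H0 - [(a1-d3) x2* -
# (r10-d1) log(x2*)], found by bisection.
orbit_extremes <- function(params, x1_0, x2_0) {
  eq <- lv_equilibrium(params)
  H0 <- lv_invariant(x1_0, x2_0, params)
  rhs <- H0 - ((params$a1 - params$d3) * eq$x2 -
                 (params$r10 - params$d1) * log(eq$x2))
  f <- function(x) (params$a2 - params$d2) * x - params$r20 * log(x) - rhs
  c(
    lower = uniroot(f, c(1e-10, eq$x1), tol = 1e-12)$root,
    upper = uniroot(f, c(eq$x1, 1e10), tol = 1e-12)$root
  )
}

# Plain fixed-step classical RK4 on the projected vector field; independent
# of the adaptive integration path used by simulate_mp().
rk4_trajectory <- function(params, init, t_end, h, freeze_toxin = FALSE) {
  f <- function(y) {
    raw <- unlist(mp_derivatives(
      c(x1 = y[1], x2 = y[2], C1 = y[3], C2 = y[4]), params
    ))
    if (freeze_toxin) raw[3:4] <- 0
    project_rates(y, raw)
  }
  n <- ceiling(t_end / h)
  out <- matrix(NA_real_, n + 1, 5)
  y <- unname(init)
  out[1, ] <- c(0, y)
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(pmax(y + h / 2 * k1, 0))
    k3 <- f(pmax(y + h / 2 * k2, 0))
    k4 <- f(pmax(y + h * k3, 0))
    y <- pmax(y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    out[i + 1, ] <- c(i * h, y)
  }
  colnames(out) <- c("t", "x1", "x2", "C1", "C2")
  tibble::as_tibble(out)
}

# coarse settings used where the property under test tolerates them
coarse_settings <- function(...) {
  solver_settings(rtol = 1e-6, atol = 1e-8, dt_out = 0.01, ...)
}

# synthetic trajectory-like table for summary-level unit tests
fake_traj <- function(t, x1, x2) {
  tibble::tibble(t = t, x1 = x1, x2 = x2,
                 C1 = rep(0, length(t)), C2 = rep(0, length(t)))
}
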