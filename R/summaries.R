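#' Locate prominent local extrema of simulated series
#'
#' Finds alternating local maxima and minima of one or more columns of a
#' trajectory, discards oscillations whose vertical extent is below
#' `prominence_fraction` of the series' global range (suppressing
#' solver-grid wiggles), and refines each surviving extremum by a quadratic
#' fit through the three bracketing samples.
#'
#' @param data A data frame with a time column and one column per series
#'   (typically an `mp_trajectory`).
#' @param series Character vector of series columns to scan.
#' @param time_col Name of the time column.
#' @param prominence_fraction Minimum vertical extent of a retained
#'   oscillation, as a fraction of the series' global range (in (0, 1)).
#' @return A tibble with columns `series`, `time`, `value`, `kind`
#'   (`"max"`/`"min"`), times strictly increasing and kinds alternating
#'   within each series.
#' @export
find_extrema <- function(data, series = c("x1", "x2"), time_col = "t",
                         prominence_fraction = 0.01) {
  stopifnot(prominence_fraction > 0, prominence_fraction < 1)
  if (nrow(data) < 3) abort("need at least 3 samples to locate extrema")
  t <- data[[time_col]]
  out <- map(series, function(nm) {
    ex <- locate_extrema(t, data[[nm]], prominence_fraction)
    if (nrow(ex) > 0) ex$series <- nm
    ex
  })
  res <- list_rbind(out)
  if (nrow(res) == 0) {
    return(tibble(series = character(), time = double(), value = double(),
                  kind = character()))
  }
  select(res, "series", "time", "value", "kind")
}

# core extremum finder for one series; returns tibble(time, value, kind)
locate_extrema <- function(t, v, prominence_fraction) {
  n <- length(v)
  d <- diff(v)
  s <- sign(d)
  # carry direction across flat segments
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  turn <- which(s[-1] != 0 & s[-length(s)] != 0 & s[-1] != s[-length(s)]) + 1L
  if (length(turn) == 0) {
    return(tibble(time = double(), value = double(), kind = character()))
  }
  kind <- ifelse(s[turn - 1L] > 0, "max", "min")
  # prune low-prominence wiggles: repeatedly delete the adjacent
  # (max, min) pair with the smallest vertical extent
  thr <- prominence_fraction * diff(range(v))
  idx <- turn
  while (length(idx) >= 2) {
    gaps <- abs(v[idx[-1]] - v[idx[-length(idx)]])
    jmin <- which.min(gaps)
    if (gaps[jmin] >= thr) break
    idx <- idx[-c(jmin, jmin + 1L)]
    kind <- kind[-c(jmin, jmin + 1L)]
  }
  if (length(idx) == 0) {
    return(tibble(time = double(), value = double(), kind = character()))
  }
  refined <- map(seq_along(idx), function(j) refine_quadratic(t, v, idx[j]))
  tibble(time = map_dbl(refined, 1), value = map_dbl(refined, 2), kind = kind)
}

# vertex of the parabola through the three samples bracketing index i
refine_quadratic <- function(t, v, i) {
  if (i <= 1L || i >= length(t)) return(c(t[i], v[i]))
  t1 <- t[i - 1]; t2 <- t[i]; t3 <- t[i + 1]
  v1 <- v[i - 1]; v2 <- v[i]; v3 <- v[i + 1]
  den <- v1 * (t2 - t3) + v2 * (t3 - t1) + v3 * (t1 - t2)
  if (abs(den) < .Machine$double.eps * max(abs(c(v1, v2, v3)), 1)) {
    return(c(t2, v2))
  }
  ts <- (v1 * (t2^2 - t3^2) + v2 * (t3^2 - t1^2) + v3 * (t1^2 - t2^2)) /
    (2 * den)
  # Lagrange evaluation at the vertex
  vs <- v1 * (ts - t2) * (ts - t3) / ((t1 - t2) * (t1 - t3)) +
    v2 * (ts - t1) * (ts - t3) / ((t2 - t1) * (t2 - t3)) +
    v3 * (ts - t1) * (ts - t2) / ((t3 - t1) * (t3 - t2))
  c(ts, vs)
}

#' Oscillation period from a peak list
#'
#' Mean spacing between consecutive local maxima of one series; `NA` when
#' fewer than two maxima exist. The prey series is used by default (at the
#' symmetric reference rates prey and predator periods coincide).
#'
#' @param extrema A peak list from [find_extrema()].
#' @param series Which series' maxima to use.
#' @return Period in months, or `NA`.
#' @export
estimate_period <- function(extrema, series = "x1") {
  tm <- extrema$time[extrema$series == series & extrema$kind == "max"]
  if (length(tm) < 2) return(NA_real_)
  mean(diff(tm))
}

#' Operational extinction time of a series
#'
#' Earliest time after which the series stays below `threshold` until the
#' end of the record (crossing time linearly interpolated); `NA` if the
#' series ends at or above the threshold. Monotone nonincreasing in the
#' threshold.
#'
#' @param t,v Equal-length time and value vectors.
#' @param threshold Nonnegative density threshold.
#' @return Time in months, or `NA`.
#' @export
extinction_time <- function(t, v, threshold = 1e-3) {
  stopifnot(length(t) == length(v), threshold >= 0)
  n <- length(v)
  if (v[n] >= threshold) return(NA_real_)
  above <- which(v >= threshold)
  if (length(above) == 0) return(t[1])
  i <- max(above)            # last sample at/above the threshold
  t[i] + (v[i] - threshold) / (v[i] - v[i + 1]) * (t[i + 1] - t[i])
}

#' Qualitative outcome of a simulated run
#'
#' Labels a trajectory `"coexistence"`, `"predator_extinct"` or
#' `"both_extinct"`. A species counts as extinction-bound within the window
#' when any of three signals fires:
#' \enumerate{
#'   \item threshold crossing: it falls below the extinction threshold and
#'     stays there to the end ([extinction_time()] is finite);
#'   \item terminal collapse: it declines monotonically from its last
#'     maximum to below `collapse_fraction` of its global maximum, for
#'     longer than its own mean peak spacing (a non-oscillatory crash that
#'     has not yet reached the threshold; the duration guard keeps the
#'     descending phase of a still-cycling series from counting);
#'   \item oscillatory decay: its last `min_troughs`-or-more troughs are
#'     strictly decreasing, the final trough is at most `trough_decay`
#'     times the first of that run, and its peak envelope has not grown by
#'     more than `peak_growth_cap` over the same span (a growing peak
#'     envelope signals a persisting, amplifying cycle rather than decay).
#' }
#' A prey-only extinction signal is labelled `"both_extinct"`: with the
#' prey gone the predator has no food source and follows.
#'
#' @param traj An `mp_trajectory`.
#' @param extrema Optional precomputed [find_extrema()] table for `traj`.
#' @param threshold Extinction threshold; defaults to the trajectory's
#'   solver setting.
#' @param collapse_fraction,trough_decay,peak_growth_cap,min_troughs
#'   Constants of the collapse/decay signals (see above).
#' @return A single string.
#' @export
classify_outcome <- function(traj, extrema = NULL, threshold = NULL,
                             collapse_fraction = 0.05, trough_decay = 0.5,
                             peak_growth_cap = 1.5, min_troughs = 3) {
  if (is.null(threshold)) {
    st <- attr(traj, "settings")
    threshold <- if (is.null(st)) 1e-3 else st$extinction_threshold
  }
  if (is.null(extrema)) extrema <- find_extrema(traj)
  flag <- function(sp) {
    species_extinct(traj$t, traj[[sp]],
                    extrema[extrema$series == sp, , drop = FALSE],
                    threshold, collapse_fraction, trough_decay,
                    peak_growth_cap, min_troughs)
  }
  prey <- flag("x1"); pred <- flag("x2")
  if (prey) "both_extinct" else if (pred) "predator_extinct" else "coexistence"
}

species_extinct <- function(t, v, ex, threshold, collapse_fraction,
                            trough_decay, peak_growth_cap, min_troughs) {
  if (!is.na(extinction_time(t, v, threshold))) return(TRUE)
  # terminal collapse: monotone slide from the last peak to near zero,
  # lasting longer than one oscillation spacing (so the descending phase of
  # a still-cycling series does not count)
  vmax <- max(v)
  tmax <- ex$time[ex$kind == "max"]
  t_from <- if (length(tmax) > 0) max(tmax) else t[which.max(v)]
  long_enough <- length(tmax) < 2 ||
    (t[length(t)] - t_from) > mean(diff(tmax))
  seg <- v[t >= t_from]
  if (long_enough && length(seg) >= 2 &&
      v[length(v)] < collapse_fraction * vmax &&
      all(diff(seg) <= 1e-9 * vmax)) {
    return(TRUE)
  }
  # oscillatory decay: troughs sliding toward zero without a growing peak
  mins <- ex[ex$kind == "min", , drop = FALSE]
  maxs <- ex[ex$kind == "max", , drop = FALSE]
  if (nrow(mins) >= min_troughs) {
    dec <- diff(mins$value) < 0
    run <- 0L
    for (ok in rev(dec)) { if (ok) run <- run + 1L else break }
    if (run + 1L >= min_troughs) {
      first <- mins$value[nrow(mins) - run]
      last <- mins$value[nrow(mins)]
      span_maxs <- maxs$value[maxs$time >= mins$time[nrow(mins) - run]]
      peak_ok <- length(span_maxs) == 0 ||
        max(span_maxs) <= peak_growth_cap * span_maxs[1]
      if (last <= trough_decay * first && peak_ok) return(TRUE)
    }
  }
  FALSE
}

#' Relative drift of the toxin-free first integral
#'
#' Evaluates [lv_invariant()] along a trajectory and reports its spread
#' normalised by the orbit's depth below the equilibrium value of `H`
#' (`H` is minimal at the coexistence fixed point, so
#' `mean(H) - H(equilibrium)` measures how far the orbit sits above the
#' bottom of the well). For a toxin-free run this is a pure
#' integration-accuracy diagnostic and should be tiny; with active toxin
#' terms `H` is not conserved and the value is large. A constant trajectory
#' at the fixed point yields exactly 0.
#'
#' @param traj An `mp_trajectory` with strictly positive densities.
#' @param params Parameter set; defaults to the trajectory's own.
#' @return A nonnegative scalar.
#' @export
invariant_drift <- function(traj, params = attr(traj, "params")) {
  H <- lv_invariant(traj$x1, traj$x2, params)
  spread <- max(H) - min(H)
  if (spread == 0) return(0)
  eq <- lv_equilibrium(params)
  depth <- mean(H) - lv_invariant(eq$x1, eq$x2, params)
  spread / depth
}

#' Summarise one trajectory
#'
#' Extracts the quantities the scenario analysis reports: peak/trough lists
#' for both species, the prey oscillation period, operational extinction
#' times, per-series ranges, first and global maxima, and the qualitative
#' outcome label.
#'
#' @inheritParams classify_outcome
#' @param prominence_fraction Passed to [find_extrema()].
#' @return A one-row tibble of class `mp_summary` with an `extrema`
#'   list-column holding the full peak table.
#' @export
summarize_trajectory <- function(traj, prominence_fraction = 0.01,
                                 threshold = NULL) {
  if (is.null(threshold)) {
    st <- attr(traj, "settings")
    threshold <- if (is.null(st)) 1e-3 else st$extinction_threshold
  }
  ex <- find_extrema(traj, prominence_fraction = prominence_fraction)
  fm <- function(sp) {
    m <- ex[ex$series == sp & ex$kind == "max", , drop = FALSE]
    if (nrow(m) == 0) NA_real_ else m$value[1]
  }
  # time of the prey's global maximum, quadratically refined when it is a
  # proper interior peak
  gm <- ex[ex$series == "x1" & ex$kind == "max", , drop = FALSE]
  t_gmax <- if (nrow(gm) > 0 && max(gm$value) >= max(traj$x1) * (1 - 1e-9)) {
    gm$time[which.max(gm$value)]
  } else {
    traj$t[which.max(traj$x1)]
  }
  out <- tibble(
    outcome = classify_outcome(traj, extrema = ex, threshold = threshold),
    period = estimate_period(ex, series = "x1"),
    extinction_x1 = extinction_time(traj$t, traj$x1, threshold),
    extinction_x2 = extinction_time(traj$t, traj$x2, threshold),
    min_x1 = min(traj$x1), max_x1 = max(traj$x1),
    min_x2 = min(traj$x2), max_x2 = max(traj$x2),
    first_max_x1 = fm("x1"), first_max_x2 = fm("x2"),
    t_global_max_x1 = t_gmax,
    n_max_x1 = sum(ex$series == "x1" & ex$kind == "max"),
    n_max_x2 = sum(ex$series == "x2" & ex$kind == "max"),
    extrema = list(ex)
  )
  class(out) <- c("mp_summary", class(out))
  out
}
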