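#' Read a run configuration file
#'
#' Parses a YAML run configuration. Recognised top-level keys:
#' \describe{
#'   \item{`scenario`}{a registry scenario name, a vector of names, or
#'     `"campaign"` for the whole registry;}
#'   \item{`ensemble`}{a block with `n` and (mandatory) `seed` requesting a
#'     synthetic ensemble instead of registry scenarios;}
#'   \item{`solver`}{a block overriding [solver_settings()] fields;}
#'   \item{model parameter names}{any field of [mp_params()] as a flat
#'     override applied to every selected scenario;}
#'   \item{`t_end`, `output_dir`, `outputs`}{horizon, destination directory
#'     and which artifacts to write (`"trajectory"`, `"summary"`,
#'     `"plots"`).}
#' }
#' Unknown keys are rejected by name.
#'
#' @param path Path to a YAML file.
#' @return A validated config list of class `mp_run_config`.
#' @seealso [config_scenarios()]
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  # keep keys like `n` literal (YAML 1.1 would read them as booleans)
  raw <- yaml::read_yaml(path, handlers = list("bool#yes" = identity,
                                               "bool#no" = identity))
  if (!is.list(raw)) abort("config must be a key-value document")
  known <- c("scenario", "ensemble", "solver", "t_end", "output_dir",
             "outputs", param_fields())
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  solver <- raw$solver %||% list()
  bad <- setdiff(names(solver), names(formals(solver_settings)))
  if (length(bad) > 0) {
    abort(paste0("unknown solver key(s): ", paste(bad, collapse = ", ")))
  }
  settings <- do.call(solver_settings, solver)
  ensemble <- raw$ensemble
  if (!is.null(ensemble)) {
    if (is.null(ensemble$n)) abort("ensemble block requires n")
    if (is.null(ensemble$seed)) abort("ensemble block requires a seed")
  }
  if (is.null(raw$scenario) && is.null(ensemble)) {
    abort("config must select a scenario, 'campaign', or an ensemble")
  }
  overrides <- raw[intersect(names(raw), param_fields())]
  out <- list(
    scenario = raw$scenario,
    ensemble = ensemble,
    settings = settings,
    t_end = raw$t_end %||% 10,
    overrides = overrides,
    output_dir = raw$output_dir %||% ".",
    outputs = raw$outputs %||% c("trajectory", "summary")
  )
  class(out) <- "mp_run_config"
  out
}

#' Resolve a run configuration to scenario rows
#'
#' @param config An `mp_run_config` from [read_run_config()].
#' @return A scenario tibble with at least one row.
#' @export
config_scenarios <- function(config) {
  stopifnot(inherits(config, "mp_run_config"))
  sc <- if (!is.null(config$ensemble)) {
    random_ensemble(config$ensemble$n, config$ensemble$seed,
                    t_end = config$t_end)
  } else if (identical(config$scenario, "campaign")) {
    campaign_scenarios(t_end = config$t_end)
  } else {
    reg <- campaign_scenarios(t_end = config$t_end)
    hit <- reg[reg$name %in% config$scenario, , drop = FALSE]
    if (nrow(hit) != length(unique(config$scenario))) {
      missing <- setdiff(config$scenario, reg$name)
      abort(paste0("unknown scenario name(s): ",
                   paste(missing, collapse = ", ")))
    }
    hit
  }
  if (length(config$overrides) > 0) {
    for (i in seq_len(nrow(sc))) {
      p <- as.list(sc$params[[i]])
      p[names(config$overrides)] <- config$overrides
      sc$params[[i]] <- do.call(mp_params, p[param_fields()])
      sc$r11 <- sc$params[[i]]$r11
      sc$r21 <- sc$params[[i]]$r21
    }
  }
  sc
}

#' Write / read a trajectory table
#'
#' Plain comma-delimited text with header `t,x1,x2,C1,C2`, one row per
#' dense-grid point, written at 17 significant digits so that
#' `read_trajectory()` recovers every double bit-exactly.
#'
#' @param traj An `mp_trajectory` (or any data frame with those columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (is.null(traj) || nrow(traj) == 0) abort("empty trajectory")
  cols <- c("t", state_fields())
  if (!all(cols %in% names(traj))) {
    abort("trajectory must have columns t, x1, x2, C1, C2")
  }
  num <- as.data.frame(traj)[cols]
  # 17 significant digits: exact binary round trip through the reader
  txt <- vapply(num, function(col) sprintf("%.17g", col), character(nrow(num)))
  lines <- c(paste(cols, collapse = ","),
             apply(matrix(txt, ncol = length(cols)), 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  out <- as_tibble(utils::read.csv(path, colClasses = "numeric"))
  if (!all(c("t", state_fields()) %in% names(out))) {
    abort("file is not a trajectory table (t,x1,x2,C1,C2)")
  }
  class(out) <- c("mp_trajectory", class(out))
  out
}

#' Write / read a campaign summary document
#'
#' Serialises a sweep result to a nested key-value (YAML) document: one
#' block per scenario with its parameters, intensity ratio, peak tables,
#' period, extinction times and outcome label, plus the solver settings and
#' package version used.
#'
#' @param sweep An `mp_sweep` from [run_campaign()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(sweep, path) {
  if (is.null(sweep) || nrow(sweep) == 0) abort("empty sweep result")
  settings <- attr(sweep, "settings")
  num <- function(x) if (is.na(x)) NULL else as.double(x)
  scen <- map(seq_len(nrow(sweep)), function(i) {
    row <- sweep[i, ]
    ex <- row$summary[[1]]$extrema[[1]]
    peaks <- function(sp, kd) {
      sub <- ex[ex$series == sp & ex$kind == kd, , drop = FALSE]
      list(time = as.double(sub$time), value = as.double(sub$value))
    }
    list(
      name = row$name,
      label = row$label,
      provenance = row$provenance,
      parameters = lapply(as.list(row$params[[1]]), as.double),
      delta = num(row$delta),
      outcome = row$outcome,
      period = num(row$period),
      extinction_time = list(x1 = num(row$extinction_x1),
                             x2 = num(row$extinction_x2)),
      peaks = list(x1 = peaks("x1", "max"), x2 = peaks("x2", "max")),
      troughs = list(x1 = peaks("x1", "min"), x2 = peaks("x2", "min"))
    )
  })
  doc <- list(
    software = list(package = "mplv",
                    version = as.character(utils::packageVersion("mplv"))),
    solver = unclass(settings),
    n_scenarios = nrow(sweep),
    scenarios = scen
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_summary
#' @export
read_run_summary <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$scenarios)) abort("file is not a run summary document")
  num <- function(x) if (is.null(x)) NA_real_ else as.double(x)
  rows <- map(doc$scenarios, function(s) {
    tibble(
      name = s$name, label = s$label, provenance = s$provenance,
      r11 = num(s$parameters$r11), r21 = num(s$parameters$r21),
      delta = num(s$delta), outcome = s$outcome, period = num(s$period),
      extinction_x1 = num(s$extinction_time$x1),
      extinction_x2 = num(s$extinction_time$x2),
      params = list(do.call(mp_params, s$parameters[param_fields()])),
      peaks_x1 = list(tibble(time = as.double(s$peaks$x1$time),
                             value = as.double(s$peaks$x1$value))),
      peaks_x2 = list(tibble(time = as.double(s$peaks$x2$time),
                             value = as.double(s$peaks$x2$value)))
    )
  })
  out <- list_rbind(rows)
  attr(out, "solver") <- doc$solver
  out
}
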