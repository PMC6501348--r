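## Run configuration, named presets matching the published study
## conditions, and the dispatcher that turns a validated configuration into
## trajectory + report artifacts.

## Frozen study conditions. Full-protocol run lengths are kept as stated;
## callers scale `tmax` down for desk-scale work via overrides.
.presets <- list(
  langevin_benchmark = list(
    model = "langevin", M = 1, D = 1, gamma = 10, k = 1e6, ell0 = 0.32,
    dt = 1e-4, tmax = 200, sample_interval = 1e-3, burn_in = NA),
  ## NOTE: at L = 0.72 the per-step boundary-influx probability bound
  ## (6 p_in <= 0.1) forces a step below 1e-6; the preset uses 2.5e-7.
  short_range_one_bath = list(
    model = "short_range", mode = "one_bath", r0 = 0.08, mu = 1e3,
    gamma = 10, D = 1, M = 1, k = 1e6, ell0 = 4 * 0.08, L = 0.72,
    dt = 2.5e-7, tmax = 100, sample_interval = 1e-3, burn_in = NA),
  short_range_two_bath = list(
    model = "short_range", mode = "two_bath", r0 = 0.08, mu = 1e3,
    gamma = 10, D = 1, M = 1, k = 1e6, ell0 = 4 * 0.08, L = 0.32,
    dt = 1e-6, tmax = 100, sample_interval = 1e-3, burn_in = NA),
  short_range_mixed = list(
    model = "short_range", mode = "mixed", r0 = 0.08, mu = 1e3,
    gamma = 10, D = 1, M = 1, k = 1e6, ell0 = 4 * 0.08, L = 0.32,
    dt = 1e-6, tmax = 500, sample_interval = 1e-3, burn_in = NA),
  long_range_two_bath = list(
    model = "long_range", mode = "two_bath", M = 1, m = 1e-3, gamma = 10,
    D = 1, k = 1e6, ell0 = 4 * 0.08, N = 1e4, omega_bar = 100, dt = NA,
    tmax = 200, sample_interval = 1e-3, burn_in = 100),
  long_range_shared = list(
    model = "long_range", mode = "shared", M = 1, m = 1e-3, gamma = 10,
    D = 1, k = 1e6, ell0 = 4 * 0.08, N = 1e4, omega_bar = 100, dt = NA,
    tmax = 200, sample_interval = 1e-3, burn_in = 100),
  long_range_split = list(
    model = "long_range", mode = "split", M = 1, m = 1e-3, gamma = 10,
    D = 1, k = 1e6, ell0 = 4 * 0.08, N = 1e4, N1 = 5e3, omega_bar = 100,
    dt = NA, tmax = 200, sample_interval = 1e-3, burn_in = 100),
  long_range_mixed = list(
    model = "long_range", mode = "mixed", M = 1, m = 1e-3, gamma = 10,
    D = 1, k = 1e6, ell0 = 0.32, N = 1e5, omega_bar = 100, dt = NA,
    tmax = 1000, sample_interval = 1e-3, burn_in = NA)
)

#' Names of the shipped presets
#' @export
preset_names <- function() names(.presets)

#' Build a validated run configuration
#'
#' @param model `"langevin"`, `"short_range"` or `"long_range"`.
#' @param ... model parameters (see the presets returned by
#'   [load_run_config()] for the recognized fields).
#' @param seed integer seed.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(model, ..., seed = 1L) {
  cfg <- c(list(model = model), list(...))
  cfg$seed <- as.integer(seed)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (!cfg$model %in% c("langevin", "short_range", "long_range"))
    stopf("unknown model `%s`", cfg$model)
  for (f in c("gamma", "D", "M", "k", "ell0", "tmax"))
    if (is.null(cfg[[f]])) stopf("config misses required field `%s`", f)
  if (cfg$model == "short_range") {
    if (is.null(cfg$r0) || is.null(cfg$mu) || is.null(cfg$L))
      stopf("short_range config needs r0, mu and L")
    if (cfg$L <= 2 * cfg$r0)
      stopf("constraint violated: L = %g must exceed 2 * r0 = %g",
            cfg$L, 2 * cfg$r0)
    if (!is.null(cfg$dt) && is.finite(cfg$dt)) {
      if (cfg$dt <= 0) stopf("dt must be positive")
      bath <- short_range_bath_params(cfg$r0, cfg$mu, cfg$gamma, cfg$D,
                                      cfg$M)
      ## static bound on the insertion probability (frame at rest)
      p0 <- bath$lambda_mu * cfg$L^2 * cfg$dt * bath$sigma_mu / sqrt(2 * pi)
      if (6 * p0 > 0.1)
        stopf("constraint violated: 6 * p_in = %.3g > 0.1 at dt = %g; reduce dt",
              6 * p0, cfg$dt)
    }
  }
  if (cfg$model == "long_range") {
    if (is.null(cfg$N) || is.null(cfg$omega_bar) || is.null(cfg$m))
      stopf("long_range config needs N, omega_bar and m")
    if (!is.na(cfg$dt %||% NA) && cfg$dt * cfg$omega_bar > 0.5)
      stopf("constraint violated: dt * omega_bar = %.3g too large",
            cfg$dt * cfg$omega_bar)
  }
  if (cfg$model == "langevin" && cfg$dt * cfg$gamma >= 1)
    stopf("constraint violated: dt * gamma >= 1")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a preset name or JSON file
#'
#' Presets freeze the published study conditions (frame sizes, densities,
#' steps, run lengths). A JSON file may set `preset` to inherit one and
#' override individual fields; `overrides` does the same programmatically.
#'
#' @param source preset name (see [preset_names()]) or path to a JSON file.
#' @param overrides named list of fields replacing the loaded values.
#' @param seed integer seed stored in the configuration.
#' @return A validated `"run_config"`.
#' @examples
#' cfg <- load_run_config("short_range_two_bath",
#'                        overrides = list(tmax = 1), seed = 7)
#' @export
load_run_config <- function(source, overrides = list(), seed = 1L) {
  if (source %in% names(.presets)) {
    cfg <- .presets[[source]]
    cfg$preset <- source
  } else if (file.exists(source)) {
    cfg <- jsonlite::read_json(source, simplifyVector = TRUE)
    if (!is.null(cfg$preset)) {
      if (!cfg$preset %in% names(.presets))
        stopf("unknown preset `%s` in %s", cfg$preset, source)
      cfg <- modifyList(.presets[[cfg$preset]], cfg)
    }
  } else {
    stopf("`%s` is neither a preset name nor an existing file", source)
  }
  cfg <- modifyList(cfg, overrides)
  cfg$seed <- as.integer(seed)
  cfg[vapply(cfg, function(x) length(x) == 1L && is.na(x), logical(1))] <-
    NULL
  validate_run_config(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run config: model = %s%s, tmax = %g, seed = %d\n",
              x$model,
              if (!is.null(x$mode)) paste0(" (", x$mode, ")") else "",
              x$tmax, x$seed))
  invisible(x)
}

#' Execute a run configuration
#'
#' Dispatches to the matching simulator, then computes the standard summary
#' report (mean length with confidence interval; VACF-integral diffusion
#' constant when the run is long enough). Optionally writes the trajectory
#' (CSV + JSON metadata) and the report (JSON).
#'
#' @param cfg a `"run_config"`.
#' @param out optional output path stem; writes `<out>.csv`,
#'   `<out>.csv.meta.json` and `<out>.report.json`.
#' @return List with `trajectory` and `report`.
#' @export
run_simulation <- function(cfg, out = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  spring <- spring_params(cfg$k, cfg$ell0)
  p <- langevin_params(cfg$M, cfg$D, cfg$gamma)
  traj <- switch(cfg$model,
    langevin = simulate_langevin_dimer(
      spring, p, tmax = cfg$tmax, dt = cfg$dt, seed = cfg$seed,
      sample_interval = cfg$sample_interval %||% 1e-3),
    short_range = simulate_short_range(
      spring, short_range_bath_params(cfg$r0, cfg$mu, cfg$gamma, cfg$D,
                                      cfg$M),
      L = cfg$L, tmax = cfg$tmax, dt = cfg$dt, seed = cfg$seed,
      mode = cfg$mode, sample_interval = cfg$sample_interval %||% 1e-3),
    long_range = simulate_long_range(
      spring, p, N = cfg$N, omega_bar = cfg$omega_bar, m = cfg$m,
      tmax = cfg$tmax, seed = cfg$seed, mode = cfg$mode,
      dt = cfg$dt %||% NULL, N1 = cfg$N1 %||% NULL,
      sample_interval = cfg$sample_interval %||% 1e-3))
  burn <- cfg$burn_in %||% (cfg$tmax / 2)
  len <- estimate_mean_length(traj, burn_in = burn)
  report <- list(model = traj$model, seed = cfg$seed,
                 L_d = len$L_d, L_d_ci = len$ci,
                 config = serialize_params(unclass(cfg)))
  span <- cfg$tmax - burn
  if (span >= 1) {
    vacf <- estimate_vacf(traj, max_lag = min(1, span / 2), burn_in = burn)
    report$D_d <- diffusion_from_vacf(vacf, upper = max(vacf$lags))
    report$D_d_upper <- max(vacf$lags)
  }
  if (!is.null(out)) {
    write_trajectory(traj, paste0(out, ".csv"))
    jsonlite::write_json(report, paste0(out, ".report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(trajectory = traj, report = report)
}
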