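#' Default run configuration
#'
#' Returns the reference configuration for one of the three studies:
#' \describe{
#'   \item{study 1}{diurnal cortisol reproduction — 10,000 persons, 200
#'     days, Scenario I with gamma work-impulse rates, cortisol kept for
#'     curve/index summaries;}
#'   \item{study 2}{robustness sweep — 5,000 persons, evenly spread
#'     (uniform 1..50) work-impulse rates, 27-combination grid of
#'     \eqn{\rho_R}, \eqn{\epsilon_L}, \eqn{\epsilon_D}, odds ratios at
#'     checkpoint days, both scenarios;}
#'   \item{study 3}{workweek comparison — 5,000 persons, Scenario II, six
#'     configurations at 30/40/50 weekly hours, relative risks versus the
#'     standard week.}
#' }
#'
#' @param study 1, 2 or 3.
#' @return A named list of class \code{"run_config"}.
#' @export
default_config <- function(study = 1) {
  stopifnot(length(study) == 1L, study %in% 1:3)
  structure(list(
    study = as.integer(study),
    n_people = if (study == 1) 10000L else 5000L,
    n_days = 200L,
    sampling_per_hour = 2,
    seed = 1L,
    scenario = if (study == 1) "I" else "II",
    work_rate_dist = if (study == 1) list(kind = "gamma", shape = 3, scale = 6)
                     else list(kind = "uniform", min = 1, max = 50),
    night_rate_dist = list(kind = "gamma", shape = 3, scale = 14),
    coupling_dist = list(kind = "gamma", shape = 1, scale = 8),
    decay_mean = 0.52, decay_sd = 0.05,
    kappa_hpa = 2.2, tau = 0.5,
    rho_r = 0.6, eps_l = 20, eps_d = 400,
    decay_mode = "euler",
    wake = 7, work_start = 8.5,
    working_days = 0:4, hours_per_day = 8,
    weekly_hours_levels = c(30, 40, 50),
    checkpoint_days = c(50, 100, 150, 200),
    sweep_rho_r = c(0.3, 0.6, 1.2),
    sweep_eps_l = c(10, 20, 40),
    sweep_eps_d = c(200, 400, 800),
    out_dir = "."
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Unset keys take the study's defaults (see \code{\link{default_config}});
#' unknown keys and invariant violations fail with a message naming the
#' key. An empty file yields the full default configuration.
#'
#' @param path YAML file; may set any field of \code{\link{default_config}}.
#' @return A validated \code{"run_config"} list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config must be a key-value mapping")
  cfg <- default_config(user$study %||% 1)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  validate_config(cfg)
}

#' Write a run configuration to YAML
#'
#' Round-trips losslessly through \code{\link{load_config}}.
#'
#' @param config A \code{"run_config"} list.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

parse_dist <- function(x, key) {
  if (inherits(x, "dist_spec")) return(x)
  if (!is.list(x) || is.null(x$kind))
    stop("config key '", key, "' must be a distribution spec with a 'kind'")
  out <- try(switch(x$kind,
                    gamma = gamma_spec(x$shape, x$scale),
                    uniform = uniform_spec(x$min, x$max),
                    normal = normal_spec(x$mean, x$sd),
                    stop("unknown distribution kind: ", x$kind)),
             silent = TRUE)
  if (inherits(out, "try-error"))
    stop("invalid distribution for config key '", key, "': ",
         attr(out, "condition")$message)
  out
}

validate_config <- function(cfg) {
  chk <- function(ok, key, why)
    if (!ok) stop("invalid config key '", key, "': ", why)
  chk(cfg$study %in% 1:3, "study", "must be 1, 2 or 3")
  chk(cfg$n_people >= 0, "n_people", "must be non-negative")
  chk(cfg$n_days >= 1, "n_days", "must be at least 1")
  chk(cfg$sampling_per_hour > 0, "sampling_per_hour", "must be positive")
  chk(cfg$scenario %in% c("I", "II"), "scenario", "must be 'I' or 'II'")
  chk(cfg$decay_mean > 0, "decay_mean", "must be positive")
  chk(cfg$decay_sd >= 0, "decay_sd", "must be non-negative")
  chk(all(cfg$checkpoint_days >= 0), "checkpoint_days", "must be non-negative")
  # constructing the component objects enforces the remaining invariants
  parse_dist(cfg$work_rate_dist, "work_rate_dist")
  parse_dist(cfg$night_rate_dist, "night_rate_dist")
  parse_dist(cfg$coupling_dist, "coupling_dist")
  dt <- 1 / cfg$sampling_per_hour
  dynamics_params(cfg$kappa_hpa, cfg$tau, cfg$rho_r, cfg$eps_l, cfg$eps_d,
                  dt = dt, decay_mode = cfg$decay_mode)
  workweek_config("#1", cfg$working_days, cfg$hours_per_day,
                  work_start = cfg$work_start, wake = cfg$wake)
  structure(cfg, class = "run_config")
}

config_scenario <- function(cfg) {
  scenario_spec(cfg$scenario,
                work_rate_dist = parse_dist(cfg$work_rate_dist, "work_rate_dist"),
                night_rate_dist = parse_dist(cfg$night_rate_dist, "night_rate_dist"),
                coupling_dist = parse_dist(cfg$coupling_dist, "coupling_dist"))
}

config_params <- function(cfg) {
  dynamics_params(cfg$kappa_hpa, cfg$tau, cfg$rho_r, cfg$eps_l, cfg$eps_d,
                  dt = 1 / cfg$sampling_per_hour, decay_mode = cfg$decay_mode)
}

config_workweek <- function(cfg) {
  workweek_config("#1", cfg$working_days, cfg$hours_per_day,
                  work_start = cfg$work_start, wake = cfg$wake)
}

#' Run one of the three studies end-to-end
#'
#' Orchestrates the documented simulation procedures and writes their CSV
#' outputs plus a YAML run manifest to \code{out_dir}. Deterministic given
#' \code{config$seed}.
#'
#' \describe{
#'   \item{study 1}{\code{population.csv}, \code{day_curve.csv} (wake to
#'     wake+16 h, day 0), \code{night_curve.csv} (wake-4 h to wake),
#'     \code{indices.csv} (AUCg, AUCi, slope per person).}
#'   \item{study 2}{\code{sweep.csv}: odds ratios for the 27 parameter
#'     combinations at each checkpoint day, Scenarios II and I.}
#'   \item{study 3}{\code{workweeks.csv}: incidence and relative risk
#'     versus the standard week for the six configurations at each weekly
#'     hours level and checkpoint day.}
#' }
#'
#' @param config A \code{"run_config"} list.
#' @param out_dir Output directory (created if missing); defaults to
#'   \code{config$out_dir}.
#' @param verbose Print progress lines.
#' @return Invisibly, a list of the result objects written.
#' @export
run_study <- function(config, out_dir = config$out_dir, verbose = TRUE) {
  config <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(sprintf(...))
  scenario <- config_scenario(config)
  params <- config_params(config)
  seed <- config$seed
  written <- character(0)
  results <- list()

  if (config$study == 1) {
    say("study 1: simulating %d persons, %d days (Scenario %s)",
        config$n_people, config$n_days, config$scenario)
    pop <- build_population(config$n_people, scenario,
                            normal_spec(config$decay_mean, config$decay_sd),
                            seed = seed)
    res <- simulate_population(pop, config_workweek(config), params,
                               config$n_days, seed = seed + 1L,
                               keep_cortisol = TRUE)
    write_population(pop, file.path(out_dir, "population.csv"))
    write_day_curve(day_curve(res), file.path(out_dir, "day_curve.csv"))
    write_day_curve(day_curve(res, from = -4, to = 0),
                    file.path(out_dir, "night_curve.csv"))
    write_indices(diurnal_indices(res), file.path(out_dir, "indices.csv"))
    written <- c("population.csv", "day_curve.csv", "night_curve.csv",
                 "indices.csv")
    res$cortisol <- NULL  # not carried in the return value
    results <- list(population = pop, result = res)
    say("study 1: %d/%d diseased by day %d",
        sum(!is.na(res$people$onset_day)), config$n_people,
        config$n_days - 1L)
  } else if (config$study == 2) {
    grid <- sweep_grid(config$sweep_rho_r, config$sweep_eps_l,
                       config$sweep_eps_d)
    sweeps <- lapply(c("II", "I"), function(sc) {
      say("study 2: sweep over %d combinations, Scenario %s (n=%d, %d days)",
          nrow(grid), sc, config$n_people, config$n_days)
      sc_spec <- scenario_spec(sc,
                               work_rate_dist = scenario$work_rate_dist,
                               night_rate_dist = scenario$night_rate_dist,
                               coupling_dist = scenario$coupling_dist)
      run_sweep(grid, sc_spec, config$n_people, config$n_days,
                config_workweek(config), params,
                checkpoint_days = config$checkpoint_days, seed = seed)
    })
    sweep_tab <- rbind(sweeps[[1]], sweeps[[2]])
    utils::write.csv(sweep_tab, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
    written <- "sweep.csv"
    results <- list(sweep = sweep_tab)
  } else {
    tabs <- lapply(config$weekly_hours_levels, function(wh) {
      say("study 3: %g h/week across 6 configurations (n=%d, %d days)",
          wh, config$n_people, config$n_days)
      compare_workweeks(wh, config$n_people, config$n_days, scenario,
                        params,
                        checkpoint_days =
                          config$checkpoint_days[
                            config$checkpoint_days <= config$n_days],
                        seed = seed)
    })
    rr_tab <- do.call(rbind, tabs)
    utils::write.csv(rr_tab, file.path(out_dir, "workweeks.csv"),
                     row.names = FALSE)
    written <- "workweeks.csv"
    results <- list(workweeks = rr_tab)
  }

  elapsed <- proc.time()[["elapsed"]] - t0
  manifest <- list(config = unclass(config),
                   package_version = as.character(
                     utils::packageVersion("allostasim")),
                   files = written, wall_time_seconds = round(elapsed, 2))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  say("study %d: wrote %s in %.1f s", config$study,
      paste(written, collapse = ", "), elapsed)
  invisible(results)
}
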