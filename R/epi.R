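#' Cumulative disease incidence
#'
#' @param result A \code{\link{simulate_population}} result.
#' @param day 0-based day; persons with onset at or before it count as
#'   diseased. Defaults to the last simulated day.
#' @return Proportion diseased in \code{[0, 1]}.
#' @export
incidence <- function(result, day = result$days - 1L) {
  stopifnot(day >= 0, day <= result$days)
  onset <- result$people$onset_day
  if (!length(onset)) stop("empty population")
  mean(!is.na(onset) & onset <= day)
}

#' Odds ratio of disease per SD of exposure
#'
#' Fits a logistic regression of disease status on the z-scored exposure
#' and returns the exponentiated coefficient: the odds ratio per one
#' standard deviation of exposure. Odds ratios above \code{cap} (default
#' 100, e.g. under complete separation) are reported as \code{cap} with
#' attribute \code{capped = TRUE}. When the outcome does not vary the OR
#' is undefined and \code{NA} is returned with attribute \code{reason}.
#'
#' @param exposure Numeric exposure vector (non-zero variance).
#' @param diseased Logical (or 0/1) outcome vector.
#' @param cap Upper reporting cap (default 100).
#' @return Scalar OR (possibly \code{NA}), with attributes \code{capped}
#'   and, when undefined, \code{reason}.
#' @examples
#' set.seed(1)
#' z <- rnorm(2000)
#' y <- runif(2000) < plogis(-1 + 0.7 * z)
#' or_per_sd(z, y)   # close to exp(0.7)
#' @export
or_per_sd <- function(exposure, diseased, cap = 100) {
  stopifnot(length(exposure) == length(diseased), length(exposure) > 0)
  diseased <- as.logical(diseased)
  if (stats::sd(exposure) == 0) stop("exposure has zero variance")
  if (all(diseased) || !any(diseased))
    return(structure(NA_real_, capped = FALSE,
                     reason = "no variation in disease outcome"))
  z <- as.numeric(scale(exposure))
  fit <- suppressWarnings(
    stats::glm(diseased ~ z, family = stats::binomial()))
  or <- exp(unname(stats::coef(fit)["z"]))
  if (!is.finite(or) || or > cap)
    structure(cap, capped = TRUE)
  else
    structure(or, capped = FALSE)
}

#' @rdname or_per_sd
#' @param result A \code{\link{simulate_population}} result.
#' @param day Disease status is "onset by \code{day}".
#' @param exposure_var \code{"realized"} uses the realized mean work
#'   impulses per working day (default); \code{"lambda"} uses the latent
#'   rate \eqn{\lambda_W}.
#' @export
odds_ratio_per_sd <- function(result, day = result$days - 1L,
                              exposure_var = c("realized", "lambda"),
                              cap = 100) {
  exposure_var <- match.arg(exposure_var)
  x <- switch(exposure_var,
              realized = result$people$mean_work_impulses,
              lambda = result$people$lambda_work)
  onset <- result$people$onset_day
  or_per_sd(x, !is.na(onset) & onset <= day, cap = cap)
}

#' Relative risk of disease versus a benchmark configuration
#'
#' Ratio of cumulative incidences at the same day. Both results should be
#' simulated from the same population and master seed (common random
#' numbers), so that the ratio isolates the workweek effect.
#'
#' @param result,benchmark \code{\link{simulate_population}} results.
#' @param day Evaluation day (defaults to the last simulated day).
#' @return Scalar RR; \code{NA} with attribute \code{reason} when the
#'   benchmark incidence is zero.
#' @export
relative_risk <- function(result, benchmark, day = result$days - 1L) {
  stopifnot(result$days == benchmark$days)
  p1 <- incidence(result, day)
  p0 <- incidence(benchmark, day)
  if (p0 == 0)
    return(structure(NA_real_, reason = "benchmark incidence is zero"))
  p1 / p0
}

#' Parameter grid for the robustness sweep
#'
#' Three values per dynamics parameter, 27 combinations. The model's
#' strain/load/disease scales are arbitrary, so the defaults bracket the
#' reference values geometrically (halved and doubled).
#'
#' @param rho_r,eps_l,eps_d Three values each.
#' @return Data frame of class \code{"sweep_grid"} with 27 rows
#'   (\code{rho_r}, \code{eps_l}, \code{eps_d}).
#' @export
sweep_grid <- function(rho_r = c(0.3, 0.6, 1.2),
                       eps_l = c(10, 20, 40),
                       eps_d = c(200, 400, 800)) {
  stopifnot(all(rho_r > 0), all(eps_l >= 0), all(eps_d > 0),
            !anyDuplicated(rho_r), !anyDuplicated(eps_l),
            !anyDuplicated(eps_d))
  g <- expand.grid(rho_r = rho_r, eps_l = eps_l, eps_d = eps_d,
                   KEEP.OUT.ATTRS = FALSE)
  structure(g, class = c("sweep_grid", "data.frame"))
}

#' Robustness sweep: odds ratios over a dynamics-parameter grid
#'
#' Simulates one population once per scenario and evaluates the odds ratio
#' of disease per SD of work-impulse exposure for every grid combination
#' of \eqn{\rho_R}, \eqn{\epsilon_L}, \eqn{\epsilon_D} at each checkpoint
#' day. Cortisol time courses depend on none of the swept parameters, so
#' they are computed once per person and the cheap strain/load/threshold
#' stages are re-run per combination.
#'
#' @param grid A \code{\link{sweep_grid}}.
#' @param scenario A \code{\link{scenario_spec}}; the reference analysis
#'   uses evenly spread work-impulse rates (\code{uniform_spec(1, 50)}).
#' @param n_people Population size.
#' @param days Simulated days.
#' @param config A \code{\link{workweek_config}}.
#' @param params Baseline \code{\link{dynamics_params}} supplying
#'   \code{kappa_hpa}, \code{tau}, \code{dt}, \code{decay_mode}.
#' @param checkpoint_days Evaluation days; entries beyond \code{days - 1}
#'   are dropped.
#' @param seed Master seed.
#' @return Data frame: \code{rho_r, eps_l, eps_d, scenario, day, n,
#'   n_diseased, odds_ratio, capped}; \code{odds_ratio} is \code{NA} where
#'   undefined.
#' @export
run_sweep <- function(grid = sweep_grid(),
                      scenario = scenario_spec("II", uniform_spec(1, 50)),
                      n_people, days, config = standard_week(),
                      params = dynamics_params(),
                      checkpoint_days = c(50, 100, 150, 200), seed) {
  stopifnot(inherits(grid, "sweep_grid"), inherits(scenario, "scenario_spec"))
  checkpoint_days <- checkpoint_days[checkpoint_days <= days]
  if (!length(checkpoint_days)) stop("no checkpoint day within the horizon")

  population <- build_population(n_people, scenario, seed = seed)
  seeds <- person_seeds(seed + 1L, n_people)
  horizon <- 24 * days
  n_working_days <- sum((seq_len(days) - 1L) %% 7L %in% config$working_days)

  rho_r_vals <- unique(grid$rho_r)
  combos <- nrow(grid)
  onset <- matrix(NA_integer_, nrow = n_people, ncol = combos)
  exposure <- numeric(n_people)

  for (i in seq_len(n_people)) {
    set.seed(seeds[i])
    person <- population[i, ]
    train <- build_train(person, config, days)
    raster <- rasterize(train, dt = params$dt, horizon = horizon)
    t <- attr(raster, "t")
    keep <- t >= 0
    C <- integrate_cortisol(raster, person$rho_c, params)
    S_by_rho <- lapply(rho_r_vals, function(r)
      integrate_strain(C, r, params$dt))
    names(S_by_rho) <- as.character(rho_r_vals)
    for (g in seq_len(combos)) {
      L <- accumulate_load(S_by_rho[[as.character(grid$rho_r[g])]],
                           grid$eps_l[g], params$dt)[keep]
      hit <- L >= grid$eps_d[g]
      if (any(hit))
        onset[i, g] <- as.integer(t[keep][which.max(hit)] %/% 24)
    }
    exposure[i] <- if (n_working_days > 0)
      sum(train$kind == "work") / n_working_days else 0
  }

  rows <- expand.grid(g = seq_len(combos), day = checkpoint_days,
                      KEEP.OUT.ATTRS = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(r) {
    g <- rows$g[r]; day <- rows$day[r]
    diseased <- !is.na(onset[, g]) & onset[, g] <= day
    or <- or_per_sd(exposure, diseased)
    data.frame(rho_r = grid$rho_r[g], eps_l = grid$eps_l[g],
               eps_d = grid$eps_d[g], scenario = scenario$scenario,
               day = day, n = n_people, n_diseased = sum(diseased),
               odds_ratio = as.numeric(or),
               capped = as.integer(isTRUE(attr(or, "capped"))))
  }))
  rownames(out) <- NULL
  out
}

#' Compare workweek configurations against the standard week
#'
#' Simulates one shared population under each of the six benchmark
#' workweek configurations (common random numbers: the same master seed
#' gives every person identical night impulses across configurations) and
#' reports cumulative incidence and relative risk versus the Mon-Fri
#' standard week at each checkpoint day.
#'
#' @param weekly_hours Weekly working hours shared by all configurations.
#' @param n_people Population size.
#' @param days Simulated days.
#' @param scenario A \code{\link{scenario_spec}} (reference: Scenario II
#'   with evenly spread work-impulse rates).
#' @param params A \code{\link{dynamics_params}}.
#' @param checkpoint_days Evaluation days (default: last day only).
#' @param seed Master seed.
#' @param configs Optional named list of \code{\link{workweek_config}}s;
#'   defaults to \code{\link{workweek_presets}(weekly_hours)}. The
#'   benchmark is the configuration named \code{"#1"}.
#' @return Data frame: \code{config_name, weekly_hours, day, incidence,
#'   rr_vs_benchmark}.
#' @export
compare_workweeks <- function(weekly_hours = 40, n_people, days,
                              scenario = scenario_spec("II", uniform_spec(1, 50)),
                              params = dynamics_params(),
                              checkpoint_days = days - 1L, seed,
                              configs = workweek_presets(weekly_hours)) {
  stopifnot("#1" %in% names(configs))
  population <- build_population(n_people, scenario, seed = seed)
  results <- lapply(configs, function(cfg)
    simulate_population(population, cfg, params, days, seed = seed + 1L))
  benchmark <- results[["#1"]]
  out <- do.call(rbind, lapply(names(results), function(nm) {
    do.call(rbind, lapply(checkpoint_days, function(day) {
      data.frame(config_name = nm, weekly_hours = weekly_hours, day = day,
                 incidence = incidence(results[[nm]], day),
                 rr_vs_benchmark = as.numeric(
                   relative_risk(results[[nm]], benchmark, day)))
    }))
  }))
  rownames(out) <- NULL
  out
}
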