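# Per-person RNG substreams: prefix-stable in n, so growing the population
# never perturbs earlier persons, and the same master seed reproduces the
# same night-impulse realizations across workweek configurations.
person_seeds <- function(master_seed, n) {
  if (n == 0L) return(integer(0))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n, replace = TRUE)
}

#' Simulate a population's disease outcomes
#'
#' Runs the full pipeline — impulse trains, cortisol, strain, load,
#' disease — for every person in a population under one workweek
#' configuration, and collects the per-person exposure and outcome
#' summaries used by the epidemiological analyses.
#'
#' Each person gets an independent RNG substream derived from
#' \code{seed}, so results are reproducible, independent of population
#' order, and comparable across workweek configurations under common
#' random numbers (identical night impulses for the same person).
#'
#' @param population An \code{\link{allosta_population}}.
#' @param config A \code{\link{workweek_config}}.
#' @param params A \code{\link{dynamics_params}}.
#' @param days Number of simulated days (day 0 is a Monday).
#' @param seed Master seed (integer).
#' @param keep_cortisol If \code{TRUE}, the full cortisol series of every
#'   person is retained (matrix \code{steps x persons}) for diurnal-curve
#'   summaries; memory scales as \code{2 * 24 * days * n} doubles.
#' @return An object of class \code{"population_result"}: a list with
#'   \itemize{
#'     \item \code{people}: data frame with \code{person_id},
#'       \code{lambda_work}, \code{lambda_night}, \code{rho_c},
#'       \code{mean_work_impulses} (realized work impulses per working
#'       day), \code{final_load}, \code{onset_day} (\code{NA} if never
#'       diseased);
#'     \item \code{config}, \code{params}, \code{days}, \code{seed};
#'     \item when requested, \code{cortisol} (matrix) and \code{t}
#'       (grid times, pre-roll excluded).
#'   }
#' @examples
#' pop <- build_population(50, scenario_spec("II", uniform_spec(1, 50)),
#'                         seed = 7)
#' res <- simulate_population(pop, standard_week(), dynamics_params(),
#'                            days = 30, seed = 7)
#' summary(res)
#' @export
simulate_population <- function(population, config = standard_week(),
                                params = dynamics_params(), days, seed,
                                keep_cortisol = FALSE) {
  stopifnot(inherits(config, "workweek"), inherits(params, "dynamics_params"),
            days >= 1)
  n <- nrow(population)
  horizon <- 24 * days
  seeds <- person_seeds(seed, n)

  people <- data.frame(person_id = population$person_id,
                       lambda_work = population$lambda_work,
                       lambda_night = population$lambda_night,
                       rho_c = population$rho_c,
                       mean_work_impulses = NA_real_,
                       final_load = NA_real_,
                       onset_day = NA_integer_)
  n_working_days <- sum((seq_len(days) - 1L) %% 7L %in% config$working_days)
  cort <- NULL
  t_keep <- NULL

  for (i in seq_len(n)) {
    set.seed(seeds[i])
    person <- population[i, ]
    train <- build_train(person, config, days)
    tc <- simulate_person(person, train, params, horizon)
    if (keep_cortisol) {
      if (is.null(cort)) {
        t_keep <- tc$t
        cort <- matrix(NA_real_, nrow = nrow(tc), ncol = n)
      }
      cort[, i] <- tc$cortisol
    }
    n_work <- sum(train$kind == "work")
    people$mean_work_impulses[i] <-
      if (n_working_days > 0) n_work / n_working_days else 0
    people$final_load[i] <- tc$load[nrow(tc)]
    people$onset_day[i] <- attr(tc, "onset_day")
  }

  structure(list(people = people, config = config, params = params,
                 days = days, seed = seed, cortisol = cort, t = t_keep),
            class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  n <- nrow(x$people)
  cat(sprintf("Population result: %d persons, %d days, workweek %s\n",
              n, x$days, x$config$name))
  cat(sprintf("  diseased by day %d: %d (%.1f%%)\n", x$days - 1L,
              sum(!is.na(x$people$onset_day)),
              if (n) 100 * mean(!is.na(x$people$onset_day)) else 0))
  invisible(x)
}

#' @export
summary.population_result <- function(object, ...) {
  print(object)
  p <- object$people
  if (nrow(p)) {
    cat(sprintf("  exposure (work impulses/working day): mean %.2f, SD %.2f\n",
                mean(p$mean_work_impulses), stats::sd(p$mean_work_impulses)))
    cat(sprintf("  final load: median %.3g, max %.3g\n",
                stats::median(p$final_load), max(p$final_load)))
    if (any(!is.na(p$onset_day)))
      cat(sprintf("  onset day: median %.0f among diseased\n",
                  stats::median(p$onset_day, na.rm = TRUE)))
  }
  invisible(object)
}

#' Write population-result summaries to CSV
#'
#' One row per person: \code{person_id, lambda_work, lambda_night, rho_c,
#' mean_work_impulses, final_load, onset_day}.
#'
#' @param result A \code{\link{simulate_population}} result.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_population_result <- function(result, path) {
  utils::write.csv(result$people, path, row.names = FALSE)
  invisible(path)
}
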