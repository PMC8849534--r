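#' Scenario specification for person-level impulse rates
#'
#' A simulated person carries two mean impulse rates: \eqn{\lambda_N},
#' expected night impulses per night, and \eqn{\lambda_W}, expected work
#' impulses per standard 8-hour working day.  Two population scenarios are
#' supported:
#' \describe{
#'   \item{Scenario I (uncorrelated)}{\eqn{\lambda_W} and \eqn{\lambda_N}
#'     are drawn independently (\code{work_rate_dist},
#'     \code{night_rate_dist}).}
#'   \item{Scenario II (correlated)}{\eqn{\lambda_W} is drawn from
#'     \code{work_rate_dist} and \eqn{\lambda_N = \lambda_W +} a draw from
#'     \code{coupling_dist}, modelling anticipation of the workday: people
#'     with more work stressors mount a larger pre-waking cortisol surge.}
#' }
#'
#' @param scenario \code{"I"} or \code{"II"}.
#' @param work_rate_dist Distribution of \eqn{\lambda_W} (gamma or uniform
#'   spec). Default \code{gamma_spec(3, 6)} (mean 18).
#' @param night_rate_dist Distribution of \eqn{\lambda_N} under Scenario I.
#'   Default \code{gamma_spec(3, 14)} (mean 42). Ignored under Scenario II.
#' @param coupling_dist Non-negative additive coupling under Scenario II.
#'   Default \code{gamma_spec(1, 8)}.
#' @return An object of class \code{"scenario_spec"}.
#' @seealso \code{\link{build_population}}
#' @export
scenario_spec <- function(scenario = c("I", "II"),
                          work_rate_dist = gamma_spec(3, 6),
                          night_rate_dist = gamma_spec(3, 14),
                          coupling_dist = gamma_spec(1, 8)) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(work_rate_dist, "dist_spec"),
            inherits(night_rate_dist, "dist_spec"),
            inherits(coupling_dist, "dist_spec"))
  structure(list(scenario = scenario,
                 work_rate_dist = work_rate_dist,
                 night_rate_dist = night_rate_dist,
                 coupling_dist = coupling_dist),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %s (%s night/work rates)\n", x$scenario,
              if (x$scenario == "I") "uncorrelated" else "correlated"))
  cat("  work rate : "); print(x$work_rate_dist)
  if (x$scenario == "I") {
    cat("  night rate: "); print(x$night_rate_dist)
  } else {
    cat("  coupling  : "); print(x$coupling_dist)
  }
  invisible(x)
}

#' Sample cortisol decay constants
#'
#' Draws per-person first-order cortisol decay constants \eqn{\rho_C}
#' (per hour) from a normal distribution, redrawing the (practically
#' impossible at the default parameters) non-positive values so that every
#' person has a valid exponential decay.  The implied half-life is
#' \eqn{60\ln 2/\rho_C} minutes.
#'
#' @param n Number of persons.
#' @param spec A \code{\link{normal_spec}}; default mean 0.52/h, SD 0.05/h,
#'   placing mean half-life near 80 minutes.
#' @param max_attempts Redraw budget for non-positive values before failing.
#' @return Numeric vector of \code{n} positive decay constants.
#' @export
sample_decay_constants <- function(n, spec = normal_spec(0.52, 0.05),
                                   max_attempts = 100L) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == as.integer(n))
  stopifnot(inherits(spec, "normal_spec"))
  if (spec$mean <= 0)
    stop("decay spec mean must be positive (redraws would dominate)")
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  rho <- draw_spec(spec, n)
  attempts <- 0L
  while (any(bad <- rho <= 0)) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not draw positive decay constants within ",
           max_attempts, " attempts")
    rho[bad] <- draw_spec(spec, sum(bad))
  }
  rho
}

#' Sample person-level impulse rates
#'
#' @param n Number of persons.
#' @param spec A \code{\link{scenario_spec}}.
#' @return Data frame with columns \code{lambda_work}, \code{lambda_night}
#'   and \code{anticipation}: the share of \code{lambda_night} that
#'   mirrors the workday (\code{lambda_work} under Scenario II, 0 under
#'   Scenario I). \code{lambda_night} refers to the standard 8-hour
#'   working day; for other day lengths the anticipation share scales with
#'   the day length (see \code{\link{build_train}}).
#' @export
sample_person_rates <- function(n, spec = scenario_spec("I")) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == as.integer(n))
  stopifnot(inherits(spec, "scenario_spec"))
  n <- as.integer(n)
  lambda_work <- draw_spec(spec$work_rate_dist, n)
  if (spec$scenario == "I") {
    lambda_night <- draw_spec(spec$night_rate_dist, n)
    anticipation <- rep(0, n)
  } else {
    lambda_night <- lambda_work + draw_spec(spec$coupling_dist, n)
    anticipation <- lambda_work
  }
  data.frame(lambda_work = lambda_work, lambda_night = lambda_night,
             anticipation = anticipation)
}

#' Build a simulated population
#'
#' Draws \code{n} persons' traits — work/night impulse rates under the given
#' scenario and cortisol decay constants — reproducibly from a seed.
#'
#' @param n Population size.
#' @param scenario A \code{\link{scenario_spec}}.
#' @param decay A \code{\link{normal_spec}} for \eqn{\rho_C}.
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and independent of the prior RNG state.
#' @return A data frame of class \code{"allosta_population"} with columns
#'   \code{person_id} (0-based), \code{lambda_work}, \code{lambda_night},
#'   \code{rho_c}.
#' @examples
#' pop <- build_population(5, scenario_spec("II"), seed = 1)
#' pop
#' @export
build_population <- function(n, scenario = scenario_spec("I"),
                             decay = normal_spec(0.52, 0.05), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rates <- sample_person_rates(n, scenario)
  rho <- sample_decay_constants(n, decay)
  pop <- data.frame(person_id = seq_len(nrow(rates)) - 1L,
                    lambda_work = rates$lambda_work,
                    lambda_night = rates$lambda_night,
                    anticipation = rates$anticipation,
                    rho_c = rho)
  structure(pop, scenario = scenario$scenario, seed = seed,
            class = c("allosta_population", "data.frame"))
}

#' @export
print.allosta_population <- function(x, ...) {
  cat(sprintf("Simulated population: %d persons (Scenario %s)\n",
              nrow(x), attr(x, "scenario") %||% "?"))
  NextMethod()
}

#' @export
summary.allosta_population <- function(object, ...) {
  cat(sprintf("Simulated population: %d persons (Scenario %s)\n",
              nrow(object), attr(object, "scenario") %||% "?"))
  if (nrow(object)) {
    cat(sprintf("  lambda_work : mean %.2f, range [%.2f, %.2f]\n",
                mean(object$lambda_work), min(object$lambda_work),
                max(object$lambda_work)))
    cat(sprintf("  lambda_night: mean %.2f, range [%.2f, %.2f]\n",
                mean(object$lambda_night), min(object$lambda_night),
                max(object$lambda_night)))
    cat(sprintf("  rho_c       : mean %.3f/h (half-life %.0f min)\n",
                mean(object$rho_c), 60 * log(2) / mean(object$rho_c)))
    cat(sprintf("  cor(work, night) = %.3f\n",
                if (nrow(object) > 2)
                  stats::cor(object$lambda_work, object$lambda_night)
                else NA_real_))
  }
  invisible(object)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write populations as CSV
#'
#' Columns: \code{person_id, lambda_work, lambda_night, rho_c} plus the
#' optional \code{anticipation} share (absent means 0, i.e. night rates
#' not coupled to workday length); header required, UTF-8, '.' decimal
#' separator.
#'
#' @param pop An \code{allosta_population} (or compatible data frame).
#' @param path File path.
#' @return \code{read_population} returns an \code{allosta_population};
#'   \code{write_population} returns \code{path} invisibly.
#' @export
write_population <- function(pop, path) {
  cols <- c("person_id", "lambda_work", "lambda_night", "rho_c")
  stopifnot(all(cols %in% names(pop)))
  if ("anticipation" %in% names(pop)) cols <- c(cols, "anticipation")
  utils::write.csv(as.data.frame(pop)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  pop <- utils::read.csv(path)
  cols <- c("person_id", "lambda_work", "lambda_night", "rho_c")
  if (!all(cols %in% names(pop)))
    stop("population CSV must have columns: ", paste(cols, collapse = ", "))
  if (!"anticipation" %in% names(pop)) pop$anticipation <- 0
  if (nrow(pop) && any(pop$rho_c <= 0)) stop("rho_c must be positive")
  if (nrow(pop) && any(pop$lambda_night <= 0)) stop("lambda_night must be positive")
  if (nrow(pop) && any(pop$lambda_work < 0)) stop("lambda_work must be non-negative")
  if (nrow(pop) && any(pop$anticipation < 0 | pop$anticipation > pop$lambda_night))
    stop("anticipation must lie in [0, lambda_night]")
  structure(pop[, c(cols, "anticipation")],
            class = c("allosta_population", "data.frame"))
}
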