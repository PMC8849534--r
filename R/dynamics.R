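#' Dynamics parameters
#'
#' Parameters of the four coupled model equations integrated on the
#' sampling grid:
#' \describe{
#'   \item{cortisol}{\eqn{dC/dt = -\rho_C C_t + \kappa_{HPA} \sum I_{t-\tau}}:
#'     production proportional to the delayed impulse count, first-order
#'     decay.}
#'   \item{strain}{\eqn{dS/dt = -\rho_R S_t + C_t}: reversible allostatic
#'     strain recovering at rate \eqn{\rho_R}.}
#'   \item{load}{\eqn{dL/dt = \max(0, S_t - \epsilon_L)}: irreversible
#'     allostatic load accrues from strain in excess of the allostatic
#'     threshold.}
#'   \item{disease}{\eqn{D_t = (L_t \ge \epsilon_D)}: disease once load
#'     reaches the disease threshold (inclusive).}
#' }
#'
#' @param kappa_hpa HPA scaling constant, cortisol production per active
#'   impulse per hour (default 2.20).
#' @param tau Cortisol response delay in hours (default 0.5); must be a
#'   non-negative multiple of \code{dt}.
#' @param rho_r Strain recovery coefficient per hour (default 0.6).
#' @param eps_l Allostatic threshold in strain units (default 20).
#' @param eps_d Disease threshold in load units (default 400).
#' @param dt Grid step in hours (default 0.5 = 2 samples/hour).
#' @param decay_mode \code{"euler"} (forward Euler throughout) or
#'   \code{"exact"} (exponential decay factor for cortisol, preserving the
#'   true half-life \eqn{60\ln2/\rho_C} minutes at any step size).
#' @return An object of class \code{"dynamics_params"}.
#' @export
dynamics_params <- function(kappa_hpa = 2.2, tau = 0.5, rho_r = 0.6,
                            eps_l = 20, eps_d = 400, dt = 0.5,
                            decay_mode = c("euler", "exact")) {
  decay_mode <- match.arg(decay_mode)
  stopifnot(kappa_hpa > 0, tau >= 0, rho_r > 0, eps_l >= 0, eps_d > 0, dt > 0)
  if (abs(tau / dt - round(tau / dt)) > 1e-9)
    stop("tau must be a multiple of dt")
  structure(list(kappa_hpa = kappa_hpa, tau = tau, rho_r = rho_r,
                 eps_l = eps_l, eps_d = eps_d, dt = dt,
                 decay_mode = decay_mode),
            class = "dynamics_params")
}

#' @export
print.dynamics_params <- function(x, ...) {
  cat(sprintf(paste0("Dynamics: kappa_HPA=%.3g, tau=%.3g h, rho_R=%.3g/h, ",
                     "eps_L=%.3g, eps_D=%.3g, dt=%.3g h (%s decay)\n"),
              x$kappa_hpa, x$tau, x$rho_r, x$eps_l, x$eps_d, x$dt,
              x$decay_mode))
  invisible(x)
}

# y[k+1] = a * y[k] + f[k], y[1] = 0 — C-level recursive filter.
.recur <- function(f, a) {
  n <- length(f)
  if (n == 0L) return(numeric(0))
  c(0, as.numeric(stats::filter(f[-n], a, method = "recursive")))
}

#' Integrate the cortisol equation
#'
#' Integrates \eqn{dC/dt = -\rho_C C + \kappa_{HPA}\sum I_{t-\tau}} on the
#' grid with \eqn{C_0 = 0}. In \code{euler} mode
#' \eqn{C_{k+1} = C_k + dt(-\rho_C C_k + \kappa \Sigma I_{k-d})} with
#' \eqn{d = \tau/dt}; in \code{exact} mode the decay factor is
#' \eqn{e^{-\rho_C dt}}. The result is clipped at zero.
#'
#' @param impulses Gridded impulse counts (see \code{\link{rasterize}}).
#' @param rho_c Cortisol decay constant per hour (> 0).
#' @param params A \code{\link{dynamics_params}}.
#' @return Numeric vector of cortisol values at the grid times.
#' @export
integrate_cortisol <- function(impulses, rho_c, params = dynamics_params()) {
  stopifnot(rho_c > 0, inherits(params, "dynamics_params"))
  dt <- params$dt
  a <- if (params$decay_mode == "euler") {
    if (dt * rho_c >= 1)
      stop("unstable Euler step: dt * rho_c must be < 1")
    1 - rho_c * dt
  } else {
    exp(-rho_c * dt)
  }
  d <- as.integer(round(params$tau / dt))
  u <- as.numeric(impulses)
  lagged <- if (d > 0) c(rep(0, d), u[seq_len(max(length(u) - d, 0L))]) else u
  pmax(.recur(dt * params$kappa_hpa * lagged, a), 0)
}

#' Integrate the allostatic strain equation
#'
#' \eqn{S_{k+1} = S_k + dt(-\rho_R S_k + C_k)}, \eqn{S_0 = 0}. With
#' constant cortisol \eqn{c} the strain converges to the fixed point
#' \eqn{c/\rho_R}.
#'
#' @param cortisol Cortisol series on the grid.
#' @param rho_r Recovery coefficient per hour (> 0).
#' @param dt Grid step in hours.
#' @return Strain series on the same grid.
#' @export
integrate_strain <- function(cortisol, rho_r, dt = 0.5) {
  stopifnot(rho_r > 0, dt > 0)
  if (dt * rho_r >= 1) stop("unstable Euler step: dt * rho_r must be < 1")
  .recur(dt * cortisol, 1 - rho_r * dt)
}

#' Accumulate allostatic load
#'
#' \eqn{L_{k+1} = L_k + dt \max(0, S_k - \epsilon_L)}, \eqn{L_0 = 0}:
#' strain at or below the allostatic threshold leaves load unchanged;
#' strict excess accrues irreversibly, so the series is non-decreasing.
#'
#' @param strain Strain series on the grid.
#' @param eps_l Allostatic threshold (>= 0).
#' @param dt Grid step in hours.
#' @return Load series on the same grid.
#' @export
accumulate_load <- function(strain, eps_l, dt = 0.5) {
  stopifnot(eps_l >= 0, dt > 0)
  n <- length(strain)
  if (n == 0L) return(numeric(0))
  cumsum(c(0, dt * pmax(strain[-n] - eps_l, 0)))
}

#' Threshold load into a disease state
#'
#' \eqn{D_k = (L_k \ge \epsilon_D)}, boundary inclusive; with
#' non-decreasing load the state flips False to True at most once.
#'
#' @param load Load series on the grid.
#' @param eps_d Disease threshold (> 0).
#' @return Logical series with attribute \code{onset_index} (first
#'   \code{TRUE}, or \code{NA} if never diseased).
#' @export
disease_state <- function(load, eps_d) {
  stopifnot(eps_d > 0)
  d <- load >= eps_d
  idx <- if (any(d)) which.max(d) else NA_integer_
  structure(d, onset_index = idx)
}

#' Simulate one person's full time course
#'
#' Pipelines the impulse raster through the cortisol, strain, load and
#' disease equations. A 24-hour pre-roll (night impulses of day 0 drawn
#' behind wake time) forces cortisol before \code{t = 0} but is excluded
#' from the returned series and from onset-day accounting.
#'
#' @param person One row of an \code{\link{allosta_population}}.
#' @param train An \code{\link{impulse_train}} for that person.
#' @param params A \code{\link{dynamics_params}}.
#' @param horizon Simulation length in hours.
#' @param preroll Pre-roll length in hours (default 24).
#' @return A data frame of class \code{"timecourse"} with columns \code{t}
#'   (hours), \code{impulses}, \code{cortisol}, \code{strain}, \code{load},
#'   \code{diseased}; attributes \code{person_id}, \code{onset_day} (first
#'   day with disease, \code{NA} if none), \code{params}.
#' @examples
#' pop <- build_population(1, scenario_spec("II"), seed = 42)
#' tr <- build_train(pop[1, ], standard_week(), days = 7)
#' tc <- simulate_person(pop[1, ], tr, dynamics_params(), horizon = 7 * 24)
#' summary(tc)
#' @export
simulate_person <- function(person, train, params = dynamics_params(),
                            horizon, preroll = 24) {
  grid <- rasterize(train, dt = params$dt, horizon = horizon,
                    preroll = preroll)
  t <- attr(grid, "t")
  C <- integrate_cortisol(grid, person$rho_c, params)
  S <- integrate_strain(C, params$rho_r, params$dt)
  L <- accumulate_load(S, params$eps_l, params$dt)
  D <- disease_state(L, params$eps_d)

  keep <- t >= 0
  tc <- data.frame(t = t[keep], impulses = as.numeric(grid)[keep],
                   cortisol = C[keep], strain = S[keep], load = L[keep],
                   diseased = as.logical(D)[keep])
  onset_day <- if (any(tc$diseased)) {
    as.integer(tc$t[which.max(tc$diseased)] %/% 24)
  } else NA_integer_
  structure(tc, person_id = person$person_id, onset_day = onset_day,
            params = params, class = c("timecourse", "data.frame"))
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("Time course, person %s: %d steps (%.4g h), final load %.4g%s\n",
              format(attr(x, "person_id")), nrow(x),
              if (nrow(x)) max(x$t) + attr(x, "params")$dt else 0,
              if (nrow(x)) x$load[nrow(x)] else 0,
              if (!is.na(attr(x, "onset_day")))
                sprintf(", disease onset day %d", attr(x, "onset_day"))
              else ", no disease"))
  invisible(x)
}

#' @export
summary.timecourse <- function(object, ...) {
  print(object)
  cat(sprintf("  cortisol: max %.3g, mean %.3g\n",
              max(object$cortisol), mean(object$cortisol)))
  cat(sprintf("  strain  : max %.3g; load: final %.3g\n",
              max(object$strain), object$load[nrow(object)]))
  invisible(object)
}

#' @export
plot.timecourse <- function(x, ...) {
  op <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t / 24, x$impulses, type = "h", xlab = "",
                 ylab = "impulses", ...)
  graphics::plot(x$t / 24, x$cortisol, type = "l", xlab = "",
                 ylab = "cortisol", ...)
  graphics::plot(x$t / 24, x$strain, type = "l", xlab = "",
                 ylab = "strain", ...)
  graphics::plot(x$t / 24, x$load, type = "l", xlab = "day",
                 ylab = "load", ...)
  invisible(x)
}

#' Write a time course to CSV
#'
#' Columns: \code{person_id, t_hours, cortisol, strain, load, diseased}
#' (0/1), one row per grid step.
#'
#' @param tc A \code{\link{simulate_person}} result.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  utils::write.csv(data.frame(person_id = attr(tc, "person_id"),
                              t_hours = tc$t, cortisol = tc$cortisol,
                              strain = tc$strain, load = tc$load,
                              diseased = as.integer(tc$diseased)),
                   path, row.names = FALSE)
  invisible(path)
}
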