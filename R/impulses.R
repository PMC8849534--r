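#' Daily impulse counts
#'
#' The number of impulses a person receives on a given day is Poisson with
#' that person's mean rate.
#'
#' @param lambda Expected count(s), >= 0; vectorized.
#' @return Integer vector of Poisson draws, one per element of
#'   \code{lambda}.
#' @export
daily_count <- function(lambda) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  stats::rpois(length(lambda), lambda)
}

#' Draw night-impulse onset times
#'
#' Night impulses become exponentially more likely towards the end of the
#' night, with maximum probability at awakening: each onset is wake time
#' minus an Exponential(rate 1/h) offset, so all onsets fall strictly
#' before waking.
#'
#' @param count Number of impulses.
#' @param wake_abs Wake time in hours since simulation start.
#' @return Numeric vector of onsets (hours since simulation start), all
#'   \code{< wake_abs}.
#' @export
draw_night_times <- function(count, wake_abs) {
  stopifnot(count >= 0)
  if (count == 0) return(numeric(0))
  wake_abs - stats::rexp(count, rate = 1)
}

#' Draw work-impulse onset times
#'
#' Work impulses can occur at any moment within working hours: onsets are
#' i.i.d. uniform over the work window.
#'
#' @param count Number of impulses.
#' @param window \code{c(start, end)} in hours since simulation start.
#' @return Numeric vector of onsets within \code{[start, end)}.
#' @export
draw_work_times <- function(count, window) {
  stopifnot(count >= 0)
  if (count == 0) return(numeric(0))
  if (is.null(window)) stop("no work window on this day but count > 0")
  stopifnot(length(window) == 2L, window[1] < window[2])
  stats::runif(count, window[1], window[2])
}

#' Build one person's impulse train
#'
#' Realizes a person's night and work impulses over \code{days} simulation
#' days under a workweek configuration. For every day the night count is
#' Poisson(\eqn{\lambda_N}) with onsets clustered exponentially before that
#' day's wake time; on working days the work count is Poisson with the
#' day-length-scaled rate \code{\link{scaled_work_rate}(lambda_work,
#' hours_per_day)} and onsets uniform over the work window. Free days carry
#' no work impulses.
#'
#' Both rates refer to the standard 8-hour working day. For other day
#' lengths the work rate scales in full (\code{\link{scaled_work_rate}}),
#' and the person's \code{anticipation} share of the night rate — the part
#' that mirrors the upcoming workday under the correlated scenario —
#' scales with it, so the effective nightly rate is
#' \code{lambda_night + anticipation * (hours_per_day/8 - 1)}: longer
#' workdays are anticipated by proportionally larger pre-waking surges.
#' The remaining base share is unaffected, and the nightly rate is the
#' same on every day of a given configuration, free days included.
#'
#' All night draws are consumed before any work draws, so two calls from
#' the same RNG state but different workweek configurations realize
#' identical night-impulse streams at equal day lengths (common random
#' numbers).
#'
#' @param person One row of an \code{\link{allosta_population}} (or any
#'   list with \code{person_id}, \code{lambda_work}, \code{lambda_night},
#'   and optionally \code{anticipation}, default 0).
#' @param config A \code{\link{workweek_config}}.
#' @param days Number of simulated days (>= 1); day 0 is a Monday.
#' @return A data frame of class \code{"impulse_train"} with columns
#'   \code{onset} (hours since simulation start; day-0 night impulses may
#'   be negative) and \code{kind} (\code{"night"}/\code{"work"}), sorted by
#'   onset, with attribute \code{person_id}.
#' @export
build_train <- function(person, config = standard_week(), days) {
  stopifnot(inherits(config, "workweek"),
            is.numeric(days), days >= 1, days == as.integer(days))
  days <- as.integer(days)
  lambda_w <- person$lambda_work
  anticipation <- person$anticipation %||% 0
  lambda_n <- person$lambda_night +
    anticipation * (config$hours_per_day / 8 - 1)
  stopifnot(lambda_n > 0, lambda_w >= 0,
            anticipation >= 0, anticipation <= person$lambda_night)

  schedules <- lapply(seq_len(days) - 1L, resolve_schedule, config = config)

  # night impulses: every day, onsets behind that day's wake time
  n_counts <- daily_count(rep(lambda_n, days))
  night_wakes <- rep(vapply(schedules, `[[`, numeric(1), "wake_abs"), n_counts)
  night_onsets <- night_wakes - stats::rexp(length(night_wakes), rate = 1)

  # work impulses: working days only, rate scaled to the day length
  working <- !vapply(schedules, function(s) is.null(s$work_window), logical(1))
  rate <- scaled_work_rate(lambda_w, config$hours_per_day)
  w_counts <- integer(days)
  w_counts[working] <- daily_count(rep(rate, sum(working)))
  starts <- rep(NA_real_, days); ends <- rep(NA_real_, days)
  for (i in which(working)) {
    starts[i] <- schedules[[i]]$work_window[1]
    ends[i] <- schedules[[i]]$work_window[2]
  }
  work_onsets <- stats::runif(sum(w_counts),
                              rep(starts, w_counts), rep(ends, w_counts))

  train <- data.frame(
    onset = c(night_onsets, work_onsets),
    kind = rep(c("night", "work"), c(length(night_onsets), length(work_onsets))),
    stringsAsFactors = FALSE)
  train <- train[order(train$onset), , drop = FALSE]
  rownames(train) <- NULL
  structure(train, person_id = person$person_id, days = days,
            class = c("impulse_train", "data.frame"))
}

#' @export
print.impulse_train <- function(x, ...) {
  cat(sprintf("Impulse train, person %s: %d night + %d work impulses over %d days\n",
              format(attr(x, "person_id")), sum(x$kind == "night"),
              sum(x$kind == "work"), attr(x, "days") %||% NA_integer_))
  NextMethod()
}

#' Rasterize an impulse train onto the sampling grid
#'
#' Impulses have binary intensity and a fixed 30-minute duration equal to
#' one grid step; each impulse occupies exactly the step containing its
#' onset, and simultaneous impulses add (a count of 2 is a doubly strong
#' impulse). The grid starts \code{preroll} hours before simulation start
#' so that day-0 night impulses with negative onsets still force cortisol.
#'
#' @param train An \code{\link{impulse_train}} (or data frame with an
#'   \code{onset} column).
#' @param dt Grid step in hours (default 0.5, i.e. 2 samples per hour).
#' @param horizon Simulation length in hours (a multiple of \code{dt}).
#' @param preroll Pre-simulation padding in hours (default 24; a multiple
#'   of \code{dt}). Onsets outside \code{[-preroll, horizon)} are dropped
#'   with a warning.
#' @return Integer vector of counts per grid step, with attributes
#'   \code{t} (step start times, from \code{-preroll} by \code{dt}) and
#'   \code{dt}.
#' @export
rasterize <- function(train, dt = 0.5, horizon, preroll = 24) {
  stopifnot(dt > 0, horizon > 0,
            abs(horizon / dt - round(horizon / dt)) < 1e-9,
            preroll >= 0, abs(preroll / dt - round(preroll / dt)) < 1e-9)
  onsets <- train$onset
  inside <- onsets >= -preroll & onsets < horizon
  if (any(!inside)) {
    warning(sum(!inside), " impulse(s) outside [-", preroll, ", ", horizon,
            ") dropped")
    onsets <- onsets[inside]
  }
  n_steps <- as.integer(round((horizon + preroll) / dt))
  idx <- floor((onsets + preroll) / dt) + 1
  counts <- tabulate(idx, nbins = n_steps)
  structure(counts, t = seq(-preroll, by = dt, length.out = n_steps), dt = dt)
}

#' Write impulse trains and grids to CSV
#'
#' \code{write_train}: \code{person_id, onset_hours, kind}.
#' \code{write_impulse_grid}: \code{person_id, t_hours, impulse_count},
#' one row per grid step.
#'
#' @param train An \code{\link{impulse_train}}.
#' @param grid A \code{\link{rasterize}} result.
#' @param person_id Person identifier for the grid rows.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_train <- function(train, path) {
  utils::write.csv(data.frame(person_id = attr(train, "person_id"),
                              onset_hours = train$onset, kind = train$kind),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_train
#' @export
write_impulse_grid <- function(grid, person_id, path) {
  utils::write.csv(data.frame(person_id = person_id, t_hours = attr(grid, "t"),
                              impulse_count = as.integer(grid)),
                   path, row.names = FALSE)
  invisible(path)
}
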