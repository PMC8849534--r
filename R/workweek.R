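#' Workweek configurations
#'
#' A workweek configuration fixes which weekdays are worked, for how many
#' hours per day, and when work starts.  Simulation day 0 is a Monday and
#' \code{weekday(d) = d mod 7} with Mon = 0.
#'
#' When the requested window would run past midnight at the default start
#' time (only the longest compressed days do), the start is advanced just
#' enough for the window to end at 24:00, but never before wake time;
#' a window that cannot fit within one calendar day is rejected.
#'
#' @param name Label, e.g. \code{"#1"}.
#' @param working_days Integer weekdays worked, Mon = 0 .. Sun = 6, or
#'   abbreviated English day names.
#' @param hours_per_day Working hours per working day (> 0).
#' @param work_start Clock hour at which work starts (default 8.5, i.e.
#'   08:30).
#' @param wake Wake time as clock hour (default 7).
#' @return An object of class \code{"workweek"}.
#' @examples
#' standard_week()                       # Mon-Fri, 8 h, 08:30-16:30
#' workweek_config("#4", c("Mon", "Tue", "Thu"), hours_per_day = 40 / 3)
#' @export
workweek_config <- function(name, working_days, hours_per_day,
                            work_start = 8.5, wake = 7) {
  if (is.character(working_days)) {
    idx <- match(working_days, c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
    if (anyNA(idx)) stop("unknown day name in working_days")
    working_days <- idx - 1L
  }
  working_days <- sort(unique(as.integer(working_days)))
  stopifnot(length(working_days) >= 1L, length(working_days) <= 7L,
            all(working_days >= 0L), all(working_days <= 6L),
            is.numeric(hours_per_day), hours_per_day > 0,
            is.numeric(work_start), work_start >= 0, work_start < 24,
            wake >= 0, wake < 24)
  if (hours_per_day > 24 - wake)
    stop("work window of ", hours_per_day, " h cannot fit between wake and midnight")
  if (work_start + hours_per_day > 24) {
    # only the default start is silently advanced (e.g. 16h40m days start
    # at 07:20 so the window ends at midnight); an explicit start that
    # crosses midnight is a user error
    if (!missing(work_start))
      stop("work window crosses midnight")
    work_start <- 24 - hours_per_day
    if (work_start < wake)
      stop("work window crosses midnight and cannot be shifted past wake time")
  }
  structure(list(name = as.character(name), working_days = working_days,
                 hours_per_day = hours_per_day, work_start = work_start,
                 wake = wake,
                 weekly_hours = hours_per_day * length(working_days)),
            class = "workweek")
}

#' @export
print.workweek <- function(x, ...) {
  days <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  cat(sprintf("Workweek %s: %s | %s/day (%.4g h/week), work %s-%s\n",
              x$name, paste(days[x$working_days + 1L], collapse = ","),
              format_hours(x$hours_per_day), x$weekly_hours,
              format_clock(x$work_start),
              format_clock(x$work_start + x$hours_per_day)))
  invisible(x)
}

#' Standard Monday-Friday week
#'
#' @param weekly_hours Total weekly hours (default 40, i.e. 8 h/day).
#' @return A \code{\link{workweek_config}} for Mon-Fri with
#'   \code{weekly_hours/5} hours per day; the benchmark configuration.
#' @export
standard_week <- function(weekly_hours = 40) {
  workweek_config("#1", 0:4, weekly_hours / 5)
}

#' The six benchmark workweek configurations
#'
#' Returns the configuration set compared in the workweek study:
#' \tabular{lll}{
#'   #1 \tab Mon-Fri (5 days) \tab benchmark \cr
#'   #2 \tab Mon-Tue, Thu-Sat (5 days) \tab free days spread out \cr
#'   #3 \tab Mon-Tue, Thu-Fri (4 days) \tab compressed \cr
#'   #4 \tab Mon-Tue, Thu (3 days) \tab strongly compressed \cr
#'   #5 \tab Mon-Sat (6 days) \tab spread out \cr
#'   #6 \tab Mon-Sun (7 days) \tab maximally spread out
#' }
#'
#' @param weekly_hours Total weekly hours shared by all configurations
#'   (default 40; the study also uses 30 and 50).
#' @return Named list of six \code{\link{workweek_config}} objects.
#' @export
workweek_presets <- function(weekly_hours = 40) {
  days <- list("#1" = 0:4, "#2" = c(0L, 1L, 3L, 4L, 5L),
               "#3" = c(0L, 1L, 3L, 4L), "#4" = c(0L, 1L, 3L),
               "#5" = 0:5, "#6" = 0:6)
  lapply(stats::setNames(names(days), names(days)), function(nm) {
    workweek_config(nm, days[[nm]], weekly_hours / length(days[[nm]]))
  })
}

#' Per-day working hours for a weekly total
#'
#' @param config A \code{\link{workweek_config}} used as a template (its
#'   working-day set is kept, hours are recomputed).
#' @param weekly_hours Weekly total (> 0).
#' @return Hours per working day (\code{weekly_hours / number of days}).
#' @examples
#' hours_per_day(workweek_presets()[["#4"]], 30)  # 10
#' @export
hours_per_day <- function(config, weekly_hours) {
  stopifnot(inherits(config, "workweek"), weekly_hours > 0)
  if (!length(config$working_days)) stop("no working days")
  weekly_hours / length(config$working_days)
}

#' Format durations and clock times
#'
#' \code{format_hours} renders a duration as \code{"XhYYm"} rounded to the
#' nearest minute, dropping the minute part when it is zero (\code{"8h"},
#' \code{"13h20m"}).  \code{format_clock} renders a clock hour as
#' \code{"HH:MM"}.
#'
#' @param hours Duration or clock time in hours.
#' @return Character scalar/vector.
#' @export
format_hours <- function(hours) {
  total_min <- round(hours * 60)
  h <- total_min %/% 60
  m <- total_min %% 60
  ifelse(m == 0, sprintf("%dh", h), sprintf("%dh%02dm", h, m))
}

#' @rdname format_hours
#' @export
format_clock <- function(hours) {
  total_min <- round(hours * 60)
  sprintf("%02d:%02d", total_min %/% 60, total_min %% 60)
}

#' Resolve the schedule of one simulation day
#'
#' @param config A \code{\link{workweek_config}}.
#' @param day_index 0-based simulation day; day 0 is a Monday.
#' @param wake Wake clock hour; defaults to the configuration's wake time.
#' @return List with \code{day_index}, \code{weekday} (0 = Mon),
#'   \code{wake_abs} (hours since simulation start) and \code{work_window}
#'   (\code{c(start, end)} in hours since simulation start, or \code{NULL}
#'   on free days).
#' @examples
#' resolve_schedule(standard_week(), 0)$work_window  # 8.5 16.5
#' resolve_schedule(standard_week(), 6)$work_window  # NULL (Sunday)
#' @export
resolve_schedule <- function(config, day_index, wake = config$wake) {
  stopifnot(inherits(config, "workweek"),
            is.numeric(day_index), day_index >= 0,
            day_index == as.integer(day_index))
  day_index <- as.integer(day_index)
  weekday <- day_index %% 7L
  base <- 24 * day_index
  window <- NULL
  if (weekday %in% config$working_days) {
    if (config$work_start + config$hours_per_day > 24)
      stop("work window crosses midnight")
    window <- base + c(config$work_start,
                       config$work_start + config$hours_per_day)
  }
  list(day_index = day_index, weekday = weekday,
       wake_abs = base + wake, work_window = window)
}

#' Scale a work-impulse rate to the day length
#'
#' \eqn{\lambda_W} is defined per standard 8-hour working day; longer
#' (shorter) days expose a person to proportionally more (fewer) work
#' stressors, so the effective daily rate is
#' \eqn{\lambda_W \times \mathrm{hours}/8}.
#'
#' @param lambda_work Rate per 8-hour day (>= 0).
#' @param hours_per_day Actual working-day length in hours (> 0).
#' @return Effective expected work impulses for that day.
#' @examples
#' scaled_work_rate(16, 4)   # 8
#' @export
scaled_work_rate <- function(lambda_work, hours_per_day) {
  stopifnot(all(lambda_work >= 0), hours_per_day > 0)
  lambda_work * hours_per_day / 8
}
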