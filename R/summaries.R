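#' Group diurnal cortisol curve
#'
#' Aggregates per-person cortisol over a window aligned to wake time on one
#' simulation day: per-step mean, standard error, and percentile bands
#' across persons. By convention the curve spans wake to 16 hours after
#' waking; pass \code{from = -4, to = 0} for the night window.
#'
#' @param result A \code{\link{simulate_population}} result obtained with
#'   \code{keep_cortisol = TRUE}.
#' @param day 0-based simulation day (default 0, as the comparison plots
#'   use only the first simulated day).
#' @param from,to Window in hours relative to wake (defaults 0 and 16).
#' @param wake Wake clock hour (default: the configuration's wake time).
#' @param probs Percentiles for the bands (default 2.5\% and 97.5\%).
#' @return Data frame of class \code{"day_curve"}: \code{t_since_wake},
#'   \code{mean}, \code{se}, and one \code{p<q>} column per percentile.
#' @export
day_curve <- function(result, day = 0, from = 0, to = 16,
                      wake = result$config$wake, probs = c(0.025, 0.975)) {
  if (is.null(result$cortisol))
    stop("simulate_population() must be run with keep_cortisol = TRUE")
  stopifnot(day >= 0, day < result$days, to > from)
  wake_abs <- 24 * day + wake
  sel <- which(result$t >= wake_abs + from - 1e-9 &
               result$t <= wake_abs + to + 1e-9)
  if (!length(sel)) stop("window outside the simulated horizon")
  m <- result$cortisol[sel, , drop = FALSE]
  n <- ncol(m)
  if (n < 1L) stop("empty population")
  qs <- t(apply(m, 1, stats::quantile, probs = probs, names = FALSE))
  out <- data.frame(t_since_wake = result$t[sel] - wake_abs,
                    mean = rowMeans(m),
                    se = apply(m, 1, stats::sd) / sqrt(n))
  for (j in seq_along(probs))
    out[[sprintf("p%g", 100 * probs[j])]] <- qs[, j]
  structure(out, day = day, n = n, class = c("day_curve", "data.frame"))
}

#' @export
plot.day_curve <- function(x, ...) {
  graphics::plot(x$t_since_wake, x$mean, type = "l", lwd = 2,
                 xlab = "hours since waking", ylab = "cortisol (a.u.)", ...)
  lo <- grep("^p", names(x), value = TRUE)
  for (nm in lo) graphics::lines(x$t_since_wake, x[[nm]], lty = 3)
  invisible(x)
}

#' Area under the diurnal cortisol curve, with respect to ground
#'
#' Trapezoidal area of the sampled curve over its full span (the AUCg of
#' the diurnal-cortisol literature).
#'
#' @param samples Cortisol values.
#' @param times Strictly increasing sampling times (hours).
#' @return Area in concentration-hours.
#' @export
auc_g <- function(samples, times) {
  stopifnot(length(samples) == length(times), length(samples) >= 2L,
            all(diff(times) > 0))
  pracma::trapz(times, samples)
}

#' Area under the curve with respect to the increase
#'
#' AUCg minus the rectangle at the first (waking) sample:
#' \code{auc_g - samples[1] * (max(times) - min(times))}. Negative when the
#' curve mostly falls below its waking value.
#'
#' @inheritParams auc_g
#' @return Area in concentration-hours.
#' @export
auc_i <- function(samples, times) {
  auc_g(samples, times) - samples[1] * (times[length(times)] - times[1])
}

#' Wake-to-bed cortisol slope
#'
#' Two-point slope between the samples nearest to wake and bed times;
#' bed defaults to 16 hours after waking.  \code{method = "regression"}
#' instead fits an ordinary least-squares line through all samples in the
#' window.
#'
#' @inheritParams auc_g
#' @param wake_t Wake time (hours, same axis as \code{times}).
#' @param bed_t Bed time; default \code{wake_t + 16}.
#' @param method \code{"endpoints"} (default) or \code{"regression"}.
#' @return Slope in concentration per hour (negative for the typical
#'   declining day profile).
#' @export
wake_bed_slope <- function(samples, times, wake_t, bed_t = wake_t + 16,
                           method = c("endpoints", "regression")) {
  method <- match.arg(method)
  stopifnot(length(samples) == length(times), length(samples) >= 2L)
  if (bed_t <= wake_t) stop("bed_t must be after wake_t")
  if (method == "endpoints") {
    i <- which.min(abs(times - wake_t))
    j <- which.min(abs(times - bed_t))
    if (i == j) stop("no distinct samples at wake and bed times")
    (samples[j] - samples[i]) / (times[j] - times[i])
  } else {
    keep <- times >= wake_t & times <= bed_t
    unname(stats::coef(stats::lm(samples[keep] ~ times[keep]))[2])
  }
}

#' Per-person diurnal cortisol indices
#'
#' Computes AUCg, AUCi and the wake-to-bed slope for every person on one
#' simulation day, over the wake-to-bed window (wake + 16 h), on the full
#' sampling grid.
#'
#' @inheritParams day_curve
#' @param span Hours from wake to bed (default 16).
#' @return Data frame of \code{person_id}, \code{auc_g}, \code{auc_i},
#'   \code{slope}.
#' @export
diurnal_indices <- function(result, day = 0, wake = result$config$wake,
                            span = 16) {
  if (is.null(result$cortisol))
    stop("simulate_population() must be run with keep_cortisol = TRUE")
  wake_abs <- 24 * day + wake
  sel <- which(result$t >= wake_abs - 1e-9 &
               result$t <= wake_abs + span + 1e-9)
  times <- result$t[sel]
  m <- result$cortisol[sel, , drop = FALSE]
  data.frame(
    person_id = result$people$person_id,
    auc_g = apply(m, 2, auc_g, times = times),
    auc_i = apply(m, 2, auc_i, times = times),
    slope = apply(m, 2, wake_bed_slope, times = times, wake_t = times[1],
                  bed_t = times[length(times)]))
}

#' Fraction of allostatic load accrued near the morning peak
#'
#' Share of the total load increase that occurs within \code{window} hours
#' after waking (any day). In the reference parameterization most load
#' accrues at the cortisol morning peak rather than during working hours.
#'
#' @param tc A \code{\link{simulate_person}} time course.
#' @param wake Wake clock hour (default 7).
#' @param window Hours after waking to attribute to the morning peak
#'   (default 2).
#' @return Fraction in \code{[0, 1]}; \code{NA} when no load accrued.
#' @export
morning_load_fraction <- function(tc, wake = 7, window = 2) {
  n <- nrow(tc)
  if (n < 2L) return(NA_real_)
  dL <- diff(tc$load)
  total <- sum(dL)
  if (total == 0) return(NA_real_)
  tod <- tc$t[-n] %% 24
  sum(dL[tod >= wake & tod < wake + window]) / total
}

#' Write diurnal summaries to CSV
#'
#' \code{write_indices}: \code{person_id, auc_g, auc_i, slope}.
#' \code{write_day_curve}: \code{t_since_wake_hours, mean, se} plus
#' percentile columns.
#'
#' @param x A \code{\link{diurnal_indices}} or \code{\link{day_curve}}
#'   result.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_indices <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_indices
#' @export
write_day_curve <- function(x, path) {
  out <- as.data.frame(x)
  names(out)[names(out) == "t_since_wake"] <- "t_since_wake_hours"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
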