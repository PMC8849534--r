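#' Distribution specifications
#'
#' Light-weight validated containers for the distributions from which
#' person-level traits are drawn: gamma (impulse-rate heterogeneity),
#' uniform (evenly spread exposure, work-impulse timing) and normal
#' (cortisol decay constants).
#'
#' @param shape,scale Gamma shape \eqn{k > 0} and scale \eqn{\theta > 0};
#'   the mean is \eqn{k\theta}.
#' @param min,max Uniform bounds, \code{min <= max}.
#' @param mean,sd Normal mean and standard deviation (\code{sd >= 0}).
#'
#' @return An object of class \code{c("<kind>_spec", "dist_spec")}.
#' @examples
#' gamma_spec(3, 14)          # night-impulse rates, mean 42/night
#' uniform_spec(1, 50)        # evenly spread work-impulse rates
#' normal_spec(0.52, 0.05)    # cortisol decay constants (per hour)
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
gamma_spec <- function(shape, scale) {
  stopifnot(is.numeric(shape), length(shape) == 1L, is.finite(shape), shape > 0,
            is.numeric(scale), length(scale) == 1L, is.finite(scale), scale > 0)
  structure(list(shape = shape, scale = scale),
            class = c("gamma_spec", "dist_spec"))
}

#' @rdname dist_spec
#' @export
uniform_spec <- function(min, max) {
  stopifnot(is.numeric(min), length(min) == 1L, is.finite(min),
            is.numeric(max), length(max) == 1L, is.finite(max), min <= max)
  structure(list(min = min, max = max),
            class = c("uniform_spec", "dist_spec"))
}

#' @rdname dist_spec
#' @export
normal_spec <- function(mean, sd) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sd), length(sd) == 1L, is.finite(sd), sd >= 0)
  structure(list(mean = mean, sd = sd),
            class = c("normal_spec", "dist_spec"))
}

#' Draw from a distribution specification
#'
#' @param spec A \code{\link{dist_spec}} object.
#' @param n Number of draws.
#' @return Numeric vector of length \code{n}, drawn from the current RNG
#'   stream.
#' @export
draw_spec <- function(spec, n) UseMethod("draw_spec")

#' @export
draw_spec.gamma_spec <- function(spec, n) {
  stats::rgamma(n, shape = spec$shape, scale = spec$scale)
}

#' @export
draw_spec.uniform_spec <- function(spec, n) {
  stats::runif(n, min = spec$min, max = spec$max)
}

#' @export
draw_spec.normal_spec <- function(spec, n) {
  stats::rnorm(n, mean = spec$mean, sd = spec$sd)
}

#' @export
draw_spec.default <- function(spec, n) {
  stop("not a distribution specification: ", paste(class(spec), collapse = "/"))
}

# Theoretical mean, used for validation messages and sanity checks.
spec_mean <- function(spec) {
  switch(class(spec)[1L],
         gamma_spec   = spec$shape * spec$scale,
         uniform_spec = (spec$min + spec$max) / 2,
         normal_spec  = spec$mean,
         stop("not a distribution specification"))
}

#' @export
print.dist_spec <- function(x, ...) {
  kind <- sub("_spec$", "", class(x)[1L])
  args <- paste(sprintf("%s = %g", names(unclass(x)), unlist(x)),
                collapse = ", ")
  cat(sprintf("<%s(%s), mean %g>\n", kind, args, spec_mean(x)))
  invisible(x)
}
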