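#' Distribution specifications for the synthetic iEEG generator
#'
#' HFO pulse trains are parameterized by distributions of the inter-pulse gap
#' `s` (s), pulse duration `d` (s), pulse amplitude `K` (uV), intra-event
#' oscillation frequency `f0` (Hz) and the HFO-generating tissue proportion
#' `rho` (area of HFO-generating tissue relative to the reference electrode
#' contact area, dimensionless). A `dist_spec` is a small serializable
#' description of one such distribution.
#'
#' @param value Point-mass value (`dist_const`).
#' @param mean Mean of the distribution.
#' @param shape Gamma shape parameter; the rate is `shape / mean`.
#' @param sd Standard deviation of the untruncated normal.
#' @param lower,upper Truncation bounds (`dist_truncnorm`) or range
#'   (`dist_uniform`).
#' @return An object of class `dist_spec`.
#' @examples
#' draw_dist(dist_gamma(mean = 0.05, shape = 4), 5)
#' @name dist_spec
NULL

new_dist_spec <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_const <- function(value) {
  stopifnot(is.finite(value))
  new_dist_spec("const", value = value)
}

#' @rdname dist_spec
#' @export
dist_exponential <- function(mean) {
  stopifnot(is.finite(mean), mean > 0)
  new_dist_spec("exponential", mean = mean)
}

#' @rdname dist_spec
#' @export
dist_gamma <- function(mean, shape) {
  stopifnot(mean > 0, shape > 0)
  new_dist_spec("gamma", mean = mean, shape = shape)
}

#' @rdname dist_spec
#' @export
dist_truncnorm <- function(mean, sd, lower = 0, upper = Inf) {
  stopifnot(sd >= 0, lower < upper)
  new_dist_spec("truncnorm", mean = mean, sd = sd, lower = lower, upper = upper)
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(lower, upper) {
  stopifnot(lower < upper)
  new_dist_spec("uniform", lower = lower, upper = upper)
}

#' Draw from a distribution specification
#'
#' Uses the current R random-number state; callers control reproducibility by
#' seeding (see [simulate_recording()]).
#'
#' @param spec A [dist_spec] object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$kind,
    const = rep(spec$value, n),
    exponential = stats::rexp(n, rate = 1 / spec$mean),
    gamma = stats::rgamma(n, shape = spec$shape, rate = spec$shape / spec$mean),
    truncnorm = {
      # inverse-CDF sampling keeps truncation exact and vectorized
      plo <- stats::pnorm(spec$lower, spec$mean, spec$sd)
      phi <- stats::pnorm(spec$upper, spec$mean, spec$sd)
      stats::qnorm(stats::runif(n, plo, phi), spec$mean, spec$sd)
    },
    uniform = stats::runif(n, spec$lower, spec$upper),
    stop("unknown distribution kind: ", spec$kind)
  )
}

#' Support of a distribution specification
#'
#' @param spec A [dist_spec] object.
#' @return Length-2 numeric `c(lower, upper)` (bounds of the support).
#' @export
dist_support <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$kind,
    const = c(spec$value, spec$value),
    exponential = c(0, Inf),
    gamma = c(0, Inf),
    truncnorm = c(spec$lower, spec$upper),
    uniform = c(spec$lower, spec$upper)
  )
}

#' Expected value of a distribution specification
#'
#' Used by renewal-process sanity checks on pulse counts.
#'
#' @param spec A [dist_spec] object.
#' @return Numeric scalar.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$kind,
    const = spec$value,
    exponential = spec$mean,
    gamma = spec$mean,
    truncnorm = {
      a <- (spec$lower - spec$mean) / spec$sd
      b <- (spec$upper - spec$mean) / spec$sd
      z <- stats::pnorm(b) - stats::pnorm(a)
      spec$mean + spec$sd * (stats::dnorm(a) - stats::dnorm(b)) / z
    },
    uniform = (spec$lower + spec$upper) / 2
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  cat("<dist_spec>", x$kind, paste(names(pars), unlist(pars), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

dist_to_list <- function(spec) unclass(spec)

dist_from_list <- function(lst) {
  do.call(new_dist_spec, c(list(kind = lst$kind), lst[setdiff(names(lst), "kind")]))
}
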