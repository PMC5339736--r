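#' Moment-matched stochastic drivers
#'
#' Annual water availability `W` and tax fraction `T` fluctuate around fixed
#' means; only their coefficient of variation (CV = sd / mean) is dialled.
#' `W` follows a lognormal law (only positive values make sense for water);
#' `T` a beta law (a tax fraction lives in `[0, 1]`). `cv = 0` denotes an
#' exactly constant driver, so the fixed-driver benchmark runs through the
#' same code path.
#'
#' `lognormal_from_mean_cv()` solves the lognormal moment equations
#' `sigma^2 = log(1 + cv^2)`, `mu = log(mean) - sigma^2 / 2`.
#'
#' `beta_from_mean_cv()` solves the beta moment equations via the precision
#' `nu = mean (1 - mean) / var - 1` (with `var = (cv * mean)^2`),
#' `alpha = mean * nu`, `beta = (1 - mean) * nu`. A beta law with the given
#' mean exists only for `cv^2 < (1 - mean) / mean`; an infeasible `cv`
#' raises an error naming that bound.
#'
#' @param mean driver mean; positive (lognormal) or in (0, 1) (beta).
#' @param cv coefficient of variation, `>= 0`.
#' @return an object of class `driver_spec`: a list with `kind`, `mean`,
#'   `cv`, and the natural parameters (`mu`, `sigma` or `alpha`, `beta`;
#'   `NA` for a degenerate `cv = 0` spec).
#' @examples
#' lognormal_from_mean_cv(1, 0.2)
#' beta_from_mean_cv(0.2, 0.8)   # alpha = 1.05, beta = 4.2
#' @name driver_spec
NULL

new_driver_spec <- function(kind, mean, cv, ...) {
  structure(list(kind = kind, mean = mean, cv = cv, ...),
            class = "driver_spec")
}

#' @rdname driver_spec
#' @export
lognormal_from_mean_cv <- function(mean, cv) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    stop("lognormal mean must be a positive scalar", call. = FALSE)
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv < 0)
    stop("cv must be a nonnegative scalar", call. = FALSE)
  if (cv == 0)
    return(new_driver_spec("lognormal", mean, 0, mu = NA_real_,
                           sigma = NA_real_))
  sigma2 <- log(1 + cv^2)
  new_driver_spec("lognormal", mean, cv,
                  mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' @rdname driver_spec
#' @export
beta_from_mean_cv <- function(mean, cv) {
  if (!is.numeric(mean) || length(mean) != 1L || mean <= 0 || mean >= 1)
    stop("beta mean must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv < 0)
    stop("cv must be a nonnegative scalar", call. = FALSE)
  if (cv == 0)
    return(new_driver_spec("beta", mean, 0, alpha = NA_real_,
                           beta = NA_real_))
  bound <- (1 - mean) / mean
  if (cv^2 >= bound)
    stop(sprintf(paste0("infeasible beta driver: cv^2 = %g must be below ",
                        "(1 - mean)/mean = %g for mean = %g"),
                 cv^2, bound, mean), call. = FALSE)
  nu <- mean * (1 - mean) / (cv * mean)^2 - 1
  new_driver_spec("beta", mean, cv, alpha = mean * nu, beta = (1 - mean) * nu)
}

#' @export
print.driver_spec <- function(x, ...) {
  cat(sprintf("%s driver: mean = %g, cv = %g", x$kind, x$mean, x$cv))
  if (x$cv == 0) cat(" (degenerate)\n")
  else if (x$kind == "lognormal")
    cat(sprintf(" (mu = %.6g, sigma = %.6g)\n", x$mu, x$sigma))
  else cat(sprintf(" (alpha = %.6g, beta = %.6g)\n", x$alpha, x$beta))
  invisible(x)
}

#' Draw annual values from a driver
#'
#' @param spec a [driver_spec] object.
#' @param n number of annual draws.
#' @return a numeric vector of length `n`; constant for a degenerate spec.
#'   Uses the current R RNG stream (seed with `set.seed()`).
#' @export
draw_driver <- function(spec, n) {
  stopifnot(inherits(spec, "driver_spec"), n >= 1)
  if (spec$cv == 0) return(rep(spec$mean, n))
  switch(spec$kind,
         lognormal = stats::rlnorm(n, spec$mu, spec$sigma),
         beta      = stats::rbeta(n, spec$alpha, spec$beta),
         stop("unknown driver kind: ", spec$kind, call. = FALSE))
}

#' Draw a paired annual series of water and taxation
#'
#' The drivers change once per model year; within a year they are constant.
#' Water and taxation series are drawn independently of each other (the
#' model studies each driver's stochasticity in isolation), all water values
#' first, then all tax values, from a single seeded stream -- so the same
#' seed always reproduces the same pair of series.
#'
#' @param w_spec,t_spec [driver_spec] objects for water and taxation.
#' @param n_years number of years.
#' @param seed integer seed.
#' @return a data.frame with columns `year`, `W`, `T`.
#' @export
draw_annual_series <- function(w_spec, t_spec, n_years, seed) {
  stopifnot(n_years >= 1)
  set.seed(seed)
  data.frame(year = seq_len(n_years),
             W = draw_driver(w_spec, n_years),
             T = draw_driver(t_spec, n_years))
}
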