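#' Model parameters for the irrigation population model
#'
#' Bundles every constant of the payoff construction and of the demographic
#' process into a validated `irristoch_params` object.
#'
#' The model tracks the number of irrigators `N` as a birth-death process.
#' Per-capita payoff inside the system is
#' \deqn{\pi(N; W, T) = (1 - T)\, h\, W(N)\, g(x),}
#' where `W(N) = max(0, W - aN)` is the water left after per-capita usage `a`,
#' and `g(x) = z / (z + kappa)` with `z = max(0, x - x0)` is the performance of
#' the shared infrastructure as a saturating function of the maintenance
#' funding index `x = T N h W(N)` (total tax revenue). Below the funding
#' threshold `x0` the infrastructure is inoperative and the payoff is zero.
#'
#' Entry and exit rates respond to the payoff gap against the outside option
#' `pi_o` on top of a baseline demographic turnover `m`; see
#' [entry_exit_rates()].
#'
#' The defaults are the published constants `m = 1`, `h = 0.01`, `r = 1`,
#' `a = 1e-4`, `W_bar = 1`, `T_bar = 0.2`, `dt = 5e-5` years, with
#' `(x0, kappa, pi_o)` obtained from [calibrate_payoff()] so that the
#' population landmarks are exactly `N_tilde = 727`, `N_M = 3333`,
#' `N_star = 7015` at baseline drivers.
#'
#' @param m baseline entry/exit rate (events per year); the demographic
#'   noise floor. Must be positive.
#' @param h income per person per unit of available water.
#' @param r responsiveness of population flow to the payoff incentive.
#' @param a per-capita water usage rate (water units per person).
#' @param W_bar mean annual water availability.
#' @param T_bar mean tax fraction, strictly inside (0, 1).
#' @param dt time-step length in years. The default, 5e-5 yr (about 26
#'   minutes), gives 20,000 steps per year.
#' @param scheme transition scheme: `"jump"` (forced +-1 move each step with
#'   probabilities b/(b+d), d/(b+d)) or `"bernoulli"` (rate-thinned moves
#'   with probabilities b*dt, d*dt and a stay probability).
#' @param x0 infrastructure maintenance threshold on the funding index.
#' @param kappa half-saturation constant of infrastructure performance.
#' @param pi_o outside per-capita payoff. Must be positive.
#' @param anchors integer landmarks `c(n_tilde, n_m, n_star)` used to
#'   calibrate `x0`, `kappa`, `pi_o` when those are not given explicitly.
#' @return An object of class `irristoch_params` (a named list).
#' @seealso [calibrate_payoff()], [compute_thresholds()]
#' @examples
#' p <- irristoch_params()
#' p$x0
#' compute_thresholds(p)
#' @export
irristoch_params <- function(m = 1, h = 0.01, r = 1, a = 1e-4,
                             W_bar = 1, T_bar = 0.2,
                             dt = 5e-5, scheme = c("jump", "bernoulli"),
                             x0 = NULL, kappa = NULL, pi_o = NULL,
                             anchors = c(727L, 3333L, 7015L)) {
  scheme <- match.arg(scheme)
  # range checks that calibration itself depends on come first, so config
  # errors name the offending field rather than a downstream domain check
  if (!is.numeric(T_bar) || length(T_bar) != 1L || !is.finite(T_bar) ||
      T_bar <= 0 || T_bar >= 1)
    stop("parameter 'T_bar' must lie strictly inside (0, 1)", call. = FALSE)
  for (f in c(m = m, h = h, r = r, a = a, W_bar = W_bar)) {
    if (!is.numeric(f) || !is.finite(f) || f <= 0)
      stop("parameters m, h, r, a, W_bar must be positive", call. = FALSE)
  }
  p <- list(m = m, h = h, r = r, a = a, W_bar = W_bar, T_bar = T_bar,
            dt = dt, scheme = scheme, x0 = x0, kappa = kappa, pi_o = pi_o)
  if (is.null(x0) || is.null(kappa) || is.null(pi_o)) {
    cal <- calibrate_payoff(anchors[1], anchors[2], anchors[3], base = p)
    if (is.null(p$x0))    p$x0    <- cal$x0
    if (is.null(p$kappa)) p$kappa <- cal$kappa
    if (is.null(p$pi_o))  p$pi_o  <- cal$pi_o
  }
  class(p) <- "irristoch_params"
  validate_params(p)
  p
}

#' @export
print.irristoch_params <- function(x, ...) {
  cat("Irrigation SES model parameters (", x$scheme, " scheme)\n", sep = "")
  cat(sprintf("  m = %g, h = %g, r = %g, a = %g\n", x$m, x$h, x$r, x$a))
  cat(sprintf("  W_bar = %g, T_bar = %g, dt = %g yr (%d steps/yr)\n",
              x$W_bar, x$T_bar, x$dt, steps_per_year(x)))
  cat(sprintf("  x0 = %.6g, kappa = %.6g, pi_o = %.6g\n",
              x$x0, x$kappa, x$pi_o))
  invisible(x)
}

#' Validate an `irristoch_params` object
#'
#' Checks positivity and range constraints on every field and, for the
#' `bernoulli` scheme, that `(b + d) * dt <= 1` over the reachable range of
#' `N` so the per-step move probabilities are valid.
#'
#' @param p an `irristoch_params` object.
#' @return `p`, invisibly; errors name the offending field.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "irristoch_params"))
  pos <- c("m", "h", "r", "a", "W_bar", "dt", "kappa", "pi_o")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) ||
        p[[f]] <= 0)
      stop("parameter '", f, "' must be a positive finite scalar", call. = FALSE)
  }
  if (!is.numeric(p$x0) || p$x0 < 0)
    stop("parameter 'x0' must be nonnegative", call. = FALSE)
  if (!is.numeric(p$T_bar) || p$T_bar <= 0 || p$T_bar >= 1)
    stop("parameter 'T_bar' must lie strictly inside (0, 1)", call. = FALSE)
  if (!p$scheme %in% c("jump", "bernoulli"))
    stop("parameter 'scheme' must be 'jump' or 'bernoulli'", call. = FALSE)
  if (p$scheme == "bernoulli") {
    n_cap <- default_n_cap(p)
    rates <- entry_exit_rates(0:n_cap, p$W_bar, p$T_bar, p)
    if (max(rates$b + rates$d) * p$dt > 1)
      stop("bernoulli scheme invalid: (b + d) * dt exceeds 1 for some N; ",
           "reduce dt", call. = FALSE)
  }
  invisible(p)
}

#' Number of simulation steps per model year
#'
#' @param p an `irristoch_params` object (or anything with a `dt` field).
#' @return `round(1 / dt)` as an integer; 20,000 at the default `dt`.
#' @export
steps_per_year <- function(p) as.integer(round(1 / p$dt))

# Reachable-state cap used for stationary supports and guard rails: the
# population cannot drift above W_bar / a (payoff is zero there), so a 20%
# margin is ample.
default_n_cap <- function(p) as.integer(ceiling(1.2 * p$W_bar / p$a))

#' Calibrate the payoff constants from the population landmarks
#'
#' Pins the three free constants of the payoff family -- the maintenance
#' threshold `x0`, the half-saturation constant `kappa`, and the outside
#' payoff `pi_o` -- to three integer population landmarks evaluated at the
#' baseline drivers `(W_bar, T_bar)`:
#' \itemize{
#'   \item `x0 = x(n_tilde)`: the funding index at `n_tilde`, making
#'     `n_tilde` the largest population with inoperative infrastructure;
#'   \item `kappa`: the unique positive root of the first-order condition
#'     for the payoff maximum at `n_m`,
#'     `a z_M (z_M + kappa) = (W_bar - a n_m) kappa x'(n_m)` with
#'     `z_M = x(n_m) - x0` (linear in `kappa`, solved in closed form);
#'   \item `pi_o = pi(n_star)`: so the `pi >= pi_o` comparison recovers
#'     `n_star` exactly, without tolerance.
#' }
#'
#' With the default anchors `(727, 3333, 7015)` this yields
#' `x0 ~ 1.3483`, `kappa ~ 7.102`, `pi_o ~ 6.821e-4`, and
#' [compute_thresholds()] on the calibrated parameters recovers the anchors
#' exactly (integer equality).
#'
#' @param n_tilde,n_m,n_star integer anchors with
#'   `n_tilde < n_m < n_star < W_bar / a`.
#' @param base a list (or `irristoch_params`) carrying `m, h, r, a, W_bar,
#'   T_bar`; `x0`, `kappa`, `pi_o` fields are ignored.
#' @return a list with components `x0`, `kappa`, `pi_o`.
#' @examples
#' calibrate_payoff(727, 3333, 7015,
#'                  base = list(m = 1, h = 0.01, r = 1, a = 1e-4,
#'                              W_bar = 1, T_bar = 0.2))
#' @export
calibrate_payoff <- function(n_tilde, n_m, n_star, base) {
  a <- base$a; h <- base$h; W <- base$W_bar; T <- base$T_bar
  stopifnot(is.numeric(a), is.numeric(h), is.numeric(W), is.numeric(T))
  n_tilde <- as.integer(n_tilde); n_m <- as.integer(n_m)
  n_star <- as.integer(n_star)
  if (!(n_tilde < n_m && n_m < n_star && n_star < W / a))
    stop("anchors must satisfy n_tilde < n_m < n_star < W_bar/a", call. = FALSE)
  # evaluate x and pi through the very same code paths the model uses, so
  # the calibrated constants recover the anchors bitwise (no tolerance)
  tmp <- list(m = base$m %||% 1, h = h, r = base$r %||% 1, a = a,
              W_bar = W, T_bar = T, x0 = 0, kappa = 1)
  x_of  <- function(N) funding_index(N, W, T, tmp)
  xp_of <- function(N) T * h * (W - 2 * a * N)
  x0  <- x_of(n_tilde)
  z_M <- x_of(n_m) - x0
  if (z_M <= 0)
    stop("calibration error: funding index at n_m does not exceed x0",
         call. = FALSE)
  den <- (W - a * n_m) * xp_of(n_m) - a * z_M
  kappa <- a * z_M^2 / den
  if (!is.finite(kappa) || kappa <= 0)
    stop("calibration error: first-order condition has no positive root; ",
         "anchors are inconsistent with the payoff family", call. = FALSE)
  tmp$x0 <- x0; tmp$kappa <- kappa
  pi_o <- per_capita_payoff(n_star, W, T, tmp)
  if (pi_o <= 0)
    stop("calibration error: payoff at n_star is not positive", call. = FALSE)
  list(x0 = x0, kappa = kappa, pi_o = pi_o)
}
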