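#' Water available per unit time after population usage
#'
#' `max(0, W - a N)`: the water left once `N` irrigators each draw `a`.
#' Available water is exactly zero for `N >= W / a` -- one cannot have a
#' negative amount of water.
#'
#' @param N population size(s), nonnegative integer(s). Vectorized.
#' @param W annual water availability, nonnegative.
#' @param params an [irristoch_params()] object.
#' @return available water, same length as `N`.
#' @export
available_water <- function(N, W, params) {
  check_N(N); check_W(W)
  pmax(0, W - params$a * N)
}

# funding index: total tax revenue available for infrastructure maintenance
funding_index <- function(N, W, T, params) {
  T * N * params$h * available_water(N, W, params)
}

#' Infrastructure performance
#'
#' The condition of the shared irrigation infrastructure as a function of the
#' maintenance funding it receives. Tax revenue `x = T N h W(N)` above the
#' maintenance threshold `x0` improves performance with saturating returns:
#' `g = z / (z + kappa)` where `z = max(0, x - x0)`. The more people use the
#' water and the more tax they pay, the better the infrastructure -- up to
#' diminishing returns set by `kappa`. At or below the threshold (`x <= x0`)
#' the infrastructure is inoperative and performance is exactly 0.
#'
#' @inheritParams available_water
#' @param T tax fraction in `[0, 1]`.
#' @return performance in `[0, 1)`, same length as `N`.
#' @export
infrastructure_performance <- function(N, W, T, params) {
  check_N(N); check_W(W); check_T(T)
  z <- pmax(0, funding_index(N, W, T, params) - params$x0)
  z / (z + params$kappa)
}

#' Per-capita payoff inside the irrigation system
#'
#' After-tax income from the water an individual can actually harvest given
#' the state of the infrastructure:
#' \deqn{\pi(N; W, T) = (1 - T)\, h\, \max(0, W - aN)\, g(x).}
#' Always nonnegative; identically zero when the infrastructure is
#' unmaintained (`N <= N_tilde`), when the water is exhausted
#' (`N >= W / a`), and at full or zero taxation.
#'
#' @inheritParams infrastructure_performance
#' @return payoff per person per year, same length as `N`.
#' @export
per_capita_payoff <- function(N, W, T, params) {
  (1 - T) * params$h * available_water(N, W, params) *
    infrastructure_performance(N, W, T, params)
}

#' Population entry and exit rates
#'
#' Rates of the birth-death process for the irrigator population. Both sides
#' carry the baseline demographic turnover `m` (birth, death, background
#' migration). The side favoured by the payoff gap
#' `Delta = pi(N; W, T) - pi_o` gains an incentive term `r N |Delta|`:
#' entry if working inside pays better than outside (`Delta >= 0`), exit
#' otherwise. At the boundary `N = 0` the process can only gain its first
#' member: `b(0) = m`, `d(0) = 0`.
#'
#' @inheritParams infrastructure_performance
#' @return a list with numeric vectors `b` (entry) and `d` (exit), in events
#'   per year.
#' @export
entry_exit_rates <- function(N, W, T, params) {
  check_N(N)
  delta <- per_capita_payoff(N, W, T, params) - params$pi_o
  inc <- params$r * N * abs(delta)
  b <- ifelse(delta >= 0, params$m + inc, params$m)
  d <- ifelse(delta >= 0, params$m, params$m + inc)
  b[N == 0] <- params$m
  d[N == 0] <- 0
  list(b = b, d = d)
}

#' Population landmarks of the payoff landscape
#'
#' Computes, at fixed drivers `(W, T)`:
#' \describe{
#'   \item{`n_tilde`}{the critical maintenance threshold: the largest integer
#'     population with zero infrastructure performance. Below it, irrigators
#'     cannot fund enough maintenance to keep the system operative.}
#'   \item{`n_low`}{the lower payoff-parity crossing: the smallest integer
#'     with `pi >= pi_o`. Together with `n_star` it delimits the attraction
#'     basin where entry outpaces exit.}
#'   \item{`n_m`}{the payoff-maximizing population, by exhaustive integer
#'     scan over `[0, floor(W/a)]`, ties broken toward the smaller `N`.}
#'   \item{`n_star`}{the largest integer with `pi >= pi_o`: where the
#'     incentive to work inside the system equals the outside option; the
#'     stochastic attractor of the viable system.}
#'   \item{`pi_max`}{the payoff at `n_m`.}
#' }
#' `n_low` and `n_star` are located by integer bisection on the rising branch
#' `(n_tilde, n_m)` and the falling branch `(n_m, floor(W/a))` respectively,
#' exploiting the unimodality of `pi`.
#'
#' If the payoff never reaches `pi_o` the system is nonviable -- exit
#' outpaces entry at every population size and the population ultimately
#' collapses; `n_low`, `n_star` and `pi_max`-related landmarks are returned
#' as `NA` with `viable = FALSE`.
#'
#' @param params an [irristoch_params()] object.
#' @param W,T drivers at which to evaluate; default to the baseline means.
#' @return an object of class `irristoch_thresholds`: a list with
#'   `n_tilde`, `n_low`, `n_m`, `n_star`, `pi_max`, `viable`, `W`, `T`.
#' @examples
#' compute_thresholds(irristoch_params())  # 727 / 1199 / 3333 / 7015
#' @export
compute_thresholds <- function(params, W = params$W_bar, T = params$T_bar) {
  check_W(W); check_T(T)
  n_hi <- as.integer(floor(W / params$a))
  grid <- 0:n_hi
  pay <- per_capita_payoff(grid, W, T, params)
  n_m <- grid[which.max(pay)]          # ties to smaller N (first max)
  pi_max <- pay[n_m + 1L]

  # maintenance threshold: upper edge of the low-N dead zone, i.e. the first
  # upward crossing x(n_tilde) <= x0 < x(n_tilde + 1). (Performance is also
  # zero at N >= W/a because the water is exhausted; that is not a
  # maintenance threshold.)
  perf <- infrastructure_performance(grid, W, T, params)
  pos <- which(perf > 0)
  n_tilde <- if (length(pos)) grid[min(pos)] - 1L else n_hi

  viable <- pi_max >= params$pi_o
  if (!viable || T <= 0 || T >= 1) {
    res <- list(n_tilde = n_tilde, n_low = NA_integer_, n_m = n_m,
                n_star = NA_integer_, pi_max = pi_max,
                viable = FALSE, W = W, T = T)
  } else {
    ok <- function(N) per_capita_payoff(N, W, T, params) >= params$pi_o
    n_low  <- bisect_first_true(ok, lo = max(0L, n_tilde), hi = n_m)
    n_star <- bisect_last_true(ok, lo = n_m, hi = n_hi)
    res <- list(n_tilde = n_tilde, n_low = n_low, n_m = n_m,
                n_star = n_star, pi_max = pi_max,
                viable = TRUE, W = W, T = T)
  }
  class(res) <- "irristoch_thresholds"
  res
}

#' @export
print.irristoch_thresholds <- function(x, ...) {
  cat("Population landmarks at W =", x$W, ", T =", x$T, "\n")
  if (x$viable) {
    cat(sprintf("  N_tilde = %d  (maintenance threshold)\n", x$n_tilde))
    cat(sprintf("  N_low   = %d  (lower payoff-parity crossing)\n", x$n_low))
    cat(sprintf("  N_M     = %d  (payoff maximum, pi_max = %.4g)\n",
                x$n_m, x$pi_max))
    cat(sprintf("  N_star  = %d  (attractor: inside payoff = outside)\n",
                x$n_star))
  } else {
    cat("  NONVIABLE: max payoff", format(x$pi_max, digits = 4),
        "< pi_o; exit outpaces entry at every N\n")
  }
  invisible(x)
}

# integer bisection: smallest N in [lo, hi] with pred(N) TRUE, where pred is
# FALSE at lo (or lo itself qualifies) and TRUE at hi; monotone on the range
bisect_first_true <- function(pred, lo, hi) {
  if (pred(lo)) return(as.integer(lo))
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pred(mid)) hi <- mid else lo <- mid
  }
  as.integer(hi)
}

# largest N in [lo, hi] with pred(N) TRUE; TRUE at lo, FALSE at hi (or hi
# itself qualifies)
bisect_last_true <- function(pred, lo, hi) {
  if (pred(hi)) return(as.integer(hi))
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pred(mid)) lo <- mid else hi <- mid
  }
  as.integer(lo)
}

#' Payoff surface over population and taxation
#'
#' Evaluates `pi(N; W, T)` on a grid, one row per population size and one
#' column per tax level, at fixed water availability. The `pi = pi_o` level
#' set of this surface separates the region where entry outpaces exit
#' (`b > d`) from the region where exit outpaces entry (`b < d`).
#'
#' @param N_grid integer populations (rows).
#' @param T_grid tax fractions in `[0, 1]` (columns).
#' @param W water availability.
#' @param params an [irristoch_params()] object.
#' @return a numeric matrix with `dimnames` carrying the grids.
#' @export
payoff_surface <- function(N_grid, T_grid, W, params) {
  stopifnot(length(N_grid) > 0, length(T_grid) > 0)
  check_T(T_grid)
  out <- vapply(T_grid,
                function(T) per_capita_payoff(N_grid, W, T, params),
                numeric(length(N_grid)))
  out <- matrix(out, nrow = length(N_grid), ncol = length(T_grid),
                dimnames = list(N = N_grid, T = T_grid))
  out
}

# ---- domain checks ---------------------------------------------------------
check_N <- function(N) {
  if (any(!is.finite(N)) || any(N < 0))
    stop("N must be nonnegative", call. = FALSE)
  if (any(N != floor(N)))
    stop("N must be integer-valued", call. = FALSE)
  invisible(N)
}
check_W <- function(W) {
  if (any(!is.finite(W)) || any(W < 0))
    stop("W must be nonnegative", call. = FALSE)
  invisible(W)
}
check_T <- function(T) {
  if (any(!is.finite(T)) || any(T < 0) || any(T > 1))
    stop("T must lie in [0, 1]", call. = FALSE)
  invisible(T)
}
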