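#' Exact stationary distribution of the population chain
#'
#' At fixed drivers `(W, T)` the population is a one-dimensional birth-death
#' chain, whose invariant distribution has the classical product form.
#' For the `bernoulli` (rate-thinned) scheme,
#' \deqn{\mu(N) \propto \prod_{n=1}^{N} b(n-1)/d(n),}
#' and for the `jump` (forced-move) scheme the same product holds with the
#' move probabilities `p_up`, `p_down` in place of the rates, which
#' telescopes to the bernoulli form reweighted by the total rate
#' `b(N) + d(N)`. Masses are accumulated in log space and normalized; the
#' probability valley between the collapsed state and the viable basin
#' spans thousands of orders of magnitude, so structural questions (modes,
#' barrier depth) must be asked of `log_mass`, where the full landscape is
#' representable.
#'
#' This is the analytic oracle against which simulated occupation measures
#' are checked.
#'
#' @param params an [irristoch_params()] object; `params$scheme` selects the
#'   product form unless `scheme` is given.
#' @param W,T fixed drivers; default to the baseline means.
#' @param N_max support truncation; must leave negligible tail (checked:
#'   mass at `N_max` below `1e-10`). Default covers the reachable range
#'   `W_bar / a` with margin.
#' @param scheme optional override of `params$scheme`.
#' @return an object of class `irristoch_distribution`: a list with
#'   integer `support` (0..N_max), numeric `mass` (sums to 1), `log_mass`
#'   (unnormalized, base e), `scheme`, `W`, `T`.
#' @examples
#' d <- stationary_product_form(irristoch_params())
#' summarize_population(d)
#' @export
stationary_product_form <- function(params, W = params$W_bar,
                                    T = params$T_bar,
                                    N_max = default_n_cap(params),
                                    scheme = params$scheme) {
  N_max <- as.integer(N_max)
  grid <- 0:N_max
  rt <- entry_exit_rates(grid, W, T, params)
  # log mu(N) - log mu(0) = sum_{n=1..N} log b(n-1) - log d(n)
  lr <- log(rt$b[1:N_max]) - log(rt$d[2:(N_max + 1)])
  lp <- c(0, cumsum(lr))
  if (scheme == "jump") lp <- lp + log(rt$b + rt$d)  # total-rate reweighting
  lp <- lp - max(lp)
  mass <- exp(lp)
  mass <- mass / sum(mass)
  if (mass[N_max + 1] > 1e-10)
    stop("tail mass at N_max = ", N_max, " is ", format(mass[N_max + 1]),
         " > 1e-10; increase N_max", call. = FALSE)
  structure(list(support = grid, mass = mass, log_mass = lp,
                 scheme = scheme, W = W, T = T),
            class = "irristoch_distribution")
}

#' @export
print.irristoch_distribution <- function(x, ...) {
  s <- summarize_population(x)
  cat(sprintf(paste0("Distribution over N = 0..%d (%s)\n",
                     "  mean = %.2f, sd = %.3f, cv = %.4g, mode = %d\n"),
              max(x$support), if (is.null(x$scheme)) "empirical" else x$scheme,
              s$mean, s$sd, s$cv, x$support[which.max(x$mass)]))
  invisible(x)
}

#' Long-run occupation distribution by simulation
#'
#' Empirical occupation measure of the chain at fixed drivers, accumulated
#' over every step (not just recorded samples) by the compiled core. For the
#' `bernoulli` scheme the stay-steps are aggregated through their exact
#' geometric holding times, so horizons of 1e11+ steps -- needed because the
#' rate-thinned chain relaxes over hundreds of model years -- cost only as
#' much as their (b+d)dt-fraction of actual moves.
#'
#' @inheritParams stationary_product_form
#' @param n_steps number of steps to accumulate (may exceed 2^31).
#' @param N0 initial state.
#' @param seed integer seed.
#' @param burn_in_steps steps discarded before accumulation starts.
#' @return an `irristoch_distribution` (empirical; masses sum to 1).
#' @export
occupation_distribution <- function(params, W = params$W_bar,
                                    T = params$T_bar, n_steps, N0, seed,
                                    N_max = default_n_cap(params),
                                    scheme = params$scheme,
                                    burn_in_steps = 0) {
  stopifnot(n_steps >= 1, N0 >= 0, N0 <= N_max)
  set.seed(seed)
  sch <- if (scheme == "jump") 0L else 1L
  occ <- occupation_core(as.integer(N0), W, T, unclass(params), sch,
                         as.numeric(burn_in_steps + n_steps),
                         as.integer(N_max))
  if (burn_in_steps > 0) {
    # re-run is avoided: discard by weight is not possible after the fact,
    # so burn-in is handled by a separate short pre-run
    set.seed(seed)
    pre <- occupation_core(as.integer(N0), W, T, unclass(params), sch,
                           as.numeric(burn_in_steps), as.integer(N_max))
    occ <- occ - pre
    occ[occ < 0] <- 0
  }
  mass <- occ / sum(occ)
  structure(list(support = 0:N_max, mass = mass, log_mass = log(mass),
                 scheme = scheme, W = W, T = T),
            class = "irristoch_distribution")
}

#' Empirical distribution of a simulated trajectory
#'
#' Normalized histogram of the recorded population samples after discarding
#' a burn-in, padded to a common support so it can be compared state by
#' state with an analytic oracle.
#'
#' @param traj an [run_trajectory()] result.
#' @param burn_in_years years discarded from the start; must be smaller
#'   than the trajectory horizon.
#' @param N_max support upper end (default: reachable-state cap).
#' @return an `irristoch_distribution` with `scheme = NULL` marker replaced
#'   by the trajectory's scheme.
#' @export
empirical_distribution <- function(traj, burn_in_years = 0,
                                   N_max = default_n_cap(traj$params)) {
  stopifnot(inherits(traj, "irristoch_trajectory"))
  if (burn_in_years >= traj$n_years)
    stop("burn_in_years must be smaller than the trajectory horizon",
         call. = FALSE)
  keep <- traj$time > burn_in_years
  if (!any(keep)) stop("no samples left after burn-in", call. = FALSE)
  N <- traj$N[keep]
  if (max(N) > N_max) stop("samples exceed N_max", call. = FALSE)
  mass <- tabulate(N + 1L, nbins = N_max + 1L)
  mass <- mass / sum(mass)
  structure(list(support = 0:N_max, mass = mass, log_mass = log(mass),
                 scheme = traj$scheme,
                 W = unique(traj$drivers$W), T = unique(traj$drivers$T)),
            class = "irristoch_distribution")
}

#' Moments of a population distribution
#'
#' @param dist an `irristoch_distribution`.
#' @return a list with `mean`, `sd`, and `cv = sd / mean` (errors if the
#'   mean is zero).
#' @export
summarize_population <- function(dist) {
  stopifnot(inherits(dist, "irristoch_distribution"))
  mu <- sum(dist$support * dist$mass)
  v <- sum((dist$support - mu)^2 * dist$mass)
  sd <- sqrt(max(0, v))
  if (mu == 0) stop("cv undefined: distribution has zero mean", call. = FALSE)
  list(mean = mu, sd = sd, cv = sd / mu)
}

#' Total variation distance between two distributions on a common support
#'
#' @param d1,d2 `irristoch_distribution` objects over the same support.
#' @return `0.5 * sum |p - q|`, in `[0, 1]`.
#' @export
total_variation <- function(d1, d2) {
  stopifnot(length(d1$mass) == length(d2$mass))
  0.5 * sum(abs(d1$mass - d2$mass))
}

#' Local modes of a distribution
#'
#' States whose log mass strictly exceeds both neighbours' (boundary states
#' compare against their single neighbour). The comparison is made on the
#' log scale because the collapsed-state basin lies thousands of orders of
#' magnitude below the viable basin: on the normalized probability scale it
#' underflows to zero, yet it is a genuine mode of the landscape. Used to
#' verify the bistable structure: one mode at/near the collapsed state, one
#' near the attractor `n_star`.
#'
#' @param dist an `irristoch_distribution`.
#' @return integer vector of mode locations.
#' @export
local_modes <- function(dist) {
  lm <- dist$log_mass
  n <- length(lm)
  left <- c(-Inf, lm[-n])
  right <- c(lm[-1], -Inf)
  dist$support[is.finite(lm) & lm > left & lm > right]
}

#' Collapse detection on a trajectory
#'
#' Collapse is operationalized as first passage of the recorded population
#' below the maintenance threshold `n_tilde`: once there, irrigators cannot
#' fund the infrastructure, payoff is zero, and drift is negative at every
#' positive population, making the decline effectively irreversible.
#'
#' @param traj an [run_trajectory()] result.
#' @param n_tilde the maintenance threshold (persons).
#' @return an object of class `collapse_report`: `collapsed`,
#'   `first_passage_year` (NA when not collapsed), `min_N`, `final_N`.
#' @export
detect_collapse <- function(traj, n_tilde) {
  stopifnot(inherits(traj, "irristoch_trajectory"))
  below <- which(traj$N < n_tilde)
  collapsed <- length(below) > 0
  structure(list(
    collapsed = collapsed,
    first_passage_year = if (collapsed)
      floor(max(0, traj$step[below[1]] - 1) / traj$steps_per_year) + 1
      else NA_real_,
    min_N = min(traj$N), final_N = traj$final_N,
    n_tilde = n_tilde), class = "collapse_report")
}

#' @export
print.collapse_report <- function(x, ...) {
  if (x$collapsed)
    cat(sprintf("COLLAPSED: fell below N_tilde = %d in year %d (min N = %d)\n",
                x$n_tilde, as.integer(x$first_passage_year), x$min_N))
  else
    cat(sprintf("No collapse: min N = %d stayed at or above N_tilde = %d\n",
                x$min_N, x$n_tilde))
  invisible(x)
}

#' Signed population drift profile
#'
#' `b(N) - d(N)` across a range of states at fixed drivers: positive where
#' entry outpaces exit. At the calibrated baseline the sign pattern is
#' positive only on the attraction basin `[n_low, n_star]` (plus the
#' boundary state 0, which can only gain its first member) and negative
#' elsewhere. Because payoff vanishes for `N >= W/a` while the outside
#' option `pi_o` is positive, drift is negative at large `N` for every
#' `(W, T)`: conditions can make exit dominate everywhere, but never entry.
#'
#' @inheritParams stationary_product_form
#' @param N_range integer states to evaluate.
#' @return a data.frame with columns `N` and `drift` (events per year).
#' @export
drift_profile <- function(params, W = params$W_bar, T = params$T_bar,
                          N_range = 0:default_n_cap(params)) {
  rt <- entry_exit_rates(N_range, W, T, params)
  data.frame(N = N_range, drift = rt$b - rt$d)
}

#' Three-phase collapse-trap protocol
#'
#' Demonstrates the one-way transition: phase A (calm drivers) holds the
#' population near the attractor; phase B (storm: strong driver CVs) pushes
#' it below the maintenance threshold; phase C restores calm, but the
#' population -- now in the all-negative-drift region -- cannot climb back.
#' Recovery is flagged when the population exceeds the lower basin edge
#' `n_low` at any recorded sample of phase C (a run that never collapsed
#' recovers vacuously).
#'
#' @param params an [irristoch_params()] object.
#' @param calm_w,calm_t driver specs for the calm phases (default:
#'   degenerate at the baseline means).
#' @param storm_w,storm_t driver specs for the storm phase (default:
#'   `CV_W = 0.2`, `CV_T = 0.8`, the strongest published levels).
#' @param years integer vector `c(n_A, n_B, n_C)` of phase lengths.
#' @param seed integer seed; phases consume consecutive derived seeds.
#' @param N0 initial population (default: the attractor `n_star`).
#' @param record_stride steps between recorded samples.
#' @return a list with the three `irristoch_trajectory` objects (`phase_A`,
#'   `phase_B`, `phase_C`), the thresholds used, a `collapse_report` for the
#'   storm phase, and logicals `collapsed_in_storm`, `recovered`.
#' @export
collapse_trap_protocol <- function(params = irristoch_params(),
                                   calm_w = lognormal_from_mean_cv(params$W_bar, 0),
                                   calm_t = beta_from_mean_cv(params$T_bar, 0),
                                   storm_w = lognormal_from_mean_cv(params$W_bar, 0.2),
                                   storm_t = beta_from_mean_cv(params$T_bar, 0.8),
                                   years = c(10L, 20L, 30L), seed = 1L,
                                   N0 = NULL, record_stride = 1000L) {
  th <- compute_thresholds(params)
  if (!th$viable) stop("baseline landscape nonviable", call. = FALSE)
  if (is.null(N0)) N0 <- th$n_star
  seeds <- replicate_seeds(seed, 3)
  run_phase <- function(w, t, ny, sd, n0)
    run_trajectory(sim_config(params, w, t, n_years = ny, N0 = n0,
                              seed = sd, record_stride = record_stride))
  A <- run_phase(calm_w, calm_t, years[1], seeds[1], N0)
  B <- run_phase(storm_w, storm_t, years[2], seeds[2], A$final_N)
  C <- run_phase(calm_w, calm_t, years[3], seeds[3], B$final_N)
  storm_report <- detect_collapse(B, th$n_tilde)
  collapsed <- B$min_N < th$n_tilde
  recovered <- if (collapsed) any(C$N > th$n_low) else TRUE
  list(phase_A = A, phase_B = B, phase_C = C, thresholds = th,
       storm_report = storm_report,
       collapsed_in_storm = collapsed, recovered = recovered)
}

#' Collapse fraction across driver stochasticity levels
#'
#' For each CV level of one driver (the other held constant at its mean),
#' runs a replicate ensemble and reports the fraction of replicates whose
#' population fell below the maintenance threshold. This is the
#' stochasticity-sweep experiment: collapse probability grows with driver
#' CV, abruptly so once bad years (payoff below the outside option at every
#' population size) become likely.
#'
#' @param params an [irristoch_params()] object.
#' @param driver which driver to perturb, `"T"` or `"W"`.
#' @param cv_levels CV values to sweep (defaults: the published levels).
#' @param n_years horizon per replicate.
#' @param n_reps replicates per level.
#' @param base_seed root seed (each level gets a derived root).
#' @return a data.frame with `driver`, `cv`, `n_reps`, `n_collapsed`,
#'   `collapse_fraction`.
#' @export
run_cv_sweep <- function(params = irristoch_params(),
                         driver = c("T", "W"), cv_levels = NULL,
                         n_years = 30L, n_reps = 20L, base_seed = 1L) {
  driver <- match.arg(driver)
  if (is.null(cv_levels))
    cv_levels <- if (driver == "T") c(0.1, 0.3, 0.8) else c(0.02, 0.1, 0.2)
  th <- compute_thresholds(params)
  if (!th$viable) stop("baseline landscape nonviable", call. = FALSE)
  level_seeds <- replicate_seeds(base_seed + 104729L, length(cv_levels))
  out <- vector("list", length(cv_levels))
  for (i in seq_along(cv_levels)) {
    cv <- cv_levels[i]
    w_spec <- lognormal_from_mean_cv(params$W_bar,
                                     if (driver == "W") cv else 0)
    t_spec <- beta_from_mean_cv(params$T_bar, if (driver == "T") cv else 0)
    cfg <- sim_config(params, w_spec, t_spec, n_years = n_years,
                      N0 = th$n_star, record_stride = steps_per_year(params))
    reps <- run_replicates(cfg, n_reps, level_seeds[i], n_tilde = th$n_tilde)
    out[[i]] <- data.frame(driver = driver, cv = cv, n_reps = n_reps,
                           n_collapsed = sum(reps$collapsed),
                           collapse_fraction = mean(reps$collapsed))
  }
  do.call(rbind, out)
}
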