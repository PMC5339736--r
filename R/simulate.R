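#' Simulation configuration
#'
#' Bundles model parameters, annual driver specs, horizon, initial state and
#' seed for [run_trajectory()]. Validated on construction.
#'
#' @param params an [irristoch_params()] object.
#' @param w_spec,t_spec [driver_spec] objects for annual water and taxation;
#'   default to degenerate drivers at the baseline means (the fixed-driver
#'   benchmark).
#' @param n_years simulation horizon in years (`>= 1`).
#' @param N0 initial population, nonnegative integer; defaults to the
#'   attractor `n_star` of the calibrated landscape (errors if nonviable).
#' @param seed integer seed; the whole run (driver draws and stepping) is
#'   reproducible from it.
#' @param record_stride steps between recorded trajectory samples (`>= 1`).
#'   The final state is always recorded.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(params = irristoch_params(),
                       w_spec = lognormal_from_mean_cv(params$W_bar, 0),
                       t_spec = beta_from_mean_cv(params$T_bar, 0),
                       n_years = 100L, N0 = NULL, seed = 1L,
                       record_stride = 1L) {
  validate_params(params)
  stopifnot(inherits(w_spec, "driver_spec"), inherits(t_spec, "driver_spec"))
  if (!is.numeric(n_years) || n_years < 1 || n_years != floor(n_years))
    stop("n_years must be a positive integer", call. = FALSE)
  if (!is.numeric(record_stride) || record_stride < 1 ||
      record_stride != floor(record_stride))
    stop("record_stride must be a positive integer", call. = FALSE)
  if (is.null(N0)) {
    th <- compute_thresholds(params)
    if (!th$viable)
      stop("default N0 = n_star unavailable: baseline landscape nonviable; ",
           "give N0 explicitly", call. = FALSE)
    N0 <- th$n_star
  }
  if (!is.numeric(N0) || N0 < 0 || N0 != floor(N0))
    stop("N0 must be a nonnegative integer", call. = FALSE)
  if (!is.numeric(seed) || seed != floor(seed))
    stop("seed must be an integer", call. = FALSE)
  structure(list(params = params, w_spec = w_spec, t_spec = t_spec,
                 n_years = as.integer(n_years), N0 = as.integer(N0),
                 seed = as.integer(seed),
                 record_stride = as.integer(record_stride)),
            class = "sim_config")
}

#' Per-step transition probabilities
#'
#' Under the `jump` scheme every step is a forced +-1 move:
#' `p_up = b/(b+d)`, `p_down = d/(b+d)`, `p_stay = 0` -- the literal
#' discrete-step reading of the transition rule. Under the `bernoulli`
#' scheme the rates are thinned by the step length:
#' `p_up = b dt`, `p_down = d dt`, `p_stay = 1 - (b+d) dt` (requires
#' `(b+d) dt <= 1`). At `N = 0` the jump scheme moves up with probability 1.
#'
#' @inheritParams infrastructure_performance
#' @return a list of numeric vectors `p_up`, `p_down`, `p_stay` summing to 1.
#' @export
step_probabilities <- function(N, W, T, params) {
  rt <- entry_exit_rates(N, W, T, params)
  if (params$scheme == "jump") {
    tot <- rt$b + rt$d
    list(p_up = rt$b / tot, p_down = rt$d / tot,
         p_stay = rep(0, length(tot)))
  } else {
    p_up <- rt$b * params$dt
    p_down <- rt$d * params$dt
    if (any(p_up + p_down > 1))
      stop("bernoulli scheme: (b + d) * dt > 1 at some N; reduce dt",
           call. = FALSE)
    list(p_up = p_up, p_down = p_down, p_stay = 1 - p_up - p_down)
  }
}

#' Simulate a population trajectory
#'
#' Runs the +-1 population walk for `n_years * round(1/dt)` steps. Water and
#' taxation are redrawn once per year from the driver specs (the year's pair
#' is drawn before its first step; year 1 uses the first draw) and held
#' constant within the year. The compiled stepping loop consumes the same
#' seeded RNG stream as the driver draws, so a `sim_config` reproduces its
#' trajectory bit-for-bit.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `irristoch_trajectory`: a list with
#'   `step`, `time` (years), `N` (recorded samples), `drivers` (the annual
#'   `year`/`W`/`T` table), `final_N`, `min_N` (over every step, not only
#'   recorded ones), `first_passage` (function of a threshold; see
#'   [detect_collapse()]), `scheme`, `seed`, `params`.
#' @export
run_trajectory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$params
  spy <- steps_per_year(p)
  set.seed(config$seed)
  drv <- data.frame(year = seq_len(config$n_years),
                    W = draw_driver(config$w_spec, config$n_years),
                    T = draw_driver(config$t_spec, config$n_years))
  # guard rail: the population cannot drift above W/a in the wettest drawn
  # year; a 20% margin absorbs fluctuation around that bound
  n_cap <- max(default_n_cap(p),
               as.integer(ceiling(1.2 * max(drv$W) / p$a)))
  if (config$N0 > n_cap)
    stop("N0 exceeds the reachable-state cap ", n_cap, call. = FALSE)
  res <- sim_core(config$N0, drv$W, drv$T, spy, unclass(p),
                  scheme = if (p$scheme == "jump") 0L else 1L,
                  record_stride = config$record_stride,
                  below_threshold = -1L, n_cap = n_cap)
  structure(list(step = res$step, time = res$step * p$dt, N = res$N,
                 drivers = drv, final_N = res$final_N, min_N = res$min_N,
                 steps_per_year = spy, n_years = config$n_years,
                 scheme = p$scheme, seed = config$seed,
                 record_stride = config$record_stride, params = p),
            class = "irristoch_trajectory")
}

#' @export
print.irristoch_trajectory <- function(x, ...) {
  cat(sprintf(paste0("Population trajectory: %d years (%s scheme, seed %d)\n",
                     "  N0 = %d, final N = %d, min N = %d, %d samples\n"),
              x$n_years, x$scheme, x$seed, x$N[1], x$final_N, x$min_N,
              length(x$N)))
  invisible(x)
}

#' Replicate seeds derived from a base seed
#'
#' Deterministic spawning rule: `seed_i = (base_seed + 777767 * i) mod
#' (2^31 - 2) + 1`, distinct for up to several thousand replicates.
#'
#' @param base_seed integer root seed.
#' @param n_reps number of replicates.
#' @return integer vector of `n_reps` positive seeds.
#' @export
replicate_seeds <- function(base_seed, n_reps) {
  as.integer((as.numeric(base_seed) + 777767 * seq_len(n_reps)) %%
               (2^31 - 2) + 1)
}

#' Run independent replicate trajectories
#'
#' Re-runs a configuration under `n_reps` seeds derived deterministically
#' from `base_seed` (see [replicate_seeds()]) and summarizes each replicate.
#' First passage below `n_tilde` is detected at full step resolution inside
#' the compiled loop, not from the recorded samples.
#'
#' @param config a [sim_config()] object (its own seed is ignored).
#' @param n_reps number of replicates.
#' @param base_seed root seed for the replicate ensemble.
#' @param n_tilde collapse threshold used for first-passage detection;
#'   defaults to the maintenance threshold of the calibrated landscape.
#' @return a data.frame with one row per replicate: `rep`, `seed`,
#'   `final_N`, `min_N`, `collapsed`, `first_passage_year` (NA if the
#'   trajectory never fell below `n_tilde`).
#' @export
run_replicates <- function(config, n_reps, base_seed,
                           n_tilde = compute_thresholds(config$params)$n_tilde) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  p <- config$params
  spy <- steps_per_year(p)
  seeds <- replicate_seeds(base_seed, n_reps)
  out <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(seeds[i])
    Wv <- draw_driver(config$w_spec, config$n_years)
    Tv <- draw_driver(config$t_spec, config$n_years)
    n_cap <- max(default_n_cap(p),
                 as.integer(ceiling(1.2 * max(Wv) / p$a)))
    res <- sim_core(config$N0, Wv, Tv, spy, unclass(p),
                    scheme = if (p$scheme == "jump") 0L else 1L,
                    record_stride = spy,  # year-level samples suffice here
                    below_threshold = as.integer(n_tilde), n_cap = n_cap)
    fp <- res$first_step_below
    out[[i]] <- data.frame(
      rep = i, seed = seeds[i], final_N = res$final_N, min_N = res$min_N,
      collapsed = fp >= 0,
      first_passage_year = if (fp >= 0) floor((fp - 1) / spy) + 1
                           else NA_real_)
  }
  do.call(rbind, out)
}
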