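#' Experiment presets
#'
#' Fully specified configurations for the four canonical experiments:
#' \describe{
#'   \item{`fig1`}{deterministic landscape: calibrated thresholds plus the
#'     payoff surface over `(N, T)` at mean water. No simulation.}
#'   \item{`fig2`}{the fixed-driver benchmark: both CVs zero, a long run
#'     whose occupation measure exhibits the intrinsic demographic
#'     fluctuation around the attractor `n_star`.}
#'   \item{`fig3`}{the stochasticity sweep: six replicate ensembles, one
#'     driver perturbed at a time, at the published CV levels
#'     (`CV_T` in 0.1/0.3/0.8, `CV_W` in 0.02/0.1/0.2), means fixed at the
#'     baseline (1 and 0.2).}
#'   \item{`fig4`}{the collapse-trap protocol: calm / storm / calm phases
#'     with the storm at the strongest published CVs.}
#' }
#'
#' @param name one of `"fig1"`, `"fig2"`, `"fig3"`, `"fig4"`.
#' @param params an [irristoch_params()] object.
#' @param seed root seed carried into the stochastic presets.
#' @return a named list describing the experiment; stochastic presets carry
#'   `sim_config` objects or sweep arguments ready to execute.
#' @export
preset <- function(name, params = irristoch_params(), seed = 1L) {
  th <- compute_thresholds(params)
  switch(name,
    fig1 = list(kind = "thresholds_surface", params = params,
                N_grid = seq(0L, as.integer(params$W_bar / params$a), by = 10L),
                T_grid = seq(0.02, 0.98, by = 0.02), W = params$W_bar),
    fig2 = list(kind = "benchmark",
                config = sim_config(params,
                                    lognormal_from_mean_cv(params$W_bar, 0),
                                    beta_from_mean_cv(params$T_bar, 0),
                                    n_years = 100L, N0 = th$n_star,
                                    seed = seed, record_stride = 1L)),
    fig3 = list(kind = "cv_sweep", params = params,
                sweeps = list(
                  T = list(driver = "T", cv_levels = c(0.1, 0.3, 0.8)),
                  W = list(driver = "W", cv_levels = c(0.02, 0.1, 0.2))),
                n_years = 30L, n_reps = 20L, base_seed = seed),
    fig4 = list(kind = "collapse_trap", params = params,
                storm_w = lognormal_from_mean_cv(params$W_bar, 0.2),
                storm_t = beta_from_mean_cv(params$T_bar, 0.8),
                years = c(10L, 20L, 30L), seed = seed),
    stop("unknown preset: ", name,
         " (expected fig1, fig2, fig3 or fig4)", call. = FALSE))
}
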