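#' Load a simulation configuration from a YAML or JSON file
#'
#' The file may carry any subset of three blocks; unspecified fields take
#' the published defaults (`m = 1`, `h = 0.01`, `r = 1`, `a = 1e-4`,
#' `W_bar = 1`, `T_bar = 0.2`, `dt = 5e-5`, calibrated `x0`/`kappa`/`pi_o`,
#' `jump` scheme, degenerate drivers):
#'
#' ```yaml
#' params:  {m: 1, h: 0.01, r: 1, a: 1e-4, W_bar: 1, T_bar: 0.2,
#'           dt: 5.0e-5, scheme: jump}       # x0/kappa/pi_o optional
#' drivers: {W: {mean: 1, cv: 0.1}, T: {mean: 0.2, cv: 0.3}}
#' sim:     {n_years: 30, N0: 7015, seed: 1, record_stride: 1000}
#' ```
#'
#' All `irristoch_params` and driver invariants are validated with
#' field-naming messages; in particular, an infeasible beta `cv` for the
#' taxation driver surfaces here.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return a [sim_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be a .yaml/.yml or .json file", call. = FALSE)
  config_from_list(raw)
}

#' @rdname load_config
#' @param raw a nested list with the same structure as the file contents.
#' @export
config_from_list <- function(raw) {
  if (is.null(raw)) raw <- list()
  pf <- raw$params
  if (is.null(pf)) pf <- list()
  known <- c("m", "h", "r", "a", "W_bar", "T_bar", "dt", "scheme",
             "x0", "kappa", "pi_o")
  bad <- setdiff(names(pf), known)
  if (length(bad))
    stop("unknown params field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  params <- do.call(irristoch_params, pf[!vapply(pf, is.null, TRUE)])
  drv <- raw$drivers
  w_mean <- drv$W$mean %||% params$W_bar
  w_cv <- drv$W$cv %||% 0
  t_mean <- drv$T$mean %||% params$T_bar
  t_cv <- drv$T$cv %||% 0
  sim <- raw$sim
  sim_config(params,
             w_spec = lognormal_from_mean_cv(w_mean, w_cv),
             t_spec = beta_from_mean_cv(t_mean, t_cv),
             n_years = sim$n_years %||% 100L,
             N0 = sim$N0,
             seed = sim$seed %||% 1L,
             record_stride = sim$record_stride %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a simulation configuration
#'
#' Writes a [sim_config()] back to YAML or JSON (by extension) in the schema
#' [load_config()] reads, so `load_config(save_config(cfg, f))` round-trips
#' to an identical configuration.
#'
#' @param config a [sim_config()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$params
  raw <- list(
    params = p[c("m", "h", "r", "a", "W_bar", "T_bar", "dt", "scheme",
                 "x0", "kappa", "pi_o")],
    drivers = list(W = list(mean = config$w_spec$mean, cv = config$w_spec$cv),
                   T = list(mean = config$t_spec$mean, cv = config$t_spec$cv)),
    sim = list(n_years = config$n_years, N0 = config$N0, seed = config$seed,
               record_stride = config$record_stride))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    # 17 significant digits uniquely determine a double (the yaml package's
    # own precision argument caps lower, hence the verbatim handler)
    yaml::write_yaml(raw, path, handlers = list(
      numeric = function(z) structure(sprintf("%.17g", z),
                                      class = "verbatim")))
  else
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(path)
}
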