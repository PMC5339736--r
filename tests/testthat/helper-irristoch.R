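# Shared fixtures and independent oracles for the test suite.

# default calibrated parameters, computed once
default_pars <- irristoch_params()
default_th <- compute_thresholds(default_pars)

# a scaled-down calibrated model whose state space (0..120) is small enough
# for dense linear algebra; r is raised so the viable basin is tight and the
# stationary tail at the cap is negligible
small_pars <- function(scheme = "jump")
  irristoch_params(a = 0.01, r = 50, scheme = scheme,
                   anchors = c(7L, 33L, 70L))

# Independent stationary-distribution oracle: build the full one-step
# transition matrix of the chain truncated at N_max (excess up-probability
# reflected into staying) and solve mu P = mu by dense linear algebra.
# Truncation-by-reflection preserves detailed balance on interior edges, so
# this equals the product form renormalized -- but is computed without it.
stationary_eigen_oracle <- function(params, W, T, N_max, scheme) {
  states <- 0:N_max
  rt <- entry_exit_rates(states, W, T, params)
  if (scheme == "jump") {
    pu <- rt$b / (rt$b + rt$d)
    pd <- rt$d / (rt$b + rt$d)
  } else {
    pu <- rt$b * params$dt
    pd <- rt$d * params$dt
  }
  n <- N_max + 1L
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i < n) P[i, i + 1] <- pu[i] else P[i, i] <- P[i, i] + pu[i]
    if (i > 1) P[i, i - 1] <- pd[i]
    P[i, i] <- P[i, i] + 1 - pu[i] - pd[i]
  }
  A <- t(P) - diag(n)
  A[n, ] <- 1
  mu <- solve(A, c(rep(0, n - 1), 1))
  mu / sum(mu)
}

# brute-force integer-scan oracle for the payoff-parity crossings
scan_thresholds_oracle <- function(params, W, T) {
  grid <- 0:floor(W / params$a)
  pay <- per_capita_payoff(grid, W, T, params)
  ok <- pay >= params$pi_o
  if (!any(ok)) return(list(viable = FALSE))
  list(viable = TRUE, n_low = grid[min(which(ok))],
       n_star = grid[max(which(ok))], n_m = grid[which.max(pay)])
}

# delta-method Monte Carlo standard errors for the sample mean and sample CV
mc_se <- function(x) {
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  cv <- sqrt(v) / m
  var_cv <- cv^2 * v / (n * m^2) + (m4 - v^2) / (4 * m^2 * v * n) -
    m3 / (m^3 * n)
  list(mean = m, cv = cv, se_mean = sqrt(v / n),
       se_cv = sqrt(max(var_cv, .Machine$double.eps)))
}

# hand-built distribution object for moment tests
make_dist <- function(support, mass)
  structure(list(support = support, mass = mass / sum(mass),
                 log_mass = log(mass / sum(mass)), scheme = "test",
                 W = NA, T = NA),
            class = "irristoch_distribution")

# hand-built minimal trajectory object
make_traj <- function(N, steps_per_year = 10L, params = default_pars) {
  step <- seq_along(N) - 1
  structure(list(step = step, time = step / steps_per_year, N = N,
                 drivers = data.frame(year = 1, W = params$W_bar,
                                      T = params$T_bar),
                 final_N = N[length(N)], min_N = min(N),
                 steps_per_year = steps_per_year,
                 n_years = ceiling(length(N) / steps_per_year),
                 scheme = "jump", seed = 0L, record_stride = 1L,
                 params = params),
            class = "irristoch_trajectory")
}
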