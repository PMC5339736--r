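# Stationary distributions, summaries, collapse detection, experiments.

p <- default_pars
th <- default_th

test_that("product form matches an independent dense linear-algebra
           stationary solve on a scaled-down model, both schemes", {
  for (scheme in c("jump", "bernoulli")) {
    ps <- small_pars(scheme)
    N_max <- 120L
    got <- stationary_product_form(ps, N_max = N_max)
    want <- stationary_eigen_oracle(ps, ps$W_bar, ps$T_bar, N_max, scheme)
    expect_lt(max(abs(got$mass - want)), 1e-10)
    expect_equal(sum(got$mass), 1, tolerance = 1e-12)
  }
})

test_that("the default landscape is bistable: a collapsed mode, a viable
           mode at the attractor, and a deep valley between them", {
  for (scheme in c("jump", "bernoulli")) {
    d <- stationary_product_form(p, scheme = scheme)
    modes <- local_modes(d)
    expect_identical(length(modes), 2L)
    expect_lt(modes[1], th$n_low)
    expect_gt(modes[2], th$n_low)
    expect_identical(modes[2], 7015L)
    # valley floor sits at the lower basin edge, hundreds of orders deep
    valley_at <- d$support[which.min(d$log_mass[1:(th$n_star + 1)])]
    expect_lt(abs(valley_at - th$n_low), 3)
    valley <- min(d$log_mass[d$support <= th$n_star])
    expect_lt((valley - max(d$log_mass)) / log(10), -100)
    if (scheme == "bernoulli") {
      # mass increments log(b(N-1)/d(N)) are positive wherever the inside
      # payoff strictly beats the outside option
      basin <- d$support > th$n_low & d$support <= th$n_star
      inc <- diff(d$log_mass[basin])
      pay_sign <- sign(per_capita_payoff(d$support[basin][-1], p$W_bar,
                                         p$T_bar, p) - p$pi_o)
      expect_true(all(sign(inc[pay_sign > 0]) > 0))
    }
  }
})

test_that("too small a support is rejected by the tail check", {
  expect_error(stationary_product_form(p, N_max = 7100), "tail mass")
})

test_that("empirical distributions histogram the post-burn-in samples", {
  tr <- make_traj(rep(5L, 100))
  d <- empirical_distribution(tr, burn_in_years = 0, N_max = 10)
  expect_identical(d$mass, c(rep(0, 5), 1, rep(0, 5)))
  expect_error(empirical_distribution(tr, burn_in_years = 10), "horizon")
  # burn-in removes the leading samples
  tr2 <- make_traj(c(rep(0L, 50), rep(3L, 50)), steps_per_year = 10L)
  d2 <- empirical_distribution(tr2, burn_in_years = 5, N_max = 5)
  expect_identical(d2$mass[4], 1)
})

test_that("population moments follow from the masses", {
  s <- summarize_population(make_dist(0:200, c(rep(0, 100), 1, rep(0, 100))))
  expect_identical(c(s$mean, s$sd, s$cv), c(100, 0, 0))
  s2 <- summarize_population(make_dist(c(90, 110), c(0.5, 0.5)))
  expect_equal(c(s2$mean, s2$sd, s2$cv), c(100, 10, 0.1), tolerance = 1e-12)
  expect_error(summarize_population(make_dist(0:3, c(1, 0, 0, 0))),
               "zero mean")
  # the oracle distribution's upper basin: cv of order 1e-3..1e-2
  s3 <- summarize_population(stationary_product_form(p))
  expect_gt(s3$cv, 1e-3); expect_lt(s3$cv, 1e-2)
  expect_equal(s3$mean, 7015, tolerance = 1e-4)
})

test_that("collapse detection reports first passage below the maintenance
           threshold", {
  ok <- detect_collapse(make_traj(rep(800L, 50)), th$n_tilde)
  expect_false(ok$collapsed)
  expect_true(is.na(ok$first_passage_year))

  # dips below 727 at sample 25 of a 10-step year: year 3
  N <- c(seq(800L, by = -3L, length.out = 50))
  tr <- make_traj(N, steps_per_year = 10L)
  rep <- detect_collapse(tr, th$n_tilde)
  expect_true(rep$collapsed)
  expect_identical(rep$first_passage_year,
                   floor((which(N < 727L)[1] - 2) / 10) + 1)
  expect_identical(rep$min_N, min(N))
})

test_that("drift profile has the published sign pattern at baseline and
           all-negative drift under drought", {
  dr <- drift_profile(p, N_range = 0:12000)
  expect_equal(dr$drift[dr$N == 3333], 3.123436, tolerance = 1e-6)
  expect_equal(dr$drift[dr$N == 500], -0.3410524, tolerance = 1e-6)
  nonneg <- dr$N[dr$drift >= 0 & dr$N >= 1]   # drift is exactly 0 at n_star
  expect_identical(range(nonneg), c(th$n_low, th$n_star))
  expect_true(all(diff(nonneg) == 1))         # one contiguous basin
  expect_true(all(dr$drift[dr$N > th$n_star] < 0))
  expect_true(all(drift_profile(p, W = 0.7)$drift[-1] < 0))
})

test_that("a degenerate storm leaves the trap protocol collapse-free and
           vacuously recovered", {
  res <- collapse_trap_protocol(
    p, storm_w = lognormal_from_mean_cv(1, 0),
    storm_t = beta_from_mean_cv(0.2, 0),
    years = c(1L, 1L, 1L), seed = 3L, record_stride = 1000L)
  expect_false(res$collapsed_in_storm)
  expect_true(res$recovered)
  expect_gt(res$phase_C$final_N, th$n_low)
})

test_that("a real storm collapses the system and calm aftermath hovers near
           zero without re-entering the basin", {
  res <- collapse_trap_protocol(p, years = c(2L, 15L, 10L), seed = 31L,
                                record_stride = 1000L)
  expect_true(res$collapsed_in_storm)
  expect_false(res$recovered)
  expect_lt(res$phase_C$final_N, th$n_tilde)
  # phase C hovers near 0: entry at rate m balanced by payoff-driven exit
  expect_lt(mean(res$phase_C$N[-(1:20)]), 100)
})

test_that("bad-year probabilities under the preset driver levels support
           the experiment horizons", {
  set.seed(911)
  nonviable_frac <- function(w_cv, t_cv, n = 1000) {
    W <- draw_driver(lognormal_from_mean_cv(p$W_bar, w_cv), n)
    T <- draw_driver(beta_from_mean_cv(p$T_bar, t_cv), n)
    viable <- logical(n); dead <- logical(n)
    for (i in seq_len(n)) {
      tt <- compute_thresholds(p, W[i], T[i])
      viable[i] <- tt$viable
      dead[i] <- tt$pi_max == 0
    }
    c(nonviable = mean(!viable), payoff_zero = mean(dead))
  }
  # storm (fig4): nonviable ~0.39/yr, payoff identically zero ~0.22/yr
  storm <- nonviable_frac(0.2, 0.8)
  expect_gt(storm["nonviable"], 0.3); expect_lt(storm["nonviable"], 0.5)
  expect_gt(storm["payoff_zero"], 0.15); expect_lt(storm["payoff_zero"], 0.3)
  # weakest sweep levels: no nonviable years on simulated horizons
  expect_identical(unname(nonviable_frac(0.02, 0)["nonviable"]), 0)
  expect_identical(unname(nonviable_frac(0, 0.1)["nonviable"]), 0)
})
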