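# Deterministic payoff core: water constraint, infrastructure, payoff,
# rates, calibration and threshold finding.

p <- default_pars
th <- default_th

test_that("available water is the clamped linear form", {
  expect_identical(available_water(0, 1, p), 1)
  expect_identical(available_water(10000, 1, p), 0)   # N >= W/a exhausts W
  expect_equal(available_water(5000, 1, p), 0.5)
  expect_equal(available_water(c(0, 2000, 20000), 1, p), c(1, 0.8, 0))
  expect_error(available_water(-1, 1, p), "nonnegative")
  expect_error(available_water(10, -0.1, p), "nonnegative")
  expect_error(available_water(10.5, 1, p), "integer")
})

test_that("infrastructure performance is zero at the funding threshold and
           saturating above it", {
  # x0 is calibrated to equal the funding index at N = 727 exactly
  expect_identical(infrastructure_performance(727, 1, 0.2, p), 0)
  expect_gt(infrastructure_performance(728, 1, 0.2, p), 0)
  expect_equal(infrastructure_performance(3333, 1, 0.2, p), 0.3035903,
               tolerance = 1e-6)
  expect_identical(infrastructure_performance(0, 1, 0.2, p), 0)
  expect_identical(infrastructure_performance(500, 5, 0, p), 0)  # no tax
  # monotone nondecreasing in T at fixed N
  g <- infrastructure_performance(rep(3000, 9), 1, seq(0.1, 0.9, 0.1), p)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0 & g < 1))
  expect_error(infrastructure_performance(10, 1, 1.2, p), "T must")
})

test_that("per-capita payoff matches hand-evaluated anchors and vanishes on
           the dead regions", {
  expect_equal(per_capita_payoff(3333, 1, 0.2, p), 1.619229e-3,
               tolerance = 1e-6)
  # pi(n_star) recovers pi_o bitwise by calibration construction
  expect_identical(per_capita_payoff(7015, 1, 0.2, p), p$pi_o)
  expect_identical(per_capita_payoff(500, 1, 0.2, p), 0)  # unmaintained
  grid <- 0:12000
  pay <- per_capita_payoff(grid, 1, 0.2, p)
  expect_true(all(pay >= 0))
  expect_true(all(pay[grid >= 10000] == 0))
  expect_true(all(per_capita_payoff(grid, 1, 1, p) == 0))  # full taxation
  expect_true(all(per_capita_payoff(grid, 1, 0, p) == 0))  # zero taxation
})

test_that("entry/exit rates respond to the payoff gap with the m floor and
           the N = 0 boundary", {
  r0 <- entry_exit_rates(0, 1, 0.2, p)
  expect_identical(c(r0$b, r0$d), c(1, 0))
  r1 <- entry_exit_rates(3333, 1, 0.2, p)
  expect_equal(r1$b, 4.123436, tolerance = 1e-6)
  expect_identical(r1$d, 1)
  r2 <- entry_exit_rates(500, 1, 0.2, p)   # pi = 0, full outside pull
  expect_identical(r2$b, 1)
  expect_equal(r2$d, 1.341052, tolerance = 1e-6)
  rall <- entry_exit_rates(1:12000, 1, 0.2, p)
  expect_true(all(pmin(rall$b, rall$d) == p$m))
  expect_error(entry_exit_rates(-3, 1, 0.2, p), "nonnegative")
})

test_that("thresholds recover the calibrated landmarks and flag nonviable
           driver levels", {
  expect_identical(th$n_tilde, 727L)
  expect_identical(th$n_low, 1199L)
  expect_identical(th$n_m, 3333L)
  expect_identical(th$n_star, 7015L)
  expect_equal(th$pi_max, 1.619229e-3, tolerance = 1e-6)
  expect_true(th$viable)
  expect_lt(th$n_star, p$W_bar / p$a)

  dry <- compute_thresholds(p, W = 0.5)
  expect_false(dry$viable)
  expect_true(is.na(dry$n_low) && is.na(dry$n_star))
  expect_false(compute_thresholds(p, T = 0)$viable)
})

test_that("calibration pins the constants and round-trips through the
           thresholds exactly", {
  base <- list(m = 1, h = 0.01, r = 1, a = 1e-4, W_bar = 1, T_bar = 0.2)
  cal <- calibrate_payoff(727, 3333, 7015, base)
  expect_equal(cal$x0, 1.3482942, tolerance = 1e-7)
  expect_equal(cal$kappa, 7.1017888, tolerance = 1e-7)
  expect_equal(cal$pi_o, 6.8210475e-4, tolerance = 1e-7)

  # exact integer recovery, for the default anchors and a second set
  for (anch in list(c(727L, 3333L, 7015L), c(7L, 33L, 70L))) {
    pp <- if (anch[1] == 7L) small_pars() else p
    tt <- compute_thresholds(pp)
    expect_identical(c(tt$n_tilde, tt$n_m, tt$n_star), anch)
  }
  expect_error(calibrate_payoff(727, 7015, 7015, base), "anchors")
  expect_error(calibrate_payoff(7015, 3333, 727, base), "anchors")
})

test_that("payoff surface is consistent with pointwise payoff and zero on
           degenerate rows/columns", {
  Ng <- c(0L, 500L, 3333L, 7015L, 10000L)
  Tg <- c(0, 0.2, 0.5, 1)
  s <- payoff_surface(Ng, Tg, 1, p)
  expect_equal(dim(s), c(5L, 4L))
  expect_equal(s[, 2], per_capita_payoff(Ng, 1, 0.2, p),
               ignore_attr = TRUE)
  expect_true(all(s[1, ] == 0))      # N = 0
  expect_true(all(s[, 4] == 0))      # T = 1
  expect_true(all(s[, 1] == 0))      # T = 0
})

test_that("payoff is unimodal in N and monotone in W", {
  set.seed(4001)
  for (i in 1:20) {
    W <- runif(1, 0.8, 1.5); T <- runif(1, 0.12, 0.6)
    pay <- per_capita_payoff(0:floor(W / p$a), W, T, p)
    pos <- which(pay > 0)
    if (length(pos) < 3) next
    expect_true(all(diff(pos) == 1))   # positive region is contiguous
    d <- diff(pay[pos])
    sg <- sign(d[d != 0])
    # rises then falls: at most one sign change of the discrete difference
    expect_lte(sum(diff(sg) != 0), 1)
    if (length(sg)) expect_identical(sg[length(sg)], -1)
  }
  for (N in c(1000L, 3333L, 7015L, 9000L)) {
    pw <- per_capita_payoff(rep(N, 8), seq(0.6, 2, 0.2), 0.2, p)
    expect_true(all(diff(pw) >= 0))
  }
})

test_that("bisection crossings agree with the exhaustive-scan oracle over
           random parameter draws", {
  set.seed(4002)
  n_checked <- 0
  for (i in 1:60) {
    W <- runif(1, 0.6, 1.6); T <- runif(1, 0.05, 0.95)
    got <- compute_thresholds(p, W, T)
    want <- scan_thresholds_oracle(p, W, T)
    expect_identical(got$viable, want$viable)
    if (want$viable) {
      expect_identical(got$n_low, want$n_low)
      expect_identical(got$n_star, want$n_star)
      expect_identical(got$n_m, want$n_m)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 25)  # the draw box straddles the viability boundary
})

test_that("no driver level makes entry dominate at every population size", {
  set.seed(4003)
  for (i in 1:40) {
    W <- runif(1, 0.2, 3); T <- runif(1, 0.01, 0.99)
    dr <- drift_profile(p, W, T, N_range = 0:ceiling(1.2 * W / p$a))
    expect_true(any(dr$drift[dr$N >= 1] < 0))
  }
  # ...but exit can dominate everywhere (asymmetry of the collapse trap)
  dr <- drift_profile(p, W = 0.7, T = 0.2)
  expect_true(all(dr$drift[dr$N >= 1] < 0))
})
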