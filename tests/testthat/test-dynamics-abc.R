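cfg <- run_config()
grid24 <- 0:24

test_that("smoothing spline reproduces straight lines exactly", {
  d <- tibble::tibble(time_h = rep(seq(0, 24, by = 1), 3),
                      log_fc = rep(0.3 - 0.02 * seq(0, 24, by = 1), 3))
  s <- fit_spline(d, df = 6, grid = grid24)
  expect_equal(s$values, 0.3 - 0.02 * grid24, tolerance = 1e-6)
})

test_that("effective df matches the requested df and the smoother trace", {
  set.seed(8)
  tt <- seq(0, 24, by = 0.5)
  d <- tibble::tibble(time_h = tt, log_fc = sin(tt / 4) + rnorm(length(tt), 0, 0.1))
  s <- fit_spline(d, df = 6, grid = grid24)
  expect_lt(abs(s$effective_df - 6), 0.05)

  # independent check: trace of the dense smoother matrix assembled by
  # smoothing unit vectors at the fitted penalty
  lam <- s$fit$lambda
  diag_S <- vapply(seq_along(tt), function(i) {
    ei <- numeric(length(tt)); ei[i] <- 1
    fit_i <- stats::smooth.spline(tt, ei, lambda = lam, all.knots = TRUE)
    stats::predict(fit_i, tt[i])$y
  }, 0)
  expect_lt(abs(sum(diag_S) - s$effective_df), 0.05)
})

test_that("penalty -> 0 limit approaches interpolation", {
  tt <- seq(0, 24, length.out = 25)
  y <- 0.001 * tt^3 - 0.03 * tt^2 + 0.1 * tt
  s <- fit_spline(tibble::tibble(time_h = tt, log_fc = y), df = 24,
                  grid = tt)
  expect_lt(max(abs(s$values - y)), 1e-3)
})

test_that("fit_spline enforces its preconditions", {
  d <- tibble::tibble(time_h = c(0, 8, 16, 24), log_fc = rnorm(4))
  expect_error(fit_spline(d, df = 1, grid = grid24),
               class = "abc_error_value")
  expect_error(fit_spline(d, df = 6, grid = grid24),
               class = "abc_error_value")
})

test_that("trapezoid ABC matches closed-form integrals", {
  a <- constant_spline(grid24, 0)

  # identical curves
  expect_equal(abc_between(a, a)$abc, 0)

  # constant offset 0.5 over 24 h
  b <- constant_spline(grid24, 0.5)
  r <- abc_between(a, b)
  expect_equal(r$abc, 12)
  expect_equal(r$area_pos, 12)
  expect_equal(r$area_neg, 0)

  # sign-crossing line b(t) = t - 12: integral of |t - 12| over [0, 24]
  bl <- curve_on_grid(grid24, grid24 - 12)
  rl <- abc_between(a, bl)
  expect_equal(rl$abc, 144)
  expect_equal(rl$area_pos, 72)
  expect_equal(rl$area_neg, 72)
  expect_equal(rl$net_area, 0)

  # decomposition identity holds to near machine precision
  expect_equal(rl$abc, rl$area_pos + rl$area_neg, tolerance = 1e-9)

  # grid mismatch is an error
  short <- constant_spline(0:23, 0)
  expect_error(abc_between(a, short), class = "abc_error_grid")
})

test_that("ABC is symmetric and dominates the net signed area", {
  set.seed(21)
  for (i in 1:20) {
    a <- curve_on_grid(grid24, rnorm(25, 0, 0.3))
    b <- curve_on_grid(grid24, rnorm(25, 0, 0.3))
    rab <- abc_between(a, b)
    rba <- abc_between(b, a)
    expect_equal(rab$abc, rba$abc, tolerance = 1e-12)
    expect_gte(rab$abc + 1e-12, abs(rab$net_area))
    expect_equal(rab$abc, rab$area_pos + rab$area_neg, tolerance = 1e-9)
  }
})

test_that("grid-step refinement changes spline ABC by less than 0.1%", {
  p <- signal_params(noise_sd = 0, delta_max = 0.4)
  plate <- simulate_timecourse(p, 10, cfg, seed = 5)
  norm <- normalize_plate(plate, cfg)
  coarse <- compute_abc(norm, run_config(eval_grid_step_h = 0.5))
  fine <- compute_abc(norm, run_config(eval_grid_step_h = 0.005))
  expect_lt(abs(coarse$abc - fine$abc) / fine$abc, 0.001)
})

test_that("sum of ABC aggregates concentrations and tracks the oracle", {
  p <- signal_params(noise_sd = 0, delta_max = 0.4, ec50 = 10)
  conc <- c(2.5, 5, 10, 20, 40)
  plate <- simulate_timecourse(p, conc, cfg, seed = 1)
  norm <- normalize_plate(plate, cfg)

  # singleton: the chemical sum equals its only ABC
  sub <- norm[norm$concentration_ug_ml %in% c(0, 10), ]
  one <- summarise_chemicals(sub, cfg)
  single_abc <- compute_abc(sub, cfg)$abc
  expect_equal(one$sum_abc, single_abc)

  summ <- summarise_chemicals(norm, cfg)
  per_conc <- compute_abc(norm, cfg)
  expect_equal(summ$sum_abc, sum(per_conc$abc), tolerance = 1e-9)

  truth <- sum(vapply(conc, function(cc) noiseless_abc_truth(p, cc, cfg), 0))
  expect_lt(abs(summ$sum_abc - truth) / truth, 0.05)

  # positive disruption at every concentration
  expect_equal(summ$direction_profile, "uniform_positive")
  # noiseless ABC grows with concentration (Hill monotonicity propagates)
  expect_true(all(diff(per_conc$abc) > 0))
})

test_that("direction profile distinguishes suppression and mixed responses", {
  p_neg <- signal_params(noise_sd = 0, delta_max = -0.4)
  plate <- simulate_timecourse(p_neg, c(5, 20), cfg, seed = 2)
  summ <- summarise_chemicals(normalize_plate(plate, cfg), cfg)
  expect_equal(summ$direction_profile, "uniform_negative")

  # tie rule: all-zero net areas count as uniformly positive
  expect_equal(abcscreen:::direction_from_net(c(0, 0)), "uniform_positive")
  expect_equal(abcscreen:::direction_from_net(c(1, -1)), "mixed")
})

test_that("the 24 h endpoint score is the terminal curve distance", {
  a <- constant_spline(grid24, 0)
  expect_equal(endpoint_score(a, a), 0)
  expect_equal(endpoint_score(a, constant_spline(grid24, 0.5)), 0.5)
  expect_error(endpoint_score(constant_spline(0:23, 0),
                              constant_spline(0:23, 0)),
               class = "abc_error_grid")
})

test_that("a transient disruption is invisible at 24 h but not to the ABC", {
  # pulse peaking near 4 h, decayed by 24 h: the single-endpoint comparator
  # misses it even though the integrated disruption is large
  p <- signal_params(noise_sd = 0, delta_max = 0.5, ec50 = 5,
                     profile = "transient")
  plate <- simulate_timecourse(p, c(10, 20), cfg, seed = 3)
  summ <- summarise_chemicals(normalize_plate(plate, cfg), cfg)
  expect_gt(summ$sum_abc, 2)
  expect_lt(summ$endpoint_score_24h, 0.1 * summ$sum_abc)
})

test_that("log-base change rescales ABC linearly", {
  p <- signal_params(noise_sd = 0, delta_max = 0.4)
  plate <- simulate_timecourse(p, 10, cfg, seed = 6)
  nat <- compute_abc(normalize_plate(plate, run_config(log_base = "natural")),
                     run_config(log_base = "natural"))
  b10 <- compute_abc(normalize_plate(plate, run_config(log_base = "10")),
                     run_config(log_base = "10"))
  expect_equal(b10$abc, nat$abc / log(10), tolerance = 1e-9)
})
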