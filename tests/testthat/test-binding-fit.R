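test_that("noise-free two-site sw data are recovered to 1e-4 relative", {
  truth <- two_site_params()
  d <- simulate_sw_titration(truth, sim_titration_design(noise_cv = 1e-12,
                                                         seed = 5))
  fit <- fit_binding(d, "two-site", n_starts = 8, seed = 2)
  expect_true(fit$converged)
  expect_equal(fit$estimates$kd1, truth$kd1, tolerance = 1e-4)
  expect_equal(fit$estimates$kd2, truth$kd2, tolerance = 1e-4)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("noise-free two-site fluorescence recovers Kds and amplitudes", {
  truth <- fluor_params()
  d <- simulate_fluor_titration(truth, sim_titration_design(
    l_tot_grid = seq(0, 2e-5, length.out = 12), noise_cv = 1e-12, seed = 5))
  fit <- fit_binding(d, "two-site", n_starts = 8, seed = 2)
  expect_true(fit$converged)
  expect_equal(fit$estimates$kd1, truth$kd1, tolerance = 1e-3)
  expect_equal(fit$estimates$kd2, truth$kd2, tolerance = 1e-2)
  expect_equal(fit$estimates$f0, truth$f0, tolerance = 1e-6)
  expect_equal(fit$estimates$df1, truth$df1, tolerance = 1e-3)
})

test_that("one-site fits of two-site data are worse and non-random", {
  d <- simulate_sw_titration(two_site_params(),
                             sim_titration_design(noise_cv = 0.01, seed = 17))
  f2 <- fit_binding(d, "two-site", n_starts = 8, seed = 1)
  f1 <- fit_binding(d, "one-site", n_starts = 8, seed = 1)
  expect_gt(f2$r_squared, f1$r_squared)
  cmp <- compare_models(f1, f2)
  expect_equal(cmp$preferred, "two-site")
  expect_gt(cmp$delta_r2, 0)
})

test_that("fitting is deterministic for a fixed seed", {
  d <- simulate_sw_titration(two_site_params(),
                             sim_titration_design(noise_cv = 0.01, seed = 3))
  f_a <- fit_binding(d, "two-site", n_starts = 4, seed = 77)
  f_b <- fit_binding(d, "two-site", n_starts = 4, seed = 77)
  expect_identical(f_a$estimates, f_b$estimates)
  expect_identical(f_a$residuals, f_b$residuals)
})

test_that("fits are invariant to concentration unit rescaling", {
  truth <- two_site_params()
  d <- simulate_sw_titration(truth, sim_titration_design(noise_cv = 0.01,
                                                         seed = 9))
  # same data expressed in "nM-like" units: totals x1000, so Kds scale x1000;
  # refit after rescaling back should agree
  d2 <- d
  d2$a_tot_molar <- d$a_tot_molar * 1e3
  d2$l_tot_molar <- d$l_tot_molar * 1e3
  class(d2) <- class(d)
  f <- fit_binding(d, "two-site", n_starts = 8, seed = 4)
  f2 <- fit_binding(d2, "two-site", n_starts = 8, seed = 4,
                    kd_bounds = c(1e-6, 1))
  expect_equal(f2$estimates$kd1 / f$estimates$kd1, 1e3, tolerance = 0.02)
  expect_equal(f2$estimates$kd2 / f$estimates$kd2, 1e3, tolerance = 0.05)
})

test_that("degenerate and undersized titrations error", {
  d <- sw_titration(rep(2.5e-6, 8), seq(0, 5e-6, length.out = 8),
                    rep(4, 8), rep(0.04, 8))
  expect_error(fit_binding(d, "two-site"), "zero variance")
  d2 <- sw_titration(2.5e-6, c(0, 5e-6), c(3.9, 5), c(0.04, 0.05))
  expect_error(fit_binding(d2, "two-site"), "points")
})

test_that("runs test matches exhaustive enumeration of arrangements", {
  s_obs <- c(1, 1, -1, -1, 1, 1, -1, -1)
  got <- runs_test(s_obs)
  expect_equal(got$runs, 4L)
  # enumerate all arrangements of 4 plus and 4 minus signs
  idx <- utils::combn(8, 4)
  runs_of <- function(pos) {
    s <- rep(-1, 8); s[pos] <- 1
    1 + sum(diff(s) != 0)
  }
  all_runs <- apply(idx, 2, runs_of)
  expect_equal(got$p_value, mean(all_runs <= 4))
})

test_that("runs test flags systematic residuals of a wrong model", {
  # one long positive run then one long negative run: minimal runs
  p <- runs_test(c(rep(0.5, 6), rep(-0.5, 6)))
  expect_lt(p$p_value, 0.05)
  p2 <- runs_test(rep(c(1, -1), 8))  # perfectly alternating
  expect_equal(p2$p_value, 1, tolerance = 1e-12)
})

test_that("compare_models rejects mismatched data and ties are neutral", {
  d <- simulate_sw_titration(two_site_params(),
                             sim_titration_design(noise_cv = 0.01, seed = 21))
  d2 <- simulate_sw_titration(two_site_params(),
                              sim_titration_design(noise_cv = 0.01, seed = 22))
  f <- fit_binding(d, "two-site", n_starts = 4, seed = 1)
  g <- fit_binding(d2, "two-site", n_starts = 4, seed = 1)
  expect_error(compare_models(f, g), "identical data")
  cmp <- compare_models(f, f)
  expect_equal(cmp$delta_r2, 0)
  expect_equal(cmp$preferred, "none")
})
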