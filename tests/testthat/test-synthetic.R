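# Synthetic experiment generator: calibrations, length/angle draws,
# intensity profiles, determinism, and closure with the analysis modules.

test_that("built-in calibrations cover the full condition grid", {
  tab <- builtin_calibrations()
  expect_equal(nrow(tab), 21)  # 3 controls + 3 scaffolds x 2 cues x 3 doses
  expect_true(all(tab$mean_length_um >= 0))
  expect_true(all(tab$q1_target >= 0 & tab$q1_target <= 1))
  expect_true(all(tab$q1_target + tab$q3_target <= 1))
  expect_true(all(nzchar(tab$provenance)))
  # anchor values
  ctrl <- get_calibration("collagen_2mg", "none")
  expect_equal(c(ctrl$mean_length_um, ctrl$sd_length_um), c(15, 3))
  igf <- get_calibration("collagen_1mg", "IGF1", 1)
  expect_equal(c(igf$mean_length_um, igf$sd_length_um), c(42, 9))
  mat <- get_calibration("matrigel", "none")
  expect_equal(c(mat$mean_length_um, mat$sd_length_um), c(18, 4))
  expect_error(get_calibration("agarose", "IGF1", 1), "no built-in")
})

test_that("generated lengths are reproducible and match their calibration", {
  cal <- get_calibration("collagen_2mg", "none")
  a <- generate_lengths(cal, 500, seed = 7)
  b <- generate_lengths(cal, 500, seed = 7)
  expect_identical(a, b)
  expect_true(all(a >= 0))
  # degenerate sd = 0, no tails: all values at the mean
  cal0 <- cal
  cal0$sd_length_um <- 0
  expect_equal(generate_lengths(cal0, 10, seed = 1), rep(15, 10))
  # control collagen sample recovers 15 +/- 3 um
  big <- generate_lengths(cal, 1e4, seed = 11)
  expect_equal(mean(big), 15, tolerance = 0.02)
  expect_equal(sd(big), 3, tolerance = 0.1)
  # long-tail condition reproduces the printed tail bins
  cal1 <- get_calibration("collagen_2mg", "IGF1", 1)
  lens <- generate_lengths(cal1, 1e4, seed = 13)
  expect_equal(mean(lens), 45, tolerance = 0.02)
  expect_equal(mean(lens > 31 & lens <= 100), 0.20, tolerance = 0.15)
  expect_equal(mean(lens > 101 & lens <= 290), 0.10, tolerance = 0.15)
  # inconsistent tails are a calibration error
  cal_bad <- cal1
  cal_bad$tail_fraction_31_100 <- 0.9
  cal_bad$tail_fraction_101_290 <- 0.2
  expect_error(generate_lengths(cal_bad, 10, seed = 1), "at most 1")
})

test_that("generated angles hit the calibrated toward-gradient mass", {
  # unbiased target: uniform angles
  cal_u <- get_calibration("collagen_1mg", "none")
  a <- generate_angles(cal_u, 2e4, seed = 3)
  expect_true(all(a >= 0 & a < 360))
  expect_equal(turning_summary(a)$q1_fraction, 0.25, tolerance = 0.05)
  # biased target: expected Q1 mass solved through the von Mises CDF
  cal_b <- get_calibration("collagen_2mg", "IGF1", 1)
  ab <- generate_angles(cal_b, 1e5, seed = 5)
  expect_equal(turning_summary(ab)$q1_fraction, 0.49, tolerance = 0.021)
  # determinism
  expect_identical(ab, generate_angles(cal_b, 1e5, seed = 5))
  # repulsive targets are out of scope; near-degenerate targets capped
  cal_r <- cal_b
  cal_r$q1_target <- 0.10
  expect_error(generate_angles(cal_r, 10, seed = 1), "repulsion")
  cal_one <- cal_b
  cal_one$q1_target <- 1
  expect_warning(generate_angles(cal_one, 10, seed = 1), "capped")
})

test_that("von Mises mass solver matches a direct Monte Carlo check", {
  # kappa = 0 is the uniform limit
  expect_equal(neuritaxis:::.vm_q1_mass(0), 0.25)
  # sampled mass agrees with the CDF integral at a mid-range kappa
  kap <- 1.7
  withr::with_seed(21, th <- neuritaxis:::.rvonmises(2e5, kap))
  expect_equal(mean(abs(th) < pi / 4), neuritaxis:::.vm_q1_mass(kap),
               tolerance = 0.01)
})

test_that("intensity profiles follow the series solution with gain and noise", {
  dom <- gel_domain(5000, Dc_um2_s = 8, n_grid = 41)
  t6 <- hours_to_seconds(6)
  # noiseless: exactly gain times the series solution
  p0 <- generate_intensity_profiles(dom, 1, t6, noise_cv = 0, seed = 1,
                                    gain = 50)
  expect_equal(p0$intensity,
               50 * exact_concentration(dom, 1, dom$x_um, t6))
  # t = 0: zero everywhere except the boundary node
  pz <- generate_intensity_profiles(dom, 1, 0, noise_cv = 0, seed = 1)
  expect_equal(pz$intensity[-1], rep(0, 40))
  expect_gt(pz$intensity[1], 0)
  # noisy round trip: Dc recovered within 10% from 4 time points at 5% CV
  times <- hours_to_seconds(c(6, 12, 24, 48))
  pn <- generate_intensity_profiles(dom, 1, times, noise_cv = 0.05,
                                    seed = 17)
  expect_equal(estimate_dc_from_profiles(pn)$Dc_um2_s, 8, tolerance = 0.1)
})

test_that("full synthetic experiments close the loop with morphometry", {
  cal <- get_calibration("matrigel", "IGF1", 0.1)
  exp1 <- generate_experiment(cal, 2000, seed = 23)
  exp2 <- generate_experiment(cal, 2000, seed = 23)
  expect_identical(exp1, exp2)
  expect_equal(length(unique(exp1$device)), 6)
  ctrl <- generate_experiment(get_calibration("matrigel", "none"),
                              2000, seed = 24)
  s <- summarize_outgrowth(exp1, control = ctrl)
  expect_equal(s$fold, 2.4, tolerance = 0.05)
  expect_gt(turning_summary(exp1)$n, 0)
})

test_that("model-driven generation recovers the generating law via fit_staged", {
  # displacements embedded in synthetic mean lengths at the two
  # calibration concentrations invert back to the generating (k, m)
  cfg <- fit_config(gel_domain(5000, Dc_um2_s = 8, n_grid = 251))
  ctrl_mean <- get_calibration("collagen_2mg", "none")$mean_length_um
  cals <- list(low = get_calibration("collagen_2mg", "IGF1", 0.1),
               high = get_calibration("collagen_2mg", "IGF1", 1))
  d_obs <- vapply(seq_along(cals), function(i) {
    lens <- generate_lengths(cals[[i]], 500, seed = 30 + i,
                             mode = "model_driven", config = cfg)
    mean(lens) - ctrl_mean
  }, 0)
  fit <- fit_staged(d_obs[1], d_obs[2], config = cfg)
  expect_equal(fit$law$k, 9, tolerance = 0.05)
  expect_equal(fit$law$m, 15, tolerance = 0.05)
})

test_that("model-driven mode requires a fitted parameter set", {
  cal <- get_calibration("collagen_1mg", "BDNF", 1)
  expect_error(generate_lengths(cal, 10, seed = 1, mode = "model_driven"),
               "no fitted")
})
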