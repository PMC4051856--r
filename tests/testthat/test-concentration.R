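# Cue diffusion field: series solution, gradient diagnostics, Dc recovery.

test_that("series solution satisfies the initial and boundary conditions", {
  dom <- gel_domain(5000, Dc_um2_s = 8, n_grid = 201)
  # initial condition: zero everywhere except the source boundary
  expect_equal(exact_concentration(dom, 1, c(10, 500, 5000), 0),
               c(0, 0, 0))
  expect_equal(exact_concentration(dom, 1, 0, 0), 1)
  # Dirichlet boundary at x = 0 for all times
  for (t in c(60, 3600, 172800)) {
    expect_equal(exact_concentration(dom, 2.5, 0, t), 2.5,
                 tolerance = 1e-7)
  }
  # maximum principle and monotone non-increasing profile on dense samples
  xs <- seq(0, 5000, by = 10)
  for (t in c(600, 3600, 75600, 172800)) {
    cc <- exact_concentration(dom, 1, xs, t)
    expect_true(all(cc >= -1e-9 & cc <= 1 + 1e-9))
    expect_true(all(diff(cc) <= 1e-9))
  }
  # steady state: flat at c0 after many slowest-mode decay times
  tau_mode <- 4 * 5000^2 / (pi^2 * 8)
  cc <- exact_concentration(dom, 1, xs, 100 * tau_mode)
  expect_equal(cc, rep(1, length(xs)), tolerance = 1e-6)
})

test_that("series solution matches an independent finite-difference solve", {
  l <- 5000; Dc <- 8; c0 <- 1
  times <- hours_to_seconds(c(1, 21, 48))
  fd <- fd_concentration(l, Dc, c0, times, n_grid = 2001)
  dom <- gel_domain(l, Dc_um2_s = Dc, n_grid = 2001)
  for (i in seq_along(times)) {
    ser <- exact_concentration(dom, c0, fd$x, times[i])
    rel_linf <- max(abs(ser - fd$c[i, ])) / max(fd$c[i, ])
    expect_lt(rel_linf, 0.005)
  }
})

test_that("requesting too few series terms warns with an error bound", {
  dom <- gel_domain(5000, Dc_um2_s = 8)
  expect_warning(exact_concentration(dom, 1, 2500, 3600, n_terms = 3),
                 "error bound")
  # at late times few terms suffice: no warning
  expect_silent(exact_concentration(dom, 1, 2500, 1e7, n_terms = 10))
})

test_that("series evaluation rejects invalid inputs", {
  dom <- gel_domain(5000, Dc_um2_s = 8)
  expect_error(exact_concentration(dom, 1, -5, 100), "x")
  expect_error(exact_concentration(dom, 1, 6000, 100), "within")
  expect_error(exact_concentration(dom, 1, 100, -1), "t")
  expect_error(exact_concentration(dom, NA, 100, 1), "c0")
  expect_error(gel_domain(-1, Dc_um2_s = 8), "length_um")
  expect_error(gel_domain(5000, Dc_um2_s = 8, n_grid = 2), "n_grid")
})

test_that("diffusion time follows tau = l^2 / (4 pi^2 Dc)", {
  # IGF-1 across 5 mm at 8e-12 m^2/s establishes in about 21 h
  tau_h <- seconds_to_hours(diffusion_time(gel_domain(5000, Dc_m2_s = 8e-12)))
  expect_gt(tau_h, 21)
  expect_lt(tau_h, 22)
  # quadratic scaling in l
  d1 <- gel_domain(2500, Dc_um2_s = 8)
  d2 <- gel_domain(5000, Dc_um2_s = 8)
  expect_equal(diffusion_time(d2) / diffusion_time(d1), 4)
  # unit identity: l = 2 pi mm, Dc = 1 mm^2/s -> 1 s
  expect_equal(diffusion_time(gel_domain(2 * pi * 1000, Dc_um2_s = 1e6)), 1)
})

test_that("steepness measures the fractional drop across 10 um", {
  # flat field (t -> infinity limit): zero steepness
  dom <- gel_domain(5000, Dc_um2_s = 8, n_grid = 101)
  fld <- concentration_field(dom, 1, 1e9)
  expect_equal(steepness(fld, 2500), 0, tolerance = 1e-6)
  # linear profile closed form: 100 * w / l at x = 0
  expect_equal(steepness(function(x) 1 - x / 5000, 0), 0.2)
  # series field vs numerical-gradient oracle at mid-domain, 48 h
  t48 <- hours_to_seconds(48)
  fld <- concentration_field(dom, 1, t48)
  s <- steepness(fld, 2500)
  h <- 0.5
  grad <- (exact_concentration(dom, 1, 2500 + h, t48) -
           exact_concentration(dom, 1, 2500 - h, t48)) / (2 * h)
  s_oracle <- 100 * 10 * (-grad) / exact_concentration(dom, 1, 2500, t48)
  expect_equal(s, s_oracle, tolerance = 0.02)
  expect_gt(s, 0)  # profile is monotone non-increasing
  # undefined where c = 0
  expect_error(steepness(function(x) 0 * x, 100), "undefined")
})

test_that("Stokes-Einstein mass scaling uses the cube-root radius law", {
  expect_equal(scale_dc_by_mass(8, 17, 17), 8)
  # 17 -> 27 kDa: ~14-15% slower
  slowdown <- 1 - scale_dc_by_mass(8, 17, 27) / 8
  expect_gt(slowdown, 0.13)
  expect_lt(slowdown, 0.16)
  # mass ratio 8 halves the coefficient
  expect_equal(scale_dc_by_mass(8, 17, 8 * 17), 4)
})

test_that("Dc is recovered from intensity profiles", {
  dom <- gel_domain(5000, Dc_um2_s = 8, n_grid = 41)
  times <- hours_to_seconds(c(6, 12, 24, 48))
  # noiseless self-consistency, arbitrary gain: within 1%
  prof <- generate_intensity_profiles(dom, 1, times, noise_cv = 0,
                                      seed = 1, gain = 1234)
  fit <- estimate_dc_from_profiles(prof)
  expect_equal(fit$Dc_um2_s, 8, tolerance = 0.01)
  expect_equal(fit$gain, 1234, tolerance = 0.01)
  expect_lt(fit$rss, 1e-6)
  # 5% multiplicative noise over 10 time points: within 10%
  times10 <- hours_to_seconds(seq(4, 48, length.out = 10))
  profn <- generate_intensity_profiles(dom, 1, times10, noise_cv = 0.05,
                                       seed = 42)
  fitn <- estimate_dc_from_profiles(profn)
  expect_equal(fitn$Dc_um2_s, 8, tolerance = 0.1)
  # non-identifiable cases error
  p0 <- generate_intensity_profiles(dom, 1, c(0, 0), noise_cv = 0, seed = 1)
  expect_error(estimate_dc_from_profiles(p0), "identifiable|distinct")
  expect_error(estimate_dc_from_profiles(prof[prof$time_s == times[1], ]),
               "distinct")
})

test_that("intensity profile CSV round-trips through read_intensity_profiles", {
  dom <- gel_domain(5000, Dc_um2_s = 8, n_grid = 21)
  prof <- generate_intensity_profiles(dom, 1, hours_to_seconds(c(6, 24)),
                                      noise_cv = 0.05, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(prof, path, row.names = FALSE)
  back <- read_intensity_profiles(path)
  expect_equal(back$intensity, prof$intensity)
  # missing columns are a format error
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_intensity_profiles(bad), "missing")
})
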