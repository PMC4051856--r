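# Trace-table morphometry: I/O, outgrowth summaries, turning quadrants,
# group comparisons.

test_that("trace CSVs are read and malformed rows collected with reasons", {
  df <- data.frame(
    neuron_id = 1:5, condition = "CTRL",
    length_um = c(12, 15, 18, -3, 20),
    angle_deg = c(10, 180, 200, 90, 400))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  tr <- read_traces(path)
  expect_s3_class(tr, "neurite_traces")
  expect_equal(nrow(tr), 3)
  rej <- attr(tr, "rejected")
  expect_equal(nrow(rej), 2)
  expect_setequal(rej$reason, c("negative length", "angle outside [0, 360)"))
  # missing columns are a format error
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(neuron_id = 1), bad, row.names = FALSE)
  expect_error(read_traces(bad), "missing")
})

test_that("SWC morphologies yield path length and planar orientation", {
  # straight neurite of two 10-um segments along -x: length 20, angle 180
  swc <- c("# synthetic two-segment neurite",
           "1 1 0 0 0 1 -1",
           "2 3 -10 0 0 0.5 1",
           "3 3 -20 0 0 0.5 2")
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(swc, path)
  tr <- read_traces(path, condition = "CTRL")
  expect_equal(tr$length_um, 20)
  expect_equal(tr$angle_deg, 180)
  # branched tree: the longest soma-to-tip path wins
  swc2 <- c("1 1 0 0 0 1 -1",
            "2 3 0 10 0 0.5 1",    # short branch along +y (tip at 10 um)
            "3 3 -10 0 0 0.5 1",
            "4 3 -25 0 0 0.5 3")   # long branch along -x (tip at 25 um)
  path2 <- withr::local_tempfile(fileext = ".swc")
  writeLines(swc2, path2)
  tr2 <- read_traces(path2)
  expect_equal(tr2$length_um, 25)
  expect_equal(tr2$angle_deg, 180)
  # no soma node is a format error
  swc3 <- c("1 3 0 0 0 1 -1", "2 3 5 0 0 1 1")
  path3 <- withr::local_tempfile(fileext = ".swc")
  writeLines(swc3, path3)
  expect_error(read_traces(path3), "soma")
})

test_that("outgrowth summaries report mean, sd, fold and histogram", {
  s <- summarize_outgrowth(rep(20, 6), control = rep(10, 6))
  expect_equal(s$mean_um, 20)
  expect_equal(s$sd_um, 0)
  expect_equal(s$fold, 2)
  expect_equal(s$fold_sd, 0)
  # identical samples give fold 1
  s1 <- summarize_outgrowth(c(10, 20, 30), control = c(10, 20, 30))
  expect_equal(s1$fold, 1)
  # histogram fractions sum to one; sub-micron neurites are excluded
  s2 <- summarize_outgrowth(c(0.5, 3, 12, 25, 95))
  expect_equal(sum(s2$histogram$fraction), 1, tolerance = 1e-9)
  expect_equal(s2$n_below_1um, 1)
  expect_equal(sum(s2$histogram$count), 4)
  # empty or zero-mean control flags the fold as undefined
  expect_warning(sz <- summarize_outgrowth(c(1, 2), control = c(0, 0)),
                 "undefined")
  expect_true(is.na(sz$fold))
})

test_that("re-binning a finer histogram reproduces the coarse bins", {
  withr::with_seed(5, lens <- rgamma(500, shape = 4, rate = 0.15))
  fine <- neuritaxis:::.length_histogram(lens, binwidth_um = 5)
  coarse <- neuritaxis:::.length_histogram(lens, binwidth_um = 10)
  # aggregate fine bins up to each coarse bin edge
  agg <- vapply(seq_len(nrow(coarse)), function(i) {
    sum(fine$count[fine$bin_lo >= coarse$bin_lo[i] &
                   fine$bin_hi <= coarse$bin_hi[i]])
  }, 0)
  expect_equal(agg, as.numeric(coarse$count))
})

test_that("turning quadrants partition the circle as printed", {
  expect_equal(as.character(classify_turning(180)), "Q1")
  expect_equal(as.character(classify_turning(0)), "Q3")
  # boundary angles are strict: none of them count as Q1/Q3
  expect_equal(as.character(classify_turning(c(45, 135, 225, 315))),
               rep("other", 4))
  expect_error(classify_turning(400), "\\[0, 360\\)")
  # every angle maps to exactly one class, and Q1/Q3 each cover 90 degrees
  grid <- seq(0, 359.9, by = 0.1)
  cls <- classify_turning(grid)
  expect_equal(length(cls), length(grid))
  expect_equal(sum(cls == "Q1") / length(grid), 0.25, tolerance = 0.01)
  expect_equal(sum(cls == "Q3") / length(grid), 0.25, tolerance = 0.01)
})

test_that("turning summaries match analytic expectations", {
  # uniform angles: a quarter of the mass in each quadrant
  withr::with_seed(7, ang <- runif(1e5, 0, 360))
  ts <- turning_summary(ang)
  expect_equal(ts$q1_fraction, 0.25, tolerance = 0.04)
  expect_equal(ts$q3_fraction, 0.25, tolerance = 0.04)
  expect_equal(ts$q1_fraction + ts$q3_fraction + ts$other_fraction, 1)
  expect_equal(sum(ts$windrose$count), 1e5)
  expect_equal(nrow(ts$windrose), 24)
  # all neurites pointing at the source
  expect_equal(turning_summary(rep(180, 50))$q1_fraction, 1)
})

test_that("group comparisons pick sensible tests and p-values", {
  # identical samples: rank-sum test, p = 1
  cmp <- compare_groups(c(1, 2, 3), c(1, 2, 3), method = "mann_whitney")
  expect_equal(cmp$p_value, 1)
  # clearly separated samples under Welch: p < 0.001
  cmpw <- compare_groups(c(1, 2, 3), c(101, 102, 103), method = "welch_t")
  expect_lt(cmpw$p_value, 0.001)
  # degenerate zero-variance samples fall back with a warning
  expect_warning(
    cmpd <- compare_groups(rep(5, 4), rep(7, 4), method = "welch_t"),
    "falling back")
  expect_equal(cmpd$method, "mann_whitney")
  # auto mode: heavy-tailed data routed to the rank-sum test
  withr::with_seed(9, {
    a <- rexp(30)^3
    b <- rexp(30)^3
  })
  expect_equal(compare_groups(a, b)$method, "mann_whitney")
  withr::with_seed(10, {
    a <- rnorm(30)
    b <- rnorm(30)
  })
  expect_equal(compare_groups(a, b)$method, "welch_t")
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "n >= 3")
})
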