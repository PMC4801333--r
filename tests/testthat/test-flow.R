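fake_increments <- function(increment, quadrant, included = TRUE) {
  data.frame(grid_row = seq_along(increment), grid_col = 1,
             quadrant = quadrant, included = included,
             filling = increment > 0, increment = increment,
             degenerate = FALSE, stringsAsFactors = FALSE)
}

test_that("flow increment follows the rise-over-frames definition", {
  # rise from 0% to 40% over 10 frame intervals -> 4 percent per frame
  tt <- seq(0, 1200, by = 30)
  n <- length(tt)
  series <- downsample(constant_stack(value = 0, rows = 8, cols = 8,
                                      n_frames = n), 8, 8)
  pa <- build_mask(full_annulus_geometry(8, 8, corneal_frac = 0), series)
  # piecewise-linear course: 0 at t=0 rising to 80 at t=600, flat after
  for (i in which(pa$included))
    series$intensity[, pa$grid_row[i], pa$grid_col[i]] <-
      pmin(tt * 80 / 600, 80)
  series$percent <- TRUE  # values already on a percent scale
  fits <- fit_all(series, pa)
  inc <- impute_flow(fits, assignment = pa, source = "individual")
  # I_half = 40, reached at t = 300 = 10 intervals, baseline ~ 0
  expect_equal(mean(inc$increment[inc$included]), 4, tolerance = 0.05)

  # flat macropixels contribute zero
  series0 <- downsample(constant_stack(value = 5, rows = 8, cols = 8,
                                       n_frames = n), 8, 8)
  series0$percent <- TRUE
  fits0 <- fit_all(series0, pa)
  inc0 <- impute_flow(fits0, assignment = pa, source = "individual")
  expect_true(all(inc0$increment == 0))
})

test_that("quadrant flows reproduce the worked fraction example", {
  inc <- fake_increments(c(0.30, 0.3667, 0.20, 0.1333),
                         c("IN", "SN", "ST", "IT"))
  qf <- quadrant_flows(inc, total_flow_ul_min = 3)
  expect_equal(qf$quadrant, c("IN", "SN", "ST", "IT"))
  expect_equal(round(qf$flow_ul_min, 2), c(0.90, 1.10, 0.60, 0.40))
})

test_that("all flow in one quadrant attributes the full total there", {
  inc <- fake_increments(c(0, 5, 0, 0), c("IN", "SN", "ST", "IT"))
  qf <- quadrant_flows(inc, total_flow_ul_min = 3)
  expect_equal(qf$flow_ul_min, c(0, 3, 0, 0))
})

test_that("quadrant flows always conserve the configured total", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    inc <- fake_increments(runif(n, 0, 10),
                           sample(c("IN", "SN", "ST", "IT"), n, replace = TRUE))
    tot <- runif(1, 0.5, 10)
    qf <- quadrant_flows(inc, total_flow_ul_min = tot)
    expect_lt(abs(sum(qf$flow_ul_min) - tot) / tot, 1e-9)
    expect_equal(sum(qf$flow_fraction), 1, tolerance = 1e-12)
    expect_true(all(qf$flow_ul_min >= 0))
  }
})

test_that("zero increments raise a no-detectable-flow error", {
  inc <- fake_increments(c(0, 0, 0, 0), c("IN", "SN", "ST", "IT"))
  expect_error(quadrant_flows(inc), "no detectable flow")
})

test_that("filling time reports the first threshold crossing per quadrant", {
  n <- 41
  series <- downsample(constant_stack(value = 0, rows = 16, cols = 16,
                                      n_frames = n), 8, 8)
  pa <- build_mask(full_annulus_geometry(16, 16, corneal_frac = 0.1), series)
  # one IN macropixel jumps to 100 at frame 16 (t = 450 s = 7.5 min)
  in_cells <- which(pa$included & pa$quadrant == "IN")
  i <- in_cells[1]
  series$intensity[16:n, pa$grid_row[i], pa$grid_col[i]] <- 100
  series$percent <- TRUE
  ft <- quadrant_filling_time(series, pa, onset_threshold = 5)
  expect_equal(ft$filling_time_min[ft$quadrant == "IN"], 7.5)
  expect_false(ft$censored[ft$quadrant == "IN"])
  expect_true(all(ft$censored[ft$quadrant != "IN"]))
  expect_true(all(ft$filling_time_min[ft$quadrant != "IN"] == 20))

  # threshold 0: any positive change counts from its first frame
  series2 <- series
  for (q in which(pa$included))
    series2$intensity[2:n, pa$grid_row[q], pa$grid_col[q]] <-
      pmax(series2$intensity[2:n, pa$grid_row[q], pa$grid_col[q]], 1e-6)
  ft0 <- quadrant_filling_time(series2, pa, onset_threshold = 0)
  expect_true(all(ft0$filling_time_min == 0.5))
})

test_that("paired comparison matches the closed-form t statistic", {
  # identical vectors: t = 0, p = 1
  same <- paired_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # differences (-1, -2, 0): t = -sqrt(3), p = 2 * P(T_2 < -sqrt(3))
  res <- paired_compare(c(1, 2, 3), c(2, 4, 3))
  expect_equal(res$t, -sqrt(3), tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-sqrt(3), df = 2), tolerance = 1e-12)

  # antisymmetry: swapping arguments negates t, keeps p
  swapped <- paired_compare(c(2, 4, 3), c(1, 2, 3))
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)

  # constant non-zero difference flagged as degenerate
  deg <- paired_compare(c(1, 2, 3), c(0, 1, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
})

test_that("scaling the raw stack leaves fractions, timing and t_half fixed", {
  sp <- preset("whole_eye", seed = 21, rows = 96, cols = 96, noise_sd = 2)
  sim <- generate(sp, grid_rows = 16, grid_cols = 16)
  fit1 <- canaloflow(sim, grid_rows = 16, grid_cols = 16,
                     fit_macropixels = FALSE)

  scaled <- sim$stack
  scaled$frames <- scaled$frames * 2
  fit2 <- canaloflow(scaled, sim$geometry, grid_rows = 16, grid_cols = 16,
                     fit_macropixels = FALSE)

  expect_equal(fit1$quadrants$flow_fraction, fit2$quadrants$flow_fraction,
               tolerance = 1e-9)
  expect_equal(fit1$quadrants$filling_time_min, fit2$quadrants$filling_time_min)
  expect_equal(fit1$regional$table$t_half_s, fit2$regional$table$t_half_s,
               tolerance = 1e-9)
})
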