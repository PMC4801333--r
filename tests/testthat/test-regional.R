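# region series over a full annulus with per-ring logistic timing
ring_timed_series <- function(t50_by_ring = c(240, 420, 600), rows = 64,
                              cols = 64, n_frames = 41) {
  tt <- (seq_len(n_frames) - 1) * 30
  stack0 <- constant_stack(value = 0, rows = rows, cols = cols,
                           n_frames = n_frames)
  series <- downsample(stack0, 32, 32)
  geom <- full_annulus_geometry(rows, cols, corneal_frac = 0.1)
  pa <- build_mask(geom, series)
  for (i in which(pa$included)) {
    r <- pa$ring[i]
    series$intensity[, pa$grid_row[i], pa$grid_col[i]] <-
      logistic_fill(tt, 100, t50_by_ring[r], 60)
  }
  list(series = series, pa = pa)
}

test_that("region aggregation equals brute-force group means", {
  set.seed(5)
  frames <- array(runif(6 * 48 * 48, 0, 100), c(6, 48, 48))
  stack <- canalogram_stack(frames)
  series <- downsample(stack, 16, 16)
  geom <- full_annulus_geometry(48, 48, corneal_frac = 0.12)
  pa <- build_mask(geom, series)
  regions <- aggregate_regions(series, pa)

  expect_equal(nrow(regions), 36 * 6)
  inc <- pa[pa$included, ]
  for (j in sample(nrow(regions), 20)) {
    h <- regions$clock_hour[j]; r <- regions$ring[j]; f <- regions$frame[j]
    mem <- inc[inc$clock_hour == h & inc$ring == r, ]
    if (nrow(mem) == 0) {
      expect_true(is.na(regions$intensity[j]))
    } else {
      vals <- mapply(function(gr, gc) series$intensity[f, gr, gc],
                     mem$grid_row, mem$grid_col)
      expect_equal(regions$intensity[j], mean(vals))
    }
  }
})

test_that("uniform intensity gives every region the same constant series", {
  series <- downsample(constant_stack(value = 42, rows = 48, cols = 48,
                                      n_frames = 5), 16, 16)
  pa <- build_mask(full_annulus_geometry(48, 48), series)
  regions <- aggregate_regions(series, pa)
  nonempty <- regions[regions$n_members > 0, ]
  expect_true(all(abs(nonempty$intensity - 42) < 1e-10))
})

test_that("a single hot region stands out and the rest stay at zero", {
  series <- downsample(constant_stack(value = 0, rows = 48, cols = 48,
                                      n_frames = 4), 16, 16)
  pa <- build_mask(full_annulus_geometry(48, 48), series)
  target <- pa$included & pa$clock_hour == 3 & pa$ring == 2
  for (i in which(target))
    series$intensity[, pa$grid_row[i], pa$grid_col[i]] <- 100
  regions <- aggregate_regions(series, pa)
  hot <- regions$clock_hour == 3 & regions$ring == 2
  expect_true(all(regions$intensity[hot & regions$n_members > 0] == 100))
  cold <- !hot & regions$n_members > 0
  expect_true(all(regions$intensity[cold] == 0))
})

test_that("the global model resolves ring-specific fill timing", {
  dat <- ring_timed_series(t50_by_ring = c(240, 420, 600))
  regions <- aggregate_regions(dat$series, dat$pa)
  fit <- fit_global(regions)

  expect_equal(nrow(fit$table), 36)
  tab <- fit$table[!fit$table$empty, ]

  # ring 1 fills before ring 3 at every clock hour
  for (h in unique(tab$clock_hour)) {
    t1 <- tab$t_half_s[tab$clock_hour == h & tab$ring == 1]
    t3 <- tab$t_half_s[tab$clock_hour == h & tab$ring == 3]
    if (length(t1) && length(t3)) expect_lt(t1, t3)
  }

  # per-region half-max from the global fit agrees with independent
  # per-region curve fits within one frame interval (noiseless data)
  tt <- sort(unique(regions$time_s))
  for (j in sample(which(!fit$table$empty), 6)) {
    h <- fit$table$clock_hour[j]; r <- fit$table$ring[j]
    y <- regions$intensity[regions$clock_hour == h & regions$ring == r]
    single <- fit_curve(tt, y)
    hm <- extract_half_max(single, tt[1], tt[length(tt)])
    expect_lt(abs(fit$table$t_half_s[j] - hm$t_half_s), 30)
  }
})

test_that("identical fill courses give equal timing across all regions", {
  stack <- uniform_logistic_stack(rows = 64, cols = 64, n_frames = 41,
                                  t50 = 400)
  series <- downsample(stack, 32, 32)
  pa <- build_mask(full_annulus_geometry(64, 64), series)
  fit <- fit_global(aggregate_regions(series, pa))
  tab <- fit$table[!fit$table$empty, ]
  expect_lt(diff(range(tab$t_half_s)), 30)
  expect_equal(tab$filling_rate, tab$I_half / tab$t_half_s)
})

test_that("the fitted surface is periodic in clock hour", {
  dat <- ring_timed_series()
  fit <- fit_global(aggregate_regions(dat$series, dat$pa))
  for (tprobe in c(100, 600, 1100)) {
    p0 <- fit$predict(0, 2, tprobe)
    p12 <- fit$predict(12, 2, tprobe)
    expect_equal(p0, p12, tolerance = 1e-8)
  }
})

test_that("all-empty aggregation is rejected", {
  series <- downsample(constant_stack(rows = 32, cols = 32, n_frames = 5),
                       16, 16)
  pa <- build_mask(full_annulus_geometry(32, 32), series)
  regions <- aggregate_regions(series, pa)
  regions$n_members <- 0L
  expect_error(fit_global(regions), "empty")
})

test_that("circumferential profile localizes a fast sector", {
  # one fast 3-hour sector (hours 2-4), the rest slow
  tt <- (0:40) * 30
  series <- downsample(constant_stack(rows = 64, cols = 64, n_frames = 41),
                       32, 32)
  pa <- build_mask(full_annulus_geometry(64, 64), series)
  for (i in which(pa$included)) {
    fast <- pa$clock_hour[i] %in% 2:4
    series$intensity[, pa$grid_row[i], pa$grid_col[i]] <-
      logistic_fill(tt, 100, if (fast) 250 else 650, 60)
  }
  fit <- fit_global(aggregate_regions(series, pa))
  prof <- circumferential_profile(fit)
  expect_equal(nrow(prof), 12)
  expect_true(which.min(prof$t_half_s) %in% 2:4)

  # rotationally symmetric input gives a flat profile
  stack_sym <- uniform_logistic_stack(rows = 64, cols = 64, n_frames = 41)
  series_sym <- downsample(stack_sym, 32, 32)
  pa_sym <- build_mask(full_annulus_geometry(64, 64), series_sym)
  prof_sym <- circumferential_profile(
    fit_global(aggregate_regions(series_sym, pa_sym)))
  expect_lt(max(prof_sym$t_half_s) - min(prof_sym$t_half_s), 30)
})
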