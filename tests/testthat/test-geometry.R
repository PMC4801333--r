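test_that("quadrant assignment partitions the circle and mirrors laterality", {
  # one label per 90-degree step, each occurring exactly once
  sweep_od <- assign_quadrant(c(45, 135, 225, 315), "OD")
  expect_setequal(sweep_od, c("IN", "SN", "ST", "IT"))
  sweep_os <- assign_quadrant(c(45, 135, 225, 315), "OS")
  expect_setequal(sweep_os, c("IN", "SN", "ST", "IT"))

  # flipping laterality swaps nasal and temporal at the same image angle
  swap <- c(IN = "IT", IT = "IN", SN = "ST", ST = "SN")
  angles <- seq(0, 355, by = 5)
  expect_identical(unname(swap[assign_quadrant(angles, "OD")]),
                   assign_quadrant(angles, "OS"))

  # angles wrap mod 360
  expect_identical(assign_quadrant(45 + 720, "OD"), assign_quadrant(45, "OD"))

  # meridian angle goes to the clockwise-following sector
  expect_identical(assign_quadrant(0, "OD"), assign_quadrant(1, "OD"))
  expect_identical(assign_quadrant(90, "OD"), assign_quadrant(91, "OD"))
  expect_identical(assign_quadrant(270, "OD"), assign_quadrant(271, "OD"))
})

test_that("clock hours span 30 degrees centered on their label, 12 superior", {
  expect_equal(canaloflow:::clock_hour_from_angle(0), 12L)
  expect_equal(canaloflow:::clock_hour_from_angle(c(-14.9, 14.9)), c(12L, 12L))
  expect_equal(canaloflow:::clock_hour_from_angle(30), 1L)
  expect_equal(canaloflow:::clock_hour_from_angle(90), 3L)
  expect_equal(canaloflow:::clock_hour_from_angle(180), 6L)
  expect_equal(canaloflow:::clock_hour_from_angle(270), 9L)
  # boundary goes to the clockwise-following hour
  expect_equal(canaloflow:::clock_hour_from_angle(15), 1L)
  expect_equal(canaloflow:::clock_hour_from_angle(14.999), 12L)
})

test_that("full annulus on a 32x32 grid yields exactly 36 labelled regions", {
  stack <- constant_stack(rows = 64, cols = 64, n_frames = 2)
  series <- downsample(stack, 32, 32)
  geom <- full_annulus_geometry(64, 64, corneal_frac = 0.15)
  pa <- build_mask(geom, series)

  inc <- pa[pa$included, ]
  expect_gt(nrow(inc), 0)
  expect_equal(nrow(unique(inc[, c("clock_hour", "ring")])), 36)

  # partition properties: one hour, ring, quadrant each; quadrants disjoint
  expect_false(any(is.na(inc$clock_hour)))
  expect_false(any(is.na(inc$ring)))
  expect_false(any(is.na(inc$quadrant)))
  expect_true(all(inc$ring %in% 1:3))
  expect_true(all(inc$clock_hour %in% 1:12))
  expect_setequal(unique(inc$quadrant), c("IN", "SN", "ST", "IT"))
})

test_that("ring index follows equal-width radial bands with inner tie-break", {
  stack <- constant_stack(rows = 60, cols = 60, n_frames = 2)
  series <- downsample(stack, 30, 30)
  geom <- eye_geometry(29.5, 29.5, corneal_radius_px = 6,
                       outer_radius_px = 27)
  pa <- build_mask(geom, series)
  inc <- pa[pa$included, ]
  width <- (27 - 6) / 3
  # recompute rings independently from radii
  expected <- pmin(pmax(ceiling((inc$radius_px - 6) / width), 1), 3)
  expect_equal(inc$ring, as.integer(expected))
  # a radius exactly on the first boundary belongs to the inner ring
  expect_equal(ceiling((6 + width - 6) / width), 1)

  # macropixel one sixth of the annulus width out, superior: ring 1, hour 12
  r_probe <- 6 + width / 2
  ang_probe <- 0
  expect_equal(min(3, max(1, ceiling((r_probe - 6) / width))), 1)
  expect_equal(canaloflow:::clock_hour_from_angle(ang_probe), 12L)
})

test_that("degenerate cornea of radius zero includes the center macropixel", {
  stack <- constant_stack(rows = 32, cols = 32, n_frames = 2)
  series <- downsample(stack, 16, 16)
  geom <- eye_geometry(15.5, 15.5, corneal_radius_px = 0,
                       outer_radius_px = 14)
  pa <- build_mask(geom, series)
  ctr <- pa[abs(pa$center_row - 15.5) < 1 & abs(pa$center_col - 15.5) < 1, ]
  expect_true(all(ctr$included))
})

test_that("rotating the superior direction by 360 degrees is the identity", {
  stack <- constant_stack(rows = 48, cols = 48, n_frames = 2)
  series <- downsample(stack, 16, 16)
  g0 <- eye_geometry(23.5, 23.5, 5, 20, superior_angle_deg = 0)
  g360 <- eye_geometry(23.5, 23.5, 5, 20, superior_angle_deg = 360)
  expect_equal(build_mask(g0, series)$clock_hour,
               build_mask(g360, series)$clock_hour)
  expect_equal(build_mask(g0, series)$quadrant,
               build_mask(g360, series)$quadrant)
})

test_that("auto_outer_radius finds the largest complete ring", {
  g <- eye_geometry(160, 160, corneal_radius_px = 30)
  expect_equal(auto_outer_radius(g, c(320, 320)), 159.5)

  # compression ring caps the radius; verify against a brute-force scan
  r_auto <- auto_outer_radius(g, c(320, 320), ring_inner_radius_px = 100)
  expect_lte(r_auto, 100)
  candidates <- seq(30.5, 200, by = 0.5)
  ok <- vapply(candidates, function(r) {
    r <= 100 && 160 - r >= -0.5 && 160 + r <= 319.5
  }, TRUE)
  expect_equal(r_auto, max(candidates[ok]))

  # off-center eye limited by the nearest edge
  g_off <- eye_geometry(160, 10, corneal_radius_px = 3)
  expect_equal(auto_outer_radius(g_off, c(320, 320)), 10.5)
  g_bad <- eye_geometry(160, 10, corneal_radius_px = 30)
  expect_error(auto_outer_radius(g_bad, c(320, 320)), "incomplete ring")
})

test_that("analysis circle exceeding the image bounds is rejected", {
  stack <- constant_stack(rows = 32, cols = 32, n_frames = 2)
  series <- downsample(stack, 16, 16)
  geom <- eye_geometry(15.5, 15.5, corneal_radius_px = 3,
                       outer_radius_px = 30)
  expect_error(build_mask(geom, series), "incomplete ring")
})

test_that("geometry configs load from YAML and JSON", {
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("center_row: 160", "center_col: 160",
               "corneal_radius_px: 30", "outer_radius_px: auto",
               "laterality: OS"), fy)
  gy <- read_geometry(fy)
  expect_true(is.na(gy$outer_radius_px))
  expect_equal(gy$laterality, "OS")

  fj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"center_row": 10, "center_col": 12, "corneal_radius_px": 2,
              "outer_radius_px": 8}', fj)
  gj <- read_geometry(fj)
  expect_equal(gj$outer_radius_px, 8)
  expect_equal(gj$laterality, "OD")
})
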