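test_that("depth, height and resolution follow the pinhole relations", {
  expect_equal(depth_from_disparity(100, f = 1000, b = 1), 10)
  # algebraic round trip
  l <- 7.3; f <- 2800; b <- 0.6
  expect_identical(depth_from_disparity(f * b / l, f, b), l)
  # linear in baseline
  expect_equal(depth_from_disparity(50, 1000, 2), 2 * depth_from_disparity(50, 1000, 1))
  expect_error(depth_from_disparity(0, 1000, 1), "positive")

  expect_equal(plant_height(100, 100, 1000, 1), 0)
  expect_equal(plant_height(585, 670, 3000, 0.81), 2430 * (1 / 585 - 1 / 670))
  # monotone in the plant disparity
  h1 <- plant_height(585, 650, 3000, 0.81)
  h2 <- plant_height(585, 700, 3000, 0.81)
  expect_gt(h2, h1)

  expect_equal(depth_step_resolution(10, 999), 0.01)
  expect_equal(depth_step_resolution(4.1, 2320), 4.1 / 2321)
})

test_that("the depth-step identity holds exactly for any (f, b, d)", {
  set.seed(10)
  for (k in 1:30) {
    f <- runif(1, 500, 8000); b <- runif(1, 0.1, 2); d <- sample(50:3000, 1)
    l <- depth_from_disparity(d, f, b)
    expect_equal(depth_step_resolution(l, d),
                 f * b / d - f * b / (d + 1), tolerance = 1e-12)
  }
})

test_that("per-level resolution reproduces the field worked examples", {
  # short-baseline buckwheat pair: 570 mm over 199 levels
  expect_equal(round(1000 * per_level_height_resolution(0.570, 1374, 1573), 1), 2.9)
  # long-baseline pair: 570 mm over 363 levels
  expect_equal(round(1000 * per_level_height_resolution(0.570, 1957, 2320), 1), 1.6)
  # high-altitude fake plant: 595 mm over the printed 37-level difference
  # (per-pixel arithmetic on the printed extrema 1224 and 1188 gives 36;
  #  both readings round to 16-17 mm)
  expect_equal(round(1000 * per_level_height_resolution(0.595, 0, 37)), 16)
  expect_equal(1000 * per_level_height_resolution(0.595, 1188, 1224),
               595 / 36, tolerance = 1e-12)
  expect_error(per_level_height_resolution(0.5, 100, 100), "exceed")
})

test_that("error reduction reproduces the comparative arithmetic", {
  expect_equal(round(error_reduction(3.4, 9.0), 1), 62.2)
  expect_equal(round(error_reduction(3.4, 11.1), 1), 69.4)
  expect_equal(error_reduction(5, 5), 0)
  expect_error(error_reduction(1, 0), "positive")
})

test_that("plant height scales linearly with the baseline", {
  h1 <- plant_height(585, 670, 3000, 0.4)
  h2 <- plant_height(585, 670, 3000, 0.8)
  expect_equal(h2, 2 * h1, tolerance = 1e-12)
})

test_that("measure_plant recovers a rendered box height", {
  pr <- fixture("plantpair3", function() plant_pair(3L))
  dm <- compute_disparity_map(pr$left, pr$right, std_cfg(),
                              baseline = std_baseline, focal = std_focal)
  rect <- plant_rect_from_truth(pr)
  m <- measure_plant(dm, list(plant = rect), std_intr(), std_baseline)
  truth <- pr$truth$plant_heights[1]
  res_level <- truth / (m$plant_disparity - m$ground_disparity)
  expect_lt(abs(m$plant_height - truth), 2 * res_level)
  expect_gte(m$plant_disparity, m$ground_disparity)
  expect_gt(m$resolution_per_level, 0)
})

test_that("a ground-only region measures (near) zero height", {
  pr <- flat_pair()
  dm <- compute_disparity_map(pr$left, pr$right, std_cfg(),
                              baseline = std_baseline, focal = std_focal)
  m <- measure_plant(dm, list(plant = c(200, 120, 260, 180)),
                     std_intr(), std_baseline)
  expect_lt(abs(m$plant_height), 1.5 * m$resolution_per_level)
})

test_that("a fully invalid region raises a measurement failure", {
  pr <- flat_pair()
  dm <- compute_disparity_map(pr$left, pr$right, std_cfg(),
                              baseline = std_baseline, focal = std_focal)
  # the left margin of the map is outside the overlap region, hence invalid
  expect_error(measure_plant(dm, list(plant = c(5, 5, 40, 40),
                                      ground = c(2, 2, 50, 50)),
                             std_intr(), std_baseline),
               class = "dronestereo_measurement_error")
})
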