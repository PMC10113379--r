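d2r <- pi / 180

test_that("solve_beta matches substitution and symmetry cases", {
  # two line pairs, direct substitution
  ab <- data.frame(a = c(0.010, 0.020), b = c(200, 100))
  expect_equal(solve_beta(ab, focal = 3000), atan(-0.3), tolerance = 1e-12)
  expect_equal(solve_beta(ab[2:1, ], focal = 3000), atan(-0.3),
               tolerance = 1e-12)           # order of the pair is irrelevant
  # equal slopes: gradients already equal
  expect_equal(solve_beta(data.frame(a = c(0.01, 0.01, 0.01),
                                     b = c(-50, 0, 50)), 3000), 0)
  expect_error(solve_beta(data.frame(a = c(0.1, 0.2), b = c(5, 5)), 3000),
               "degenerate")
})

test_that("solve_beta with many lines equals the pairwise least squares", {
  set.seed(7)
  beta <- 0.01
  f <- 3000
  b <- seq(-300, 300, length.out = 7)
  a <- tan(beta) * b / f
  expect_equal(solve_beta(data.frame(a = a, b = b), f), beta, tolerance = 1e-9)
})

test_that("solve_gamma is the arctangent of the mean slope", {
  mk <- function(a) data.frame(a = a, b = seq_along(a))
  expect_equal(solve_gamma(mk(c(0, 0, 0))), 0)
  expect_equal(solve_gamma(mk(c(1, 1, 1))), pi / 4)
  expect_equal(solve_gamma(mk(c(0.01, 0.012, 0.011))), atan(0.011),
               tolerance = 1e-12)
})

test_that("solve_alpha matches the spacing formula on single triples", {
  expect_equal(solve_alpha(c(100, 210, 300), focal = 3000),
               atan(60000 / 114000), tolerance = 1e-12)
  # equally spaced intercepts: numerator vanishes
  expect_equal(solve_alpha(c(-80, 0, 80), 3000), 0)
  # swapping the outer intercepts leaves the formula unchanged
  expect_equal(solve_alpha(c(300, 210, 100), 3000),
               solve_alpha(c(100, 210, 300), 3000))
  expect_error(solve_alpha(c(1, 2), 3000), "3 intercepts")
  expect_error(solve_alpha(c(1, 2, -2 / 3), 3000), "degenerate")
})

test_that("solve_translation recovers shift and central scale", {
  C <- seq(-100, 100, 25)
  tr <- solve_translation(C, C)
  expect_equal(tr$delta_y, 0)
  expect_equal(tr$delta_z_scale, 1)
  tr <- solve_translation(C + 10, C)
  expect_equal(tr$delta_y, 10)
  expect_equal(tr$delta_z_scale, 1, tolerance = 1e-12)
  tr <- solve_translation(1.05 * C, C)
  expect_equal(tr$delta_z_scale, 1 / 1.05, tolerance = 1e-12)
  expect_error(solve_translation(c(1, 2, 3), c(5, 5, 5)), "indeterminate")
})

test_that("fit_ground_plane recovers exact and noisy planes", {
  set.seed(8)
  x <- runif(200, -2, 2); y <- runif(200, -2, 2)
  z <- 0.01 * x + 0.02 * y + 4
  pl <- fit_ground_plane(data.frame(x = x, y = y, z = z))
  expect_equal(pl$a, 0.01, tolerance = 1e-10)
  expect_equal(pl$b, 0.02, tolerance = 1e-10)
  expect_equal(pl$c, 4, tolerance = 1e-10)
  expect_lt(pl$fit_rms, 1e-10)
  # horizontal plane
  pl0 <- fit_ground_plane(data.frame(x = x, y = y, z = rep(4, 200)))
  expect_equal(pl0$a, 0); expect_equal(pl0$b, 0)
  # Gaussian noise: coefficients within 3 analytic standard errors
  sigma <- 0.005
  zn <- z + rnorm(200, 0, sigma)
  pln <- fit_ground_plane(data.frame(x = x, y = y, z = zn))
  X <- cbind(1, x, y)
  se <- sigma * sqrt(diag(solve(crossprod(X))))
  expect_lt(abs(pln$c - 4), 3 * se[1])
  expect_lt(abs(pln$a - 0.01), 3 * se[2])
  expect_lt(abs(pln$b - 0.02), 3 * se[3])
  # collinear support is rejected
  expect_error(fit_ground_plane(data.frame(x = 1:5, y = 2 * (1:5), z = 1:5)),
               "collinear")
})

test_that("phase 1 recovers in-plane rotation and scale of the right image", {
  left <- flat_pair()$left
  cfg <- std_cfg()
  # identical images: identity transform (search centred on zero shift)
  cfg0 <- match_config(window_radius = 5, search_center = 0, search_span = 16)
  p <- phase1_rough_align(left, left, cfg0)
  expect_equal(p$z_rotation, 0, tolerance = 0.01 * d2r)
  expect_equal(p$scale, 1, tolerance = 1e-3)
  # right = left rotated by +0.5 degrees about the centre; warp_image maps
  # output to input coordinates, so the content rotation is the inverse of H
  th <- 0.5 * d2r
  Hrot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
  rot <- warp_image(left, Hrot)
  p <- phase1_rough_align(left, rot, cfg0)
  expect_lt(abs(p$z_rotation - (-0.5 * d2r)), 0.05 * d2r)
  # right scaled by 1.02
  Hs <- diag(c(1 / 1.02, 1 / 1.02, 1))
  p <- phase1_rough_align(left, warp_image(left, Hs), cfg0)
  expect_lt(abs(p$scale - 1 / 1.02), 0.002)
  # featureless image: failure signal
  flat <- gray_image(matrix(128, 360, 480))
  expect_error(phase1_rough_align(flat, flat, cfg0),
               class = "dronestereo_calibration_error")
})

test_that("scanline matching yields identity line pairs on an aligned pair", {
  pr <- flat_pair()
  lp <- match_scanlines(pr$left, pr$right, std_spec(), std_cfg())
  expect_gte(length(lp), 9)
  for (p in lp) {
    expect_lt(abs(p$right_slope), 0.002)
    expect_lt(abs(p$right_intercept - p$left_row), 0.2)
    expect_gte(nrow(p$support), 2)
    expect_gte(p$rms, 0)
  }
})

test_that("scanline matching sees an in-plane rotation in every slope", {
  pr <- render_stereo_pair(flat_scene(5L), std_altitude, std_baseline,
                           perturbations = list(gamma = 0.5 * d2r),
                           intrinsics = std_intr(), image_size = std_size)
  lp <- match_scanlines(pr$left, pr$right, std_spec(), std_cfg())
  slopes <- vapply(lp, function(p) p$right_slope, numeric(1))
  expect_equal(mean(abs(slopes)), tan(0.5 * d2r), tolerance = 0.1)
  expect_true(all(abs(abs(slopes) - tan(0.5 * d2r)) < 0.1 * tan(0.5 * d2r)))
})

test_that("line fitting resists a contaminated minority of matches", {
  set.seed(9)
  x <- seq(-150, 150, 5)
  y <- 0.004 * x + 20 + rnorm(length(x), 0, 0.1)
  clean <- dronestereo:::robust_line_fit(x, y)
  yout <- y
  bad <- sample(length(x), round(0.1 * length(x)))
  yout[bad] <- runif(length(bad), -40, 80)
  cont <- dronestereo:::robust_line_fit(x, yout)
  expect_lt(abs(cont$b - clean$b), 0.5)
  expect_lt(abs(cont$a - clean$a) * 150, 0.5)
})

test_that("calibrating an unperturbed pair returns the identity", {
  pr <- flat_pair()
  cal <- calibrate_pair(pr$left, pr$right, std_intr(), baseline = std_baseline,
                        spec = std_spec(), cfg = std_cfg())
  expect_true(cal$converged)
  expect_lt(abs(cal$beta), 0.05 * d2r)
  expect_lt(abs(cal$gamma), 0.05 * d2r)
  expect_lt(abs(cal$alpha), 0.05 * d2r)
  expect_lt(abs(cal$delta_y), 0.5)
  expect_equal(cal$delta_z_scale, 1, tolerance = 2e-3)
  # SSE is non-increasing across outer iterations
  expect_true(all(diff(cal$sse_trace) <= 1e-9))
})

test_that("calibration recovers commanded perturbations on a rendered pair", {
  pert <- list(beta = 1.0 * d2r, gamma = 0.5 * d2r, alpha = 0.8 * d2r,
               delta_y = 6, tilt = c(0.4, 0.7) * d2r)
  pr <- render_stereo_pair(flat_scene(4L), std_altitude, std_baseline,
                           perturbations = pert, intrinsics = std_intr(),
                           image_size = std_size)
  cal <- calibrate_pair(pr$left, pr$right, std_intr(), baseline = std_baseline,
                        spec = std_spec(), cfg = std_cfg())
  expect_true(cal$converged)
  expect_lt(abs(cal$beta - pert$beta), 0.1 * d2r)
  expect_lt(abs(cal$gamma - pert$gamma), 0.1 * d2r)
  expect_lt(abs(cal$alpha - pert$alpha), 0.1 * d2r)
  expect_lt(abs(cal$delta_y - pert$delta_y), 1)
  expect_lt(abs(cal$left_tilt_alphab - pert$tilt[1]), 0.1 * d2r)
  expect_lt(abs(cal$left_tilt_betab - pert$tilt[2]), 0.1 * d2r)
  expect_true(all(diff(cal$sse_trace) <= 1e-9))
})

test_that("gnss fixes can stand in for an explicit baseline", {
  pr <- flat_pair()
  cal <- calibrate_pair(pr$left, pr$right, std_intr(), gnss = pr$gnss,
                        spec = std_spec(), cfg = std_cfg())
  expect_equal(cal$baseline, std_baseline, tolerance = 0.02)
  expect_true(cal$converged)
})

test_that("a strongly non-planar scene is flagged as uncalibratable", {
  scene <- make_field_scene(extent = c(12, 9), texture_seed = 6,
                            terrain_amplitude = 0.5, terrain_scale = 1.5)
  pr <- render_stereo_pair(scene, std_altitude, std_baseline,
                           intrinsics = std_intr(), image_size = std_size)
  cal <- calibrate_pair(pr$left, pr$right, std_intr(), baseline = std_baseline,
                        spec = std_spec(), cfg = std_cfg())
  expect_false(cal$converged)
  expect_identical(cal$failure_reason, "non_planar_scene")
  expect_gt(cal$ground_spread, 0.02)
})

test_that("calibration is idempotent on an already-calibrated pair", {
  # run at half scale (960 x 720): a 0.02-degree angular bound corresponds
  # to a fraction of a pixel only once the row spread is large enough to
  # resolve it
  intr <- camera_intrinsics(1100)
  cfg <- match_config(window_radius = 5,
                      search_center = round(1100 * std_baseline / std_altitude),
                      search_span = 48)
  spec <- scanline_spec(n_rows = 15, stride = 8, band_halfwidth = 32)
  pert <- list(beta = 0.6 * d2r, alpha = -0.5 * d2r, delta_y = -4)
  pr <- render_stereo_pair(flat_scene(7L), std_altitude, std_baseline,
                           perturbations = pert, intrinsics = intr,
                           image_size = c(960, 720))
  cal1 <- calibrate_pair(pr$left, pr$right, intr, baseline = std_baseline,
                         spec = spec, cfg = cfg)
  expect_true(cal1$converged)
  cal2 <- calibrate_pair(cal1$rectified_left, cal1$rectified_right,
                         intr, baseline = std_baseline,
                         spec = spec, cfg = cfg)
  expect_lt(abs(cal2$beta), 0.02 * d2r)
  expect_lt(abs(cal2$gamma), 0.02 * d2r)
  expect_lt(abs(cal2$alpha), 0.02 * d2r)
  expect_equal(cal2$delta_z_scale, 1, tolerance = 1e-3)
})
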