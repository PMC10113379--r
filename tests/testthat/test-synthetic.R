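test_that("scene construction validates plants and is deterministic", {
  s1 <- make_field_scene(texture_seed = 21)
  s2 <- make_field_scene(texture_seed = 21)
  wide <- camera_intrinsics(100)  # wide field of view for thumbnail renders
  pr1 <- render_stereo_pair(s1, std_altitude, std_baseline,
                            intrinsics = wide, image_size = c(96, 72))
  pr2 <- render_stereo_pair(s2, std_altitude, std_baseline,
                            intrinsics = wide, image_size = c(96, 72))
  expect_identical(unclass(pr1$left), unclass(pr2$left))
  expect_identical(unclass(pr1$right), unclass(pr2$right))

  expect_error(make_field_scene(plants = list(plant_spec(c(20, 2)))),
               "outside")
  expect_error(
    make_field_scene(plants = list(plant_spec(c(6, 4.5)),
                                   plant_spec(c(6.2, 4.6)))),
    "overlapping")
})

test_that("the truth bundle lists the commanded plant heights", {
  scene <- make_field_scene(plants = list(
    plant_spec(c(4, 4.5), height = 0.240, albedo_seed = 11),
    plant_spec(c(8, 4.5), height = 0.595, albedo_seed = 12)))
  pr <- render_stereo_pair(scene, 18.7, 1.45, intrinsics = camera_intrinsics(400),
                           image_size = c(96, 72))
  expect_identical(pr$truth$plant_heights, c(0.240, 0.595))
})

test_that("a flat zero-perturbation render has the analytic disparity", {
  pr <- flat_pair()
  expect_equal(pr$truth$ground_disparity,
               std_focal * std_baseline / std_altitude)
  dm <- compute_disparity_map(pr$left, pr$right, std_cfg())
  dtrue <- pr$truth$ground_disparity
  agree <- mean(dm$disparity[dm$valid] %in% c(floor(dtrue), ceiling(dtrue)))
  expect_gte(agree, 0.99)
})

test_that("rendering guards altitude and overlap preconditions", {
  scene <- make_field_scene(plants = list(plant_spec(c(6, 4.5), height = 0.5)))
  expect_error(render_stereo_pair(scene, 0.4, 0.3, intrinsics = std_intr()),
               "altitude")
  expect_error(render_stereo_pair(flat_scene(), 4.1, 2.5,
                                  intrinsics = std_intr(),
                                  image_size = c(320, 240)),
               class = "dronestereo_overlap_error")
  expect_error(render_stereo_pair(flat_scene(), 4.1, 0.81,
                                  perturbations = list(beta = 5 * pi / 180),
                                  intrinsics = std_intr()),
               "2 degrees")
})

test_that("generated GNSS tracks reproduce commanded spacings", {
  start <- geo_position(1, 36.11878417, 140.0937983)
  tr <- make_gnss_track(start, heading = 112, spacing = 0.36, n = 7)
  m <- pairwise_baselines(tr)
  expect_equal(unname(m[cbind(1:6, 2:7)]), rep(0.36, 6), tolerance = 0.04)
  # without rounding the spacing is exact to a micrometre
  tre <- make_gnss_track(start, 112, 0.36, 7, rounding = NULL)
  me <- pairwise_baselines(tre)
  expect_equal(unname(me[cbind(1:6, 2:7)]), rep(0.36, 6), tolerance = 1e-6 / 0.36)
  # due north: longitude never changes
  trn <- make_gnss_track(start, 0, 0.5, 5, rounding = NULL)
  expect_true(all(trn$longitude == trn$longitude[1]))
  expect_error(make_gnss_track(start, 0, 0.5, 1), "at least 2")
})

test_that("rendered pairs carry GNSS fixes matching the commanded baseline", {
  pr <- render_stereo_pair(flat_scene(9L), std_altitude, 0.376,
                           intrinsics = camera_intrinsics(100),
                           image_size = c(96, 72))
  tr <- as_gnss_track(pr$gnss)
  expect_equal(baseline_length(tr[[1]], tr[[2]]), 0.376, tolerance = 0.02 / 0.376)
})
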