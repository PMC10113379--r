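test_that("zncc_score matches its definition and invariances", {
  set.seed(1)
  a <- matrix(runif(25, 0, 255), 5)
  expect_equal(zncc_score(a, a), 1)
  expect_equal(zncc_score(a, 2 * a + 10), 1)        # affine invariance
  expect_equal(zncc_score(a, -(a - mean(a)) + mean(a)), -1)
  # hand evaluation of the definition on fixed integer patches
  p <- matrix(c(1, 5, 3, 2, 8, 4, 7, 6, 9), 3)
  q <- matrix(c(2, 4, 1, 3, 9, 5, 6, 6, 8), 3)
  va <- p - mean(p); vb <- q - mean(q)
  hand <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  expect_equal(zncc_score(p, q), hand, tolerance = 1e-12)
  # zero variance is signalled, not scored
  expect_true(is.na(zncc_score(matrix(5, 3, 3), q)))
  expect_error(zncc_score(a, matrix(0, 3, 3)), "shape")
})

test_that("match_pixel finds pure translations and refuses flat texture", {
  set.seed(2)
  base <- matrix(runif(80 * 60, 0, 255), 60, 80)
  left <- gray_image(base)
  right <- gray_image(cbind(base[, 6:80], base[, 1:5]))  # content shifted left by 5
  cfg <- match_config(window_radius = 3, search_center = 5, search_span = 8)
  for (x in c(30, 45, 60)) {
    m <- match_pixel(left, right, x = x, y = 30, cfg = cfg)
    expect_identical(m$disparity, 5L)
    expect_equal(m$score, 1, tolerance = 1e-9)
  }
  flat <- gray_image(matrix(100, 60, 80))
  expect_null(match_pixel(flat, flat, 40, 30, cfg))
})

test_that("dense matching recovers a constant shift and is deterministic", {
  set.seed(3)
  base <- matrix(runif(90 * 70, 0, 255), 70, 90)
  left <- gray_image(base)
  right <- gray_image(cbind(base[, 8:90], base[, 1:7]))
  cfg <- match_config(window_radius = 3, search_center = 7, search_span = 8)
  dm1 <- compute_disparity_map(left, right, cfg)
  expect_true(all(dm1$disparity[dm1$valid] == 7L))
  expect_gt(mean(dm1$valid), 0.5)
  dm2 <- compute_disparity_map(left, right, cfg)
  expect_identical(dm1$disparity, dm2$disparity)
  expect_identical(dm1$valid, dm2$valid)
})

test_that("valid disparities are unchanged by affine lighting of one image", {
  set.seed(4)
  base <- matrix(runif(80 * 60, 0, 200), 60, 80)
  left <- gray_image(base)
  right <- gray_image(cbind(base[, 6:80], base[, 1:5]))
  bright <- gray_image(unclass(right) * 1.3 + 12)
  cfg <- match_config(window_radius = 3, search_center = 5, search_span = 6)
  dm <- compute_disparity_map(left, right, cfg)
  dmb <- compute_disparity_map(left, bright, cfg)
  expect_identical(dm$disparity[dm$valid], dmb$disparity[dm$valid])
})

test_that("the compiled matcher equals the brute-force oracle pixel-for-pixel", {
  pr <- flat_pair()
  l <- unclass(pr$left)[101:160, 151:214]    # 60 x 64 crop
  r <- unclass(pr$right)[101:160, 48:111]    # same rows, offset so the true
  # crop-frame disparity (~5.5 levels) falls mid-range of a small search
  cfg <- match_config(window_radius = 3, zncc_accept_threshold = 0.5,
                      search_center = 6, search_span = 12)
  dm <- compute_disparity_map(gray_image(l), gray_image(r), cfg)
  oracle <- naive_disparity(l, r, radius = 3, thresh = 0.5, dmin = 0, dmax = 12)
  expect_identical(dm$disparity, oracle$disparity)
  expect_identical(dm$valid, oracle$valid)
  expect_true(all(dm$score[dm$valid] >= -1 & dm$score[dm$valid] <= 1))
})

test_that("matching a rendered flat plane reproduces the analytic disparity", {
  pr <- flat_pair()
  dm <- compute_disparity_map(pr$left, pr$right, std_cfg())
  dtrue <- pr$truth$ground_disparity
  ok <- dm$disparity[dm$valid] %in% c(floor(dtrue), ceiling(dtrue))
  expect_gte(mean(ok), 0.99)
  # each valid row of a planar scene varies by at most one level
  rows <- which(rowSums(dm$valid) > 50)
  spread <- vapply(rows, function(y) {
    d <- dm$disparity[y, dm$valid[y, ]]
    diff(range(d))
  }, numeric(1))
  expect_true(all(spread <= 1))
})

test_that("an occluding box produces an invalid band at its shadowed edge", {
  pr <- fixture("plantpair3", function() plant_pair(3L))
  dm <- compute_disparity_map(pr$left, pr$right, std_cfg())
  rect <- plant_rect_from_truth(pr, margin = 0L)
  # ground is occluded in the right image just left of the box's left edge
  band_cols <- (rect[1] - 12):(rect[1] - 2)
  band_rows <- rect[2]:rect[4]
  frac_invalid <- mean(!dm$valid[band_rows, band_cols])
  ref_cols <- (rect[1] - 60):(rect[1] - 40)
  frac_ref <- mean(!dm$valid[band_rows, ref_cols])
  expect_gt(frac_invalid, frac_ref + 0.2)
})

test_that("insufficient overlap is refused with a re-shoot signal", {
  img <- gray_image(matrix(runif(100 * 80), 80, 100))
  cfg <- match_config(search_center = 80, search_span = 16)
  expect_error(compute_disparity_map(img, img, cfg),
               class = "dronestereo_overlap_error")
})

test_that("disparity maps round-trip through the 16-bit image format", {
  set.seed(5)
  base <- matrix(runif(70 * 60, 0, 255), 60, 70)
  left <- gray_image(base)
  right <- gray_image(cbind(base[, 5:70], base[, 1:4]))
  cfg <- match_config(window_radius = 3, search_center = 4, search_span = 6)
  dm <- compute_disparity_map(left, right, cfg, baseline = 0.81, focal = 550)
  tmp <- withr::local_tempfile(fileext = ".png")
  write_disparity_map(dm, tmp)
  back <- read_disparity_map(tmp)
  expect_identical(back$disparity[back$valid], dm$disparity[back$valid])
  # invalid pixels render black (0)
  expect_true(all(back$disparity[!dm$valid] == 0))
  expect_equal(back$baseline, 0.81)
  expect_equal(back$search_max, dm$search_max)
})
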