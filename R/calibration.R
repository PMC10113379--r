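#' Scanline specification for line-pair calibration
#'
#' Calibration matches points on a set of left-image scanlines `y = C_i`
#' against the right image within a band `y = C_i +/- S_R`, then fits one
#' least-squares line per scanline. At least three scanlines are needed to
#' separate the x-rotation from the y-shift and scale.
#'
#' @param rows left-image row coordinates `C_i` (1-based, strictly
#'   increasing), or `NULL` to place `n_rows` evenly over the usable image
#'   height.
#' @param band_halfwidth vertical search half-band `S_R` in pixels.
#' @param n_rows number of scanlines when `rows` is `NULL`.
#' @param stride horizontal spacing of candidate points along a scanline,
#'   pixels.
#' @return an object of class `scanline_spec`.
#' @export
scanline_spec <- function(rows = NULL, band_halfwidth = 20L, n_rows = 9L,
                          stride = 8L) {
  if (!is.null(rows)) {
    rows <- as.integer(rows)
    if (length(rows) < 3L || any(diff(rows) <= 0)) {
      stop("'rows' must be >= 3 strictly increasing row coordinates",
           call. = FALSE)
    }
  }
  if (band_halfwidth < 1) stop("'band_halfwidth' must be >= 1", call. = FALSE)
  if (is.null(rows) && n_rows < 3L) stop("'n_rows' must be >= 3", call. = FALSE)
  structure(list(rows = rows, band_halfwidth = as.integer(band_halfwidth),
                 n_rows = as.integer(n_rows), stride = as.integer(stride)),
            class = "scanline_spec")
}

# ---- homography helpers (homogeneous centred pixel coordinates) -----------

# Homography equivalent to re-projecting rays through a camera rotation R:
# a point maps as f * (R (u, v, f)') / z-component.
hom_from_rotation <- function(R, f) {
  D <- diag(c(1, 1, f))
  solve(D) %*% R %*% D
}

# v' = s (v - dy), u' = s u
hom_scale_shift <- function(s, dy) {
  matrix(c(s, 0, 0, 0, s, -s * dy, 0, 0, 1), 3, 3, byrow = TRUE)
}

apply_hom <- function(H, x, y) {
  z <- H[3, 1] * x + H[3, 2] * y + H[3, 3]
  list(x = (H[1, 1] * x + H[1, 2] * y + H[1, 3]) / z,
       y = (H[2, 1] * x + H[2, 2] * y + H[2, 3]) / z)
}

#' Warp an image by a homography
#'
#' Inverse-map bilinear warp in centred pixel coordinates. `H` maps output
#' coordinates to input coordinates; pixels sampling outside the input are
#' set to `NA` (and treated as unmatched by the stereo matcher).
#'
#' @param img a [gray_image] or numeric matrix.
#' @param H 3x3 homography (centred homogeneous pixel coordinates).
#' @return a [gray_image] of the same size.
#' @export
warp_image <- function(img, H) {
  m <- as_intensity_matrix(img)
  cx <- (ncol(m) - 1) / 2
  cy <- (nrow(m) - 1) / 2
  gray_image(warp_bilinear_cpp(m, H, cx, cy))
}

# centred coordinate offsets of a matrix image (1-based pixel k -> k - (n+1)/2)
center_off <- function(n) (n + 1) / 2

# ---- corner detection for the rough phase ---------------------------------

# Harris corner response with box-filtered gradient products (integral
# images); returns up to n corners spread over a coarse tile grid.
harris_corners <- function(img, n = 60L, window = 7L, kappa = 0.05) {
  m <- as_intensity_matrix(img)
  h <- nrow(m); w <- ncol(m)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (m[, 3:w] - m[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (m[3:h, ] - m[1:(h - 2), ]) / 2
  bf <- function(a) box_filter(a, window)
  sxx <- bf(gx * gx); syy <- bf(gy * gy); sxy <- bf(gx * gy)
  resp <- sxx * syy - sxy^2 - kappa * (sxx + syy)^2
  margin <- window + 2L
  resp[seq_len(margin), ] <- -Inf
  resp[(h - margin):h, ] <- -Inf
  resp[, seq_len(margin)] <- -Inf
  resp[, (w - margin):w] <- -Inf
  # one best corner per tile of an 8x8 grid, then the n strongest overall
  tiles <- 8L
  ty <- pmin(tiles, 1L + ((seq_len(h) - 1L) * tiles) %/% h)
  tx <- pmin(tiles, 1L + ((seq_len(w) - 1L) * tiles) %/% w)
  tile_id <- outer(ty, tx, function(a, b) (a - 1L) * tiles + b)
  ord <- order(resp, decreasing = TRUE)
  seen <- logical(tiles * tiles)
  keep <- integer(0)
  for (k in ord) {
    if (!is.finite(resp[k])) break
    id <- tile_id[k]
    if (!seen[id]) {
      seen[id] <- TRUE
      keep <- c(keep, k)
      if (length(keep) >= n) break
    }
  }
  data.frame(x = ((keep - 1L) %/% h) + 1L, y = ((keep - 1L) %% h) + 1L,
             response = resp[keep])
}

box_filter <- function(a, window) {
  r <- window %/% 2L
  h <- nrow(a); w <- ncol(a)
  cs <- rbind(0, apply(a, 2, cumsum))
  ys0 <- pmax(0L, seq_len(h) - r - 1L)
  ys1 <- pmin(h, seq_len(h) + r)
  a2 <- cs[ys1 + 1L, , drop = FALSE] - cs[ys0 + 1L, , drop = FALSE]
  cs2 <- cbind(0, t(apply(a2, 1, cumsum)))
  xs0 <- pmax(0L, seq_len(w) - r - 1L)
  xs1 <- pmin(w, seq_len(w) + r)
  cs2[, xs1 + 1L, drop = FALSE] - cs2[, xs0 + 1L, drop = FALSE]
}

#' Phase 1: rough in-plane rotation and scale
#'
#' Detects corners on the ground in the left image, matches them in the
#' right image by ZNCC (with the horizontal search bounded by the disparity
#' predicted from the GNSS baseline), fits a similarity transform, and
#' returns the rotation/scale that aligns the right image so horizontal
#' structures run parallel to the flight direction.
#'
#' @param left,right [gray_image]s.
#' @param cfg a [match_config]; its search range bounds the horizontal
#'   correspondence search.
#' @param n_corners number of corner candidates.
#' @param band vertical search half-range in pixels.
#' @param iterations similarity re-fits; the second pass re-matches corners
#'   on the corrected image, which removes most of the attenuation the
#'   window matcher shows under rotated content.
#' @return `list(z_rotation, scale, H, n_matches)` where `z_rotation`
#'   (radians) and `scale` are the corrections to apply to the right image
#'   and `H` is the output-to-input homography for [warp_image()].
#' @export
phase1_rough_align <- function(left, right, cfg = match_config(),
                               n_corners = 60L, band = 24L, iterations = 2L) {
  l <- as_intensity_matrix(left)
  cor_l <- harris_corners(l, n_corners)
  rng <- search_range(cfg)
  cx <- center_off(ncol(l)); cy <- center_off(nrow(l))
  H <- diag(3)
  n_ok <- 0L
  for (it in seq_len(iterations)) {
    r <- if (it == 1L) as_intensity_matrix(right) else
      unclass_matrix(warp_image(right, H))
    mm <- match_points2d_cpp(l, r, as.integer(cor_l$x) - 1L,
                             as.integer(cor_l$y) - 1L, cfg$window_radius,
                             -rng[2], -rng[1], -as.integer(band),
                             as.integer(band), cfg$zncc_accept_threshold)
    ok <- mm[, 4] > 0
    if (sum(ok) < 4L) {
      if (it > 1L) break
      stop_calibration("phase-1 alignment failed: fewer than 4 corner ",
                       "matches (insufficient ground texture or wrong ",
                       "search range)")
    }
    n_ok <- sum(ok)
    xl <- cor_l$x[ok] - cx; yl <- cor_l$y[ok] - cy
    xr <- mm[ok, 1] + 1 - cx; yr <- mm[ok, 2] + 1 - cy
    # similarity: (xr, yr) = s R(theta) (xl, yl) + t, solved linearly
    fit <- fit_similarity(xl, yl, xr, yr)
    # one robust re-fit: drop residuals > 2.5 MAD
    pred <- similarity_apply(fit, xl, yl)
    res <- sqrt((pred$x - xr)^2 + (pred$y - yr)^2)
    good <- res <= 2.5 * max(mad(res), 0.5)
    if (sum(good) >= 4L) {
      fit <- fit_similarity(xl[good], yl[good], xr[good], yr[good])
    }
    Hinc <- matrix(c(fit$A, -fit$B, 0, fit$B, fit$A, 0, 0, 0, 1), 3, 3,
                   byrow = TRUE)
    H <- H %*% Hinc
  }
  sR <- H[1:2, 1:2]
  theta <- atan2(sR[2, 1], sR[1, 1])
  s_content <- sqrt(abs(det(sR)))
  list(z_rotation = -theta, scale = 1 / s_content, H = H,
       n_matches = n_ok)
}

fit_similarity <- function(xl, yl, xr, yr) {
  X <- cbind(xl, -yl, 1, 0)
  Y <- cbind(yl, xl, 0, 1)
  A <- rbind(X, Y)
  b <- c(xr, yr)
  cf <- unname(qr.solve(A, b))
  list(A = cf[1], B = cf[2], tx = cf[3], ty = cf[4])
}

similarity_apply <- function(fit, x, y) {
  list(x = fit$A * x - fit$B * y + fit$tx,
       y = fit$B * x + fit$A * y + fit$ty)
}

#' Match scanlines into line pairs
#'
#' For ground points on each left-image scanline `y = C_i`, searches the
#' matching point in the right image by ZNCC within the band
#' `y = C_i +/- S_R` (and the configured horizontal disparity range), then
#' fits the least-squares line `y = a_i x + b_i` through the accepted
#' matches. This is the first error-elimination stage: points are screened
#' by their ZNCC score and then by their residual against the fitted line
#' (two reweighting passes dropping residuals above 2.5 MAD).
#'
#' @param left,right [gray_image]s (right already phase-1 aligned).
#' @param spec a [scanline_spec].
#' @param cfg a [match_config].
#' @return a list of `line_pair` objects (`left_row`, `right_slope`,
#'   `right_intercept`, `support`, `rms`; coordinates centred on the
#'   principal point). Rows with fewer than 2 accepted points are dropped;
#'   fewer than 3 surviving rows is an error.
#' @export
match_scanlines <- function(left, right, spec = scanline_spec(),
                            cfg = match_config()) {
  l <- as_intensity_matrix(left); r <- as_intensity_matrix(right)
  h <- nrow(l); w <- ncol(l)
  rng <- search_range(cfg)
  rad <- cfg$window_radius
  rows <- spec$rows
  if (is.null(rows)) {
    margin <- rad + spec$band_halfwidth + 2L
    if (h - 2L * margin < spec$n_rows) {
      stop("image too small for the requested scanlines", call. = FALSE)
    }
    rows <- as.integer(round(seq(margin, h - margin, length.out = spec$n_rows)))
  }
  x0 <- rad + rng[2] + 1L
  x1 <- w - rad - 1L
  if (x1 - x0 < 4L * spec$stride) {
    stop_overlap("insufficient overlap for scanline matching")
  }
  xs <- seq.int(x0, x1, by = spec$stride)
  cx <- center_off(w); cy <- center_off(h)
  pairs <- list()
  for (C in rows) {
    mm <- match_points2d_cpp(l, r, as.integer(xs) - 1L,
                             rep(as.integer(C) - 1L, length(xs)), rad,
                             -rng[2], -rng[1], -spec$band_halfwidth,
                             spec$band_halfwidth, cfg$zncc_accept_threshold)
    ok <- mm[, 4] > 0
    if (sum(ok) < 2L) next
    sup <- data.frame(x_left = xs[ok] - cx, y_left = C - cy,
                      x_right = mm[ok, 1] + 1 - cx,
                      y_right = mm[ok, 2] + 1 - cy,
                      score = mm[ok, 3])
    lpf <- robust_line_fit(sup$x_right, sup$y_right)
    if (is.null(lpf) || sum(lpf$keep) < 2L) next
    sup <- sup[lpf$keep, , drop = FALSE]
    pairs[[length(pairs) + 1L]] <- structure(
      list(left_row = C - cy, right_slope = lpf$a, right_intercept = lpf$b,
           support = sup, rms = lpf$rms),
      class = "line_pair")
  }
  if (length(pairs) < 3L) {
    stop_calibration("calibration failure: fewer than 3 scanlines with ",
                     "enough accepted matches")
  }
  pairs
}

# Least-squares line with two outlier-rejection passes (residual > 2.5 MAD).
robust_line_fit <- function(x, y) {
  keep <- rep(TRUE, length(x))
  a <- b <- NA_real_
  for (pass in 1:3) {
    if (sum(keep) < 2L || length(unique(x[keep])) < 2L) return(NULL)
    fit <- lm.fit(cbind(1, x[keep]), y[keep])
    b <- fit$coefficients[1]; a <- fit$coefficients[2]
    if (pass == 3) break
    res <- y - (a * x + b)
    sc <- max(mad(res[keep]), 0.25)
    keep2 <- abs(res) <= 2.5 * sc
    if (all(keep2 == keep)) break
    keep <- keep2
  }
  res <- y[keep] - (a * x[keep] + b)
  list(a = unname(a), b = unname(b), keep = keep,
       rms = sqrt(mean(res^2)))
}

# ---- closed-form parameter estimators -------------------------------------

#' Estimate the y-axis rotation from line-pair slopes
#'
#' A rotation about the y axis makes the slope of each matched line grow
#' linearly with its intercept; equating the gradients of all lines gives
#' \eqn{\beta = \tan^{-1}(f (a_i - a_j) / (b_i - b_j))}. With more than two
#' lines all index pairs are combined by a least-squares regression of
#' slopes on intercepts (identical to the pairwise formula for two lines).
#'
#' @param pairs list of `line_pair` objects, or a 2-column matrix/data frame
#'   of `(slope, intercept)`.
#' @param focal focal length in pixels.
#' @return estimated rotation in radians.
#' @export
solve_beta <- function(pairs, focal) {
  ab <- line_coefs(pairs)
  if (nrow(ab) < 2L) stop("need at least 2 line pairs", call. = FALSE)
  if (diff(range(ab$b)) < 1e-9) {
    stop("degenerate geometry: all intercepts equal", call. = FALSE)
  }
  sl <- lm.fit(cbind(1, ab$b), ab$a)$coefficients[2]
  atan(focal * unname(sl))
}

#' Estimate the z-axis rotation from line-pair slopes
#'
#' After the y-rotation is removed all lines share a common slope; the
#' in-plane rotation making them parallel to the x axis is
#' \eqn{\gamma = \tan^{-1}(\bar a)}.
#'
#' @inheritParams solve_beta
#' @return estimated rotation in radians.
#' @export
solve_gamma <- function(pairs) {
  ab <- line_coefs(pairs)
  if (nrow(ab) < 1L) stop("need at least 1 line pair", call. = FALSE)
  atan(mean(ab$a))
}

#' Estimate the x-axis rotation from line intercepts
#'
#' A rotation about the x axis makes the spacing of the matched lines
#' unequal; for three intercepts (ordered by scanline)
#' \deqn{\alpha = \tan^{-1}\!\left(-\frac{f (b_i + b_k - 2 b_j)}
#'   {b_i b_j + b_j b_k + b_k b_i}\right)}
#' With more than three lines, all ordered triples are combined by least
#' squares on the linearised form (numerator vs. denominator).
#'
#' @param intercepts numeric vector of >= 3 line intercepts `b_i`, centred
#'   pixel coordinates, ordered by their scanline rows.
#' @param focal focal length in pixels.
#' @return estimated rotation in radians.
#' @note The spacing formula assumes the middle line of the triple passes
#'   near the principal point; with more than three lines only triples
#'   symmetric about the middle of the ordered set are combined, as
#'   off-centre triples do not satisfy that assumption. On exact symmetric
#'   triples the formula measures twice the x-rotation of an exact pinhole
#'   camera; the calibration loop accounts for this.
#' @export
solve_alpha <- function(intercepts, focal) {
  b <- as.numeric(intercepts)
  n <- length(b)
  if (n < 3L) stop("need at least 3 intercepts", call. = FALSE)
  if (n == 3L) {
    tri <- matrix(1:3, 3, 1)
  } else {
    # centre-symmetric triples (i, j, n + 1 - i) of the ordered set
    j <- (n + 1L) %/% 2L
    i <- seq_len(j - 1L)
    k <- n + 1L - i
    ok <- k > j
    tri <- rbind(i[ok], j, k[ok])
  }
  num <- -focal * (b[tri[1, ]] + b[tri[3, ]] - 2 * b[tri[2, ]])
  den <- b[tri[1, ]] * b[tri[2, ]] + b[tri[2, ]] * b[tri[3, ]] +
    b[tri[3, ]] * b[tri[1, ]]
  if (all(abs(den) < 1e-9)) {
    stop("degenerate geometry: zero denominator for all triples", call. = FALSE)
  }
  atan(sum(num * den) / sum(den * den))
}

# Internal x-rotation estimator used by the calibration loop: the full
# second-difference model with known scanline rows. An x-rotation bends the
# intercepts quadratically in the row coordinate, b = C + f t + t C^2 / f
# (t = tan alpha) to first order, so the quadratic regression coefficient of
# b on C gives t directly, with unit gain and for arbitrary row placement.
# Equivalent to least squares over all row triples of the linearised
# spacing relation.
alpha_from_rows <- function(b, C, focal) {
  if (length(unique(C)) < 3L) return(0)
  cf <- lm.fit(cbind(1, C, C^2), b)$coefficients
  q2 <- unname(cf[3])
  if (!is.finite(q2)) return(0)
  atan(focal * q2)
}

#' Estimate the y-shift and scale aligning intercepts with scanline rows
#'
#' The vertical shift equalises the weight balance (the means) of the
#' intercepts and the scanline rows; the subsequent scale about the image
#' centre maps each shifted intercept onto its row in least squares.
#'
#' @param intercepts numeric vector of line intercepts `b_i` (centred).
#' @param rows numeric vector of scanline rows `C_i` (centred), same length.
#' @return `list(delta_y, delta_z_scale)` such that
#'   `delta_z_scale * (b - delta_y)` best matches `rows`.
#' @export
solve_translation <- function(intercepts, rows) {
  b <- as.numeric(intercepts); C <- as.numeric(rows)
  stopifnot(length(b) == length(C), length(b) >= 2L)
  if (diff(range(C)) < 1e-9) {
    stop("scale indeterminate: zero spread of scanline rows", call. = FALSE)
  }
  dy <- mean(b) - mean(C)
  bs <- b - dy
  s <- sum(C * bs) / sum(bs * bs)
  list(delta_y = dy, delta_z_scale = s)
}

line_coefs <- function(pairs) {
  if (is.data.frame(pairs) || is.matrix(pairs)) {
    df <- as.data.frame(pairs)
    names(df)[1:2] <- c("a", "b")
    return(df[, 1:2])
  }
  data.frame(
    a = vapply(pairs, function(p) p$right_slope, numeric(1)),
    b = vapply(pairs, function(p) p$right_intercept, numeric(1))
  )
}

#' Least-squares ground plane
#'
#' Fits `z = a x + b y + c` to matched points with depths, minimising the
#' squared vertical (depth) error.
#'
#' @param points data frame with columns `x`, `y`, `z` (camera-frame
#'   metres), at least 3 non-collinear points.
#' @return an object of class `ground_plane`: coefficients `a`, `b`, `c`
#'   and `fit_rms` (metres).
#' @export
fit_ground_plane <- function(points) {
  stopifnot(is.data.frame(points), all(c("x", "y", "z") %in% names(points)))
  if (nrow(points) < 3L) stop("need at least 3 points", call. = FALSE)
  X <- cbind(1, points$x, points$y)
  if (qr(X)$rank < 3L) {
    stop("degenerate support: points are collinear", call. = FALSE)
  }
  fit <- lm.fit(X, points$z)
  res <- fit$residuals
  structure(list(a = unname(fit$coefficients[2]),
                 b = unname(fit$coefficients[3]),
                 c = unname(fit$coefficients[1]),
                 fit_rms = sqrt(mean(res^2))),
            class = "ground_plane")
}

#' @export
print.ground_plane <- function(x, ...) {
  cat(sprintf("<ground_plane z = %.5f x + %.5f y + %.3f, rms %.4f m>\n",
              x$a, x$b, x$c, x$fit_rms))
  invisible(x)
}

# ---- full two-phase calibration -------------------------------------------

#' Calibrate a wide-baseline image pair
#'
#' Runs the full two-phase in-flight calibration: phase 1 applies a rough
#' in-plane rotation and scale from corner matches; phase 2 alternates
#' closed-form estimates of the three right-camera rotations (y, z, x), the
#' vertical shift and the altitude scale with an overfit correction, until
#' the sum of squared scanline errors stops decreasing. Matched points are
#' screened twice: per-line residual rejection when the lines are fitted,
#' and a consensus rejection against the converged transform followed by a
#' refinement pass. On convergence the left-camera tilt is read off the
#' least-squares ground plane and a rectified right image is produced,
#' ready for dense matching.
#'
#' @param left,right [gray_image]s (left is the reference).
#' @param intrinsics a [camera_intrinsics].
#' @param gnss optional data frame or list of two [geo_position] fixes; used
#'   to compute the baseline when `baseline` is not given.
#' @param spec a [scanline_spec].
#' @param cfg a [match_config]; centre its search range on the predicted
#'   ground disparity.
#' @param baseline baseline in metres; `NA` is allowed (the plane is then
#'   fitted in units of the unknown baseline, which leaves the recovered
#'   angles unchanged).
#' @param max_iter maximum outer iterations.
#' @param sse_tol stop when the SSE improves by less than this (pixels^2).
#' @param plane_rms_max planarity gate in metres: if the robust spread (MAD)
#'   of all matched points about the fitted ground plane exceeds this, the
#'   scene is flagged as too non-planar to calibrate.
#' @return an object of class `calibration_result` with the recovered
#'   angles (radians), `overfit_*` residual corrections of the last
#'   iteration, `delta_y` (pixels), `delta_z_scale`, left tilt
#'   (`left_tilt_betab`, `left_tilt_alphab`), the ground plane, iteration
#'   count, `sse_trace`, `converged` flag with `failure_reason`, the
#'   rectified pair and the right-image correction homography.
#' @export
calibrate_pair <- function(left, right, intrinsics, gnss = NULL,
                           spec = scanline_spec(), cfg = match_config(),
                           baseline = NULL, max_iter = 20L, sse_tol = 0.001,
                           plane_rms_max = 0.02) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  f <- intrinsics$focal_length
  l <- as_intensity_matrix(left)
  if (!is.null(gnss) && is.null(baseline)) {
    tr <- as_gnss_track(gnss)
    if (length(tr) != 2L) stop("'gnss' must hold exactly two fixes", call. = FALSE)
    baseline <- baseline_length(tr[[1]], tr[[2]])
  }
  if (is.null(baseline)) baseline <- NA_real_
  rng <- search_range(cfg)
  if (rng[1] > ncol(l) / 2) {
    stop_overlap("insufficient overlap (predicted disparity beyond half the ",
                 "image width); re-shoot with a shorter baseline")
  }

  p1 <- phase1_rough_align(left, right, cfg,
                           band = spec$band_halfwidth + 8L)
  # match on the original right image and apply the phase-1 correction to
  # the matched coordinates analytically: resampling the image before
  # matching would imprint interpolation bias on the estimates
  lp <- match_scanlines(left, right, spec, cfg)
  sup <- do.call(rbind, lapply(lp, function(p) p$support))
  p1c <- apply_hom(solve(p1$H), sup$x_right, sup$y_right)
  sup$x_right <- p1c$x
  sup$y_right <- p1c$y
  st <- run_phase2(sup, f, max_iter, sse_tol)
  # second elimination stage: reject points inconsistent with the consensus
  # transform, then refine
  cur <- correct_points(sup, st)
  res <- cur$y - sup$y_left
  keep <- abs(res - median(res)) <= 2.5 * max(mad(res), 0.25)
  dropped <- sum(!keep)
  if (dropped > 0L && sum(keep) >= 9L &&
      length(unique(sup$y_left[keep])) >= 3L) {
    sup <- sup[keep, , drop = FALSE]
    st <- run_phase2(sup, f, max_iter, sse_tol, init = st)
  }

  cur <- correct_points(sup, st)
  bl_for_plane <- if (is.na(baseline)) 1 else baseline
  disp <- sup$x_left - cur$x
  plane <- NULL
  plane_ok <- TRUE
  ground_spread <- NA_real_
  pts_ok <- disp > 0
  if (sum(pts_ok) >= 3L) {
    depth <- f * bl_for_plane / disp[pts_ok]
    p3 <- data.frame(x = sup$x_left[pts_ok] * depth / f,
                     y = sup$y_left[pts_ok] * depth / f,
                     z = depth)
    # matching points that fell on plants sit well above the ground plane;
    # two MAD-rejection passes confine the fit to the ground support
    p3_all <- p3
    plane <- tryCatch(fit_ground_plane(p3), error = function(e) NULL)
    for (pass in 1:2) {
      if (is.null(plane)) break
      resid <- p3$z - (plane$a * p3$x + plane$b * p3$y + plane$c)
      keep3 <- abs(resid - median(resid)) <= 2.5 * max(mad(resid), 0.002)
      if (all(keep3) || sum(keep3) < 3L) break
      p3 <- p3[keep3, , drop = FALSE]
      plane <- tryCatch(fit_ground_plane(p3), error = function(e) NULL)
    }
    if (!is.null(plane)) {
      # ground spread: robust deviation of ALL points about the plane.
      # Plants are a sparse one-sided minority and barely move the MAD;
      # terrain undulation spreads every residual and inflates it.
      resid_all <- p3_all$z -
        (plane$a * p3_all$x + plane$b * p3_all$y + plane$c)
      ground_spread <- mad(resid_all)
    }
  }
  tilt_bb <- tilt_ab <- NA_real_
  if (!is.null(plane)) {
    # left-camera tilt from the ground-plane gradient: a nadir camera sees
    # the flat ground as z = const; depth gradients are the tilt angles
    tilt_bb <- atan(plane$a)
    tilt_ab <- atan(-plane$b * cos(tilt_bb))
    if (!is.na(baseline)) {
      plane_ok <- is.finite(ground_spread) && ground_spread <= plane_rms_max
    }
  }

  angles_ok <- all(abs(c(st$beta, st$gamma + p1$z_rotation, st$alpha)) < 0.2)
  converged <- st$converged && plane_ok && angles_ok
  failure_reason <- if (!st$converged) "no_sse_convergence"
    else if (!plane_ok) "non_planar_scene"
    else if (!angles_ok) "implausible_angles"
    else NA_character_

  # rectified right image: full correction = scale/shift o rotation o phase1
  Hcorr <- hom_scale_shift(st$s, st$dy) %*% hom_from_rotation(st$Rc, f) %*%
    solve(p1$H)
  rect_right <- warp_image(right, solve(Hcorr))

  structure(
    list(beta = st$beta, gamma = st$gamma + p1$z_rotation, alpha = st$alpha,
         overfit_beta = st$last_inc[1], overfit_gamma = st$last_inc[2],
         overfit_alpha = st$last_inc[3],
         delta_y = st$dy, delta_z_scale = st$s * p1$scale,
         left_tilt_betab = tilt_bb, left_tilt_alphab = tilt_ab,
         plane = plane, ground_spread = ground_spread, baseline = baseline,
         iterations = st$iterations, final_sse = st$sse,
         sse_trace = st$trace, rows_used = length(unique(sup$y_left)),
         n_points = nrow(sup), points_dropped = dropped,
         converged = converged, failure_reason = failure_reason,
         phase1 = p1[c("z_rotation", "scale", "n_matches")],
         H_right = Hcorr,
         rectified_left = left, rectified_right = rect_right),
    class = "calibration_result"
  )
}

# Inner phase-2 loop on a support-point table (centred coordinates).
# Each outer iteration estimates incremental rotation corrections from the
# fitted lines (the "amount of overfitting" left by the previous pass),
# composes them into the running correction, and re-solves the vertical
# shift and scale over all matching points. A candidate step is accepted
# only if it does not increase the SSE; an increasing step is retried at
# half size, and if that still increases the iteration stops at the noise
# floor. The SSE trace is therefore non-increasing.
run_phase2 <- function(sup, f, max_iter, sse_tol, init = NULL) {
  st <- init %||% list(Rc = diag(3), s = 1, dy = 0,
                       beta = 0, gamma = 0, alpha = 0)
  st$f <- f
  st <- solve_shift_scale(sup, st)
  sse <- phase2_sse(sup, st)
  trace <- sse
  converged <- FALSE
  last_inc <- c(0, 0, 0)
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    stepped <- FALSE
    for (damp in c(1, 0.5)) {
      cand <- phase2_step(sup, st, damp)
      if (cand$sse <= sse + 1e-12) {
        improved <- sse - cand$sse
        last_inc <- cand$inc
        st <- cand$st
        sse <- cand$sse
        stepped <- TRUE
        break
      }
    }
    trace <- c(trace, sse)
    if (!stepped || improved < sse_tol) {
      converged <- TRUE
      break
    }
  }
  st$trace <- trace
  st$sse <- sse
  st$converged <- converged
  st$last_inc <- last_inc
  st$iterations <- iters
  st
}

# One phase-2 pass: rotation increments (y, z, x order) at damping `damp`,
# then the shift/scale refit. Returns the candidate state and its SSE.
phase2_step <- function(sup, st, damp = 1) {
  f <- st$f
  # (ii)(a) y-rotation from slope-vs-intercept gradients
  ln <- refit_lines(sup, st)
  b_inc <- damp * tryCatch(-solve_beta(ln, f), error = function(e) 0)
  st$Rc <- rot_y(b_inc) %*% st$Rc; st$beta <- st$beta + b_inc
  # (ii)(b) z-rotation making all lines parallel to the x axis
  ln <- refit_lines(sup, st)
  g_inc <- damp * tryCatch(-solve_gamma(ln), error = function(e) 0)
  st$Rc <- rot_z(g_inc) %*% st$Rc; st$gamma <- st$gamma + g_inc
  # (ii)(c) x-rotation equalising line spacing (second-difference model
  # with known rows)
  ln <- refit_lines(sup, st)
  a_inc <- damp * tryCatch(alpha_from_rows(ln$b, ln$C, f),
                           error = function(e) 0)
  st$Rc <- rot_x(a_inc) %*% st$Rc; st$alpha <- st$alpha + a_inc
  # (iii)/(iv) vertical shift and scale over all matching points
  st <- solve_shift_scale(sup, st)
  list(st = st, sse = phase2_sse(sup, st), inc = c(b_inc, g_inc, a_inc))
}

# Least-squares (delta_y, scale) so the rotated point ordinates map onto
# their scanline rows: C ~ s * (y_rot - dy), solved linearly over all
# matching points.
solve_shift_scale <- function(sup, st) {
  rot <- rotate_points(sup, st)
  cf <- lm.fit(cbind(1, rot$y), sup$y_left)$coefficients
  s <- unname(cf[2])
  if (!is.finite(s) || s <= 0) return(st)
  st$s <- s
  st$dy <- -unname(cf[1]) / s
  st
}

phase2_sse <- function(sup, st) {
  cur <- correct_points(sup, st)
  sum((cur$y - sup$y_left)^2)
}

rotate_points <- function(sup, st, f = st$f) {
  x <- sup$x_right; y <- sup$y_right
  z <- st$Rc[3, 1] * x + st$Rc[3, 2] * y + st$Rc[3, 3] * f
  list(x = f * (st$Rc[1, 1] * x + st$Rc[1, 2] * y + st$Rc[1, 3] * f) / z,
       y = f * (st$Rc[2, 1] * x + st$Rc[2, 2] * y + st$Rc[2, 3] * f) / z)
}

# full correction: rotation, then y-shift, then scale about the centre
correct_points <- function(sup, st) {
  rot <- rotate_points(sup, st)
  list(x = st$s * rot$x, y = st$s * (rot$y - st$dy))
}

# least-squares line per scanline on the currently corrected coordinates
refit_lines <- function(sup, st) {
  cur <- correct_points(sup, st)
  rows <- sort(unique(sup$y_left))
  out <- lapply(rows, function(C) {
    i <- sup$y_left == C
    if (sum(i) < 2L || diff(range(cur$x[i])) < 1e-9) return(NULL)
    cf <- lm.fit(cbind(1, cur$x[i]), cur$y[i])$coefficients
    data.frame(a = unname(cf[2]), b = unname(cf[1]), C = C)
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}
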