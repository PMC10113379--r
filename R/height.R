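#' Camera intrinsics
#'
#' @param focal_length focal length in pixels (> 0).
#' @param principal_point optional `c(cx, cy)` in pixels; defaults to the
#'   image centre of whatever image the intrinsics are used with.
#' @return an object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(focal_length, principal_point = NULL) {
  if (!is.numeric(focal_length) || length(focal_length) != 1L ||
      is.na(focal_length) || focal_length <= 0) {
    stop("'focal_length' must be a single positive number (pixels)", call. = FALSE)
  }
  if (!is.null(principal_point)) {
    stopifnot(is.numeric(principal_point), length(principal_point) == 2L)
  }
  structure(list(focal_length = focal_length, principal_point = principal_point),
            class = "camera_intrinsics")
}

#' Depth from disparity
#'
#' Distance from the camera to a point seen with disparity `d` in a
#' rectified pair with baseline `b` and focal length `f`:
#' \eqn{l = f b / d}.
#'
#' @param d disparity in pixels (> 0); vectorised.
#' @param f focal length in pixels.
#' @param b baseline in metres.
#' @return depth in metres, strictly decreasing in `d`.
#' @examples
#' depth_from_disparity(100, f = 1000, b = 1) # 10 m
#' @export
depth_from_disparity <- function(d, f, b) {
  check_pos(f, "f"); check_pos(b, "b")
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("disparity must be positive", call. = FALSE)
  }
  f * b / d
}

#' Plant height from canopy and ground disparities
#'
#' Height above ground of the canopy point with disparity `d_p`, relative to
#' ground at disparity `d_g`: \eqn{p_h = f b / d_g - f b / d_p}. The plant
#' is nearer the camera than the ground, so `d_p >= d_g` yields a
#' non-negative height.
#'
#' @param d_g disparity of the ground surrounding the plant, pixels (> 0).
#' @param d_p disparity of the highest point of the plant, pixels (> 0).
#' @param f focal length in pixels.
#' @param b baseline in metres.
#' @return plant height in metres.
#' @examples
#' plant_height(d_g = 1374, d_p = 1573, f = 6955, b = 0.81)
#' @export
plant_height <- function(d_g, d_p, f, b) {
  depth_from_disparity(d_g, f, b) - depth_from_disparity(d_p, f, b)
}

#' Depth resolution of one disparity level
#'
#' Change in measured distance when the disparity changes by one level at
#' depth `l_d` and disparity `d`: \eqn{\Delta d = l_d / (d + 1)}, identically
#' equal to \eqn{f b / d - f b / (d + 1)}.
#'
#' @param l_d depth in metres (> 0).
#' @param d disparity in pixels (> 0).
#' @return depth step in metres per disparity level.
#' @export
depth_step_resolution <- function(l_d, d) {
  if (any(!is.finite(l_d)) || any(l_d <= 0)) stop("'l_d' must be positive", call. = FALSE)
  if (any(!is.finite(d)) || any(d <= 0)) stop("'d' must be positive", call. = FALSE)
  l_d / (d + 1)
}

#' Height resolution per disparity level
#'
#' Given a plant of known height spanning `d_p - d_g` disparity levels
#' between its top and the surrounding ground, the height change represented
#' by one disparity level is `true_height / (d_p - d_g)`.
#'
#' @param true_height plant height in metres (> 0).
#' @param d_g,d_p ground and plant disparities in pixels, `d_p > d_g`.
#' @return metres of height per disparity level.
#' @examples
#' per_level_height_resolution(0.570, 1374, 1573) # ~2.9 mm
#' @export
per_level_height_resolution <- function(true_height, d_g, d_p) {
  if (!is.finite(true_height) || true_height <= 0) {
    stop("'true_height' must be positive", call. = FALSE)
  }
  if (any(d_p <= d_g)) stop("'d_p' must exceed 'd_g'", call. = FALSE)
  true_height / (d_p - d_g)
}

#' Relative error reduction of one method against another
#'
#' Percentage by which the proposed measurement error undercuts a reference
#' ("conventional") error: `100 * (err_conventional - err_proposed) /
#' err_conventional`.
#'
#' @param err_proposed error of the evaluated method (any length unit).
#' @param err_conventional error of the reference method, same unit (> 0).
#' @return reduction in percent (negative if the evaluated method is worse).
#' @examples
#' error_reduction(3.4, 9.0) # 62.2
#' @export
error_reduction <- function(err_proposed, err_conventional) {
  if (any(!is.finite(err_conventional)) || any(err_conventional <= 0)) {
    stop("'err_conventional' must be positive", call. = FALSE)
  }
  100 * (err_conventional - err_proposed) / err_conventional
}

#' Measure plant height in a disparity map
#'
#' Extracts the canopy disparity `d_p` as a robust maximum over a plant
#' region and the ground disparity `d_g` as a robust minimum over the
#' surrounding ground, then converts their difference to a height. The
#' default extrema are the 99.5th / 0.5th percentiles of the valid
#' disparities, guarding single-pixel outliers; `robust = FALSE` uses the
#' raw max/min.
#'
#' @param dm a [disparity_map].
#' @param region `list(plant = c(x0, y0, x1, y1), ground = c(x0, y0, x1, y1))`
#'   in image pixel coordinates (1-based, inclusive). `ground` may be omitted,
#'   in which case a frame of width `ground_margin` around the plant
#'   rectangle is used.
#' @param intrinsics a [camera_intrinsics].
#' @param b baseline in metres.
#' @param robust use percentile extrema (default) instead of raw max/min.
#' @param ground_gap pixels to skip between the plant rectangle and the
#'   automatic ground frame, so the frame avoids the occlusion fringe and
#'   the matching windows that straddle the canopy edge.
#' @param ground_margin width in pixels of the automatic ground frame.
#' @return an object of class `height_measurement`: plant and ground
#'   disparities, height in metres, per-level resolution (depth step at the
#'   ground disparity) and the fraction of valid pixels used.
#' @export
measure_plant <- function(dm, region, intrinsics, b, robust = TRUE,
                          ground_gap = 15L, ground_margin = 25L) {
  stopifnot(inherits(dm, "disparity_map"), inherits(intrinsics, "camera_intrinsics"))
  check_pos(b, "b")
  if (is.numeric(region) && length(region) == 4L) region <- list(plant = region)
  plant_rect <- as.integer(round(region$plant))
  pad <- ground_gap + ground_margin
  ground_rect <- if (!is.null(region$ground)) as.integer(round(region$ground)) else
    clip_rect(plant_rect + c(-pad, -pad, pad, pad), dim(dm$disparity))
  excl_rect <- if (!is.null(region$ground)) plant_rect else
    clip_rect(plant_rect + c(-ground_gap, -ground_gap, ground_gap, ground_gap),
              dim(dm$disparity))
  pd <- rect_disparities(dm, plant_rect)
  gd <- rect_disparities(dm, ground_rect, exclude = excl_rect)
  if (length(pd) == 0L || length(gd) == 0L) {
    stop_measurement("no valid disparities in plant and/or ground region; ",
                     "re-shoot or choose another region")
  }
  if (robust) {
    d_p <- as.numeric(quantile(pd, 0.995, names = FALSE, type = 7))
    d_g <- as.numeric(quantile(gd, 0.005, names = FALSE, type = 7))
  } else {
    d_p <- max(pd)
    d_g <- min(gd)
  }
  f <- intrinsics$focal_length
  h <- plant_height(d_g = d_g, d_p = d_p, f = f, b = b)
  res <- depth_step_resolution(depth_from_disparity(d_g, f, b), d_g)
  structure(
    list(plant_height = h, ground_disparity = d_g, plant_disparity = d_p,
         resolution_per_level = res, baseline = b,
         n_plant = length(pd), n_ground = length(gd),
         valid_fraction = mean(dm$valid[seq_rows(plant_rect), seq_cols(plant_rect)])),
    class = "height_measurement"
  )
}

#' @export
print.height_measurement <- function(x, ...) {
  cat(sprintf(paste0(
    "<height_measurement>\n",
    "  plant height     : %.1f mm\n",
    "  disparities      : ground %.1f px, plant %.1f px (span %.1f)\n",
    "  resolution/level : %.2f mm\n",
    "  baseline         : %.3f m\n"),
    1000 * x$plant_height, x$ground_disparity, x$plant_disparity,
    x$plant_disparity - x$ground_disparity,
    1000 * x$resolution_per_level, x$baseline))
  invisible(x)
}

# --- internal helpers -------------------------------------------------------

check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("'", name, "' must be a single positive number", call. = FALSE)
  }
}

clip_rect <- function(r, dm_dim) {
  # r = c(x0, y0, x1, y1); dm_dim = c(nrow, ncol)
  c(max(1L, r[1]), max(1L, r[2]), min(dm_dim[2], r[3]), min(dm_dim[1], r[4]))
}

seq_cols <- function(r) seq.int(r[1], r[3])
seq_rows <- function(r) seq.int(r[2], r[4])

rect_disparities <- function(dm, rect, exclude = NULL) {
  rows <- seq_rows(rect); cols <- seq_cols(rect)
  sub <- dm$disparity[rows, cols, drop = FALSE]
  ok <- dm$valid[rows, cols, drop = FALSE]
  if (!is.null(exclude)) {
    er <- outer(rows %in% seq_rows(exclude), cols %in% seq_cols(exclude), `&`)
    ok <- ok & !er
  }
  as.numeric(sub[ok])
}
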