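#' Specify a plant proxy
#'
#' Plants are rendered as textured boxes of known height standing on the
#' ground plane; the box top carries its own albedo texture so that ZNCC has
#' local variance on the canopy as well as on the soil.
#'
#' @param position `c(x, y)` of the box centre in metres (scene coordinates).
#' @param footprint `c(width, depth)` of the box in metres.
#' @param height box height in metres (>= 0).
#' @param albedo_seed integer seed of the canopy texture.
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(position, footprint = c(0.5, 0.5), height = 0.5,
                       albedo_seed = 7L) {
  stopifnot(length(position) == 2L, length(footprint) == 2L,
            all(footprint > 0), is.numeric(height), height >= 0)
  structure(list(position = as.numeric(position),
                 footprint = as.numeric(footprint),
                 height = as.numeric(height),
                 albedo_seed = as.integer(albedo_seed)),
            class = "plant_spec")
}

#' Build a synthetic field scene
#'
#' A near-flat textured ground plane with optional low-frequency terrain
#' undulation and plant proxies of known height. The soil texture is
#' band-limited lattice noise, deterministic for a fixed seed, with local
#' contrast everywhere so that window correlation is well defined.
#'
#' @param extent `c(x, y)` extent of the plot in metres.
#' @param texture_seed integer seed of the soil texture.
#' @param texture_scale metres per texel of the coarsest noise octave.
#' @param terrain_amplitude peak-to-peak ground undulation in metres
#'   (0 = flat plane).
#' @param terrain_scale horizontal wavelength of the undulation in metres.
#' @param plants list of [plant_spec] objects; footprints must lie inside
#'   the extent and must not overlap.
#' @return an object of class `field_scene`.
#' @export
make_field_scene <- function(extent = c(12, 9), texture_seed = 1L,
                             texture_scale = 0.08, terrain_amplitude = 0,
                             terrain_scale = 2, plants = list()) {
  stopifnot(length(extent) == 2L, all(extent > 0), terrain_amplitude >= 0)
  rects <- lapply(plants, function(p) {
    stopifnot(inherits(p, "plant_spec"))
    r <- c(p$position - p$footprint / 2, p$position + p$footprint / 2)
    if (r[1] < 0 || r[2] < 0 || r[3] > extent[1] || r[4] > extent[2]) {
      stop("plant footprint outside scene extent", call. = FALSE)
    }
    r
  })
  if (length(rects) > 1L) {
    for (i in seq_len(length(rects) - 1L)) {
      for (j in seq(i + 1L, length(rects))) {
        a <- rects[[i]]; b <- rects[[j]]
        if (a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]) {
          stop("overlapping plant footprints", call. = FALSE)
        }
      }
    }
  }
  structure(list(extent = as.numeric(extent),
                 texture_seed = as.integer(texture_seed),
                 texture_scale = texture_scale,
                 terrain_amplitude = terrain_amplitude,
                 terrain_scale = terrain_scale,
                 plants = plants, plant_rects = rects),
            class = "field_scene")
}

# Deterministic lattice hash in [0, 1): no RNG state involved.
lattice_hash <- function(i, j, seed) {
  v <- sin(i * 127.1 + j * 311.7 + seed * 74.77) * 43758.5453
  v - floor(v)
}

# Band-limited value noise in [0, 1]: smoothstep-interpolated lattice noise
# summed over `octaves` octaves.
value_noise <- function(x, y, seed, scale, octaves = 4L) {
  out <- 0
  wsum <- 0
  w <- 1
  s <- scale
  for (o in seq_len(octaves)) {
    xs <- x / s; ys <- y / s
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    fx <- fx * fx * (3 - 2 * fx)  # smoothstep
    fy <- fy * fy * (3 - 2 * fy)
    so <- seed * 131 + o
    v00 <- lattice_hash(x0, y0, so)
    v10 <- lattice_hash(x0 + 1, y0, so)
    v01 <- lattice_hash(x0, y0 + 1, so)
    v11 <- lattice_hash(x0 + 1, y0 + 1, so)
    out <- out + w * ((1 - fy) * ((1 - fx) * v00 + fx * v10) +
                        fy * ((1 - fx) * v01 + fx * v11))
    wsum <- wsum + w
    w <- w * 0.65   # slow decay: soil keeps strong high-frequency grain
    s <- s / 2
  }
  out / wsum
}

terrain_height <- function(scene, x, y) {
  if (scene$terrain_amplitude == 0) return(rep(0, length(x)))
  scene$terrain_amplitude *
    (value_noise(x, y, scene$texture_seed + 991L, scene$terrain_scale, 2L) - 0.5)
}

# Elementary rotations (right-handed, camera axes: x right, y down,
# z forward/toward the ground).
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                            3, 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                            3, 3, byrow = TRUE)
rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                            3, 3, byrow = TRUE)

# Ray-cast one view of the scene. cam_pos is c(x, y, z) in scene metres with
# z measured downward from the flight level (ground plane datum at
# z = altitude); R maps camera-frame ray directions to scene directions.
render_view <- function(scene, altitude, cam_pos, R, f, size, supersample = 2L,
                        noise_sd = 0, noise_seed = NULL) {
  w <- size[1]; h <- size[2]; S <- as.integer(supersample)
  ws <- w * S; hs <- h * S
  u <- (seq_len(ws) - (ws + 1) / 2) / S
  v <- (seq_len(hs) - (hs + 1) / 2) / S
  U <- matrix(u, hs, ws, byrow = TRUE)
  V <- matrix(v, hs, ws)
  # scene-frame ray directions
  dx <- R[1, 1] * U + R[1, 2] * V + R[1, 3] * f
  dy <- R[2, 1] * U + R[2, 2] * V + R[2, 3] * f
  dz <- R[3, 1] * U + R[3, 2] * V + R[3, 3] * f
  # ground intersection (fixed-point refinement for undulating terrain)
  tg <- (altitude - cam_pos[3]) / dz
  if (scene$terrain_amplitude > 0) {
    for (k in 1:3) {
      gx <- cam_pos[1] + tg * dx
      gy <- cam_pos[2] + tg * dy
      tg <- (altitude - terrain_height(scene, gx, gy) - cam_pos[3]) / dz
    }
  }
  tbest <- tg
  surf <- matrix(0L, hs, ws)   # 0 = ground, i = plant i top, -i = plant i side
  for (i in seq_along(scene$plants)) {
    p <- scene$plants[[i]]
    r <- scene$plant_rects[[i]]
    ztop <- altitude - p$height
    tt <- (ztop - cam_pos[3]) / dz
    px <- cam_pos[1] + tt * dx
    py <- cam_pos[2] + tt * dy
    hit <- tt > 0 & tt < tbest &
      px >= r[1] & px <= r[3] & py >= r[2] & py <= r[4]
    tbest[hit] <- tt[hit]
    surf[hit] <- i
    # side faces (x = const and y = const planes bounded by the box)
    for (side in 1:4) {
      if (side <= 2) {
        plane <- r[side * 2 - 1]   # x = r[1] or x = r[3]
        ts <- (plane - cam_pos[1]) / dx
        sy <- cam_pos[2] + ts * dy
        sz <- cam_pos[3] + ts * dz
        hit <- is.finite(ts) & ts > 0 & ts < tbest &
          sy >= r[2] & sy <= r[4] & sz >= ztop & sz <= altitude
      } else {
        plane <- r[(side - 2) * 2]  # y = r[2] or y = r[4]
        ts <- (plane - cam_pos[2]) / dy
        sx <- cam_pos[1] + ts * dx
        sz <- cam_pos[3] + ts * dz
        hit <- is.finite(ts) & ts > 0 & ts < tbest &
          sx >= r[1] & sx <= r[3] & sz >= ztop & sz <= altitude
      }
      tbest[hit] <- ts[hit]
      surf[hit] <- -i
    }
  }
  X <- cam_pos[1] + tbest * dx
  Y <- cam_pos[2] + tbest * dy
  # albedo
  alb <- 0.2 + 0.6 * value_noise(X, Y, scene$texture_seed, scene$texture_scale)
  for (i in seq_along(scene$plants)) {
    p <- scene$plants[[i]]
    top <- surf == i
    if (any(top)) {
      alb[top] <- 0.3 + 0.6 * value_noise(X[top], Y[top], p$albedo_seed,
                                          scene$texture_scale * 0.6)
    }
    sdm <- surf == -i
    if (any(sdm)) {
      alb[sdm] <- 0.12 + 0.35 * value_noise(X[sdm], Y[sdm], p$albedo_seed + 1L,
                                            scene$texture_scale * 0.6)
    }
  }
  img <- alb * 255
  # box-downsample the supersampled grid
  if (S > 1L) {
    img <- .colsum_fold(.rowsum_fold(img, S), S) / (S * S)
  }
  if (noise_sd > 0) {
    img <- img + matrix(local_normal(length(img), noise_seed %||% 1L),
                        nrow(img)) * noise_sd
  }
  gray_image(pmax(pmin(img, 255), 0))
}

.rowsum_fold <- function(m, S) {
  grp <- rep(seq_len(nrow(m) / S), each = S)
  rowsum(m, grp)
}
.colsum_fold <- function(m, S) {
  t(.rowsum_fold(t(m), S))
}

# Deterministic normal deviates that do not disturb the global RNG state.
local_normal <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n)
}

#' Render a synthetic stereo acquisition with ground truth
#'
#' Renders two pinhole views of a [field_scene] from nadir-looking cameras
#' separated by a horizontal baseline, with small commanded perturbations,
#' and attaches full ground truth plus a pair of GNSS fixes whose haversine
#' distance reproduces the commanded baseline up to coordinate rounding.
#'
#' Perturbation conventions: `beta`, `gamma`, `alpha` (radians) rotate the
#' right camera about its y, z and x axes *relative to the left camera*;
#' `tilt = c(alpha_b, beta_b)` (radians) tilts the left camera about its x
#' and y axes relative to nadir; `delta_y` (pixels) shifts the right image
#' content along +y; `delta_z` (metres) changes the right camera altitude.
#'
#' @param scene a [field_scene].
#' @param altitude flight altitude above the ground datum in metres; must
#'   exceed the tallest plant.
#' @param baseline horizontal camera separation in metres (> 0).
#' @param perturbations named list with any of `beta`, `gamma`, `alpha`,
#'   `tilt`, `delta_y`, `delta_z`; absent entries default to 0.
#' @param intrinsics a [camera_intrinsics].
#' @param image_size `c(width, height)` in pixels.
#' @param supersample rendering supersampling factor per axis (the default 2
#'   averages 4 samples per pixel to avoid aliasing biasing ZNCC).
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (0-255 scale).
#' @param noise_seed integer seed for the intensity noise.
#' @param gnss_origin `c(latitude, longitude)` in degrees of the left fix.
#' @param gnss_heading flight heading in degrees (0 = north, 90 = east).
#' @param gnss_rounding `c(lat_decimals, lon_decimals)` applied to the
#'   fixes, emulating the printed precision of an RTK log; `NULL` disables
#'   rounding.
#' @return an object of class `rendered_pair`: `left`, `right`
#'   ([gray_image]s), `gnss` (data frame of two fixes) and `truth` (poses,
#'   intrinsics, commanded perturbations, analytic ground disparity and
#'   per-plant heights).
#' @export
render_stereo_pair <- function(scene, altitude, baseline,
                               perturbations = list(),
                               intrinsics = camera_intrinsics(900),
                               image_size = c(320, 240), supersample = 2L,
                               noise_sd = 0, noise_seed = 1L,
                               gnss_origin = c(36.118784, 140.093798),
                               gnss_heading = 90,
                               gnss_rounding = c(8L, 7L)) {
  stopifnot(inherits(scene, "field_scene"), inherits(intrinsics, "camera_intrinsics"))
  check_pos(altitude, "altitude"); check_pos(baseline, "baseline")
  hmax <- if (length(scene$plants)) max(vapply(scene$plants, `[[`, 0, "height")) else 0
  if (altitude <= hmax) stop("altitude must exceed the tallest plant", call. = FALSE)
  f <- intrinsics$focal_length
  d_ground <- f * baseline / altitude
  if (d_ground > image_size[1] / 2) {
    stop_overlap("commanded geometry leaves less than half-width overlap ",
                 sprintf("(ground disparity %.0f px on a %d px wide image); ",
                         d_ground, image_size[1]),
                 "reduce the baseline or fly higher")
  }
  p <- modifyList(list(beta = 0, gamma = 0, alpha = 0, tilt = c(0, 0),
                       delta_y = 0, delta_z = 0), perturbations)
  for (ang in c(p$beta, p$gamma, p$alpha, p$tilt)) {
    if (abs(ang) > 2 * pi / 180 + 1e-12) {
      stop("perturbation angles must stay below 2 degrees", call. = FALSE)
    }
  }
  R_tilt <- rot_x(p$tilt[1]) %*% rot_y(p$tilt[2])
  R_rel <- rot_y(p$beta) %*% rot_z(p$gamma) %*% rot_x(p$alpha)
  cl <- c(scene$extent[1] / 2 - baseline / 2, scene$extent[2] / 2, 0)
  # +delta_y pixels of content shift corresponds to a camera move of
  # -delta_y * altitude / f metres along camera y
  cr <- cl + c(baseline, -p$delta_y * altitude / f, -p$delta_z)
  left <- render_view(scene, altitude, cl, R_tilt, f, image_size, supersample,
                      noise_sd, noise_seed)
  right <- render_view(scene, altitude, cr, R_tilt %*% R_rel, f, image_size,
                       supersample, noise_sd, noise_seed + 1L)
  gnss <- gnss_pair_for_baseline(baseline, gnss_origin, gnss_heading,
                                 gnss_rounding)
  truth <- list(
    altitude = altitude, baseline = baseline, focal = f,
    perturbations = p, left_pos = cl, right_pos = cr,
    R_left = R_tilt, R_right = R_tilt %*% R_rel,
    ground_disparity = d_ground,
    plant_heights = vapply(scene$plants, `[[`, 0, "height"),
    image_size = image_size
  )
  structure(list(left = left, right = right, gnss = gnss, truth = truth,
                 scene = scene),
            class = "rendered_pair")
}

gnss_pair_for_baseline <- function(baseline, origin, heading, rounding,
                                   earth = earth_model()) {
  tr <- make_gnss_track(geo_position(1L, origin[1], origin[2]), heading,
                        baseline, 2L, rounding)
  tr
}

#' Generate a synthetic GNSS track
#'
#' Equally spaced fixes along a constant heading, optionally rounded to the
#' printed precision of an RTK shooting log (8 decimals of latitude, about
#' 1 mm; 7 decimals of longitude, about 9 mm at mid-latitudes).
#'
#' @param start a [geo_position] for the first fix.
#' @param heading heading in degrees (0 = north, 90 = east).
#' @param spacing metres between consecutive fixes (> 0).
#' @param n number of fixes (>= 2).
#' @param rounding `c(lat_decimals, lon_decimals)` or `NULL` for exact
#'   coordinates.
#' @param earth an [earth_model].
#' @return a data frame with columns `sequence`, `latitude`, `longitude`.
#' @export
make_gnss_track <- function(start, heading, spacing, n, rounding = c(8L, 7L),
                            earth = earth_model()) {
  stopifnot(inherits(start, "geo_position"))
  check_pos(spacing, "spacing")
  if (n < 2L) stop("a track needs at least 2 fixes", call. = FALSE)
  d2r <- pi / 180
  hr <- heading * d2r
  lat <- start$latitude; lon <- start$longitude
  lats <- numeric(n); lons <- numeric(n)
  for (i in seq_len(n)) {
    lats[i] <- lat; lons[i] <- lon
    dlat <- spacing * cos(hr) / earth$radius / d2r
    dlon <- spacing * sin(hr) / (earth$radius * cos(lat * d2r)) / d2r
    lat <- lat + dlat
    lon <- lon + dlon
  }
  if (!is.null(rounding)) {
    lats <- round(lats, rounding[1])
    lons <- round(lons, rounding[2])
  }
  data.frame(sequence = seq_len(n), latitude = lats, longitude = lons)
}

#' @export
print.rendered_pair <- function(x, ...) {
  cat(sprintf(paste0(
    "<rendered_pair %d x %d px>\n",
    "  altitude %.2f m, baseline %.3f m, focal %.0f px\n",
    "  analytic ground disparity %.1f px; %d plant(s)\n"),
    x$truth$image_size[1], x$truth$image_size[2], x$truth$altitude,
    x$truth$baseline, x$truth$focal, x$truth$ground_disparity,
    length(x$truth$plant_heights)))
  invisible(x)
}
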