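# Shared synthetic study conditions: the close-range buckwheat geometry
# (4.1 m altitude, 0.81 m baseline) at desk scale: 480 x 360 px images with
# a 550 px focal length, giving a ground disparity of ~109 levels and a
# per-level height resolution of ~35 mm for a 0.57 m plant.

std_altitude <- 4.1
std_baseline <- 0.81
std_focal <- 550
std_size <- c(480L, 360L)

std_intr <- function() camera_intrinsics(std_focal)

std_cfg <- function(window_radius = 5L, span = 48L) {
  match_config(window_radius = window_radius,
               search_center = round(std_focal * std_baseline / std_altitude),
               search_span = span)
}

# the vertical band must cover the worst commanded y-displacement
# (f * tan(1.5 deg) + 8 px of delta_y plus quadratic terms ~ 25 px)
std_spec <- function() scanline_spec(n_rows = 11L, stride = 6L,
                                     band_halfwidth = 32L)

# memoised fixtures: rendering is deterministic, so cache per-key
.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, make) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- make()
  .fixtures[[key]]
}

flat_scene <- function(seed = 3L) {
  make_field_scene(extent = c(12, 9), texture_seed = seed)
}

plant_scene <- function(seed = 3L, height = 0.57) {
  make_field_scene(extent = c(12, 9), texture_seed = seed,
                   plants = list(plant_spec(c(6, 4.5), c(0.6, 0.6),
                                            height = height,
                                            albedo_seed = seed + 50L)))
}

flat_pair <- function(seed = 3L) {
  fixture(paste0("flat", seed), function() {
    render_stereo_pair(flat_scene(seed), std_altitude, std_baseline,
                       intrinsics = std_intr(), image_size = std_size)
  })
}

plant_pair <- function(seed = 3L, height = 0.57, perturbations = list()) {
  render_stereo_pair(plant_scene(seed, height), std_altitude, std_baseline,
                     perturbations = perturbations, intrinsics = std_intr(),
                     image_size = std_size)
}

# image rectangle (x0, y0, x1, y1) covering plant i of a rendered pair,
# from the ground truth
plant_rect_from_truth <- function(pr, i = 1L, margin = 2L) {
  tr <- pr$truth
  sc <- pr$scene
  r <- sc$plant_rects[[i]]
  h <- sc$plants[[i]]$height
  z <- tr$altitude - h
  f <- tr$focal
  cx <- (tr$image_size[1] + 1) / 2
  cy <- (tr$image_size[2] + 1) / 2
  x0 <- f * (r[1] - tr$left_pos[1]) / z + cx
  x1 <- f * (r[3] - tr$left_pos[1]) / z + cx
  y0 <- f * (r[2] - tr$left_pos[2]) / z + cy
  y1 <- f * (r[4] - tr$left_pos[2]) / z + cy
  round(c(x0 + margin, y0 + margin, x1 - margin, y1 - margin))
}

# independent brute-force ZNCC block matcher (triple loops, direct formula,
# including the right-to-left consistency rule) used as the oracle for the
# compiled matcher
naive_disparity <- function(left, right, radius, thresh, dmin, dmax,
                            lr_check = TRUE) {
  l <- unclass(left); r <- unclass(right)
  h <- nrow(l); w <- ncol(l)
  one_pass <- function(a, b, xlo, xhi, sgn) {
    disp <- matrix(0L, h, w)
    valid <- matrix(FALSE, h, w)
    for (y in (radius + 1):(h - radius)) {
      for (x in xlo:xhi) {
        wa <- a[(y - radius):(y + radius), (x - radius):(x + radius)]
        va <- wa - mean(wa)
        na <- sqrt(sum(va^2))
        if (na <= 1e-6) next
        best <- -2; bestd <- -1L
        for (d in dmin:dmax) {
          xc <- x + sgn * d
          wb <- b[(y - radius):(y + radius), (xc - radius):(xc + radius)]
          vb <- wb - mean(wb)
          nb <- sqrt(sum(vb^2))
          if (nb <= 1e-6) next
          s <- sum(va * vb) / (na * nb)
          if (s > best) { best <- s; bestd <- d }
        }
        if (bestd >= 0L && best >= thresh) {
          disp[y, x] <- bestd
          valid[y, x] <- TRUE
        }
      }
    }
    list(disparity = disp, valid = valid)
  }
  fw <- one_pass(l, r, radius + dmax + 1L, w - radius, -1L)
  if (lr_check) {
    bw <- one_pass(r, l, radius + 1L, w - radius - dmax, +1L)
    for (y in seq_len(h)) {
      for (x in seq_len(w)) {
        if (!fw$valid[y, x]) next
        xr <- x - fw$disparity[y, x]
        if (xr < 1L || !bw$valid[y, xr] ||
            abs(bw$disparity[y, xr] - fw$disparity[y, x]) > 1L) {
          fw$valid[y, x] <- FALSE
          fw$disparity[y, x] <- 0L
        }
      }
    }
  }
  fw
}
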