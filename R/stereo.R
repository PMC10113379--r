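#' Block-matching configuration
#'
#' Parameters of the ZNCC block matcher. The disparity search covers the
#' integer range `search_center - search_span/2` to
#' `search_center + search_span/2` (clamped at zero): centring the search on
#' the disparity predicted from the GNSS baseline, focal length and nominal
#' altitude (`d ~ f b / Z`) keeps the span small even for long baselines.
#'
#' @param window_radius half-width of the square matching window in pixels;
#'   the window is `(2 r + 1) x (2 r + 1)` (default 7, i.e. 15 x 15).
#' @param zncc_accept_threshold minimum ZNCC score for a match to be
#'   accepted, in (-1, 1); lower-scoring pixels are marked invalid.
#' @param search_center centre of the disparity search range in pixels.
#' @param search_span number of disparity levels searched (default 128).
#' @return an object of class `match_config`.
#' @export
match_config <- function(window_radius = 7L, zncc_accept_threshold = 0.6,
                         search_center = 64L, search_span = 128L) {
  if (window_radius < 1) stop("'window_radius' must be >= 1", call. = FALSE)
  if (search_span < 1) stop("'search_span' must be >= 1", call. = FALSE)
  if (zncc_accept_threshold <= -1 || zncc_accept_threshold >= 1) {
    stop("'zncc_accept_threshold' must be in (-1, 1)", call. = FALSE)
  }
  structure(list(window_radius = as.integer(window_radius),
                 zncc_accept_threshold = zncc_accept_threshold,
                 search_center = as.integer(round(search_center)),
                 search_span = as.integer(search_span)),
            class = "match_config")
}

search_range <- function(cfg) {
  dmin <- max(0L, cfg$search_center - cfg$search_span %/% 2L)
  dmax <- cfg$search_center + cfg$search_span %/% 2L
  c(dmin, dmax)
}

#' Zero-mean normalized cross-correlation of two patches
#'
#' Mean-centred, variance-normalised correlation in \[-1, 1\]; invariant to
#' positive affine intensity changes of either patch. Returns `NA` when
#' either patch has zero intensity variance (the caller should treat the
#' pixel as unmatched).
#'
#' @param window_a,window_b numeric matrices of identical shape.
#' @return ZNCC score in \[-1, 1\], or `NA`.
#' @examples
#' a <- matrix(rnorm(25), 5)
#' zncc_score(a, 2 * a + 10) # 1: affine-invariant
#' @export
zncc_score <- function(window_a, window_b) {
  zncc_cpp(as_intensity_matrix(window_a), as_intensity_matrix(window_b))
}

#' Match one left-image pixel against the right image
#'
#' Finds the integer horizontal disparity maximising the ZNCC score within
#' the configured search range, on the same row (the pair is assumed
#' rectified). Ties break toward the smallest disparity.
#'
#' @param left,right [gray_image]s of identical size.
#' @param x,y pixel coordinates in the left image (1-based, x = column).
#' @param cfg a [match_config].
#' @return `list(disparity, score)` or `NULL` when no admissible candidate
#'   reaches the acceptance threshold (flat texture, window outside the
#'   image, or occlusion).
#' @export
match_pixel <- function(left, right, x, y, cfg = match_config()) {
  l <- as_intensity_matrix(left); r <- as_intensity_matrix(right)
  rng <- search_range(cfg)
  res <- match_points2d_cpp(l, r, as.integer(x) - 1L, as.integer(y) - 1L,
                            cfg$window_radius, -rng[2], -rng[1], 0L, 0L,
                            cfg$zncc_accept_threshold)
  if (res[1, 4] < 1) return(NULL)
  list(disparity = as.integer(round(x - 1L - res[1, 1])), score = res[1, 3])
}

#' Dense disparity map by ZNCC block matching
#'
#' Matches every left-image pixel whose window fits in both images against
#' right-image candidates on the same row, producing an integer disparity
#' per pixel plus a validity mask. A left pixel `(x, y)` with disparity `d`
#' corresponds to right pixel `(x - d, y)`. Failures (texture-free windows,
#' scores below threshold, no admissible candidate) are marked invalid and
#' render black in the exported image.
#'
#' The search range must leave an overlap of more than half the image
#' width; pairs shot with less overlap cannot be calibrated reliably and
#' are refused so the flight operator can re-shoot immediately.
#'
#' @param left,right [gray_image]s of identical size (left is the
#'   reference).
#' @param cfg a [match_config].
#' @param baseline,focal optional metadata (metres, pixels) stored with the
#'   map and used by [measure_plant()].
#' @param lr_check run a right-to-left pass and invalidate pixels whose two
#'   matches disagree by more than one level (default). This removes the
#'   spurious matches that occlusion produces near depth discontinuities,
#'   at the cost of a second matching pass.
#' @return an object of class `disparity_map`: integer `disparity` matrix,
#'   logical `valid` matrix, ZNCC `score` matrix, the search range and the
#'   metadata.
#' @export
compute_disparity_map <- function(left, right, cfg = match_config(),
                                  baseline = NA_real_, focal = NA_real_,
                                  lr_check = TRUE) {
  l <- as_intensity_matrix(left); r <- as_intensity_matrix(right)
  if (!all(dim(l) == dim(r))) {
    stop("left and right images must have the same size", call. = FALSE)
  }
  rng <- search_range(cfg)
  if (rng[1] > ncol(l) / 2) {
    stop_overlap("insufficient overlap: the disparity search starts beyond ",
                 "half the image width; re-shoot with a shorter baseline or ",
                 "higher altitude")
  }
  res <- disparity_map_cpp(l, r, cfg$window_radius,
                           cfg$zncc_accept_threshold, rng[1], rng[2],
                           isTRUE(lr_check))
  structure(
    list(disparity = res$disparity, valid = res$valid, score = res$score,
         search_min = rng[1], search_max = rng[2],
         baseline = baseline, focal = focal),
    class = "disparity_map"
  )
}

#' @export
print.disparity_map <- function(x, ...) {
  vf <- mean(x$valid)
  rng <- if (any(x$valid)) range(x$disparity[x$valid]) else c(NA, NA)
  cat(sprintf(paste0(
    "<disparity_map %d x %d px>\n",
    "  search range   : [%d, %d] levels\n",
    "  valid fraction : %.1f%%\n",
    "  disparities    : %s\n",
    "  baseline       : %s m, focal %s px\n"),
    ncol(x$disparity), nrow(x$disparity), x$search_min, x$search_max,
    100 * vf,
    if (is.na(rng[1])) "none valid" else sprintf("[%d, %d]", rng[1], rng[2]),
    format(x$baseline), format(x$focal)))
  invisible(x)
}

#' Write a disparity map
#'
#' Writes the disparity map as a 16-bit single-channel PNG (invalid pixels
#' are 0) plus a JSON sidecar with the search range, baseline, focal length
#' and valid fraction.
#'
#' @param dm a [disparity_map].
#' @param path output image path (`.png`); the sidecar is written next to
#'   it with extension `.json`.
#' @return the image path, invisibly.
#' @export
write_disparity_map <- function(dm, path) {
  stopifnot(inherits(dm, "disparity_map"))
  m <- dm$disparity
  m[!dm$valid] <- 0L
  png::writePNG(m / 65535, path)
  sidecar <- sub("\\.png$", ".json", path)
  jsonlite::write_json(
    list(search_min = dm$search_min, search_max = dm$search_max,
         baseline_m = dm$baseline, focal_px = dm$focal,
         valid_fraction = mean(dm$valid)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a disparity map written by [write_disparity_map()]
#'
#' @param path path to the 16-bit PNG.
#' @return a [disparity_map] (pixels stored as 0 are marked invalid).
#' @export
read_disparity_map <- function(path) {
  m <- round(png::readPNG(path) * 65535)
  sidecar <- sub("\\.png$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  storage.mode(m) <- "integer"
  structure(
    list(disparity = m, valid = m > 0L, score = NULL,
         search_min = meta$search_min %||% min(m[m > 0L], 0L),
         search_max = meta$search_max %||% max(m),
         baseline = meta$baseline_m %||% NA_real_,
         focal = meta$focal_px %||% NA_real_),
    class = "disparity_map"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
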