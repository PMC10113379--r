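#' Pipeline configuration
#'
#' Collects everything [run_pipeline()] needs: the image pair, the GNSS log
#' linking both shots to fixes, camera intrinsics, matcher and scanline
#' parameters, the measurement regions and the output directory.
#'
#' @param left,right paths to the left/right images (left is the reference).
#' @param gnss path to the GNSS shooting log CSV
#'   (`sequence,latitude,longitude[,timestamp]`).
#' @param focal_length focal length in pixels.
#' @param sequence `c(i, j)`: sequence indices of the two shots in the log
#'   (default: the first two rows).
#' @param altitude nominal flight altitude in metres, used to predict the
#'   disparity search centre `f b / Z` when `search_center` is `NULL`.
#' @param search_center,search_span,window_radius,zncc_accept_threshold see
#'   [match_config()].
#' @param scanlines a [scanline_spec].
#' @param earth_radius Earth radius in metres for the baseline computation.
#' @param regions named list of plant regions, each a rectangle
#'   `c(x0, y0, x1, y1)` or `list(plant = ..., ground = ...)` (see
#'   [measure_plant()]); may be empty, in which case no heights are
#'   reported.
#' @param robust_extrema use percentile extrema in [measure_plant()].
#' @param out_dir output directory for artifacts (created if missing);
#'   `NULL` writes nothing.
#' @param verbose print per-stage progress and timing.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(left, right, gnss, focal_length,
                            sequence = NULL, altitude = NULL,
                            search_center = NULL, search_span = 128L,
                            window_radius = 7L, zncc_accept_threshold = 0.6,
                            scanlines = scanline_spec(),
                            earth_radius = EARTH_RADIUS_M,
                            regions = list(), robust_extrema = TRUE,
                            out_dir = NULL, verbose = FALSE) {
  structure(
    list(left = left, right = right, gnss = gnss,
         focal_length = focal_length, sequence = sequence,
         altitude = altitude, search_center = search_center,
         search_span = search_span, window_radius = window_radius,
         zncc_accept_threshold = zncc_accept_threshold,
         scanlines = scanlines, earth_radius = earth_radius,
         regions = regions, robust_extrema = robust_extrema,
         out_dir = out_dir, verbose = verbose),
    class = "pipeline_config")
}

#' Load a pipeline configuration from a file
#'
#' Reads a YAML (requires the `yaml` package) or JSON configuration whose
#' keys mirror the arguments of [pipeline_config()]. Relative paths are
#' resolved against the configuration file's directory.
#'
#' @param path path to the configuration file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_input("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- dirname(normalizePath(path))
  for (k in c("left", "right", "gnss")) {
    if (!is.null(raw[[k]]) && !grepl("^/", raw[[k]])) {
      raw[[k]] <- file.path(base, raw[[k]])
    }
  }
  if (!is.null(raw$scanlines)) {
    raw$scanlines <- do.call(scanline_spec, raw$scanlines)
  }
  do.call(pipeline_config, raw)
}

#' Run the full measurement pipeline
#'
#' Baseline from the GNSS fixes, two-phase calibration, dense ZNCC
#' disparity map, and per-region height measurements; writes a calibration
#' report (JSON), the 16-bit disparity image with its sidecar, and a height
#' table (CSV) when `out_dir` is set.
#'
#' The result carries a `status` string and numeric `code` mirroring the
#' failure taxonomy: `ok` (0), `input_error` (2), `overlap_violation` (3),
#' `calibration_failure` (4), `measurement_failure` (5). A non-`ok` status
#' is the signal to re-shoot the pair immediately rather than continue the
#' flight.
#'
#' @param cfg a [pipeline_config] (or path to a config file).
#' @return an object of class `pipeline_result`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  res <- list(status = "ok", code = 0L, timings = list())
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))
  stage <- function(name, expr) {
    t <- Sys.time()
    out <- expr
    res$timings[[name]] <<- as.numeric(Sys.time() - t, units = "secs")
    say("[%s] %.2fs", name, res$timings[[name]])
    out
  }
  fail <- function(status, code, msg) {
    res$status <- status
    res$code <- code
    res$message <- msg
    res$elapsed <- as.numeric(Sys.time() - t0, units = "secs")
    structure(res, class = "pipeline_result")
  }
  classify <- function(e) {
    if (inherits(e, "dronestereo_overlap_error")) {
      fail("overlap_violation", 3L, conditionMessage(e))
    } else if (inherits(e, "dronestereo_calibration_error")) {
      fail("calibration_failure", 4L, conditionMessage(e))
    } else if (inherits(e, "dronestereo_measurement_error")) {
      fail("measurement_failure", 5L, conditionMessage(e))
    } else {
      fail("input_error", 2L, conditionMessage(e))
    }
  }

  out <- tryCatch({
    for (p in c(cfg$left, cfg$right, cfg$gnss)) {
      if (!file.exists(p)) stop_input("input not found: ", p)
    }
    earth <- earth_model(cfg$earth_radius)
    track <- stage("gnss", read_gnss_track(cfg$gnss))
    seq_idx <- cfg$sequence %||% track$sequence[1:2]
    rows <- match(seq_idx, track$sequence)
    if (anyNA(rows) || length(rows) != 2L) {
      stop_input("GNSS log does not contain the requested two shots")
    }
    if (nrow(track) < 2L) stop_input("GNSS log needs at least two fixes")
    fixes <- as_gnss_track(track[rows, , drop = FALSE])
    b <- baseline_length(fixes[[1]], fixes[[2]], earth)
    res$baseline_m <- b

    left <- stage("read_left", read_gray_image(cfg$left))
    right <- stage("read_right", read_gray_image(cfg$right))
    intr <- camera_intrinsics(cfg$focal_length)
    center <- cfg$search_center %||% {
      if (is.null(cfg$altitude)) {
        stop_input("either 'altitude' or 'search_center' must be given to ",
                   "place the disparity search")
      }
      round(cfg$focal_length * b / cfg$altitude)
    }
    mc <- match_config(cfg$window_radius, cfg$zncc_accept_threshold,
                       center, cfg$search_span)

    cal <- stage("calibrate",
                 calibrate_pair(left, right, intr, baseline = b,
                                spec = cfg$scanlines, cfg = mc))
    res$calibration <- cal
    if (!isTRUE(cal$converged)) {
      stop_calibration("calibration did not converge (",
                       cal$failure_reason, ")")
    }

    dm <- stage("match",
                compute_disparity_map(cal$rectified_left, cal$rectified_right,
                                      mc, baseline = b,
                                      focal = cfg$focal_length))
    res$disparity <- dm

    if (length(cfg$regions)) {
      hm <- stage("height", lapply(cfg$regions, function(r) {
        measure_plant(dm, if (is.list(r)) r else list(plant = r), intr, b,
                      robust = cfg$robust_extrema)
      }))
      res$heights <- hm
    }

    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_calibration_report(cal, file.path(cfg$out_dir, "calibration.json"))
      write_disparity_map(dm, file.path(cfg$out_dir, "disparity.png"))
      if (!is.null(res$heights)) {
        write_height_report(res$heights,
                            file.path(cfg$out_dir, "heights.csv"))
      }
    }
    res$elapsed <- as.numeric(Sys.time() - t0, units = "secs")
    structure(res, class = "pipeline_result")
  }, dronestereo_error = classify)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %s (code %d)>\n", x$status, x$code))
  if (!is.null(x$message)) cat("  ", x$message, "\n", sep = "")
  if (!is.null(x$baseline_m)) cat(sprintf("  baseline : %.3f m\n", x$baseline_m))
  if (!is.null(x$heights)) {
    for (nm in names(x$heights)) {
      cat(sprintf("  %-8s : %.1f mm (res %.2f mm/level)\n", nm,
                  1000 * x$heights[[nm]]$plant_height,
                  1000 * x$heights[[nm]]$resolution_per_level))
    }
  }
  invisible(x)
}

#' Write a calibration report as JSON
#'
#' @param cal a `calibration_result` from [calibrate_pair()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_calibration_report <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_result"))
  r2d <- 180 / pi
  jsonlite::write_json(
    list(beta_deg = cal$beta * r2d, gamma_deg = cal$gamma * r2d,
         alpha_deg = cal$alpha * r2d,
         overfit_deg = c(cal$overfit_beta, cal$overfit_gamma,
                         cal$overfit_alpha) * r2d,
         delta_y_px = cal$delta_y, scale = cal$delta_z_scale,
         left_tilt_deg = c(cal$left_tilt_betab, cal$left_tilt_alphab) * r2d,
         iterations = cal$iterations, sse_trace = cal$sse_trace,
         rows_used = cal$rows_used, n_points = cal$n_points,
         converged = cal$converged,
         plane = if (!is.null(cal$plane)) {
           list(a = cal$plane$a, b = cal$plane$b, c = cal$plane$c,
                fit_rms_m = cal$plane$fit_rms)
         },
         baseline_m = cal$baseline),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write height measurements as CSV
#'
#' @param measurements named list of `height_measurement` objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_height_report <- function(measurements, path) {
  df <- do.call(rbind, lapply(names(measurements), function(nm) {
    m <- measurements[[nm]]
    data.frame(region_id = nm, d_g = m$ground_disparity,
               d_p = m$plant_disparity, height_m = m$plant_height,
               resolution_m = m$resolution_per_level,
               baseline_m = m$baseline, valid_fraction = m$valid_fraction)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
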