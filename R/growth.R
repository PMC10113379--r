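#' Observation epoch of a monitored plant
#'
#' Bundles the quantities needed by the baseline-free growth estimator for
#' one observation day: the baseline of the pair and the disparities of the
#' ground around the plant and of its highest point.
#'
#' @param epoch_id label of the observation (e.g. a date).
#' @param baseline baseline length of the stereo pair in metres.
#' @param ground_disparity ground disparity in pixels (> 0).
#' @param plant_disparity canopy disparity in pixels (>= ground).
#' @return an object of class `observation_epoch`.
#' @export
observation_epoch <- function(epoch_id, baseline, ground_disparity,
                              plant_disparity) {
  check_pos(baseline, "baseline")
  check_pos(ground_disparity, "ground_disparity")
  check_pos(plant_disparity, "plant_disparity")
  if (plant_disparity < ground_disparity) {
    stop("'plant_disparity' must be >= 'ground_disparity' (plant is nearer ",
         "the camera than the ground)", call. = FALSE)
  }
  structure(list(epoch_id = epoch_id, baseline = baseline,
                 ground_disparity = ground_disparity,
                 plant_disparity = plant_disparity),
            class = "observation_epoch")
}

#' Scale a disparity map to a common ground level
#'
#' Multiplies every disparity of a later observation by
#' `ground_t1 / ground_t2` so that its ground disparity equals that of the
#' reference epoch, making the two maps directly comparable without knowing
#' either baseline.
#'
#' @param dm_t2 a [disparity_map] (or plain numeric matrix) from the later
#'   epoch.
#' @param ground_t1 ground disparity of the reference epoch, pixels (> 0).
#' @param ground_t2 ground disparity of `dm_t2`, pixels (> 0).
#' @return the input with disparities rescaled (numeric, no longer
#'   integer-quantised).
#' @export
scale_to_common_ground <- function(dm_t2, ground_t1, ground_t2) {
  check_pos(ground_t1, "ground_t1")
  check_pos(ground_t2, "ground_t2")
  s <- ground_t1 / ground_t2
  if (inherits(dm_t2, "disparity_map")) {
    dm_t2$disparity <- dm_t2$disparity * s
    dm_t2$search_min <- dm_t2$search_min * s
    dm_t2$search_max <- dm_t2$search_max * s
    dm_t2
  } else {
    dm_t2 * s
  }
}

#' Growth ratio between two observation epochs
#'
#' Ratio of the plant's height at the second epoch to its height at the
#' first, computed from disparities alone:
#' \deqn{r = \frac{1 - d_g(t_2)/d_p(t_2)}{1 - d_g(t_1)/d_p(t_1)}}
#' The baselines cancel, so the ratio needs no GNSS data; scaling either
#' map by a constant (as [scale_to_common_ground()] does) leaves it
#' unchanged.
#'
#' @param e1 reference [observation_epoch] (must have nonzero height span).
#' @param e2 later [observation_epoch].
#' @return dimensionless growth ratio.
#' @examples
#' e1 <- observation_epoch("day1", 0.81, 1957, 2320)
#' e2 <- observation_epoch("day8", 0.85, 1957, 2500)
#' growth_ratio(e1, e2)
#' @export
growth_ratio <- function(e1, e2) {
  stopifnot(inherits(e1, "observation_epoch"), inherits(e2, "observation_epoch"))
  if (e1$plant_disparity == e1$ground_disparity) {
    stop("reference epoch has zero height span (d_p == d_g); the growth ",
         "ratio is undefined", call. = FALSE)
  }
  num <- 1 - e2$ground_disparity / e2$plant_disparity
  den <- 1 - e1$ground_disparity / e1$plant_disparity
  num / den
}

#' Sensitivity of the growth ratio to one disparity level
#'
#' Relative height change represented by a single disparity level across the
#' plant's span: `1 / (d_p - d_g)`. A span of 363 levels gives a sensitivity
#' of about 0.28%.
#'
#' @param d_g,d_p ground and plant disparities in pixels, `d_p > d_g`.
#' @return sensitivity as a fraction (multiply by 100 for percent).
#' @examples
#' 100 * growth_sensitivity(1957, 2320) # ~0.28
#' @export
growth_sensitivity <- function(d_g, d_p) {
  if (any(d_p <= d_g)) stop("'d_p' must exceed 'd_g'", call. = FALSE)
  1 / (d_p - d_g)
}

#' Read an epoch registry
#'
#' CSV with header `epoch_id,date,baseline_m,d_g,d_p`, one row per
#' observation of the monitored plant.
#'
#' @param path path to the CSV file.
#' @return a list of [observation_epoch] objects, named by `epoch_id`.
#' @export
read_epoch_registry <- function(path) {
  if (!file.exists(path)) stop("epoch registry not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_id", "baseline_m", "d_g", "d_p")
  if (!all(need %in% names(df))) {
    stop("epoch registry must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  eps <- lapply(seq_len(nrow(df)), function(i) {
    observation_epoch(df$epoch_id[i], df$baseline_m[i], df$d_g[i], df$d_p[i])
  })
  names(eps) <- df$epoch_id
  eps
}
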