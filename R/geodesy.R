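#' Mean Earth radius in metres
#'
#' Default sphere radius used for great-circle baseline computation.
#' @export
EARTH_RADIUS_M <- 6371000

#' Construct a GNSS shooting position
#'
#' One RTK-GNSS fix tied to an exposure in a shooting sequence.
#'
#' @param sequence_index positive integer identifying the shot within a track.
#' @param latitude latitude in decimal degrees, in \[-90, 90\].
#' @param longitude longitude in decimal degrees, in (-180, 180\].
#' @param timestamp optional time of the fix in seconds.
#' @return an object of class `geo_position`.
#' @examples
#' geo_position(1, 36.11878417, 140.0937983)
#' @export
geo_position <- function(sequence_index, latitude, longitude, timestamp = NULL) {
  if (!is.numeric(sequence_index) || length(sequence_index) != 1L ||
      sequence_index < 1 || sequence_index != round(sequence_index)) {
    stop("'sequence_index' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(latitude) || length(latitude) != 1L || is.na(latitude) ||
      latitude < -90 || latitude > 90) {
    stop("'latitude' must be in [-90, 90] degrees", call. = FALSE)
  }
  if (!is.numeric(longitude) || length(longitude) != 1L || is.na(longitude) ||
      longitude <= -180 || longitude > 180) {
    stop("'longitude' must be in (-180, 180] degrees", call. = FALSE)
  }
  structure(
    list(sequence_index = as.integer(sequence_index),
         latitude = latitude, longitude = longitude, timestamp = timestamp),
    class = "geo_position"
  )
}

#' @export
print.geo_position <- function(x, ...) {
  cat(sprintf("<geo_position #%d: %.8f deg N, %.7f deg E>\n",
              x$sequence_index, x$latitude, x$longitude))
  invisible(x)
}

#' Construct a spherical Earth model
#'
#' @param radius sphere radius in metres; defaults to the mean Earth radius
#'   [EARTH_RADIUS_M].
#' @return an object of class `earth_model`.
#' @export
earth_model <- function(radius = EARTH_RADIUS_M) {
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) || radius <= 0) {
    stop("Earth radius must be a single positive number (metres)", call. = FALSE)
  }
  structure(list(radius = radius), class = "earth_model")
}

#' Great-circle baseline length between two shooting positions
#'
#' Distance in metres between two GNSS fixes on a spherical Earth, used as
#' the stereo baseline of the image pair captured at those positions. Uses
#' the haversine form, which is numerically stable for the sub-metre to
#' few-metre separations typical of consecutive shots:
#' \deqn{b = 2 r \arcsin\sqrt{\sin^2 La_3 + \cos La_1 \cos La_2 \sin^2 Lo_3}}
#' with half-angle differences \eqn{La_3 = (La_1 - La_2)/2},
#' \eqn{Lo_3 = (Lo_1 - Lo_2)/2}.
#'
#' @param p1,p2 [geo_position] fixes.
#' @param earth an [earth_model]; defaults to the mean-radius sphere.
#' @return baseline length in metres (non-negative, symmetric in arguments).
#' @examples
#' p1 <- geo_position(1, 36.11878417, 140.0937983)
#' p2 <- geo_position(2, 36.11878317, 140.0937943)
#' baseline_length(p1, p2) # ~0.376 m
#' @export
baseline_length <- function(p1, p2, earth = earth_model()) {
  stopifnot(inherits(earth, "earth_model"))
  p1 <- as_geo_position(p1)
  p2 <- as_geo_position(p2)
  d <- pi / 180
  la1 <- p1$latitude * d; la2 <- p2$latitude * d
  lo1 <- p1$longitude * d; lo2 <- p2$longitude * d
  la3 <- (la1 - la2) / 2
  lo3 <- (lo1 - lo2) / 2
  h <- sin(la3)^2 + cos(la1) * cos(la2) * sin(lo3)^2
  2 * earth$radius * asin(sqrt(pmin(1, h)))
}

as_geo_position <- function(x) {
  if (inherits(x, "geo_position")) return(x)
  if (is.list(x) && all(c("latitude", "longitude") %in% names(x))) {
    idx <- if (!is.null(x$sequence_index)) x$sequence_index else 1L
    return(geo_position(idx, x$latitude, x$longitude, x$timestamp))
  }
  stop("cannot interpret object as a geo_position", call. = FALSE)
}

#' Pairwise baseline matrix for a GNSS track
#'
#' @param track a list of [geo_position] fixes, or a data frame as returned
#'   by [read_gnss_track()].
#' @param earth an [earth_model].
#' @return a symmetric matrix of baseline lengths in metres with zero
#'   diagonal; row/column names are the sequence indices.
#' @export
pairwise_baselines <- function(track, earth = earth_model()) {
  track <- as_gnss_track(track)
  n <- length(track)
  if (n < 2L) stop("a track needs at least 2 positions", call. = FALSE)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      m[i, j] <- m[j, i] <- baseline_length(track[[i]], track[[j]], earth)
    }
  }
  ids <- vapply(track, function(p) p$sequence_index, integer(1))
  dimnames(m) <- list(ids, ids)
  m
}

as_gnss_track <- function(track) {
  if (is.data.frame(track)) {
    need <- c("sequence", "latitude", "longitude")
    if (!all(need %in% names(track))) {
      stop("GNSS track data frame needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    ts <- if ("timestamp" %in% names(track)) track$timestamp else
      rep(list(NULL), nrow(track))
    track <- lapply(seq_len(nrow(track)), function(i) {
      geo_position(track$sequence[i], track$latitude[i], track$longitude[i],
                   if (is.numeric(ts)) ts[i] else NULL)
    })
  }
  if (!is.list(track)) stop("track must be a list or data frame", call. = FALSE)
  track <- lapply(track, as_geo_position)
  ids <- vapply(track, function(p) p$sequence_index, integer(1))
  if (anyDuplicated(ids)) stop("duplicated sequence_index in track", call. = FALSE)
  track
}

#' Read a GNSS shooting log
#'
#' Reads a CSV with header `sequence,latitude,longitude[,timestamp]`
#' (decimal degrees, one row per shot) into a data frame suitable for
#' [pairwise_baselines()] and [run_pipeline()].
#'
#' @param path path to the CSV file.
#' @return a data frame with columns `sequence`, `latitude`, `longitude`
#'   and, when present in the file, `timestamp`.
#' @examples
#' log <- system.file("extdata", "shooting_positions.csv",
#'                    package = "dronestereo")
#' head(read_gnss_track(log))
#' @export
read_gnss_track <- function(path) {
  if (!file.exists(path)) stop_input("GNSS log not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sequence", "latitude", "longitude")
  if (!all(need %in% names(df))) {
    stop_input("GNSS log must have columns ", paste(need, collapse = ", "))
  }
  # validate eagerly so bad logs fail at read time
  invisible(as_gnss_track(df))
  df
}
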