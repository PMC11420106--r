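# Dead-reckoning: behavior-class speeds integrated along magnetic
# headings, drift-corrected by anchoring to sparse GPS fixes.

M_PER_DEG <- 6378137 * pi / 180  # meters per degree of latitude (WGS84 a)

#' Convert latitude/longitude to local east/north meters
#'
#' Local equirectangular projection about `origin`; adequate for
#' enclosure-to-landscape scale tracks (few km), where projection error
#' is negligible.
#'
#' @param lat,lon Numeric vectors, WGS84 degrees.
#' @param origin `c(lat, lon)` of the local origin.
#' @return Data frame with `east_m`, `north_m`.
#' @export
latlon_to_enu <- function(lat, lon, origin) {
  data.frame(east_m = (lon - origin[[2]]) * M_PER_DEG * cos(deg2rad(origin[[1]])),
             north_m = (lat - origin[[1]]) * M_PER_DEG)
}

#' Convert local east/north meters to latitude/longitude
#'
#' Inverse of [latlon_to_enu()].
#'
#' @param east_m,north_m Numeric vectors, meters.
#' @param origin `c(lat, lon)` of the local origin.
#' @return Data frame with `lat`, `lon`.
#' @export
enu_to_latlon <- function(east_m, north_m, origin) {
  data.frame(lat = origin[[1]] + north_m / M_PER_DEG,
             lon = origin[[2]] + east_m / (M_PER_DEG * cos(deg2rad(origin[[1]]))))
}

#' Per-step speed series from behavioral events
#'
#' Assigns each sample step the speed coefficient of the behavioral
#' event containing it.
#'
#' @param events Event data frame (`behavior`, `t_start`, `t_end`),
#'   contiguous.
#' @param speed_coefficients Named numeric vector, m/s per class; see
#'   [default_speed_coefficients()].
#' @param fs Sampling rate, Hz.
#' @return Data frame with `t` (step start time) and `speed` (m/s).
#' @export
speed_series <- function(events, speed_coefficients = default_speed_coefficients(),
                         fs = 10) {
  missing_cls <- setdiff(unique(events$behavior), names(speed_coefficients))
  if (length(missing_cls))
    stop("no speed coefficient for class(es): ",
         paste(missing_cls, collapse = ", "))
  lo <- min(events$t_start)
  hi <- max(events$t_end)
  dt <- 1 / fs
  n <- floor((hi - lo) * fs + 1e-9)
  t <- lo + (seq_len(n) - 1L) * dt
  idx <- findInterval(t + 1e-12, events$t_start)
  data.frame(t = t, speed = unname(speed_coefficients[events$behavior[idx]]))
}

#' Integrate headings and speeds into a dead-reckoned track
#'
#' Vector integration with step `dt = 1/fs`:
#' `east += speed * sin(heading) * dt`, `north += speed * cos(heading)
#' * dt`, starting at the origin. The returned track has one more row
#' than there are steps (position before and after every step).
#' Non-finite headings carry the last valid heading (reported via
#' message); leading invalid headings contribute no displacement.
#'
#' @param headings_deg Heading per step, degrees.
#' @param speeds Speed per step, m/s.
#' @param fs Sampling rate, Hz.
#' @param t0 Time of the first step, seconds.
#' @return Object of class `dr_track`: data frame with `t`, `east_m`,
#'   `north_m`.
#' @export
integrate_track <- function(headings_deg, speeds, fs = 10, t0 = 0) {
  n <- length(headings_deg)
  stopifnot(length(speeds) == n)
  bad <- !is.finite(headings_deg)
  if (any(bad)) {
    message(sprintf("%d invalid heading step(s); carrying last valid heading",
                    sum(bad)))
    ok <- which(!bad)
    if (!length(ok)) stop("no valid headings")
    filled <- headings_deg
    last <- NA_real_
    for (i in seq_len(n)) {
      if (bad[i]) {
        if (is.na(last)) speeds[i] <- 0 else filled[i] <- last
      } else {
        last <- filled[i]
      }
    }
    headings_deg <- filled
    headings_deg[!is.finite(headings_deg)] <- 0
  }
  dt <- 1 / fs
  h <- deg2rad(headings_deg)
  east <- c(0, cumsum(speeds * sin(h) * dt))
  north <- c(0, cumsum(speeds * cos(h) * dt))
  out <- data.frame(t = t0 + (0:n) * dt, east_m = east, north_m = north)
  class(out) <- c("dr_track", "data.frame")
  out
}

#' Anchor a dead-reckoned track to GPS fixes
#'
#' Between consecutive fixes, the end-point residual (fix minus
#' dead-reckoned position at the fix time) is distributed along the
#' intermediate steps in proportion to cumulative dead-reckoned
#' distance traveled, so stationary spans absorb no drift correction;
#' the corrected track passes through every fix. Before the first and
#' after the last fix the track is translated by the nearest residual.
#' With fewer than two fixes the track is translated only (reported
#' via message). A time-proportional weighting is available and is
#' also the fallback within a segment that covers no distance at all.
#'
#' @param track A [integrate_track()] track (`t`, `east_m`,
#'   `north_m`).
#' @param fixes GPS fixes: data frame with `t` and either
#'   `east_m`/`north_m` or `lat`/`lon` (converted about `origin`).
#' @param origin `c(lat, lon)` used when fixes are geographic; defaults
#'   to the first fix.
#' @param weighting `"distance"` (default) or `"time"`.
#' @return The anchored track, with attribute `"anchors"` holding the
#'   fix times/positions used.
#' @export
anchor_to_gps <- function(track, fixes, origin = NULL,
                          weighting = c("distance", "time")) {
  weighting <- match.arg(weighting)
  if (!all(c("east_m", "north_m") %in% names(fixes))) {
    stopifnot(all(c("lat", "lon") %in% names(fixes)))
    if (is.null(origin)) origin <- c(fixes$lat[1L], fixes$lon[1L])
    enu <- latlon_to_enu(fixes$lat, fixes$lon, origin)
    fixes <- data.frame(t = fixes$t, east_m = enu$east_m,
                        north_m = enu$north_m)
  }
  fixes <- fixes[fixes$t >= track$t[1L] - 1e-9 &
                   fixes$t <= track$t[nrow(track)] + 1e-9, , drop = FALSE]
  fixes <- fixes[order(fixes$t), , drop = FALSE]
  if (nrow(fixes) == 0L) stop("no GPS fixes within the track time span")
  dr_e <- stats::approx(track$t, track$east_m, xout = fixes$t)$y
  dr_n <- stats::approx(track$t, track$north_m, xout = fixes$t)$y
  res_e <- fixes$east_m - dr_e
  res_n <- fixes$north_m - dr_n
  n <- nrow(track)
  corr_e <- numeric(n)
  corr_n <- numeric(n)
  if (nrow(fixes) < 2L) {
    message("fewer than 2 fixes in span; translate-only anchoring")
    corr_e[] <- res_e[1L]
    corr_n[] <- res_n[1L]
  } else {
    step_d <- c(0, sqrt(diff(track$east_m)^2 + diff(track$north_m)^2))
    cum_d <- cumsum(step_d)
    before <- track$t <= fixes$t[1L]
    corr_e[before] <- res_e[1L]
    corr_n[before] <- res_n[1L]
    k <- nrow(fixes)
    after <- track$t >= fixes$t[k]
    corr_e[after] <- res_e[k]
    corr_n[after] <- res_n[k]
    cum_at <- stats::approx(track$t, cum_d, xout = fixes$t)$y
    for (s in seq_len(k - 1L)) {
      sel <- which(track$t > fixes$t[s] & track$t < fixes$t[s + 1L])
      if (!length(sel)) next
      span_d <- cum_at[s + 1L] - cum_at[s]
      if (weighting == "time" || span_d < 1e-12) {
        w <- (track$t[sel] - fixes$t[s]) / (fixes$t[s + 1L] - fixes$t[s])
      } else {
        w <- (cum_d[sel] - cum_at[s]) / span_d
      }
      corr_e[sel] <- res_e[s] + w * (res_e[s + 1L] - res_e[s])
      corr_n[sel] <- res_n[s] + w * (res_n[s + 1L] - res_n[s])
    }
    # track rows coinciding with a fix time take that fix's residual
    # exactly, so the corrected track passes through every fix
    for (s in seq_len(k)) {
      at <- which(abs(track$t - fixes$t[s]) < 1e-9)
      corr_e[at] <- res_e[s]
      corr_n[at] <- res_n[s]
    }
  }
  track$east_m <- track$east_m + corr_e
  track$north_m <- track$north_m + corr_n
  attr(track, "anchors") <- fixes
  track
}

#' Export a track as GeoJSON
#'
#' Writes a FeatureCollection with the track as a `LineString` and, if
#' the track was anchored, the GPS anchors as `Point` features.
#' Coordinates are converted from local east/north meters to
#' longitude/latitude about `origin`.
#'
#' @param track A track data frame (`t`, `east_m`, `north_m`).
#' @param origin `c(lat, lon)` of the local origin.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_track <- function(track, origin, path) {
  ll <- enu_to_latlon(track$east_m, track$north_m, origin)
  features <- list(list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = base::matrix(c(ll$lon, ll$lat), ncol = 2L)),
    properties = list(kind = "dead_reckoned_track",
                      t_start = track$t[1L], t_end = track$t[nrow(track)])))
  anchors <- attr(track, "anchors")
  if (!is.null(anchors)) {
    all <- enu_to_latlon(anchors$east_m, anchors$north_m, origin)
    for (i in seq_len(nrow(anchors))) {
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(all$lon[i], all$lat[i])),
        properties = list(kind = "gps_anchor", t = anchors$t[i]))
    }
  }
  obj <- list(type = "FeatureCollection",
              properties = list(origin_lat = origin[[1]],
                                origin_lon = origin[[2]]),
              features = features)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a track written by [export_track()]
#'
#' @param path Path to the GeoJSON file.
#' @return List with `track` (data frame `lat`, `lon`), `anchors`
#'   (data frame `t`, `lat`, `lon`, possibly empty) and `origin`.
#' @export
read_track <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  origin <- c(lat = obj$properties$origin_lat, lon = obj$properties$origin_lon)
  geoms <- obj$features$geometry
  line <- geoms$coordinates[[which(geoms$type == "LineString")[1L]]]
  pts <- which(geoms$type == "Point")
  anchors <- if (length(pts)) {
    coords <- do.call(rbind, geoms$coordinates[pts])
    data.frame(t = obj$features$properties$t[pts],
               lat = coords[, 2L], lon = coords[, 1L])
  } else {
    data.frame(t = numeric(), lat = numeric(), lon = numeric())
  }
  list(track = data.frame(lat = line[, 2L], lon = line[, 1L]),
       anchors = anchors, origin = origin)
}
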