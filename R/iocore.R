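# Data model, file I/O and time alignment shared by all pipeline stages.
#
# All on-disk formats are comma-delimited UTF-8 text with a header row.
# Timestamps may be numeric epoch seconds or ISO-8601 strings; they are
# stored internally as double seconds.

#' Construct a validated triaxial sensor series
#'
#' Container for a uniformly sampled three-axis sensor stream
#' (accelerometer, in g, or magnetometer, in normalized field units).
#'
#' Invariants enforced: timestamps strictly increasing with median spacing
#' within 1% of `1/fs`; all axis values finite and of equal length.
#'
#' @param t Numeric vector of timestamps (seconds since epoch or since
#'   recording start), strictly increasing.
#' @param x,y,z Numeric vectors of sensor values, same length as `t`.
#' @param fs Nominal sampling rate in Hz.
#' @param sensor_kind Either `"accel"` or `"mag"`.
#' @return An object of class `triaxial_series`: a list with elements
#'   `t`, `x`, `y`, `z`, `fs`, `sensor_kind`.
#' @export
triaxial_series <- function(t, x, y, z, fs, sensor_kind = c("accel", "mag")) {
  sensor_kind <- match.arg(sensor_kind)
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(t)
  if (n < 2L) stop("triaxial series needs at least 2 samples")
  if (length(x) != n || length(y) != n || length(z) != n)
    stop("t, x, y, z must have equal length")
  if (!all(is.finite(t))) stop("non-finite timestamps")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("non-finite sensor values")
  dt <- diff(t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (!is.finite(fs) || fs <= 0) stop("fs must be a positive number")
  nominal <- 1 / fs
  if (abs(stats::median(dt) - nominal) / nominal >= 0.01)
    stop("median sample spacing deviates from 1/fs by 1% or more")
  structure(list(t = t, x = x, y = y, z = z, fs = fs,
                 sensor_kind = sensor_kind),
            class = "triaxial_series")
}

#' @export
print.triaxial_series <- function(x, ...) {
  cat(sprintf("<triaxial_series: %s, %d samples @ %g Hz, %.1f s>\n",
              x$sensor_kind, length(x$t), x$fs, diff(range(x$t))))
  invisible(x)
}

#' @export
as.data.frame.triaxial_series <- function(x, ...) {
  data.frame(t = x$t, x = x$x, y = x$y, z = x$z)
}

#' Axis values of a triaxial series as an n x 3 matrix
#'
#' @param series A [triaxial_series()].
#' @return Numeric matrix with columns `x`, `y`, `z`.
#' @export
xyz <- function(series) {
  cbind(x = series$x, y = series$y, z = series$z)
}

# Internal: parse a timestamp column that may be epoch seconds or ISO-8601.
parse_timestamps <- function(t) {
  if (is.numeric(t)) return(as.numeric(t))
  tt <- suppressWarnings(as.numeric(t))
  if (!anyNA(tt)) return(tt)
  parsed <- as.POSIXct(t, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(parsed)) stop("could not parse timestamps as numbers or ISO-8601")
  as.numeric(parsed)
}

#' Read a sensor table from delimited text
#'
#' Expects a comma-delimited file with header columns `t,x,y,z`.
#' Timestamps may be epoch seconds or ISO-8601 strings (auto-detected).
#' Sampling gaps longer than `2/fs` are reported with a warning.
#'
#' @param path Path to the CSV file.
#' @param sensor_kind `"accel"` or `"mag"`.
#' @param fs Nominal sampling rate in Hz.
#' @return A [triaxial_series()].
#' @export
read_sensor_table <- function(path, sensor_kind = c("accel", "mag"), fs) {
  sensor_kind <- match.arg(sensor_kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  t <- parse_timestamps(df$t)
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  gaps <- sum(diff(t) > 2 / fs)
  if (gaps > 0)
    warning(sprintf("%d sampling gap(s) longer than %.3g s detected", gaps, 2 / fs))
  triaxial_series(t, df$x, df$y, df$z, fs = fs, sensor_kind = sensor_kind)
}

#' Write a sensor table to delimited text
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the series to full double precision.
#'
#' @param series A [triaxial_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensor_table <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("t,x,y,z", con)
  writeLines(sprintf("%.17g,%.17g,%.17g,%.17g",
                     series$t, series$x, series$y, series$z), con)
  invisible(path)
}

#' Shift a series in time
#'
#' Adds a scalar offset to every timestamp, leaving sensor values
#' untouched. Used to synchronize logger clocks with ground-truth video
#' (e.g., by aligning a physical calibration signature with its time on
#' camera); the offset itself is supplied by the user.
#'
#' @param series A [triaxial_series()].
#' @param offset_s Finite scalar offset in seconds.
#' @return The shifted [triaxial_series()].
#' @export
apply_time_offset <- function(series, offset_s) {
  if (!is.finite(offset_s)) stop("offset_s must be finite")
  series$t <- series$t + offset_s
  series
}

#' Read a ground-truth ethogram file
#'
#' Expects columns `behavior,t_start,t_end` and optionally `source`.
#' Rows whose class name is not part of the taxonomy raise an error;
#' rows with `t_end <= t_start` are dropped with a warning; overlapping
#' labels are kept but reported with a warning. Output is sorted by
#' `t_start`.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `behavior`, `t_start`, `t_end`,
#'   `source`.
#' @export
read_ethogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    return(data.frame(behavior = character(), t_start = numeric(),
                      t_end = numeric(), source = character()))
  need <- c("behavior", "t_start", "t_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$source)) df$source <- ""
  bad_class <- unique(df$behavior[!is_behavior_class(df$behavior)])
  if (length(bad_class))
    stop("unknown behavioral class(es): ", paste(bad_class, collapse = ", "),
         "; valid classes are: ", paste(all_classes(), collapse = ", "))
  df$t_start <- parse_timestamps(df$t_start)
  df$t_end <- parse_timestamps(df$t_end)
  drop <- df$t_end <= df$t_start
  if (any(drop)) {
    warning(sprintf("dropping %d row(s) with t_end <= t_start", sum(drop)))
    df <- df[!drop, , drop = FALSE]
  }
  df <- df[order(df$t_start), c("behavior", "t_start", "t_end", "source")]
  rownames(df) <- NULL
  if (nrow(df) > 1L && any(df$t_start[-1L] < df$t_end[-nrow(df)]))
    warning("overlapping ethogram labels detected (kept)")
  validate_ethogram(df)
}

# Internal: minimal structural validation used by readers and simulators.
validate_ethogram <- function(df) {
  stopifnot(all(c("behavior", "t_start", "t_end") %in% names(df)))
  if (nrow(df)) {
    stopifnot(all(df$t_end > df$t_start), all(is_behavior_class(df$behavior)))
  }
  df
}

#' Write behavioral events to delimited text
#'
#' @param events Data frame with columns `behavior`, `t_start`, `t_end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.frame(behavior = events$behavior,
                    t_start = events$t_start, t_end = events$t_end,
                    duration_s = events$t_end - events$t_start)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sparse GPS fixes
#'
#' Expects columns `t,lat,lon` (WGS84 degrees). Fixes are validated and
#' sorted by time.
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `t`, `lat`, `lon`.
#' @export
read_gps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df$t <- parse_timestamps(df$t)
  if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180))
    stop("latitude/longitude out of range")
  df <- df[order(df$t), need]
  rownames(df) <- NULL
  df
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters shared across stages. Defaults follow
#' the collar protocol this package targets: 10 Hz sampling, 4-s
#' observation windows, a 5-nearest-neighbor classifier with cityblock
#' distance, and principal components retaining 95% of training
#' variance.
#'
#' @param fs Sampling rate, Hz.
#' @param window_s Observation window length, seconds.
#' @param k_neighbors Number of nearest neighbors.
#' @param distance_metric `"cityblock"` or `"euclidean"`.
#' @param pca_variance_retained Fraction of variance the retained
#'   components must reach.
#' @param min_durations Named numeric vector of per-class minimum event
#'   durations in seconds; see [default_min_durations()].
#' @param speed_coefficients Named numeric vector of per-class speeds in
#'   m/s; see [default_speed_coefficients()].
#' @param band_edges Increasing numeric vector of 5 frequency band edges
#'   (Hz) defining 4 bands. Default: the four equal quarters of
#'   `[0, fs/2]`.
#' @param rng_seed Optional integer seed recorded for provenance.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fs = 10, window_s = 4, k_neighbors = 5,
                            distance_metric = c("cityblock", "euclidean"),
                            pca_variance_retained = 0.95,
                            min_durations = default_min_durations(),
                            speed_coefficients = default_speed_coefficients(),
                            band_edges = NULL, rng_seed = NULL) {
  distance_metric <- match.arg(distance_metric)
  if (is.null(band_edges)) band_edges <- default_band_edges(fs)
  stopifnot(fs > 0, window_s > 0, k_neighbors >= 1,
            pca_variance_retained > 0, pca_variance_retained <= 1,
            all(min_durations >= 0), all(speed_coefficients >= 0),
            length(band_edges) == 5L, all(diff(band_edges) > 0))
  structure(list(fs = fs, window_s = window_s, k_neighbors = k_neighbors,
                 distance_metric = distance_metric,
                 pca_variance_retained = pca_variance_retained,
                 min_durations = min_durations,
                 speed_coefficients = speed_coefficients,
                 band_edges = band_edges, rng_seed = rng_seed),
            class = "pipeline_config")
}

#' Default frequency band edges
#'
#' Four equal bands spanning `[0, fs/2]`. At 10 Hz these are
#' 0-1.25, 1.25-2.5, 2.5-3.75 and 3.75-5 Hz. A band specification
#' extending beyond the Nyquist frequency is accepted by
#' [band_power()] but yields zero power in the out-of-range bands.
#'
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of 5 increasing edges.
#' @export
default_band_edges <- function(fs = 10) {
  seq(0, fs / 2, length.out = 5L)
}
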