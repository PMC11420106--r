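# Hard/soft-iron magnetometer calibration, tilt-compensated magnetic
# compass headings, and the circular statistics used to validate them.

#' Fit hard- and soft-iron calibration from a free-rotation segment
#'
#' Least-squares fit of the general quadric
#' `m' M m + 2 b' m = 1` to the raw magnetometer scatter, giving the
#' hard-iron offset (ellipsoid center) and a symmetric
#' positive-definite soft-iron correction `A_inv` that maps the
#' ellipsoid onto a sphere of radius `field_norm`. Because an ellipsoid
#' fit cannot determine the absolute field strength, `field_norm`
#' defaults to the geometric-mean radius of the fitted ellipsoid;
#' supply the known field magnitude to fix the scale.
#'
#' The scatter must cover orientations in all three dimensions; a
#' near-planar cloud (smallest-to-largest covariance eigenvalue ratio
#' below 1%) is rejected with a diagnostic.
#'
#' @param cal_series Magnetometer [triaxial_series()] recorded while
#'   rotating the collar freely through 3-D space.
#' @param field_norm Optional known field magnitude (same units as the
#'   data).
#' @return Object of class `iron_calibration`: list with `b` (3-vector
#'   hard-iron offset), `A_inv` (3x3 SPD soft-iron correction) and
#'   `field_norm`.
#' @export
fit_iron_calibration <- function(cal_series, field_norm = NULL) {
  M <- xyz(cal_series)
  ctr <- sweep(M, 2L, colMeans(M))
  ecov <- eigen(stats::cov(ctr), symmetric = TRUE, only.values = TRUE)$values
  if (min(ecov) / max(ecov) < 0.01)
    stop("calibration scatter is nearly planar; rotate the collar through ",
         "all three dimensions (covariance eigenvalue ratio ",
         sprintf("%.2g", min(ecov) / max(ecov)), ")")
  x <- M[, 1]; y <- M[, 2]; z <- M[, 3]
  D <- cbind(x^2, y^2, z^2, x * y, x * z, y * z, x, y, z)
  p <- stats::lsfit(D, rep(1, nrow(M)), intercept = FALSE)$coefficients
  Q <- matrix(c(p[1], p[4] / 2, p[5] / 2,
                p[4] / 2, p[2], p[6] / 2,
                p[5] / 2, p[6] / 2, p[3]), 3L, 3L)
  eq <- eigen(Q, symmetric = TRUE)
  if (any(eq$values <= 0))
    stop("quadric fit is not an ellipsoid; calibration data insufficient")
  b <- as.numeric(-solve(Q, p[7:9]) / 2)
  s <- as.numeric(1 + t(b) %*% Q %*% b)
  if (s <= 0) stop("degenerate ellipsoid fit")
  E <- Q / s  # (m - b)' E (m - b) = 1
  ee <- eigen(E, symmetric = TRUE)
  if (is.null(field_norm)) field_norm <- prod(ee$values)^(-1 / 6)
  sqrtE <- ee$vectors %*% diag(sqrt(ee$values)) %*% t(ee$vectors)
  A_inv <- field_norm * sqrtE
  structure(list(b = b, A_inv = A_inv, field_norm = field_norm),
            class = "iron_calibration")
}

#' @export
print.iron_calibration <- function(x, ...) {
  cat(sprintf("<iron_calibration: offset (%.4g, %.4g, %.4g), field_norm %.4g>\n",
              x$b[1], x$b[2], x$b[3], x$field_norm))
  invisible(x)
}

#' Identity iron calibration
#'
#' @param field_norm Reference field magnitude.
#' @return An `iron_calibration` that leaves data unchanged.
#' @export
identity_calibration <- function(field_norm = 1) {
  structure(list(b = c(0, 0, 0), A_inv = diag(3), field_norm = field_norm),
            class = "iron_calibration")
}

#' Apply an iron calibration to a magnetometer series
#'
#' Each raw sample is corrected as `m_cal = A_inv %*% (m_raw - b)`.
#'
#' @param series Magnetometer [triaxial_series()].
#' @param cal An [fit_iron_calibration()] result.
#' @return Calibrated [triaxial_series()].
#' @export
apply_calibration <- function(series, cal) {
  v <- sweep(xyz(series), 2L, cal$b) %*% t(cal$A_inv)
  series$x <- v[, 1L]; series$y <- v[, 2L]; series$z <- v[, 3L]
  series
}

#' Estimate the gravity direction from acceleration
#'
#' Centered moving-average low-pass of the accelerometer, normalized to
#' unit length per sample: the dynamic (gait) component averages out
#' and the postural (gravity) component remains. Samples whose
#' smoothed norm vanishes carry the previous direction (reported via
#' message).
#'
#' @param accel_series Accelerometer [triaxial_series()].
#' @param smoothing_s Moving-average length, seconds (at least one
#'   sample period).
#' @return A [triaxial_series()] of unit gravity-direction vectors.
#' @export
estimate_gravity <- function(accel_series, smoothing_s = 2) {
  fs <- accel_series$fs
  if (smoothing_s < 1 / fs - 1e-9) stop("smoothing_s must be >= 1/fs")
  w <- max(1L, as.integer(round(smoothing_s * fs)))
  v <- xyz(accel_series)
  if (w > 1L) {
    n <- nrow(v)
    cs <- apply(rbind(0, v), 2L, cumsum)
    lo <- pmax(0L, seq_len(n) - 1L - (w %/% 2L))
    hi <- pmin(n, seq_len(n) - 1L + ((w + 1L) %/% 2L))
    v <- (cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) / (hi - lo)
  }
  nrm <- sqrt(rowSums(v^2))
  zero <- nrm < 1e-12
  if (any(zero)) {
    message(sprintf("%d zero-norm gravity sample(s); carrying previous direction",
                    sum(zero)))
    for (i in which(zero)) {
      j <- if (i > 1L) i - 1L else which(!zero)[1L]
      v[i, ] <- v[j, ]
      nrm[i] <- sqrt(sum(v[i, ]^2))
    }
  }
  v <- v / nrm
  accel_series$x <- v[, 1L]; accel_series$y <- v[, 2L]; accel_series$z <- v[, 3L]
  accel_series
}

#' Tilt-compensated magnetic compass heading
#'
#' Pitch and roll are derived from the gravity estimate (body frame x
#' forward, y right, z down; level rest reads `(0, 0, -1)`), the
#' calibrated magnetometer is de-rotated into the local horizontal
#' plane, and the heading is the clockwise angle of the horizontal
#' field from magnetic north with the x axis forward:
#' `heading = atan2(-m'_y, m'_x)`. Declination, if supplied, is added
#' to convert magnetic to true headings. Samples whose horizontal
#' field magnitude falls below 1% of `field_norm` are flagged invalid.
#'
#' @param mag_cal Calibrated magnetometer [triaxial_series()].
#' @param gravity Unit gravity series from [estimate_gravity()],
#'   time-aligned sample-for-sample with `mag_cal`.
#' @param declination_deg Magnetic declination to add, degrees.
#' @param field_norm Reference field magnitude used for the
#'   validity threshold (defaults to the median calibrated norm).
#' @return Data frame with columns `t`, `heading_deg` (in `[0, 360)`),
#'   `pitch_deg`, `roll_deg`, `valid`.
#' @export
tilt_compensated_heading <- function(mag_cal, gravity, declination_deg = 0,
                                     field_norm = NULL) {
  m <- xyz(mag_cal)
  g <- xyz(gravity)
  if (nrow(m) != nrow(g)) stop("magnetometer and gravity series differ in length")
  if (is.null(field_norm)) field_norm <- stats::median(sqrt(rowSums(m^2)))
  # static specific force u = (sin(pitch), -sin(roll)cos(pitch), -cos(roll)cos(pitch))
  pitch <- asin(pmin(1, pmax(-1, g[, 1L])))
  roll <- atan2(-g[, 2L], -g[, 3L])
  n <- nrow(m)
  mh_x <- numeric(n); mh_y <- numeric(n)
  cp <- cos(pitch); sp <- sin(pitch)
  cr <- cos(roll); sr <- sin(roll)
  # m' = Ry(pitch) %*% Rx(roll) %*% m, expanded per sample
  my_r <- cr * m[, 2L] - sr * m[, 3L]
  mz_r <- sr * m[, 2L] + cr * m[, 3L]
  mh_x <- cp * m[, 1L] + sp * mz_r
  mh_y <- my_r
  heading <- wrap360(rad2deg(atan2(-mh_y, mh_x)) + declination_deg)
  valid <- sqrt(mh_x^2 + mh_y^2) >= 0.01 * field_norm
  data.frame(t = mag_cal$t, heading_deg = heading,
             pitch_deg = rad2deg(pitch), roll_deg = rad2deg(roll),
             valid = valid)
}

#' Signed angular difference between headings
#'
#' `heading_error(m, t)` is the signed difference `m - t` wrapped into
#' `(-180, 180]`, so 359 degrees versus 1 degree gives -2.
#'
#' @param measured_deg,truth_deg Numeric heading vectors, degrees.
#' @return Signed errors in `(-180, 180]`.
#' @export
heading_error <- function(measured_deg, truth_deg) {
  wrap180(measured_deg - truth_deg)
}

#' Circular median of angles
#'
#' The angle minimizing the mean absolute circular deviation to the
#' sample, with candidates restricted to the data points themselves; a
#' tie goes to the smallest angle (after wrapping to `[0, 360)`).
#'
#' @param angles_deg Non-empty numeric vector of angles, degrees.
#' @return The median angle in `[0, 360)`.
#' @export
circular_median <- function(angles_deg) {
  if (!length(angles_deg)) stop("empty angle vector")
  a <- wrap360(angles_deg)
  cand <- sort(unique(a))
  dev <- vapply(cand, function(c0) {
    d <- abs(wrap180(a - c0))
    mean(d)
  }, numeric(1))
  cand[which.min(dev)]  # which.min takes the first (smallest) on ties
}

#' Bootstrap percentile confidence interval for the circular median
#'
#' Resamples the signed errors with replacement, computes the circular
#' median of each resample (reported on the signed `(-180, 180]`
#' scale), and returns the percentile interval. Deterministic under a
#' fixed seed.
#'
#' @param errors_deg Signed heading errors, degrees (n >= 2).
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return Named numeric `c(lo, hi)` in degrees.
#' @export
bootstrap_median_ci <- function(errors_deg, n_boot = 10000, level = 0.95,
                                seed = 1) {
  n <- length(errors_deg)
  if (n < 2L) stop("need at least 2 errors")
  withr_seed(seed)
  meds <- vapply(seq_len(n_boot), function(i) {
    wrap180(circular_median(errors_deg[sample.int(n, n, replace = TRUE)]))
  }, numeric(1))
  q <- stats::quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  stats::setNames(q, c("lo", "hi"))
}

#' Four-cardinal (and general) heading evaluation
#'
#' For each condition (an expected heading with repeated measured
#' headings) computes the circular median of the measurements; the
#' overall figure is the median absolute heading error pooled across
#' all samples.
#'
#' @param headings_by_condition Named list: names are the expected
#'   headings in degrees (e.g. `"0"`, `"90"`, `"180"`, `"270"`), values
#'   numeric vectors of measured headings.
#' @return List with `per_condition` (data frame `expected_deg`,
#'   `median_deg`, `median_error_deg`, `n`) and scalar
#'   `overall_median_abs_error_deg`.
#' @export
lab_cardinal_evaluation <- function(headings_by_condition) {
  stopifnot(length(headings_by_condition) >= 1L,
            !is.null(names(headings_by_condition)))
  expected <- as.numeric(names(headings_by_condition))
  med <- vapply(headings_by_condition, circular_median, numeric(1))
  errs <- unlist(lapply(seq_along(expected), function(i) {
    heading_error(headings_by_condition[[i]], expected[i])
  }))
  data_frame <- data.frame(
    expected_deg = expected,
    median_deg = unname(med),
    median_error_deg = wrap180(unname(med) - expected),
    n = vapply(headings_by_condition, length, integer(1)))
  list(per_condition = data_frame,
       overall_median_abs_error_deg = stats::median(abs(errs)))
}

# Internal: exact F test of a single-row linear hypothesis L %*% B = 0
# in the multivariate regression Y = X B + E (Hotelling T^2 form; for a
# one-degree-of-freedom hypothesis all four MANOVA statistics coincide).
mlm_row_test <- function(X, Y, L) {
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  E <- crossprod(Y - X %*% B)
  LB <- L %*% B
  H <- t(LB) %*% solve(L %*% XtXi %*% t(L)) %*% LB
  df_e <- n - p
  T_ <- sum(diag(H %*% solve(E)))
  df2 <- df_e - m + 1
  if (df2 <= 0) stop("too few observations for the multivariate test")
  F_ <- T_ * df2 / m
  list(F = F_, p = stats::pf(F_, m, df2, lower.tail = FALSE))
}

#' Uniformity test of headings with an error covariate
#'
#' Bivariate linear model with the cosine and sine of the heading (in
#' radians) as responses and the error proportion as a linear
#' covariate. The multivariate (approximate-F) test of the intercept
#' probes departure of the heading distribution from circular
#' uniformity; the covariate term probes whether error depends on
#' heading direction. The error proportion is taken exactly as
#' supplied by the caller.
#'
#' @param headings_deg Headings, degrees (n > 3).
#' @param error_proportions Numeric covariate, same length.
#' @return List with `F_intercept`, `p_intercept`, `F_slope`,
#'   `p_slope` (`NA` for the slope when the covariate is constant).
#' @export
uniform_error_test <- function(headings_deg, error_proportions) {
  n <- length(headings_deg)
  if (n <= 3L) stop("need more than 3 observations")
  stopifnot(length(error_proportions) == n)
  th <- deg2rad(headings_deg)
  Y <- cbind(cos(th), sin(th))
  if (stats::sd(error_proportions) == 0) {
    X <- base::matrix(1, n, 1L)
    it <- mlm_row_test(X, Y, base::matrix(c(1), 1L, 1L))
    return(list(F_intercept = it$F, p_intercept = it$p,
                F_slope = NA_real_, p_slope = NA_real_))
  }
  X <- cbind(1, error_proportions)
  it <- mlm_row_test(X, Y, base::matrix(c(1, 0), 1L, 2L))
  sl <- mlm_row_test(X, Y, base::matrix(c(0, 1), 1L, 2L))
  list(F_intercept = it$F, p_intercept = it$p,
       F_slope = sl$F, p_slope = sl$p)
}

#' Combine two observers' heading predictions
#'
#' Field-protocol helper: when two independent predictions differ by
#' less than `threshold_deg` they are averaged on the circle; larger
#' disagreements are returned as `NA` and must be resolved by joint
#' review.
#'
#' @param pred1_deg,pred2_deg Numeric heading vectors, degrees.
#' @param threshold_deg Maximum absolute disagreement for automatic
#'   averaging.
#' @return Numeric vector of combined headings in `[0, 360)`, `NA`
#'   where review is needed.
#' @export
average_observer_headings <- function(pred1_deg, pred2_deg,
                                      threshold_deg = 20) {
  d <- heading_error(pred2_deg, pred1_deg)
  out <- wrap360(pred1_deg + d / 2)
  out[abs(d) >= threshold_deg] <- NA_real_
  out
}
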