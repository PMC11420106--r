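# Feature extraction: 4-s observation windows -> 18-dimensional feature
# vectors (per axis: power in 4 frequency bands, median, variance) ->
# z-scored principal-component representation.

#' Number of observation windows a labeled duration yields
#'
#' Each labeled epoch is tiled with non-overlapping windows from its
#' start; the trailing remainder shorter than `window_s` is discarded,
#' so an epoch of duration `d` yields `floor(d / window_s)` windows.
#'
#' @param duration_s Numeric vector of epoch durations, seconds.
#' @param window_s Window length, seconds.
#' @return Integer vector of window counts.
#' @export
windows_per_duration <- function(duration_s, window_s = 4) {
  as.integer(floor(duration_s / window_s + 1e-9))
}

#' Cut labeled training windows from a sensor series
#'
#' Tiles each ethogram epoch with non-overlapping `window_s` windows
#' starting at the epoch start; windows inherit the epoch label and the
#' trailing remainder is discarded. Epochs shorter than `window_s`
#' contribute no windows (reported via message).
#'
#' @param series A [triaxial_series()].
#' @param ethogram Ethogram data frame whose labels lie within the
#'   series time span.
#' @param window_s Window length, seconds.
#' @return List of windows; each window is a list with `samples`
#'   (`n x 3` matrix), `t_center` (seconds) and `label`.
#' @export
make_training_windows <- function(series, ethogram, window_s = 4) {
  ethogram <- validate_ethogram(ethogram)
  nw <- as.integer(round(window_s * series$fs))
  vals <- xyz(series)
  out <- list()
  short <- 0L
  for (ep in seq_len(nrow(ethogram))) {
    sel <- which(series$t >= ethogram$t_start[ep] - 1e-9 &
                   series$t < ethogram$t_end[ep] - 1e-9)
    k <- length(sel) %/% nw
    if (k == 0L) {
      short <- short + 1L
      next
    }
    for (w in seq_len(k)) {
      idx <- sel[((w - 1L) * nw + 1L):(w * nw)]
      out[[length(out) + 1L]] <- list(
        samples = vals[idx, , drop = FALSE],
        t_center = mean(range(series$t[idx])),
        label = ethogram$behavior[ep])
    }
  }
  if (short > 0L)
    message(sprintf("%d epoch(s) shorter than %g s contributed no windows",
                    short, window_s))
  out
}

#' Welch power spectral density estimate
#'
#' Mean-detrended, Hann-tapered overlapping segments, zero-padded to
#' `nfft` points, one-sided density scaling. Defaults match the
#' pipeline's feature definition: 2-s segments with 1-s overlap and
#' 64-point transforms.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param segment_s Segment length, seconds.
#' @param overlap_s Segment overlap, seconds.
#' @param nfft Transform length (segments are zero-padded to this).
#' @return List with `freq` (Hz, 0 to fs/2) and `psd` (density,
#'   units^2/Hz).
#' @export
welch_psd <- function(x, fs, segment_s = 2, overlap_s = 1, nfft = 64) {
  seg <- as.integer(round(segment_s * fs))
  hop <- seg - as.integer(round(overlap_s * fs))
  stopifnot(seg >= 2L, hop >= 1L, nfft >= seg)
  n <- length(x)
  if (n < seg) stop("signal shorter than one Welch segment")
  starts <- seq(1L, n - seg + 1L, by = hop)
  k <- 0:(seg - 1L)
  w <- 0.5 * (1 - cos(2 * pi * k / seg))  # periodic Hann taper
  U <- sum(w^2)
  nbin <- nfft %/% 2L + 1L
  acc <- numeric(nbin)
  for (s in starts) {
    segm <- x[s:(s + seg - 1L)]
    segm <- (segm - mean(segm)) * w
    X <- stats::fft(c(segm, numeric(nfft - seg)))
    p <- Mod(X[seq_len(nbin)])^2 / (fs * U)
    p[2:(nbin - 1L)] <- 2 * p[2:(nbin - 1L)]  # fold negative frequencies
    acc <- acc + p
  }
  list(freq = (0:(nbin - 1L)) * fs / nfft, psd = acc / length(starts))
}

# Internal: trapezoid integral of (freq, psd) over [lo, hi], linearly
# interpolating the PSD at the band edges. Portions beyond the frequency
# grid contribute zero.
integrate_band <- function(freq, psd, lo, hi) {
  lo <- max(lo, min(freq))
  hi <- min(hi, max(freq))
  if (hi <= lo) return(0)
  inside <- freq > lo & freq < hi
  f <- c(lo, freq[inside], hi)
  p <- c(stats::approx(freq, psd, xout = lo)$y, psd[inside],
         stats::approx(freq, psd, xout = hi)$y)
  sum(diff(f) * (p[-1L] + p[-length(p)]) / 2)
}

#' Signal power in frequency bands
#'
#' Welch PSD (see [welch_psd()]) integrated (trapezoid rule) over each
#' of the four bands defined by `band_edges`, returned on a linear
#' scale. Bands lying beyond the Nyquist frequency yield zero power
#' with a warning.
#'
#' @param x Numeric signal for a single axis (at least 2 s of samples).
#' @param fs Sampling rate, Hz.
#' @param band_edges Increasing numeric vector of 5 edges defining 4
#'   bands; see [default_band_edges()].
#' @return Numeric vector of 4 band powers.
#' @export
band_power <- function(x, fs, band_edges = default_band_edges(fs)) {
  stopifnot(length(band_edges) == 5L, all(diff(band_edges) > 0))
  if (band_edges[5L] > fs / 2 + 1e-9)
    warning("band edges extend beyond the Nyquist frequency; ",
            "out-of-range bands have zero power")
  pw <- welch_psd(x, fs)
  vapply(seq_len(4L), function(b) {
    integrate_band(pw$freq, pw$psd, band_edges[b], band_edges[b + 1L])
  }, numeric(1))
}

# Floor added before the decibel transform so constant windows map to a
# finite value rather than -Inf.
DB_FLOOR <- 1e-12

db_scale <- function(v) 10 * log10(v + DB_FLOOR)

#' Extract the 18-feature vector from an observation window
#'
#' Per axis (x, then y, then z): power in the four frequency bands, the
#' signal median, and the signal variance. Band powers and variances
#' (guaranteed non-negative) are decibel-scaled as
#' `10*log10(v + 1e-12)`; medians are left untransformed. Feature order
#' is fixed: `x_band1..x_band4, x_median, x_var, y_..., z_...`.
#'
#' @param window A window from [make_training_windows()], or a bare
#'   `n x 3` numeric matrix.
#' @param fs Sampling rate, Hz.
#' @param band_edges Band edges; see [default_band_edges()].
#' @return Named numeric vector of length 18.
#' @export
extract_features <- function(window, fs = 10,
                             band_edges = default_band_edges(fs)) {
  samples <- if (is.list(window)) window$samples else window
  stopifnot(is.matrix(samples), ncol(samples) == 3L)
  out <- numeric(0)
  for (ax in 1:3) {
    v <- samples[, ax]
    out <- c(out, db_scale(band_power(v, fs, band_edges)),
             stats::median(v), db_scale(stats::var(v)))
  }
  names(out) <- as.vector(vapply(c("x", "y", "z"), function(a)
    paste0(a, c("_band1", "_band2", "_band3", "_band4", "_median", "_var")),
    character(6)))
  out
}

#' Feature matrix for a list of windows
#'
#' @param windows List of windows from [make_training_windows()].
#' @param fs Sampling rate, Hz.
#' @param band_edges Band edges; see [default_band_edges()].
#' @return List with `features` (matrix, one row per window), `labels`
#'   (character, `NA` where unlabeled) and `t_center`.
#' @export
extract_feature_matrix <- function(windows, fs = 10,
                                   band_edges = default_band_edges(fs)) {
  feats <- t(vapply(windows, extract_features, numeric(18L),
                    fs = fs, band_edges = band_edges))
  labels <- vapply(windows, function(w)
    if (is.null(w$label)) NA_character_ else w$label, character(1))
  tc <- vapply(windows, function(w)
    if (is.null(w$t_center)) NA_real_ else w$t_center, numeric(1))
  list(features = feats, labels = labels, t_center = tc)
}

#' Fit the standardization + principal-component projection
#'
#' Features are z-scored using their column means and standard
#' deviations, then a PCA is fitted to the z-scored matrix. The number
#' of retained components `m` is the smallest count whose cumulative
#' explained variance reaches `variance_retained`. Constant columns get
#' a unit standard deviation (with a warning) to avoid division by
#' zero. Each loading column is oriented so its largest-magnitude
#' element is positive, making the projection deterministic.
#'
#' @param features_matrix Numeric matrix, observations in rows (needs
#'   more rows than columns).
#' @param variance_retained Fraction of variance to preserve.
#' @return An object of class `projection_model`: list with `mean`,
#'   `sd`, `loadings` (p x m), `m`, `eigenvalues` (all p),
#'   `variance_retained`.
#' @export
fit_projection <- function(features_matrix, variance_retained = 0.95) {
  X <- as.matrix(features_matrix)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than features")
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  if (any(sd_ == 0)) {
    warning(sprintf("%d constant feature column(s); using unit sd",
                    sum(sd_ == 0)))
    sd_[sd_ == 0] <- 1
  }
  Z <- sweep(sweep(X, 2L, mu), 2L, sd_, "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  m <- which(cum >= variance_retained - 1e-12)[1L]
  L <- pc$rotation[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  structure(list(mean = mu, sd = sd_, loadings = L, m = m,
                 eigenvalues = ev, variance_retained = variance_retained),
            class = "projection_model")
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("<projection_model: %d features -> %d components (%.0f%% variance)>\n",
              length(x$mean), x$m, 100 * x$variance_retained))
  invisible(x)
}

#' Project features into the fitted component space
#'
#' Applies `((f - mean) / sd) %*% loadings` using the *training*
#' standardization parameters; test data must always be transformed
#' with the parameters fitted on training data.
#'
#' @param features Numeric vector (length p) or matrix (n x p).
#' @param model A [fit_projection()] model.
#' @return Numeric matrix `n x m` (a 1-row matrix for a vector input).
#' @export
project <- function(features, model) {
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1L)
  if (ncol(X) != length(model$mean))
    stop("feature dimension does not match the fitted model")
  Z <- sweep(sweep(X, 2L, model$mean), 2L, model$sd, "/")
  Z %*% model$loadings
}
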