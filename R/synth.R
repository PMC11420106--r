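# Synthetic collar-data generator: behavior sequences, class-distinct
# acceleration, magnetometer readings under known iron distortion, and
# ground-truth tracks with noisy sparse GPS. Everything is deterministic
# under a fixed seed, and every generated quantity comes with its truth,
# so downstream stages can be tested without field recordings.

#' Define a synthetic behavior profile
#'
#' A profile describes how one behavioral class looks to a collar
#' accelerometer: a gravity-referenced static (postural) offset, a gait
#' oscillation, sensor noise, a mean dwell time, a travel speed and a
#' weight in the long-run behavioral time budget.
#'
#' @param class Behavioral class name (see [all_classes()]).
#' @param static_offset Length-3 numeric, mean specific force in g in the
#'   body frame (x forward, y right, z down; level rest reads c(0,0,-1)).
#' @param osc_freq_hz Gait oscillation frequency, Hz (must be below the
#'   Nyquist frequency when data are generated).
#' @param osc_amp_g Oscillation amplitude, g.
#' @param osc_axis Length-3 non-negative weights distributing the
#'   oscillation across axes.
#' @param noise_sd_g Gaussian sensor/behavioral noise SD, g.
#' @param dwell_mean_s Mean epoch duration, seconds.
#' @param speed_mps Travel speed while in this class, m/s.
#' @param mix_weight Relative share of this class in the long-run time
#'   budget.
#' @return A list of class `behavior_profile`.
#' @export
behavior_profile <- function(class, static_offset, osc_freq_hz = 0,
                             osc_amp_g = 0, osc_axis = c(1, 0, 1),
                             noise_sd_g = 0.05, dwell_mean_s = 60,
                             speed_mps = 0, mix_weight = 1) {
  stopifnot(is_behavior_class(class), length(static_offset) == 3L,
            osc_freq_hz >= 0, osc_amp_g >= 0, length(osc_axis) == 3L,
            noise_sd_g >= 0, dwell_mean_s > 0, speed_mps >= 0,
            mix_weight > 0)
  structure(list(class = class, static_offset = as.numeric(static_offset),
                 osc_freq_hz = osc_freq_hz, osc_amp_g = osc_amp_g,
                 osc_axis = as.numeric(osc_axis), noise_sd_g = noise_sd_g,
                 dwell_mean_s = dwell_mean_s, speed_mps = speed_mps,
                 mix_weight = mix_weight),
            class = "behavior_profile")
}

#' Long-run behavioral time budget used by the default profiles
#'
#' Time shares matching the class proportions of the wild-boar training
#' ethogram this pipeline targets (Rest 47.1%, Forage 19.3%, Stand
#' 12.4%, Walk 10.7%, Run 7.7%, Other 2.7%, normalized).
#'
#' @return Named numeric vector summing to 1.
#' @export
default_behavior_mix <- function() {
  mix <- c(Walk = 10.7, Forage = 19.3, Rest = 47.1, Run = 7.7,
           Stand = 12.4, Other = 2.7)
  mix / sum(mix)
}

# Internal: embedded-jump-chain ingredients for a target time budget
# with prescribed per-class mean dwell times. Transition probabilities
# out of class i are proportional to a weight vector w (excluding i);
# w is solved by fixed-point iteration so that the long-run time shares
# pi_i * dwell_i (pi = stationary distribution of the jump chain) equal
# the target mix.
markov_ingredients <- function(mix, dwell) {
  classes <- names(mix)
  k <- length(mix)
  stopifnot(k >= 2L, all(mix > 0), length(dwell) == k, all(dwell > 0))
  mix <- mix / sum(mix)
  p_from_w <- function(w) {
    P <- matrix(0, k, k, dimnames = list(classes, classes))
    for (i in seq_len(k)) {
      v <- w
      v[i] <- 0
      P[i, ] <- v / sum(v)
    }
    P
  }
  stationary <- function(P) {
    e <- eigen(t(P))
    i1 <- which.min(abs(Re(e$values) - 1))
    pi_ <- Re(e$vectors[, i1])
    pi_ / sum(pi_)
  }
  w <- mix
  for (iter in seq_len(500L)) {
    P <- p_from_w(w)
    pi_ <- stationary(P)
    share <- pi_ * dwell
    share <- share / sum(share)
    if (max(abs(share - mix)) < 1e-12) break
    w <- w * mix / share
    w <- w / sum(w)
  }
  list(P = P, pi = stats::setNames(pi_, classes),
       w = stats::setNames(w, classes),
       share = stats::setNames(share, classes))
}

#' Default mean dwell times (seconds) for the synthetic behavior chain
#'
#' Mean epoch durations per class: long resting bouts, intermediate
#' foraging/standing bouts, short walking/running/other bouts. A
#' realism choice for enclosure-scale simulation, configurable via
#' [behavior_profile()].
#'
#' @return Named numeric vector of seconds.
#' @export
default_dwell_means <- function() {
  c(Walk = 60, Forage = 120, Rest = 300, Run = 30, Stand = 90, Other = 20)
}

#' Default synthetic behavior profiles
#'
#' Six class profiles with distinct postures (static offsets), gait
#' frequencies and noise levels: Rest is static with low noise, Stand
#' static with moderate noise, Walk a 1.5 Hz gait, Run a high-amplitude
#' 2.8 Hz gait, Forage a 1 Hz high-variance surge-axis pattern, and
#' Other broadband bursts. These are configurable stand-ins chosen to be
#' plausibly separable, not measurements of real boar. The transition
#' structure of the behavior chain is solved so that its analytic
#' long-run time budget equals `mix` under the given dwell means (see
#' [simulate_behavior_sequence()]).
#'
#' @param mix Named time-budget vector, default [default_behavior_mix()].
#' @param dwell Named vector of per-class mean dwell times, seconds.
#' @return Named list of [behavior_profile()] objects.
#' @export
default_behavior_profiles <- function(mix = default_behavior_mix(),
                                      dwell = default_dwell_means()) {
  d <- dwell[names(mix)]
  speeds <- default_speed_coefficients()
  base <- list(
    Walk   = list(off = c(0.05, 0.00, -1.00), f = 1.5, a = 0.30,
                  ax = c(0.6, 0.2, 1.0), sd = 0.08),
    Forage = list(off = c(0.45, 0.00, -0.89), f = 1.0, a = 0.50,
                  ax = c(1.0, 0.2, 0.3), sd = 0.15),
    Rest   = list(off = c(0.00, 0.30, -0.94), f = 0.0, a = 0.00,
                  ax = c(1, 0, 1), sd = 0.02),
    Run    = list(off = c(0.15, 0.00, -0.95), f = 2.8, a = 1.00,
                  ax = c(1.0, 0.3, 1.0), sd = 0.20),
    Stand  = list(off = c(0.00, 0.00, -1.00), f = 0.0, a = 0.00,
                  ax = c(1, 0, 1), sd = 0.08),
    Other  = list(off = c(0.00, -0.10, -1.00), f = 3.3, a = 0.40,
                  ax = c(0.7, 0.7, 0.7), sd = 0.30)
  )
  out <- lapply(names(mix), function(cl) {
    b <- base[[cl]]
    behavior_profile(cl, static_offset = b$off, osc_freq_hz = b$f,
                     osc_amp_g = b$a, osc_axis = b$ax, noise_sd_g = b$sd,
                     dwell_mean_s = unname(d[cl]),
                     speed_mps = unname(speeds[cl]),
                     mix_weight = unname(mix[cl]))
  })
  stats::setNames(out, names(mix))
}

#' Analytic long-run time budget of a profile set
#'
#' Computes the stationary time shares implied by the profiles'
#' `mix_weight` transition structure and dwell means, accounting for the
#' 1-s dwell floor used by [simulate_behavior_sequence()]
#' (`E[max(1, X)] = 1 + d * exp(-1/d)` for an exponential with mean `d`).
#'
#' @param profiles Named list of [behavior_profile()] objects.
#' @return Named numeric vector summing to 1.
#' @export
stationary_time_shares <- function(profiles) {
  mix <- vapply(profiles, `[[`, numeric(1), "mix_weight")
  d <- vapply(profiles, `[[`, numeric(1), "dwell_mean_s")
  ing <- markov_ingredients(mix, d)
  eff <- 1 + d * exp(-1 / d)  # mean of max(1, Exp(d))
  w <- ing$pi * eff
  w / sum(w)
}

#' Simulate a behavioral sequence
#'
#' First-order Markov chain over the profile classes: dwell times are
#' exponential with the profile's mean, floored at 1 s, and jump
#' probabilities (no self transitions) are solved so the chain's
#' analytic long-run time budget equals the profiles' `mix_weight`
#' targets. The initial class is drawn from the analytic time budget.
#' Identical seeds give identical sequences.
#'
#' @param profiles Named list of [behavior_profile()] objects.
#' @param duration_s Total simulated duration, seconds.
#' @param seed Integer seed.
#' @param t0 Start time, seconds.
#' @return Ethogram data frame (`behavior`, `t_start`, `t_end`,
#'   `source`) tiling `[t0, t0 + duration_s]` without gaps.
#' @export
simulate_behavior_sequence <- function(profiles, duration_s, seed, t0 = 0) {
  if (length(profiles) == 0L) stop("empty profile set")
  stopifnot(duration_s > 0)
  classes <- vapply(profiles, `[[`, character(1), "class")
  names(profiles) <- classes
  if (length(profiles) == 1L) {
    return(validate_ethogram(data.frame(
      behavior = classes, t_start = t0, t_end = t0 + duration_s,
      source = "sim")))
  }
  mix <- vapply(profiles, `[[`, numeric(1), "mix_weight")
  dwell <- vapply(profiles, `[[`, numeric(1), "dwell_mean_s")
  ing <- markov_ingredients(mix, dwell)
  withr_seed(seed)
  shares <- stationary_time_shares(profiles)
  cur <- sample(classes, 1L, prob = shares)
  t_start <- numeric(0); t_end <- numeric(0); beh <- character(0)
  t <- t0
  end <- t0 + duration_s
  while (t < end) {
    dw <- max(1, stats::rexp(1L, rate = 1 / dwell[[cur]]))
    te <- min(t + dw, end)
    beh <- c(beh, cur); t_start <- c(t_start, t); t_end <- c(t_end, te)
    t <- te
    cur <- sample(classes, 1L, prob = ing$P[cur, ])
  }
  validate_ethogram(data.frame(behavior = beh, t_start = t_start,
                               t_end = t_end, source = "sim"))
}

# Internal: set.seed wrapper tolerating NULL (leave RNG state alone).
withr_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Simulate triaxial acceleration for an ethogram
#'
#' Per class: static offset + sinusoidal gait at the profile frequency
#' (random phase per epoch) + Gaussian noise. Class boundaries are
#' contiguous; the series covers the full ethogram span at rate `fs`.
#'
#' @param ethogram Ethogram data frame covering the span to simulate.
#' @param profiles Named list of [behavior_profile()] objects covering
#'   every class in the ethogram.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @return An accelerometer [triaxial_series()].
#' @export
simulate_acceleration <- function(ethogram, profiles, fs = 10, seed = NULL) {
  ethogram <- validate_ethogram(ethogram)
  classes <- vapply(profiles, `[[`, character(1), "class")
  names(profiles) <- classes
  missing_cls <- setdiff(unique(ethogram$behavior), classes)
  if (length(missing_cls))
    stop("no profile for class(es): ", paste(missing_cls, collapse = ", "))
  withr_seed(seed)
  t0 <- min(ethogram$t_start)
  t_total <- max(ethogram$t_end) - t0
  dt <- 1 / fs
  n <- floor(t_total * fs + 1e-9)
  t <- t0 + (seq_len(n) - 1L) * dt
  a <- matrix(0, n, 3L)
  idx <- findInterval(t + 1e-12, ethogram$t_start)
  for (ep in seq_len(nrow(ethogram))) {
    sel <- which(idx == ep)
    if (!length(sel)) next
    p <- profiles[[ethogram$behavior[ep]]]
    if (p$osc_freq_hz >= fs / 2 && p$osc_amp_g > 0)
      stop("profile oscillation frequency must be below fs/2")
    phase <- stats::runif(1L, 0, 2 * pi)
    osc <- p$osc_amp_g * sin(2 * pi * p$osc_freq_hz * t[sel] + phase)
    for (ax in 1:3) {
      a[sel, ax] <- p$static_offset[ax] + osc * p$osc_axis[ax] +
        stats::rnorm(length(sel), 0, p$noise_sd_g)
    }
  }
  triaxial_series(t, a[, 1], a[, 2], a[, 3], fs = fs, sensor_kind = "accel")
}

#' Simulate a true heading series
#'
#' Wrapped Gaussian random walk at the sample rate, the simplest
#' movement-heading process with tunable tortuosity.
#'
#' @param duration_s Duration, seconds.
#' @param fs Sampling rate, Hz.
#' @param turn_sd_deg Per-step SD of heading change, degrees.
#' @param seed Integer seed.
#' @param init_deg Initial heading; drawn uniformly if `NULL`.
#' @return Numeric vector of headings in `[0, 360)`, one per sample.
#' @export
simulate_headings <- function(duration_s, fs = 10, turn_sd_deg = 2,
                              seed = NULL, init_deg = NULL) {
  withr_seed(seed)
  n <- floor(duration_s * fs + 1e-9)
  if (is.null(init_deg)) init_deg <- stats::runif(1L, 0, 360)
  wrap360(init_deg + cumsum(c(0, stats::rnorm(n - 1L, 0, turn_sd_deg))))
}

#' Simulate magnetometer readings under known distortion
#'
#' The body-frame field is `t(R(heading, pitch, roll)) %*% f` with
#' `f = (h, 0, v)` in NED world coordinates (h horizontal, v vertical
#' downward component), then distorted as
#' `m_raw = A %*% m_true + b + noise`. With identity iron, a level tag
#' at heading 0 reads the full horizontal component on its x axis; at
#' heading 90 the horizontal field appears along -y (documented axis
#' convention: x forward, y right, z down).
#'
#' @param true_headings_deg Heading per sample, degrees.
#' @param pitch_deg,roll_deg Attitude per sample (scalar or vector),
#'   degrees.
#' @param field_vector Length-2 numeric `c(h, v)`: horizontal and
#'   vertical (downward-positive) field components, in normalized field
#'   units.
#' @param iron `NULL` for no distortion, or `list(A = 3x3, b = 3-vector)`
#'   soft-/hard-iron distortion applied to the true field.
#' @param noise_sd Gaussian noise SD in field units.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @return A magnetometer [triaxial_series()].
#' @export
simulate_magnetometer <- function(true_headings_deg, pitch_deg = 0,
                                  roll_deg = 0,
                                  field_vector = c(h = 0.41, v = 0.91),
                                  iron = NULL, noise_sd = 0, fs = 10,
                                  seed = NULL) {
  n <- length(true_headings_deg)
  stopifnot(n >= 2L, length(field_vector) == 2L)
  pitch_deg <- rep_len(pitch_deg, n)
  roll_deg <- rep_len(roll_deg, n)
  f <- c(field_vector[[1]], 0, field_vector[[2]])
  if (is.null(iron)) iron <- list(A = diag(3), b = c(0, 0, 0))
  if (abs(det(iron$A)) < 1e-12) stop("singular soft-iron matrix A")
  withr_seed(seed)
  m <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    R <- body_to_world(true_headings_deg[i], pitch_deg[i], roll_deg[i])
    m[i, ] <- iron$A %*% (t(R) %*% f) + iron$b
  }
  if (noise_sd > 0) m <- m + matrix(stats::rnorm(3L * n, 0, noise_sd), n, 3L)
  t <- (seq_len(n) - 1L) / fs
  triaxial_series(t, m[, 1], m[, 2], m[, 3], fs = fs, sensor_kind = "mag")
}

#' Simulate accelerometer readings for a given attitude
#'
#' Returns the static specific force `g * (sin(pitch),
#' -sin(roll)cos(pitch), -cos(roll)cos(pitch))` per sample plus optional
#' noise: what an ideal accelerometer reads when the tag holds the given
#' pitch/roll.
#'
#' @param pitch_deg,roll_deg Attitude per sample (scalar or vector),
#'   degrees.
#' @param n Number of samples (defaults to the longer attitude vector).
#' @param fs Sampling rate, Hz.
#' @param noise_sd Gaussian noise SD, g.
#' @param seed Integer seed.
#' @return An accelerometer [triaxial_series()].
#' @export
simulate_attitude_accel <- function(pitch_deg = 0, roll_deg = 0, n = NULL,
                                    fs = 10, noise_sd = 0, seed = NULL) {
  if (is.null(n)) n <- max(length(pitch_deg), length(roll_deg), 2L)
  pitch <- deg2rad(rep_len(pitch_deg, n))
  roll <- deg2rad(rep_len(roll_deg, n))
  withr_seed(seed)
  ax <- sin(pitch)
  ay <- -sin(roll) * cos(pitch)
  az <- -cos(roll) * cos(pitch)
  if (noise_sd > 0) {
    ax <- ax + stats::rnorm(n, 0, noise_sd)
    ay <- ay + stats::rnorm(n, 0, noise_sd)
    az <- az + stats::rnorm(n, 0, noise_sd)
  }
  t <- (seq_len(n) - 1L) / fs
  triaxial_series(t, ax, ay, az, fs = fs, sensor_kind = "accel")
}

#' Simulate a magnetometer calibration rotation
#'
#' Emulates rotating a collar freely through three-dimensional space:
#' uniformly random orientations, so the true field vectors cover the
#' sphere of radius `|field_vector|`, then distorted by the supplied
#' iron parameters.
#'
#' @param iron `list(A, b)` distortion, or `NULL` for none.
#' @param field_vector `c(h, v)` field components as in
#'   [simulate_magnetometer()].
#' @param duration_s Duration of the rotation, seconds.
#' @param fs Sampling rate, Hz.
#' @param noise_sd Gaussian noise SD, field units.
#' @param seed Integer seed.
#' @return A magnetometer [triaxial_series()].
#' @export
simulate_calibration_rotation <- function(iron = NULL,
                                          field_vector = c(h = 0.41, v = 0.91),
                                          duration_s = 300, fs = 10,
                                          noise_sd = 0, seed = NULL) {
  withr_seed(seed)
  n <- floor(duration_s * fs + 1e-9)
  f <- c(field_vector[[1]], 0, field_vector[[2]])
  if (is.null(iron)) iron <- list(A = diag(3), b = c(0, 0, 0))
  if (abs(det(iron$A)) < 1e-12) stop("singular soft-iron matrix A")
  Rs <- random_rotations(n)
  m <- t(vapply(Rs, function(R) as.numeric(iron$A %*% (t(R) %*% f) + iron$b),
                numeric(3)))
  if (noise_sd > 0) m <- m + matrix(stats::rnorm(3L * n, 0, noise_sd), n, 3L)
  t <- (seq_len(n) - 1L) / fs
  triaxial_series(t, m[, 1], m[, 2], m[, 3], fs = fs, sensor_kind = "mag")
}

#' Simulate a ground-truth track and sparse GPS fixes
#'
#' Integrates the per-class profile speed along the true heading at each
#' step to produce true positions in local east/north meters, then emits
#' GPS fixes every `gps_interval_s` as true position plus isotropic
#' Gaussian noise, converted to latitude/longitude about `origin`.
#'
#' @param ethogram Ethogram data frame.
#' @param profiles Named list of [behavior_profile()] objects.
#' @param true_headings Heading per step, degrees (length = steps in the
#'   ethogram span).
#' @param fs Sampling rate, Hz.
#' @param gps_interval_s Interval between fixes, seconds (the field
#'   protocol this emulates used 30-min fixes; tests use shorter).
#' @param gps_noise_m Isotropic Gaussian noise SD of the fixes, meters.
#' @param seed Integer seed.
#' @param origin `c(lat, lon)` of the local frame origin.
#' @return A list of class `sim_truth` with elements `ethogram`,
#'   `true_headings`, `positions` (data frame `t`, `east_m`, `north_m`),
#'   `origin`, and `gps` (data frame `t`, `lat`, `lon`).
#' @export
simulate_track_and_gps <- function(ethogram, profiles, true_headings,
                                   fs = 10, gps_interval_s = 60,
                                   gps_noise_m = 3, seed = NULL,
                                   origin = c(lat = 49.9646, lon = 14.8374)) {
  stopifnot(gps_interval_s > 0)
  ethogram <- validate_ethogram(ethogram)
  classes <- vapply(profiles, `[[`, character(1), "class")
  speeds <- stats::setNames(vapply(profiles, `[[`, numeric(1), "speed_mps"),
                            classes)
  ev <- data.frame(behavior = ethogram$behavior,
                   t_start = ethogram$t_start, t_end = ethogram$t_end)
  sp <- speed_series(ev, speeds, fs)
  n <- nrow(sp)
  stopifnot(length(true_headings) == n)
  track <- integrate_track(true_headings, sp$speed, fs, t0 = sp$t[1L])
  withr_seed(seed)
  t_fix <- seq(track$t[1L], track$t[nrow(track)], by = gps_interval_s)
  east <- stats::approx(track$t, track$east_m, xout = t_fix)$y +
    stats::rnorm(length(t_fix), 0, gps_noise_m)
  north <- stats::approx(track$t, track$north_m, xout = t_fix)$y +
    stats::rnorm(length(t_fix), 0, gps_noise_m)
  ll <- enu_to_latlon(east, north, origin)
  structure(list(ethogram = ethogram, true_headings = true_headings,
                 positions = track, origin = origin,
                 gps = data.frame(t = t_fix, lat = ll$lat, lon = ll$lon)),
            class = "sim_truth")
}

#' Simulate one collared individual
#'
#' Convenience wrapper generating a behavior sequence and its
#' acceleration, optionally recorded in a different (rotated) collar
#' frame to emulate tags mounted in different orientations.
#'
#' @param profiles Named list of [behavior_profile()] objects.
#' @param duration_s Duration, seconds.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @param collar_rotation Optional 3x3 rotation; the recorded series is
#'   `collar_rotation %*% v` for each body-frame sample `v`. Pass its
#'   transpose to [rotate_frame()] to map recordings back to the body
#'   frame.
#' @return List with elements `ethogram` and `accel`.
#' @export
simulate_individual <- function(profiles, duration_s, fs = 10, seed = NULL,
                                collar_rotation = NULL) {
  eth <- simulate_behavior_sequence(profiles, duration_s, seed = seed)
  acc <- simulate_acceleration(eth, profiles, fs = fs,
                               seed = if (is.null(seed)) NULL else seed + 1L)
  if (!is.null(collar_rotation)) acc <- rotate_frame(acc, collar_rotation)
  list(ethogram = eth, accel = acc)
}
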