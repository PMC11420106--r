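# Iron calibration, gravity estimation, tilt-compensated headings and
# the circular statistics used to validate them.

FIELD <- c(h = 0.41, v = 0.91)
FIELD_NORM <- sqrt(sum(FIELD^2))

test_that("ellipsoid fit recovers injected iron parameters", {
  A <- diag(c(1.1, 0.9, 1.0))
  b <- c(0.2, -0.1, 0.05)
  cal_data <- simulate_calibration_rotation(iron = list(A = A, b = b),
                                            field_vector = FIELD, seed = 5)
  cal <- fit_iron_calibration(cal_data)
  # hard-iron offset within 1% of the field magnitude
  expect_lt(max(abs(cal$b - b)), 0.01 * FIELD_NORM)
  # soft-iron correction inverts A up to the inherent radius scale
  P <- cal$A_inv %*% A
  sc <- mean(diag(P))
  expect_lt(max(abs(P - sc * diag(3))), 0.01 * FIELD_NORM)
  # calibrated norms are constant (CV < 5%; noiseless data: ~0)
  calib <- apply_calibration(cal_data, cal)
  nrm <- sqrt(rowSums(xyz(calib)^2))
  expect_lt(sd(nrm) / mean(nrm), 0.05)
})

test_that("an undistorted sphere fits to identity calibration", {
  cal_data <- simulate_calibration_rotation(field_vector = FIELD, seed = 6)
  cal <- fit_iron_calibration(cal_data, field_norm = FIELD_NORM)
  expect_lt(max(abs(cal$b)), 1e-8)
  expect_equal(cal$A_inv, diag(3), tolerance = 1e-6)
})

test_that("near-planar calibration coverage is rejected with a diagnostic", {
  # rotation about a single axis only: scatter lies on a circle
  h <- seq(0, 359, length.out = 300)
  flat <- simulate_magnetometer(h, 0, 0, field_vector = FIELD)
  expect_error(fit_iron_calibration(flat), "planar")
})

test_that("calibration application is the documented affine correction", {
  s <- simulate_calibration_rotation(field_vector = FIELD, seed = 7)
  expect_equal(apply_calibration(s, identity_calibration()), s)
  A <- matrix(c(1.05, 0.02, 0, 0.02, 0.95, 0.01, 0, 0.01, 1.0), 3, 3)
  b <- c(0.1, 0.2, -0.05)
  distorted <- s
  v <- xyz(s) %*% t(A)
  distorted$x <- v[, 1] + b[1]
  distorted$y <- v[, 2] + b[2]
  distorted$z <- v[, 3] + b[3]
  cal <- structure(list(b = b, A_inv = solve(A), field_norm = FIELD_NORM),
                   class = "iron_calibration")
  back <- apply_calibration(distorted, cal)
  expect_equal(xyz(back), xyz(s), tolerance = 1e-10)
})

test_that("gravity estimation recovers the static direction under gait", {
  # static tag: gravity equals the (normalized) static acceleration
  s <- simulate_attitude_accel(20, -15, n = 100)
  g <- estimate_gravity(s)
  expect_equal(sqrt(rowSums(xyz(g)^2)), rep(1, 100), tolerance = 1e-12)
  expect_equal(g$x, s$x, tolerance = 1e-9)
  # smoothing of one sample period is the identity up to normalization
  g1 <- estimate_gravity(s, smoothing_s = 0.1)
  expect_equal(xyz(g1), xyz(s), tolerance = 1e-9)
  # static + 2.8 Hz oscillation, 2-s smoothing: direction error < 5 deg
  truth <- c(sin(deg2rad <- 20 * pi / 180), 0, -cos(20 * pi / 180))
  osc <- sin(2 * pi * 2.8 * (0:499) / 10)
  s2 <- triaxial_series((0:499) / 10,
                        truth[1] + 0.8 * osc, truth[2] + 0.2 * osc,
                        truth[3] + 0.8 * osc, fs = 10)
  g2 <- estimate_gravity(s2, smoothing_s = 2)
  cosang <- xyz(g2) %*% truth
  ang <- acos(pmin(1, cosang)) * 180 / pi
  expect_lt(median(ang), 5)
})

test_that("tilt-compensated headings anchor to the frame convention", {
  # level tag, x toward magnetic north: heading 0
  m <- simulate_magnetometer(rep(0, 10), 0, 0, field_vector = FIELD)
  g <- estimate_gravity(simulate_attitude_accel(0, 0, n = 10), 0.1)
  h <- tilt_compensated_heading(m, g)
  expect_equal(h$heading_deg, rep(0, 10), tolerance = 1e-9)
  expect_true(all(h$valid))
  # rotated 90 degrees clockwise: heading 90
  m90 <- simulate_magnetometer(rep(90, 10), 0, 0, field_vector = FIELD)
  h90 <- tilt_compensated_heading(m90, g)
  expect_equal(h90$heading_deg, rep(90, 10), tolerance = 1e-9)
  # declination shifts the output
  hd <- tilt_compensated_heading(m90, g, declination_deg = 4)
  expect_equal(hd$heading_deg, rep(94, 10), tolerance = 1e-9)
})

test_that("headings are invariant to tilt across a grid up to 45 degrees", {
  for (pitch in c(-45, -20, 0, 30, 45)) {
    for (roll in c(-45, 0, 20, 45)) {
      m <- simulate_magnetometer(rep(137, 5), pitch, roll,
                                 field_vector = FIELD)
      g <- estimate_gravity(simulate_attitude_accel(pitch, roll, n = 5), 0.1)
      h <- tilt_compensated_heading(m, g)
      expect_lt(max(abs(wrap180(h$heading_deg - 137))), 0.5)
    }
  }
})

test_that("heading errors wrap to the signed half-circle", {
  expect_equal(heading_error(359, 1), -2)
  expect_equal(heading_error(1, 359), 2)
  expect_equal(heading_error(180, 0), 180)
  th <- seq(0, 355, by = 5)
  expect_equal(heading_error(th + 360, th), rep(0, length(th)))
})

test_that("circular median minimizes circular deviation over data points", {
  expect_equal(circular_median(c(10, 20, 30)), 20)
  expect_equal(circular_median(c(350, 0, 10)), 0)  # wraparound
  expect_equal(circular_median(42), 42)
  expect_error(circular_median(numeric(0)), "empty")
  # exhaustive-candidate oracle on seeded draws
  set.seed(31)
  for (rep_i in 1:20) {
    a <- runif(15, 0, 360)
    got <- circular_median(a)
    devs <- sapply(a, function(c0) mean(abs(wrap180(a - c0))))
    best <- min(devs)
    expect_equal(mean(abs(wrap180(a - got))), best, tolerance = 1e-12)
  }
})

test_that("bootstrap CI of the circular median behaves as expected", {
  expect_equal(unname(bootstrap_median_ci(rep(2, 10), n_boot = 500, seed = 1)),
               c(2, 2))
  # symmetric errors: interval straddles zero
  errs <- c(-5, 5, -4, 4, -3, 3, -2, 2, -1, 1, 0)
  ci <- bootstrap_median_ci(errs, n_boot = 2000, seed = 4)
  expect_lte(ci[["lo"]], 0)
  expect_gte(ci[["hi"]], 0)
  # determinism under the seed
  expect_identical(bootstrap_median_ci(errs, n_boot = 1000, seed = 9),
                   bootstrap_median_ci(errs, n_boot = 1000, seed = 9))
  expect_error(bootstrap_median_ci(1), "at least 2")
})

test_that("cardinal evaluation recovers condition medians and pooled error", {
  perfect <- list(`0` = rep(0, 5), `90` = rep(90, 5),
                  `180` = rep(180, 5), `270` = rep(270, 5))
  ev <- lab_cardinal_evaluation(perfect)
  expect_equal(ev$per_condition$median_deg, c(0, 90, 180, 270))
  expect_equal(ev$overall_median_abs_error_deg, 0)
  # single sample per condition: median is that sample
  one <- lab_cardinal_evaluation(list(`0` = 3.2))
  expect_equal(one$per_condition$median_deg, 3.2)
  # gaussian noise sd 2 deg: pooled median |error| near the half-normal
  # median 0.674 * sd
  set.seed(41)
  noisy <- lapply(c(0, 90, 180, 270), function(e) wrap360(e + rnorm(100, 0, 2)))
  names(noisy) <- c(0, 90, 180, 270)
  evn <- lab_cardinal_evaluation(noisy)
  expect_gt(evn$overall_median_abs_error_deg, 1)
  expect_lt(evn$overall_median_abs_error_deg, 3)
})

test_that("the uniformity test matches car's multivariate hypothesis test", {
  set.seed(9)
  h <- runif(45, 0, 360)
  ep <- runif(45)
  r <- uniform_error_test(h, ep)
  th <- h * pi / 180
  m <- lm(cbind(cos(th), sin(th)) ~ ep)
  lh <- car::linearHypothesis(m, "(Intercept) = 0")
  T_ <- sum(diag(lh$SSPH %*% solve(lh$SSPE)))
  F_car <- T_ * (lh$df.residual - 2 + 1) / 2
  expect_equal(r$F_intercept, F_car, tolerance = 1e-10)
  # slope term against base R's multivariate anova
  sl <- anova(m, test = "Hotelling-Lawley")
  expect_equal(r$F_slope, sl["ep", "approx F"], tolerance = 1e-10)
})

test_that("the uniformity test holds its nominal level and detects clustering", {
  # type-I error under the null: uniform headings, independent covariate
  set.seed(17)
  keep <- logical(100)
  for (i in 1:100) {
    h <- runif(300, 0, 360)
    ep <- runif(300)
    keep[i] <- uniform_error_test(h, ep)$p_intercept > 0.05
  }
  expect_gte(mean(keep), 0.9)
  # concentrated headings: intercept strongly significant
  set.seed(18)
  rc <- uniform_error_test(rep(45, 50) + rnorm(50, 0, 2), runif(50))
  expect_lt(rc$p_intercept, 1e-10)
  # degenerate inputs
  expect_error(uniform_error_test(c(1, 2, 3), c(1, 2, 3)), "more than 3")
  const <- uniform_error_test(runif(20, 0, 360), rep(0.5, 20))
  expect_true(is.na(const$F_slope))
  expect_false(is.na(const$F_intercept))
})

test_that("observer predictions combine on the circle under the threshold", {
  out <- average_observer_headings(c(10, 350, 100), c(20, 8, 140))
  expect_equal(out[1], 15)
  expect_equal(out[2], 359)  # circular mean across north
  expect_true(is.na(out[3]))  # 40-degree disagreement needs review
  # a disagreement of exactly the threshold is not averaged
  expect_true(is.na(average_observer_headings(0, 20)))
})

test_that("calibrated tilt-compensated headings recover synthetic truth", {
  A <- matrix(c(1.1, 0.03, 0, 0.03, 0.9, 0.02, 0, 0.02, 1.0), 3, 3)
  b <- c(0.2, -0.1, 0.05)
  cal <- fit_iron_calibration(
    simulate_calibration_rotation(iron = list(A = A, b = b),
                                  field_vector = FIELD, seed = 8))
  hs <- simulate_headings(60, seed = 9)
  for (noise in c(0, 0.002, 0.01)) {
    mag <- simulate_magnetometer(hs, 25, -15, field_vector = FIELD,
                                 iron = list(A = A, b = b),
                                 noise_sd = noise, seed = 10)
    grav <- estimate_gravity(simulate_attitude_accel(25, -15, n = length(hs)))
    h <- tilt_compensated_heading(apply_calibration(mag, cal), grav)
    err <- abs(heading_error(h$heading_deg, hs))
    if (noise == 0) {
      expect_lt(median(err), 1)
      med0 <- median(err)
    } else if (noise == 0.002) {
      med1 <- median(err)
      expect_gte(med1, med0)
    } else {
      expect_gte(median(err), med1)  # degrades monotonically with noise
    }
  }
})
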