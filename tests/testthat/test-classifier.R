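# Frame rotation, k-NN training/prediction and sliding-window
# classification.

test_that("frame rotations parse, validate and compose", {
  expect_equal(frame_rotation("x:x,y:y,z:z"), diag(3))
  R <- frame_rotation("x:-z,y:y,z:x")
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1)
  # quarter-turn about z applied twice is the half-turn
  Rq <- frame_rotation("x:y,y:-x,z:z")
  expect_equal(Rq %*% Rq, frame_rotation("x:-x,y:-y,z:z"))
  # reflections and non-orthonormal matrices are rejected
  expect_error(frame_rotation("x:x,y:y,z:-z"), "reflection")
  expect_error(frame_rotation(matrix(1, 3, 3)), "orthonormal")
})

test_that("rotate_frame applies R to every sample and round-trips", {
  s <- triaxial_series((0:49) / 10, sin(1:50), cos(1:50), rep(-1, 50), fs = 10)
  expect_equal(rotate_frame(s, diag(3)), s)
  R <- frame_rotation("x:-z,y:y,z:x")
  r <- rotate_frame(s, R)
  expect_equal(r$x, -s$z)
  expect_equal(r$z, s$x)
  back <- rotate_frame(r, t(R))
  expect_equal(xyz(back), xyz(s), tolerance = 1e-12)
})

test_that("training validates inputs and separable classes self-classify", {
  d <- make_two_class_features(n_per = 100, seed = 1)
  model <- train_classifier(d$X, d$labels)
  pred <- predict_features(model, d$X)$predicted
  expect_gte(mean(pred == d$labels), 0.99)
  # a duplicated training row finds its own label among its neighbors
  p <- predict_step(model, d$X[1, ])
  expect_gt(p$neighbor_proportions[["Rest"]], 0)
  # fewer rows than neighbors is an error
  cfg <- pipeline_config(k_neighbors = 5)
  expect_error(train_classifier(matrix(rnorm(4 * 18), 4, 18),
                                rep("Rest", 4), cfg), "k exceeds")
  expect_error(train_classifier(d$X, rep("Sleep", 200)), "unknown class")
})

test_that("neighbor proportions sum to one and drive the vote", {
  d <- make_two_class_features(n_per = 50, seed = 2)
  model <- train_classifier(d$X, d$labels)
  for (i in c(1, 25, 60, 99)) {
    p <- predict_step(model, d$X[i, ])
    expect_equal(sum(p$neighbor_proportions), 1, tolerance = 1e-12)
    expect_equal(p$predicted,
                 names(which.max(p$neighbor_proportions))[1])
  }
})

test_that("plurality ties resolve by summed distance then alphabetically", {
  # hand-built model with a trivial 2-component projection so neighbor
  # coordinates are controlled exactly
  make_model <- function(points, labels) {
    L <- matrix(0, 18, 2)
    L[1, 1] <- 1
    L[2, 2] <- 1
    proj <- structure(list(mean = rep(0, 18), sd = rep(1, 18),
                           loadings = L, m = 2L,
                           eigenvalues = rep(1, 18),
                           variance_retained = 0.95),
                      class = "projection_model")
    structure(list(projection = proj, points = points, labels = labels,
                   k = 5L, metric = "cityblock",
                   classes = sort(unique(labels))),
              class = "knn_classifier")
  }
  # neighbors of the origin query: Run at distances 1.0 + 1.5, Rest at
  # 1.0 + 1.2, Stand at 2.4, plus one far-away Walk point
  pts <- rbind(c(-1.0, 0), c(-1.5, 0), c(1.0, 0), c(1.2, 0), c(0, 2.4),
               c(9, 5))
  labels <- c("Run", "Run", "Rest", "Rest", "Stand", "Walk")
  model <- make_model(pts, labels)
  p <- predict_step(model, rep(0, 18))
  expect_equal(p$predicted, "Rest")  # 2-2 tie, smaller summed distance
  expect_equal(sum(p$neighbor_proportions), 1, tolerance = 1e-12)
  expect_equal(p$neighbor_proportions[["Rest"]], 0.4)
  expect_equal(p$neighbor_proportions[["Run"]], 0.4)
  expect_equal(p$neighbor_proportions[["Stand"]], 0.2)
  # exactly equal summed distances: alphabetical order wins
  pts2 <- rbind(c(-1.0, 0), c(-1.2, 0), c(1.0, 0), c(1.2, 0), c(0, 2.4),
                c(9, 5))
  labels2 <- c("Run", "Run", "Stand", "Stand", "Forage", "Walk")
  p2 <- predict_step(make_model(pts2, labels2), rep(0, 18))
  expect_equal(p2$predicted, "Run")  # "Run" < "Stand" alphabetically
})

test_that("k-NN equals the exhaustive-scan oracle under both metrics", {
  d <- make_two_class_features(n_per = 60, sep = 2, seed = 3)
  set.seed(33)
  queries <- matrix(rnorm(200 * 18, mean = 1), 200, 18)
  for (metric in c("cityblock", "euclidean")) {
    cfg <- pipeline_config(distance_metric = metric)
    model <- train_classifier(d$X, d$labels, cfg)
    Q <- project(queries, model$projection)
    got <- predict_features(model, queries)$predicted
    want <- vapply(seq_len(nrow(Q)), function(i) {
      oracle_knn_predict(model$points, model$labels, Q[i, ], 5, metric)
    }, character(1))
    expect_identical(got, want)
  }
})

test_that("stream classification slides a full symmetric window", {
  fs <- 10
  p <- default_behavior_profiles()
  train <- simulate_individual(p, 1200, seed = 41)
  w <- make_training_windows(train$accel, train$ethogram)
  fm <- extract_feature_matrix(w)
  model <- train_classifier(fm$features, fm$labels)

  eth <- data.frame(behavior = "Rest", t_start = 0, t_end = 10, source = "sim")
  s <- simulate_acceleration(eth, p, fs, seed = 42)
  pred <- classify_stream(model, s)
  # one prediction per sample whose window fits: n - window*fs + 1
  expect_equal(nrow(pred), length(s$t) - 4 * fs + 1)
  expect_true(all(pred$predicted == "Rest"))
  # determinism
  pred2 <- classify_stream(model, s)
  expect_identical(pred, pred2)
  # series shorter than the window -> empty output
  short <- triaxial_series((0:19) / fs, rnorm(20), rnorm(20), rnorm(20), fs)
  expect_equal(nrow(classify_stream(model, short)), 0L)
})

test_that("classifying a rotated stream with its correction matches unrotated", {
  fs <- 10
  p <- default_behavior_profiles()
  train <- simulate_individual(p, 1200, seed = 51)
  fm <- extract_feature_matrix(make_training_windows(train$accel, train$ethogram))
  model <- train_classifier(fm$features, fm$labels)
  eth <- data.frame(behavior = "Walk", t_start = 0, t_end = 12, source = "sim")
  s <- simulate_acceleration(eth, p, fs, seed = 52)
  R <- frame_rotation("x:y,y:-x,z:z")
  s_collar <- rotate_frame(s, t(R))  # recorded in a rotated collar frame
  a <- classify_stream(model, s)
  b <- classify_stream(model, s_collar, R = R)
  expect_equal(a$predicted, b$predicted)
})

test_that("models serialize to JSON and reload losslessly", {
  d <- make_two_class_features(n_per = 30, seed = 6)
  model <- train_classifier(d$X, d$labels)
  path <- tempfile(fileext = ".json")
  write_classifier(model, path)
  m2 <- read_classifier(path)
  set.seed(61)
  q <- matrix(rnorm(10 * 18), 10, 18)
  expect_equal(predict_features(model, q), predict_features(m2, q))
})

test_that("grid-search tuning evaluates the requested grid", {
  d <- make_two_class_features(n_per = 60, seed = 7)
  res <- tune_classifier(d$X, d$labels, k_grid = c(1, 5),
                         metrics = "cityblock", seed = 2)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$accuracy >= 0.9))  # well-separated classes
})
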