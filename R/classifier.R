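# k-nearest-neighbor behavioral classification in principal-component
# space, with cross-collar frame correction and per-step sliding-window
# prediction.

#' Build a frame rotation from a signed-axis mapping
#'
#' Collars mounted in different orientations record the same body motion
#' in permuted/negated axes. A mapping string such as `"x:-z,y:y,z:x"`
#' ("training-frame x is minus the recorded z", etc.) is converted to
#' the 3x3 rotation matrix that maps recorded vectors into the training
#' frame. The result must be a proper rotation (orthonormal,
#' determinant +1).
#'
#' @param mapping Mapping string, or a 3x3 matrix passed through after
#'   validation.
#' @return 3x3 rotation matrix.
#' @export
frame_rotation <- function(mapping) {
  if (is.matrix(mapping)) {
    R <- mapping
  } else {
    parts <- strsplit(gsub("\\s", "", mapping), ",")[[1L]]
    if (length(parts) != 3L) stop("mapping must define x, y and z")
    R <- matrix(0, 3L, 3L)
    axes <- c(x = 1L, y = 2L, z = 3L)
    for (p in parts) {
      kv <- strsplit(p, ":")[[1L]]
      if (length(kv) != 2L) stop("bad mapping component: ", p)
      row <- axes[[kv[1L]]]
      sign <- if (startsWith(kv[2L], "-")) -1 else 1
      col <- axes[[sub("^[-+]", "", kv[2L])]]
      R[row, col] <- sign
    }
  }
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal")
  if (det(R) < 0) stop("mapping is a reflection, not a rotation")
  R
}

#' Rotate a triaxial series into another coordinate frame
#'
#' Replaces each sample `(x, y, z)` by `R %*% (x, y, z)`; timestamps
#' are unchanged. Used to map recordings from differently mounted
#' collars into the coordinate frame the classifier was trained in.
#'
#' @param series A [triaxial_series()].
#' @param R 3x3 orthonormal rotation matrix (or a mapping string
#'   accepted by [frame_rotation()]).
#' @return The rotated [triaxial_series()].
#' @export
rotate_frame <- function(series, R) {
  R <- frame_rotation(R)
  v <- xyz(series) %*% t(R)
  series$x <- v[, 1L]; series$y <- v[, 2L]; series$z <- v[, 3L]
  series
}

# Internal: exhaustive nearest-neighbor search. Returns per-query index
# and distance matrices (n_query x k). Distance ties at the k-th
# neighbor are resolved by stable index order (order() is stable).
knn_search <- function(points, queries, k, metric = "cityblock") {
  stopifnot(metric %in% c("cityblock", "euclidean"))
  tp <- t(points)
  nq <- nrow(queries)
  idx <- matrix(0L, nq, k)
  dist <- matrix(0, nq, k)
  for (i in seq_len(nq)) {
    dif <- tp - queries[i, ]
    d <- if (metric == "cityblock") colSums(abs(dif)) else sqrt(colSums(dif^2))
    o <- order(d)[seq_len(k)]
    idx[i, ] <- o
    dist[i, ] <- d[o]
  }
  list(idx = idx, dist = dist)
}

#' Train the k-NN behavioral classifier
#'
#' Fits the standardization/PCA projection on the training feature
#' matrix and stores the projected training points with their labels.
#'
#' @param features_matrix Numeric feature matrix (rows = observations).
#' @param labels Character vector of behavioral classes, one per row.
#' @param config A [pipeline_config()] (supplies k, metric and the
#'   retained-variance threshold).
#' @return Object of class `knn_classifier`: list with `projection`,
#'   `points` (n x m), `labels`, `k`, `metric`, `classes`.
#' @export
train_classifier <- function(features_matrix, labels,
                             config = pipeline_config()) {
  X <- as.matrix(features_matrix)
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stop("one label per feature row required")
  bad <- unique(labels[!is_behavior_class(labels)])
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  if (config$k_neighbors > nrow(X))
    stop("k exceeds the number of training observations")
  proj <- fit_projection(X, config$pca_variance_retained)
  structure(list(projection = proj, points = project(X, proj),
                 labels = labels, k = config$k_neighbors,
                 metric = config$distance_metric,
                 classes = canonical_class_order(unique(labels))),
            class = "knn_classifier")
}

#' @export
print.knn_classifier <- function(x, ...) {
  cat(sprintf("<knn_classifier: n=%d, %d components, k=%d, %s distance, %d classes>\n",
              nrow(x$points), ncol(x$points), x$k, x$metric,
              length(x$classes)))
  invisible(x)
}

# Internal: vote among neighbor labels. Plurality; a plurality tie goes
# to the tied class with the smaller summed neighbor distance, a
# remaining tie to alphabetical order.
vote_neighbors <- function(nb_labels, nb_dists, classes, k) {
  counts <- table(factor(nb_labels, levels = classes))
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L) {
    sums <- vapply(top, function(cl) sum(nb_dists[nb_labels == cl]),
                   numeric(1))
    top <- top[sums == min(sums)]
    top <- sort(top)
  }
  list(predicted = top[1L],
       proportions = as.numeric(counts) / k)
}

#' Classify a single feature vector
#'
#' Projects the 18-feature vector with the training standardization and
#' loadings, finds the k nearest training points under the configured
#' metric, and returns the plurality class together with the neighbor
#' class proportions (class counts / k, summing to 1).
#'
#' @param model A [train_classifier()] model.
#' @param feature_vector Numeric vector of raw (unstandardized)
#'   features.
#' @return List with `predicted` and named `neighbor_proportions`.
#' @export
predict_step <- function(model, feature_vector) {
  q <- project(feature_vector, model$projection)
  nn <- knn_search(model$points, q, model$k, model$metric)
  v <- vote_neighbors(model$labels[nn$idx[1L, ]], nn$dist[1L, ],
                      model$classes, model$k)
  list(predicted = v$predicted,
       neighbor_proportions = stats::setNames(v$proportions, model$classes))
}

#' Classify many feature vectors
#'
#' Matrix version of [predict_step()].
#'
#' @param model A [train_classifier()] model.
#' @param features_matrix Raw feature matrix, one observation per row.
#' @return Data frame with column `predicted` plus one proportion
#'   column `p_<class>` per model class.
#' @export
predict_features <- function(model, features_matrix) {
  Q <- project(as.matrix(features_matrix), model$projection)
  nn <- knn_search(model$points, Q, model$k, model$metric)
  n <- nrow(Q)
  pred <- character(n)
  props <- matrix(0, n, length(model$classes))
  for (i in seq_len(n)) {
    v <- vote_neighbors(model$labels[nn$idx[i, ]], nn$dist[i, ],
                        model$classes, model$k)
    pred[i] <- v$predicted
    props[i, ] <- v$proportions
  }
  out <- data.frame(predicted = pred)
  colnames(props) <- paste0("p_", model$classes)
  cbind(out, as.data.frame(props))
}

#' Per-step sliding-window classification of a sensor stream
#'
#' Applies the frame rotation, then classifies at every possible time
#' step using a symmetric, noncausal window of `window_s` seconds: one
#' prediction per sample whose full window fits inside the series
#' (`n - window_s*fs + 1` predictions; no padding at the edges). Test
#' features are standardized with the training parameters stored in the
#' model.
#'
#' @param model A [train_classifier()] model.
#' @param series An accelerometer [triaxial_series()].
#' @param R Frame rotation mapping the series into the training frame
#'   (matrix or mapping string); identity by default.
#' @param window_s Window length, seconds.
#' @param band_edges Band edges used at training time.
#' @return Data frame of step predictions: `t` (window center time),
#'   `predicted`, and `p_<class>` neighbor-proportion columns, with the
#'   sampling rate in attribute `"fs"`. Empty (zero rows) when the
#'   series is shorter than the window.
#' @export
classify_stream <- function(model, series, R = diag(3), window_s = 4,
                            band_edges = default_band_edges(series$fs)) {
  series <- rotate_frame(series, R)
  fs <- series$fs
  nw <- as.integer(round(window_s * fs))
  n <- length(series$t)
  empty <- data.frame(t = numeric(0), predicted = character(0))
  if (n < nw) return(structure(empty, fs = fs))
  vals <- xyz(series)
  half <- nw %/% 2L
  starts <- seq_len(n - nw + 1L)
  feats <- t(vapply(starts, function(s) {
    extract_features(vals[s:(s + nw - 1L), , drop = FALSE], fs, band_edges)
  }, numeric(18L)))
  out <- predict_features(model, feats)
  out <- cbind(data.frame(t = series$t[starts + half]), out)
  attr(out, "fs") <- fs
  out
}

#' Grid-search hyperparameter selection on a holdout split
#'
#' Optional utility evaluating windowed accuracy over a grid of
#' neighbor counts and distance metrics on a random holdout subset of
#' the labeled observations. Defaults of the pipeline remain k = 5 with
#' cityblock distance regardless of this utility.
#'
#' @param features_matrix Raw feature matrix.
#' @param labels Class labels, one per row.
#' @param k_grid Candidate neighbor counts.
#' @param metrics Candidate distance metrics.
#' @param holdout_frac Fraction of rows held out for evaluation.
#' @param seed Integer seed for the split.
#' @param config Base [pipeline_config()].
#' @return Data frame of `k`, `metric`, `accuracy`, sorted best-first.
#' @export
tune_classifier <- function(features_matrix, labels,
                            k_grid = c(1, 3, 5, 7, 9),
                            metrics = c("cityblock", "euclidean"),
                            holdout_frac = 0.2, seed = 1,
                            config = pipeline_config()) {
  X <- as.matrix(features_matrix)
  withr_seed(seed)
  n <- nrow(X)
  hold <- sample.int(n, max(1L, round(holdout_frac * n)))
  res <- expand.grid(k = k_grid, metric = metrics,
                     stringsAsFactors = FALSE)
  res$accuracy <- NA_real_
  for (i in seq_len(nrow(res))) {
    cfg <- config
    cfg$k_neighbors <- res$k[i]
    cfg$distance_metric <- res$metric[i]
    m <- train_classifier(X[-hold, , drop = FALSE], labels[-hold], cfg)
    pred <- predict_features(m, X[hold, , drop = FALSE])$predicted
    res$accuracy[i] <- mean(pred == labels[hold])
  }
  res[order(-res$accuracy), ]
}

#' Save a trained classifier to a JSON container
#'
#' Schema (version 1): `version`, `k`, `metric`, `classes`, `labels`,
#' `points`, and the projection (`mean`, `sd`, `loadings`, `m`,
#' `eigenvalues`, `variance_retained`). Numbers are written at full
#' precision.
#'
#' @param model A [train_classifier()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(model, path) {
  obj <- list(version = 1L, k = model$k, metric = model$metric,
              classes = model$classes, labels = model$labels,
              points = model$points,
              projection = list(
                mean = model$projection$mean, sd = model$projection$sd,
                loadings = model$projection$loadings,
                m = model$projection$m,
                eigenvalues = model$projection$eigenvalues,
                variance_retained = model$projection$variance_retained))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a classifier saved by [write_classifier()]
#'
#' @param path Path to the JSON model file.
#' @return A `knn_classifier` model.
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$version) || obj$version != 1L)
    stop("unsupported model file version")
  proj <- structure(list(mean = obj$projection$mean, sd = obj$projection$sd,
                         loadings = as.matrix(obj$projection$loadings),
                         m = obj$projection$m,
                         eigenvalues = obj$projection$eigenvalues,
                         variance_retained = obj$projection$variance_retained),
                    class = "projection_model")
  structure(list(projection = proj, points = as.matrix(obj$points),
                 labels = obj$labels, k = obj$k, metric = obj$metric,
                 classes = obj$classes),
            class = "knn_classifier")
}
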