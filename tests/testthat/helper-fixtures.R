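# Shared fixtures: all test inputs are generated in code.

# Minimal sensor CSV on disk.
write_sensor_fixture <- function(n = 40, fs = 10, path = tempfile(fileext = ".csv"),
                                 t = (seq_len(n) - 1) / fs) {
  df <- data.frame(t = t, x = sin(t), y = cos(t), z = -1 + 0.01 * t)
  write.csv(df, path, row.names = FALSE)
  path
}

# Step-prediction data frame with degenerate (one-hot) proportions.
make_steps <- function(cls, fs = 10, t0 = 0) {
  n <- length(cls)
  if (n == 0L) {
    out <- data.frame(t = numeric(0), predicted = character(0))
    attr(out, "fs") <- fs
    return(out)
  }
  classes <- sort(unique(cls))
  P <- matrix(0, n, length(classes),
              dimnames = list(NULL, paste0("p_", classes)))
  P[cbind(seq_len(n), match(cls, classes))] <- 1
  out <- cbind(data.frame(t = t0 + (seq_len(n) - 1) / fs, predicted = cls),
               as.data.frame(P))
  attr(out, "fs") <- fs
  out
}

# Two well-separated point clouds in feature space for classifier tests.
make_two_class_features <- function(n_per = 100, p = 18, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = sep), n_per, p))
  labels <- rep(c("Rest", "Run"), each = n_per)
  list(X = X, labels = labels)
}

# Independent per-query exhaustive nearest-neighbor oracle (deliberately
# naive, no shared code with the package implementation).
oracle_knn_predict <- function(points, labels, query, k, metric) {
  d <- numeric(nrow(points))
  for (j in seq_len(nrow(points))) {
    dif <- points[j, ] - query
    d[j] <- if (metric == "cityblock") sum(abs(dif)) else sqrt(sum(dif^2))
  }
  nb <- order(d)[seq_len(k)]
  counts <- table(labels[nb])
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1) {
    sums <- sapply(top, function(cl) sum(d[nb][labels[nb] == cl]))
    top <- sort(top[sums == min(sums)])
  }
  top[1]
}

expect_angle_equal <- function(a, b, tol = 1e-6) {
  expect_lt(abs(boarlogger::wrap180(a - b)), tol)
}
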