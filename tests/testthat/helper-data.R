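# Fixtures are built in code; the heavier synthetic runs are memoized so
# several test files can share one generation + ranking per seed.

.fixture_cache <- new.env(parent = emptyenv())

# Table-1-proportioned synthetic dataset (2000 cells, 500 genes, 5 markers
# per class, marker_effect 8) with its gradient-boosting ranking.
synth_with_ranking <- function(seed) {
  key <- paste0("synth", seed)
  if (is.null(.fixture_cache[[key]])) {
    gd <- generate_dataset(spec_from_table1(2000, seed = seed))
    ranked <- rank_features(gd$data, seed = seed)
    .fixture_cache[[key]] <- list(data = gd$data, truth = gd$truth,
                                  ranked = ranked)
  }
  .fixture_cache[[key]]
}

# Small perfectly separable two-class dataset: gene sep01 encodes the class.
separable_dataset <- function(n_per_class = 30, n_noise_genes = 3, seed = 42) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    labels <- rep(c("A", "B"), each = n_per_class)
    sep <- ifelse(labels == "A", stats::runif(n, 0, 1), stats::runif(n, 2, 3))
    noise <- matrix(stats::runif(n * n_noise_genes, 0, 5), nrow = n)
    m <- cbind(sep, noise)
    colnames(m) <- c("sep01", paste0("noise", seq_len(n_noise_genes)))
  })
  expression_dataset(m, sprintf("c%03d", seq_len(nrow(m))), colnames(m),
                     labels = labels)
}

# Random continuous dataset for rule/tree equivalence checks.
random_tree_data <- function(n, p, n_class, seed) {
  withr::with_seed(seed, {
    X <- matrix(stats::runif(n * p, 0, 10), n, p,
                dimnames = list(NULL, sprintf("g%02d", seq_len(p))))
    # labels loosely tied to two features so trees are non-trivial
    score <- X[, 1] - 0.5 * X[, min(2, p)] + stats::rnorm(n, sd = 2)
    y <- factor(LETTERS[cut(score, breaks = n_class, labels = FALSE)])
  })
  list(X = X, y = y)
}

# Independent per-sample metric oracle: per-class F1 by direct counting,
# multiclass MCC via the indicator-matrix covariance form.
oracle_metrics <- function(y_true, y_pred) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  present <- classes %in% y_true
  w <- vapply(classes, function(cl) mean(y_true == cl), numeric(1))
  Xi <- outer(y_true, classes, `==`) * 1
  Yi <- outer(y_pred, classes, `==`) * 1
  covf <- function(A, B) sum((t(A) - colMeans(A)) * (t(B) - colMeans(B)))
  den <- sqrt(covf(Xi, Xi)) * sqrt(covf(Yi, Yi))
  list(weighted_f1 = sum(w[present] * f1[present]),
       macro_f1 = mean(f1[present]),
       accuracy = mean(y_true == y_pred),
       mcc = if (den == 0) 0 else covf(Xi, Yi) / den)
}

# All non-negative integer 3x3 confusion matrices with a given total, as a
# list; stars-and-bars enumeration.
enumerate_confusions <- function(total, n_cells = 9) {
  res <- list()
  recurse <- function(prefix, left, cells_left) {
    if (cells_left == 1) {
      res[[length(res) + 1L]] <<- c(prefix, left)
      return(invisible())
    }
    for (v in 0:left) recurse(c(prefix, v), left - v, cells_left - 1)
  }
  recurse(integer(0), total, n_cells)
  lapply(res, function(v) matrix(v, 3, 3, byrow = TRUE))
}

# Reconstruct a canonical (y_true, y_pred) pair from a confusion matrix.
labels_from_confusion <- function(cm, classes = c("A", "B", "C")) {
  yt <- character(0); yp <- character(0)
  for (i in seq_len(nrow(cm))) for (j in seq_len(ncol(cm))) {
    k <- cm[i, j]
    if (k > 0) {
      yt <- c(yt, rep(classes[i], k))
      yp <- c(yp, rep(classes[j], k))
    }
  }
  list(y_true = yt, y_pred = yp)
}

# Memoized IFS runs on the Table-1 fixture (prefix sizes 50/100/150), so the
# end-to-end selection and robustness checks share one computation per seed.
synth_ifs <- function(seed) {
  key <- paste0("ifs", seed)
  if (is.null(.fixture_cache[[key]])) {
    fx <- synth_with_ranking(seed)
    rf <- suppressWarnings(run_ifs(
      fx$data, fx$ranked,
      ifs_config(step = 50, cap = 150,
                 classifier = classifier_spec("RF", seed = seed + 100),
                 balance = balancing_config(seed = seed + 200),
                 cv_seed = seed + 300)))
    dt <- suppressWarnings(run_ifs(
      fx$data, fx$ranked,
      ifs_config(step = 50, cap = 150,
                 classifier = classifier_spec("DT", seed = seed + 100),
                 balance = balancing_config(seed = seed + 200),
                 cv_seed = seed + 300)))
    .fixture_cache[[key]] <- list(rf = rf, dt = dt)
  }
  .fixture_cache[[key]]
}
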