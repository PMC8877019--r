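#' Stratified fold assignment
#'
#' Shuffles each class's cells (seeded) and deals them round-robin across
#' folds, so per-class counts differ across folds by at most one.
#'
#' @param y factor of labels.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..n_folds`, one per sample.
#' @export
stratified_folds <- function(y, n_folds = 10L, seed = 1L) {
  y <- as.factor(y)
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in levels(y)) {
      rows <- which(y == cls)
      rows <- rows[sample.int(length(rows))]
      folds[rows] <- rep_len(seq_len(n_folds), length(rows))
    }
  })
  folds
}

#' Cross-validated evaluation with in-fold SMOTE balancing
#'
#' Stratified k-fold cross-validation of a classifier on a chosen feature
#' subset. When `balance` is given, SMOTE is fitted and applied to each
#' training split only — never to the held-out split — so no synthetic sample
#' can leak into evaluation (`smote_before_cv = TRUE` reproduces the
#' alternative reading in which the whole dataset is balanced before
#' splitting). Out-of-fold predictions are pooled over all folds and scored
#' once.
#'
#' @param data a labeled [expression_dataset()].
#' @param feature_ids character vector of gene ids to use (subset of
#'   `data$gene_ids`).
#' @param classifier a [classifier_spec()].
#' @param n_folds number of folds (default 10).
#' @param balance a [balancing_config()], or `NULL` to disable balancing.
#' @param seed integer seed for the fold assignment.
#' @param smote_before_cv balance the full dataset before splitting
#'   (leakage-prone; off by default).
#' @return an [evaluation_report()] over the pooled out-of-fold predictions.
#' @export
cross_validate <- function(data, feature_ids, classifier, n_folds = 10L,
                           balance = balancing_config(), seed = 1L,
                           smote_before_cv = FALSE) {
  if (is.null(data$labels)) stop("input error: dataset has no labels")
  X <- subset_dataset(data, genes = feature_ids)$matrix
  y <- droplevels(data$labels)

  if (smote_before_cv && !is.null(balance)) {
    bal <- smote_balance(X, y, balance)
    X <- bal$X
    y <- bal$y
    rownames(X) <- sprintf("row%06d", seq_len(nrow(X)))
  }

  folds <- stratified_folds(y, n_folds = n_folds, seed = seed)
  # every class must appear in every training split
  for (f in seq_len(n_folds)) {
    train_classes <- unique(y[folds != f])
    absent <- setdiff(levels(y), as.character(train_classes))
    if (length(absent)) {
      stop(sprintf("fold error: class(es) absent from training split of fold %d: %s",
                   f, paste(absent, collapse = ", ")))
    }
  }

  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    X_tr <- X[tr, , drop = FALSE]
    y_tr <- y[tr]
    if (!smote_before_cv && !is.null(balance)) {
      fold_cfg <- balance
      fold_cfg$seed <- balance$seed + f
      bal <- smote_balance(X_tr, y_tr, fold_cfg)
      X_tr <- bal$X
      y_tr <- bal$y
    }
    fit <- fit_classifier(classifier, X_tr, y_tr)
    pred[!tr] <- predict_classifier(fit, X[!tr, , drop = FALSE])
  }

  evaluation_report(y, pred, classes = levels(y),
                    meta = list(classifier = classifier$name,
                                classifier_seed = classifier$seed,
                                n_folds = n_folds, cv_seed = seed,
                                n_features = length(feature_ids),
                                balanced = !is.null(balance),
                                smote_before_cv = smote_before_cv,
                                held_out_folds = folds))
}
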