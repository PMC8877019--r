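#' IFS configuration
#'
#' @param step subset-size increment (default 5).
#' @param cap largest subset size considered (default 1000; the search stops
#'   at `min(cap, n_features)`).
#' @param classifier a [classifier_spec()].
#' @param balance a [balancing_config()] or `NULL`.
#' @param n_folds cross-validation folds per subset.
#' @param cv_seed fold-assignment seed.
#' @param smote_before_cv see [cross_validate()].
#' @return an object of class `ifs_config`.
#' @export
ifs_config <- function(step = 5L, cap = 1000L,
                       classifier = classifier_spec("RF"),
                       balance = balancing_config(), n_folds = 10L,
                       cv_seed = 1L, smote_before_cv = FALSE) {
  step <- as.integer(step)
  cap <- as.integer(cap)
  if (step < 1) stop("step must be >= 1")
  if (cap < step) stop("cap must be >= step")
  structure(list(step = step, cap = cap, classifier = classifier,
                 balance = balance, n_folds = as.integer(n_folds),
                 cv_seed = as.integer(cv_seed),
                 smote_before_cv = smote_before_cv),
            class = "ifs_config")
}

#' IFS curve
#'
#' One record per evaluated feature-subset size with the four metrics; the
#' optimum is the smallest subset size attaining the maximal weighted F1.
#'
#' @param records data.frame with columns `k`, `weighted_f1`, `macro_f1`,
#'   `accuracy`, `mcc`, ordered by strictly increasing `k`.
#' @param classifier_name classifier label for the curve.
#' @return an object of class `ifs_curve` with fields `records`,
#'   `classifier_name`, `optimum_k`, `optimum_weighted_f1`.
#' @export
ifs_curve <- function(records, classifier_name = NA_character_) {
  stopifnot(is.data.frame(records),
            all(c("k", "weighted_f1", "macro_f1", "accuracy", "mcc") %in%
                  names(records)))
  if (nrow(records) > 1 && any(diff(records$k) <= 0)) {
    stop("subset sizes k must be strictly increasing")
  }
  best <- if (nrow(records)) which.max(records$weighted_f1) else NA_integer_
  structure(
    list(records = records, classifier_name = classifier_name,
         optimum_k = if (nrow(records)) records$k[best] else NA_integer_,
         optimum_weighted_f1 = if (nrow(records)) records$weighted_f1[best]
                               else NA_real_),
    class = "ifs_curve")
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat(sprintf("ifs_curve (%s): %d subsets, optimum k=%s (weighted F1 %.4f)\n",
              x$classifier_name, nrow(x$records), x$optimum_k,
              x$optimum_weighted_f1))
  invisible(x)
}

#' Nested feature-subset prefixes of a ranked list
#'
#' Prefixes of sizes `step, 2*step, ...` up to `min(cap, n_features)`; when
#' that bound is not a multiple of `step`, a final prefix of exactly
#' `min(cap, n_features)` features is appended. Each subset strictly contains
#' the previous one.
#'
#' @param ranked a [ranked_feature_list()].
#' @param step subset-size increment.
#' @param cap largest subset size considered.
#' @return list of character vectors of gene ids (prefixes of the ranking).
#' @export
generate_subsets <- function(ranked, step = 5L, cap = 1000L) {
  stopifnot(inherits(ranked, "ranked_feature_list"))
  n <- length(ranked$gene_id)
  if (n == 0) stop("input error: empty ranked list")
  if (step < 1) stop("step must be >= 1")
  top <- min(cap, n)
  sizes <- seq_len(top %/% step) * step
  if (length(sizes) == 0 || sizes[length(sizes)] != top) {
    sizes <- c(sizes, top)
  }
  lapply(sizes, function(k) ranked$gene_id[seq_len(k)])
}

#' Run incremental feature selection
#'
#' Evaluates the classifier by cross-validation on every nested prefix of the
#' ranked feature list and records the four metrics per subset size. The
#' optimal size is the smallest `k` attaining the maximal weighted F1.
#'
#' @param data a labeled [expression_dataset()].
#' @param ranked a [ranked_feature_list()].
#' @param cfg an [ifs_config()].
#' @param progress print one line per evaluated subset.
#' @return an [ifs_curve()].
#' @export
run_ifs <- function(data, ranked, cfg = ifs_config(), progress = FALSE) {
  stopifnot(inherits(cfg, "ifs_config"))
  subsets <- generate_subsets(ranked, step = cfg$step, cap = cfg$cap)
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    feats <- subsets[[i]]
    rep <- cross_validate(data, feats, cfg$classifier,
                          n_folds = cfg$n_folds, balance = cfg$balance,
                          seed = cfg$cv_seed,
                          smote_before_cv = cfg$smote_before_cv)
    rows[[i]] <- data.frame(k = length(feats),
                            weighted_f1 = rep$weighted_f1,
                            macro_f1 = rep$macro_f1,
                            accuracy = rep$accuracy,
                            mcc = rep$mcc)
    if (progress) {
      message(sprintf("IFS [%s] k=%d weighted F1=%.4f", cfg$classifier$name,
                      length(feats), rep$weighted_f1))
    }
  }
  ifs_curve(do.call(rbind, rows), classifier_name = cfg$classifier$name)
}

#' Fit the optimal classifier on the full dataset
#'
#' Trains the classifier on all cells restricted to the top `optimum_k`
#' features of the ranking. By default training uses the original
#' (unbalanced) dataset — the natural setting for rule mining, where passed
#' counts refer to real cells; set `balance` to train on a SMOTE-augmented
#' matrix instead.
#'
#' @param data a labeled [expression_dataset()].
#' @param ranked a [ranked_feature_list()].
#' @param optimum_k number of top-ranked features to keep.
#' @param classifier a [classifier_spec()].
#' @param balance optional [balancing_config()] applied before fitting.
#' @return an object of class `optimal_classifier`: the fitted model, the
#'   feature ids used, and the training matrix/labels (needed for rule
#'   mining).
#' @export
fit_optimal <- function(data, ranked, optimum_k,
                        classifier = classifier_spec("DT"), balance = NULL) {
  if (optimum_k < 1 || optimum_k > length(ranked$gene_id)) {
    stop(sprintf("input error: optimum_k=%d out of range 1..%d", optimum_k,
                 length(ranked$gene_id)))
  }
  feats <- ranked$gene_id[seq_len(optimum_k)]
  X <- subset_dataset(data, genes = feats)$matrix
  y <- droplevels(data$labels)
  if (!is.null(balance)) {
    bal <- smote_balance(X, y, balance)
    X <- bal$X
    y <- bal$y
    colnames(X) <- feats
  }
  fit <- fit_classifier(classifier, X, y)
  structure(list(fit = fit, feature_ids = feats, X_train = X, y_train = y,
                 balanced = !is.null(balance)),
            class = "optimal_classifier")
}
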