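#' Ranked feature list
#'
#' Genes ordered by split-count importance: the number of times a gene is
#' chosen as a split variable across the boosted tree ensemble. Ties are
#' broken by total split gain (descending), then by input column order.
#'
#' @param gene_id character vector of gene ids, already in rank order.
#' @param importance non-negative, non-increasing importance values
#'   (split counts).
#' @param split_count,total_gain optional per-gene backing statistics.
#' @param backend optional list describing the booster and parameters used.
#' @return an object of class `ranked_feature_list` with fields `rank`,
#'   `gene_id`, `importance`.
#' @export
ranked_feature_list <- function(gene_id, importance, split_count = NULL,
                                total_gain = NULL, backend = NULL) {
  gene_id <- as.character(gene_id)
  importance <- as.numeric(importance)
  if (length(gene_id) != length(importance)) {
    stop("gene_id and importance must have equal length")
  }
  if (anyDuplicated(gene_id)) stop("duplicate gene ids in ranked list")
  if (length(importance) > 1 && any(diff(importance) > 1e-9)) {
    stop("importance must be non-increasing with rank")
  }
  if (any(importance < 0)) stop("importance must be non-negative")
  structure(
    list(rank = seq_along(gene_id), gene_id = gene_id,
         importance = importance, split_count = split_count,
         total_gain = total_gain, backend = backend),
    class = "ranked_feature_list")
}

#' @export
print.ranked_feature_list <- function(x, ...) {
  cat(sprintf("ranked_feature_list: %d features\n", length(x$gene_id)))
  n <- min(5L, length(x$gene_id))
  if (n > 0) {
    cat("top:", paste(sprintf("%s (%g)", x$gene_id[seq_len(n)],
                              x$importance[seq_len(n)]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.ranked_feature_list <- function(x) length(x$gene_id)

#' Rank genes by gradient-boosted-tree split-count importance
#'
#' Fits a multiclass gradient-boosted tree ensemble (one tree per class per
#' boosting round) and ranks every gene by the number of times it is selected
#' as a split variable, summed over all trees. Genes never used for a split
#' receive importance 0 and keep their input column order. Ties in split
#' count are broken by total split gain, then input column order.
#'
#' @param data a labeled [expression_dataset()] with at least two classes.
#' @param params named list of booster parameters overriding the backend
#'   defaults (e.g. `nrounds`, `max_depth`, `eta` for the xgboost backend;
#'   `nrounds`, `learning_rate` for the stump backend).
#' @param seed integer seed for the booster.
#' @param method `"xgboost"` (default backend) or `"stump"` (the built-in
#'   one-vs-rest boosted-stump ranker).
#' @return a [ranked_feature_list()] covering every gene exactly once.
#' @export
rank_features <- function(data, params = list(), seed = 1L,
                          method = c("xgboost", "stump")) {
  method <- match.arg(method)
  if (is.null(data$labels)) stop("ranking error: dataset has no labels")
  y <- droplevels(data$labels)
  if (nlevels(y) < 2) {
    stop("ranking error: need at least 2 classes to rank features")
  }
  model <- if (method == "xgboost") {
    fit_xgb_booster(data$matrix, y, params = params, seed = seed)
  } else {
    fit_stump_booster(data$matrix, y, params = params)
  }
  tab <- importance_table(model)
  tab <- tab[match(data$gene_ids, tab$gene), , drop = FALSE]
  ord <- order(-tab$split_count, -tab$total_gain, seq_len(nrow(tab)))
  ranked_feature_list(
    gene_id = data$gene_ids[ord],
    importance = tab$split_count[ord],
    split_count = tab$split_count[ord],
    total_gain = tab$total_gain[ord],
    backend = attr(model, "backend"))
}

fit_xgb_booster <- function(X, y, params = list(), seed = 1L) {
  defaults <- list(nrounds = 100, max_depth = 6, eta = 0.3)
  params <- utils::modifyList(defaults, params)
  nrounds <- params$nrounds
  params$nrounds <- NULL
  K <- nlevels(y)
  dm <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L, nthread = 1)
  xgb_params <- c(list(objective = "multi:softprob", num_class = K,
                       nthread = 1, seed = as.integer(seed)), params)
  model <- xgboost::xgb.train(params = xgb_params, data = dm,
                              nrounds = nrounds, verbose = 0)
  attr(model, "backend") <- list(name = "xgboost",
                                 version = as.character(utils::packageVersion("xgboost")),
                                 params = c(xgb_params, list(nrounds = nrounds)))
  attr(model, "feature_names") <- colnames(X)
  model
}

#' Per-gene split counts and total gains of a fitted booster
#'
#' Walks the fitted ensemble's tree structures and counts, for every gene,
#' the internal nodes splitting on it, together with the summed split gain.
#' The split counts over all genes sum to the total number of internal nodes
#' in the ensemble.
#'
#' @param model a fitted booster (an `xgb.Booster` or a `stump_booster`).
#' @return a data.frame with columns `gene`, `split_count`, `total_gain`,
#'   one row per feature the model was trained on.
#' @export
importance_table <- function(model) UseMethod("importance_table")

#' @export
importance_table.xgb.Booster <- function(model) {
  feats <- attr(model, "feature_names")
  if (is.null(feats)) feats <- dimnames(model)[[2]]
  if (is.null(feats)) stop("state error: booster lacks feature names")
  dt <- xgboost::xgb.model.dt.tree(model = model)
  splits <- dt[dt$Feature != "Leaf", , drop = FALSE]
  cnt <- table(factor(splits$Feature, levels = feats))
  gain <- tapply(splits$Gain, factor(splits$Feature, levels = feats), sum)
  gain[is.na(gain)] <- 0
  data.frame(gene = feats, split_count = as.numeric(cnt),
             total_gain = as.numeric(gain), row.names = NULL)
}

#' @export
importance_table.default <- function(model) {
  stop("state error: not a fitted booster")
}

#' Built-in one-vs-rest boosted-stump ranker
#'
#' A minimal gradient-boosting backend: for each class a binary logistic
#' boosting run with depth-1 regression trees fitted to the pseudo-residuals,
#' exact split search, no subsampling. Deterministic by construction. Its
#' split counts feed [rank_features()] exactly like the default backend's.
#'
#' @param X numeric cells x genes matrix with column names.
#' @param y factor of class labels.
#' @param params list with `nrounds` (boosting rounds per class, default 50)
#'   and `learning_rate` (default 0.1).
#' @return an object of class `stump_booster`.
#' @export
fit_stump_booster <- function(X, y, params = list()) {
  defaults <- list(nrounds = 50, learning_rate = 0.1)
  params <- utils::modifyList(defaults, params)
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  stumps <- vector("list", K)
  names(stumps) <- levels(y)
  for (k in seq_len(K)) {
    yk <- as.numeric(y == levels(y)[k])
    f <- rep(0, nrow(X))
    rounds <- list()
    for (t in seq_len(params$nrounds)) {
      prob <- 1 / (1 + exp(-f))
      g <- yk - prob
      s <- cpp_best_stump(X, g)
      if (s$feature < 0) break
      left <- X[, s$feature + 1L] <= s$threshold
      f <- f + params$learning_rate *
        ifelse(left, s$left_value, s$right_value)
      rounds[[length(rounds) + 1L]] <-
        list(feature = s$feature + 1L, threshold = s$threshold,
             left_value = s$left_value, right_value = s$right_value,
             gain = s$gain)
    }
    stumps[[k]] <- rounds
  }
  structure(list(stumps = stumps, feature_names = colnames(X)),
            class = "stump_booster",
            backend = list(name = "stump", params = params))
}

#' @export
importance_table.stump_booster <- function(model) {
  feats <- model$feature_names
  cnt <- numeric(length(feats))
  gain <- numeric(length(feats))
  for (cls in model$stumps) {
    for (s in cls) {
      cnt[s$feature] <- cnt[s$feature] + 1
      gain[s$feature] <- gain[s$feature] + s$gain
    }
  }
  data.frame(gene = feats, split_count = cnt, total_gain = gain,
             row.names = NULL)
}
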