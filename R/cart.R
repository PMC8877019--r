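#' Fit a classification tree (CART, Gini impurity)
#'
#' Exact greedy CART: at each node every (feature, midpoint-threshold) split
#' is scored by Gini impurity decrease; rows with `x <= threshold` go left,
#' `x > threshold` go right. Growth continues until leaves are pure or no
#' impurity-reducing split exists (unlimited depth by default). The tree is a
#' deterministic function of the training data: score ties keep the smallest
#' feature index, then the smallest threshold; majority-class ties at a leaf
#' keep the first class in level order.
#'
#' @param X numeric samples x features matrix with column names.
#' @param y factor of class labels (level order fixes tie-breaking).
#' @param max_depth maximum depth, `Inf` for unlimited.
#' @param min_split minimum node size eligible for splitting.
#' @return an object of class `cart_tree`.
#' @export
cart_fit <- function(X, y, max_depth = Inf, min_split = 2L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nrow(X) != length(y)) stop("X and y must have equal length")
  fit <- cpp_cart_fit(X, as.integer(y) - 1L, nlevels(y),
                      if (is.finite(max_depth)) as.integer(max_depth) else -1L,
                      as.integer(min_split), 1e-12)
  structure(
    list(feature = fit$feature, threshold = fit$threshold,
         left = fit$left, right = fit$right, pred = fit$pred,
         n_node = fit$n_node, class_counts = fit$class_counts,
         classes = levels(y), feature_names = colnames(X),
         n_train = nrow(X)),
    class = "cart_tree")
}

#' @export
print.cart_tree <- function(x, ...) {
  cat(sprintf("cart_tree: %d nodes (%d leaves), %d classes, %d training rows\n",
              length(x$feature), sum(x$feature < 0), length(x$classes),
              x$n_train))
  invisible(x)
}

#' Predict with a fitted CART
#'
#' @param object a `cart_tree`.
#' @param newdata numeric matrix with the training features as columns (
#'   matched by name when column names are present).
#' @param type `"class"` for labels, `"leaf"` for 1-based leaf node indices.
#' @param ... unused.
#' @return factor of predicted classes, or integer leaf indices.
#' @export
predict.cart_tree <- function(object, newdata, type = c("class", "leaf"), ...) {
  type <- match.arg(type)
  newdata <- align_features(newdata, object$feature_names)
  nodes <- cpp_cart_route(object$feature, object$threshold, object$left,
                          object$right, newdata)
  if (type == "leaf") return(nodes + 1L)
  factor(object$classes[object$pred[nodes + 1L]  + 1L],
         levels = object$classes)
}

align_features <- function(X, feature_names) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.null(feature_names) && !is.null(colnames(X))) {
    missing <- setdiff(feature_names, colnames(X))
    if (length(missing)) {
      stop(sprintf("input error: missing feature(s): %s",
                   paste(utils::head(missing, 5), collapse = ", ")))
    }
    X <- X[, feature_names, drop = FALSE]
  }
  X
}
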