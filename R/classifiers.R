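#' Classifier specification
#'
#' The two classifier families the workflow compares: a single CART decision
#' tree (`"DT"`, interpretable, rules can be mined from it) and a random
#' forest (`"RF"`, bagged CART ensemble, majority vote).
#'
#' @param name `"DT"` or `"RF"`.
#' @param params named list of overrides. For `"RF"`: `num_trees`
#'   (default 100) and `mtry` (default `floor(sqrt(p))`). For `"DT"`:
#'   `max_depth` (default unlimited).
#' @param seed integer seed (used by the RF's bootstrap/feature sampling; the
#'   DT is deterministic).
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("DT", "RF"), params = list(), seed = 1L) {
  name <- match.arg(name)
  structure(list(name = name, params = params, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Fit / predict a classifier from its specification
#'
#' @param spec a [classifier_spec()].
#' @param X numeric samples x features training matrix with column names.
#' @param y factor of training labels.
#' @return `fit_classifier` returns a fitted model of class
#'   `fitted_classifier`; `predict_classifier` a factor of predictions.
#' @export
fit_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  model <- if (spec$name == "DT") {
    md <- spec$params$max_depth %||% Inf
    cart_fit(X, y, max_depth = md)
  } else {
    num_trees <- spec$params$num_trees %||% 100L
    mtry <- spec$params$mtry %||% max(1L, floor(sqrt(ncol(X))))
    ranger::ranger(x = X, y = y, num.trees = num_trees, mtry = mtry,
                   seed = spec$seed, num.threads = 1,
                   classification = TRUE, verbose = FALSE)
  }
  structure(list(spec = spec, model = model, classes = levels(y),
                 feature_names = colnames(X)),
            class = "fitted_classifier")
}

#' @rdname fit_classifier
#' @param fit a `fitted_classifier`.
#' @export
predict_classifier <- function(fit, X) {
  stopifnot(inherits(fit, "fitted_classifier"))
  X <- align_features(X, fit$feature_names)
  if (fit$spec$name == "DT") {
    predict(fit$model, X)
  } else {
    p <- predict(fit$model, data = X, num.threads = 1,
                 seed = fit$spec$seed)$predictions
    factor(as.character(p), levels = fit$classes)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
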