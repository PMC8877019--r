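#' SMOTE balancing configuration
#'
#' @param k_neighbors number of nearest same-class neighbors considered when
#'   interpolating (classical default 5). When a minority class has fewer
#'   than `k_neighbors + 1` members, k is clamped to class size - 1 with a
#'   warning.
#' @param seed integer seed for the interpolation draws.
#' @return an object of class `balancing_config`.
#' @export
balancing_config <- function(k_neighbors = 5L, seed = 1L) {
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  structure(list(k_neighbors = k_neighbors, target = "equalize-to-majority",
                 seed = as.integer(seed)),
            class = "balancing_config")
}

#' SMOTE oversampling to equalize class sizes
#'
#' Every class is oversampled up to the majority class count. Each synthetic
#' sample is `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`, `x` a uniformly
#' drawn member of the minority class and `x_nn` one of its `k_neighbors`
#' nearest same-class neighbors under exact Euclidean distance (ties broken
#' by row index). Original rows are preserved verbatim and come first in the
#' output; synthetic rows follow grouped by class in class-level order.
#'
#' @param X numeric feature matrix (samples x features).
#' @param y factor (or character) of class labels, one per row of `X`.
#' @param cfg a [balancing_config()].
#' @return list with elements `X` (augmented matrix) and `y` (augmented
#'   factor); every class count equals the majority count of the input.
#' @export
smote_balance <- function(X, y, cfg = balancing_config()) {
  stopifnot(inherits(cfg, "balancing_config"))
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nrow(X) != length(y)) stop("X and y must have equal length")
  counts <- table(y)
  target <- max(counts)
  deficit <- target - counts
  if (all(deficit == 0)) return(list(X = X, y = y))
  singletons <- names(counts)[counts == 1 & deficit > 0]
  if (length(singletons)) {
    stop(sprintf("balancing error: class(es) with a single member cannot be oversampled: %s",
                 paste(singletons, collapse = ", ")))
  }
  synth_X <- list()
  synth_y <- list()
  withr::with_seed(cfg$seed, {
    for (cls in levels(y)) {
      need <- deficit[[cls]]
      if (need == 0) next
      rows <- which(y == cls)
      Xc <- X[rows, , drop = FALSE]
      m <- nrow(Xc)
      k <- cfg$k_neighbors
      if (k >= m) {
        warning(sprintf("k_neighbors clamped to %d for class '%s' (size %d)",
                        m - 1L, cls, m))
        k <- m - 1L
      }
      d <- as.matrix(stats::dist(Xc))
      # k nearest same-class neighbors per sample, ties by index
      nn <- t(apply(d, 1, function(row) {
        order(row, seq_along(row))[2:(k + 1L)]
      }))
      if (k == 1L) nn <- matrix(nn, ncol = 1L)
      base <- sample.int(m, need, replace = TRUE)
      pick <- sample.int(k, need, replace = TRUE)
      u <- stats::runif(need)
      newx <- Xc[base, , drop = FALSE] +
        u * (Xc[nn[cbind(base, pick)], , drop = FALSE] -
               Xc[base, , drop = FALSE])
      synth_X[[cls]] <- newx
      synth_y[[cls]] <- rep(cls, need)
    }
  })
  X_out <- rbind(X, do.call(rbind, unname(synth_X)))
  rownames(X_out) <- NULL
  y_out <- factor(c(as.character(y), unlist(synth_y, use.names = FALSE)),
                  levels = levels(y))
  list(X = X_out, y = y_out)
}
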