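#' Heart-atlas cell-type composition
#'
#' The 11 cell types of the adult human heart single-cell atlas the workflow
#' was designed around, with their observed cell counts (total 451,513).
#' Used as the default class-proportion profile of the synthetic generator.
#'
#' @return named integer vector of cell counts per type.
#' @export
heart_cell_type_counts <- function() {
  c("Adipocytes" = 3799L,
    "Atrial cardiomyocyte" = 23483L,
    "Endothelial" = 100579L,
    "Fibroblast" = 59341L,
    "Lymphoid" = 17217L,
    "Mesothelial" = 718L,
    "Myeloid" = 23028L,
    "Neuronal" = 3961L,
    "Pericytes" = 77856L,
    "Smooth muscle cells" = 16242L,
    "Ventricular cardiomyocyte" = 125289L)
}

#' Specification for a synthetic labeled single-cell dataset
#'
#' The generator draws each value from a negative binomial with mean
#' `baseline_mean` (mean `baseline_mean * marker_effect` when the gene is a
#' marker of the cell's type), then zeroes entries independently with
#' probability `dropout_rate`, emulating sparse droplet-based counts. Class
#' sizes follow `class_proportions` via largest-remainder rounding.
#'
#' @param n_cells total number of cells.
#' @param class_proportions named numeric vector of class proportions
#'   (normalized internally). Default: the heart-atlas composition.
#' @param n_genes total number of genes.
#' @param markers_per_class number of marker genes planted per class; marker
#'   sets are disjoint across classes.
#' @param marker_effect multiplicative mean shift (> 1) of a class's markers
#'   inside that class.
#' @param baseline_mean negative-binomial mean of non-marker expression.
#' @param dispersion negative-binomial size parameter `r`
#'   (variance = m + m^2 / r).
#' @param dropout_rate probability in `[0, 1)` of independently zeroing an
#'   entry.
#' @param seed integer seed; the generated dataset is a deterministic function
#'   of the spec including the seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells,
                           class_proportions = heart_cell_type_counts() /
                             sum(heart_cell_type_counts()),
                           n_genes = 500,
                           markers_per_class = 5,
                           marker_effect = 8,
                           baseline_mean = 0.5,
                           dispersion = 10,
                           dropout_rate = 0.1,
                           seed = 1L) {
  if (is.null(names(class_proportions))) {
    names(class_proportions) <- paste0("class", seq_along(class_proportions))
  }
  class_proportions <- class_proportions / sum(class_proportions)
  spec <- structure(
    list(n_cells = as.integer(n_cells),
         class_proportions = class_proportions,
         n_genes = as.integer(n_genes),
         markers_per_class = as.integer(markers_per_class),
         marker_effect = marker_effect,
         baseline_mean = baseline_mean,
         dispersion = dispersion,
         dropout_rate = dropout_rate,
         seed = as.integer(seed)),
    class = "synthetic_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  with(spec, {
    if (n_cells < 1) stop("spec error: n_cells must be positive")
    if (markers_per_class * length(class_proportions) > n_genes) {
      stop("spec error: markers exceed available genes")
    }
    if (marker_effect < 1) stop("spec error: marker_effect must be >= 1")
    if (baseline_mean <= 0 || dispersion <= 0) {
      stop("spec error: baseline_mean and dispersion must be positive")
    }
    if (dropout_rate < 0 || dropout_rate >= 1) {
      stop("spec error: dropout_rate must be in [0, 1)")
    }
  })
  counts <- class_counts_from_proportions(spec$n_cells, spec$class_proportions)
  if (any(counts == 0)) {
    stop(sprintf("spec error: class(es) round to 0 cells at n_cells=%d: %s",
                 spec$n_cells,
                 paste(names(counts)[counts == 0], collapse = ", ")))
  }
  invisible(spec)
}

#' Largest-remainder apportionment of cells to classes
#'
#' Floors `proportions * n`, then hands the remaining cells to the classes
#' with the largest fractional remainders (ties broken by class order), so the
#' counts always sum to `n` exactly.
#'
#' @param n total count to distribute.
#' @param proportions named numeric vector summing to 1.
#' @return named integer vector summing to `n`.
#' @export
class_counts_from_proportions <- function(n, proportions) {
  x <- proportions / sum(proportions) * n
  base <- floor(x + 1e-9)
  rem <- x - base
  left <- as.integer(round(n - sum(base)))
  counts <- as.integer(base)
  if (left > 0) {
    give <- order(-rem, seq_along(rem))[seq_len(left)]
    counts[give] <- counts[give] + 1L
  }
  names(counts) <- names(proportions)
  counts
}

#' Spec with the heart-atlas class composition
#'
#' @param n_cells total cells; must be at least 110 and large enough that the
#'   rarest type (mesothelial, 718 / 451,513) receives at least one cell under
#'   largest-remainder rounding.
#' @param seed integer seed.
#' @param ... further arguments to [synthetic_spec()].
#' @return a `synthetic_spec` whose proportions equal the atlas counts
#'   normalized by 451,513, classes named and ordered as in the atlas table.
#' @export
spec_from_table1 <- function(n_cells, seed = 1L, ...) {
  if (n_cells < 110) {
    stop(sprintf("spec error: n_cells=%d too small for 11 classes", n_cells))
  }
  counts <- heart_cell_type_counts()
  synthetic_spec(n_cells = n_cells,
                 class_proportions = counts / sum(counts),
                 seed = seed, ...)
}

#' Generate a synthetic labeled expression dataset
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements `data` (an [expression_dataset()] with labels)
#'   and `truth` (a `ground_truth`: `marker_map` mapping each class to its
#'   planted marker gene ids, and `class_counts`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_spec(spec)
  counts <- class_counts_from_proportions(spec$n_cells, spec$class_proportions)
  classes <- names(counts)
  K <- length(classes)
  n <- spec$n_cells
  p <- spec$n_genes

  withr::with_seed(spec$seed, {
    gene_ids <- sprintf("gene%05d", seq_len(p))
    marker_idx <- sample.int(p, spec$markers_per_class * K)
    marker_map <- split(gene_ids[marker_idx],
                        rep(classes, each = spec$markers_per_class))
    marker_map <- marker_map[classes]

    labels <- rep(classes, times = counts)
    mu <- matrix(spec$baseline_mean, nrow = n, ncol = p)
    for (k in seq_len(K)) {
      rows <- which(labels == classes[k])
      cols <- match(marker_map[[k]], gene_ids)
      mu[rows, cols] <- spec$baseline_mean * spec$marker_effect
    }
    m <- matrix(stats::rnbinom(n * p, size = spec$dispersion, mu = mu),
                nrow = n, ncol = p)
    if (spec$dropout_rate > 0) {
      keep <- matrix(stats::runif(n * p) >= spec$dropout_rate, nrow = n)
      m <- m * keep
    }
    storage.mode(m) <- "double"
    cell_ids <- sprintf("cell%06d", seq_len(n))
  })

  data <- expression_dataset(m, cell_ids, gene_ids, labels = labels,
                             class_levels = classes)
  truth <- structure(list(marker_map = marker_map, class_counts = counts),
                     class = "ground_truth")
  list(data = data, truth = truth)
}
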