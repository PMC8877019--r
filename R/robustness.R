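#' Noise-perturbation configuration
#'
#' @param cell_fraction fraction of cells to perturb (default 0.10).
#' @param magnitude relative noise scale delta >= 0 (default 0.10): each
#'   perturbed value moves by at most `delta` per-gene standard deviations.
#' @param n_repeats number of perturb-and-evaluate repeats (default 10).
#' @param seed integer master seed.
#' @return an object of class `noise_config`.
#' @export
noise_config <- function(cell_fraction = 0.10, magnitude = 0.10,
                         n_repeats = 10L, seed = 1L) {
  if (cell_fraction < 0 || cell_fraction > 1) {
    stop("cell_fraction must be in [0, 1]")
  }
  if (magnitude < 0) stop("magnitude must be >= 0")
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  structure(list(cell_fraction = cell_fraction, magnitude = magnitude,
                 n_repeats = n_repeats, seed = as.integer(seed)),
            class = "noise_config")
}

#' Perturb a fraction of cells with bounded relative noise
#'
#' Selects exactly `floor(cell_fraction * n_cells)` cells uniformly without
#' replacement; every feature `g` of a selected cell changes by
#' `s * u * magnitude * sigma_g` with `s` a random sign, `u ~ Uniform(0, 1)`
#' and `sigma_g` the per-gene standard deviation over all cells of the input.
#' Results are clipped at 0; unselected cells are returned bit-identical.
#'
#' @param data an [expression_dataset()].
#' @param cfg a [noise_config()].
#' @param seed optional seed override (defaults to `cfg$seed`).
#' @return a perturbed [expression_dataset()].
#' @export
perturb <- function(data, cfg = noise_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "noise_config"))
  m <- data$matrix
  n_sel <- floor(cfg$cell_fraction * nrow(m))
  if (n_sel == 0 || cfg$magnitude == 0) return(data)
  sigma <- apply(m, 2, stats::sd)
  withr::with_seed(seed, {
    sel <- sample.int(nrow(m), n_sel)
    sgn <- matrix(sample(c(-1, 1), n_sel * ncol(m), replace = TRUE),
                  nrow = n_sel)
    u <- matrix(stats::runif(n_sel * ncol(m)), nrow = n_sel)
  })
  noise <- sweep(sgn * u * cfg$magnitude, 2, sigma, `*`)
  m[sel, ] <- pmax(m[sel, , drop = FALSE] + noise, 0)
  expression_dataset(m, data$cell_ids, data$gene_ids, labels = data$labels,
                     class_levels = if (!is.null(data$labels))
                       levels(data$labels))
}

#' Noise-robustness study of an optimal classifier
#'
#' Repeats `n_repeats` times: perturb the dataset (fresh noise per repeat,
#' seeded as `cfg$seed + repeat`), restrict to the top `optimum_k` ranked
#' features, run stratified 10-fold cross-validation, and record the weighted
#' F1. The unperturbed baseline uses the same fold seed, so a zero-magnitude
#' perturbation reproduces it exactly.
#'
#' @param data a labeled [expression_dataset()].
#' @param ranked a [ranked_feature_list()].
#' @param optimum_k number of top-ranked features to use.
#' @param classifier a [classifier_spec()].
#' @param cfg a [noise_config()].
#' @param balance a [balancing_config()] or `NULL`.
#' @param n_folds cross-validation folds.
#' @param cv_seed fold-assignment seed (shared by baseline and repeats).
#' @return an object of class `robustness_result`: `baseline` weighted F1,
#'   per-repeat `scores`, and `summary` (mean, sd, min, max).
#' @export
robustness_study <- function(data, ranked, optimum_k,
                             classifier = classifier_spec("RF"),
                             cfg = noise_config(),
                             balance = balancing_config(),
                             n_folds = 10L, cv_seed = 1L) {
  feats <- ranked$gene_id[seq_len(optimum_k)]
  baseline <- cross_validate(data, feats, classifier, n_folds = n_folds,
                             balance = balance, seed = cv_seed)$weighted_f1
  scores <- vapply(seq_len(cfg$n_repeats), function(i) {
    pert <- perturb(data, cfg, seed = cfg$seed + i)
    cross_validate(pert, feats, classifier, n_folds = n_folds,
                   balance = balance, seed = cv_seed)$weighted_f1
  }, numeric(1))
  structure(
    list(baseline = baseline, scores = scores,
         summary = c(mean = mean(scores), sd = stats::sd(scores),
                     min = min(scores), max = max(scores)),
         config = cfg, optimum_k = optimum_k,
         classifier = classifier$name),
    class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf(
    "robustness_result (%s, k=%d): baseline %.4f; %d repeats mean %.4f (sd %.4f, range %.4f-%.4f)\n",
    x$classifier, x$optimum_k, x$baseline, length(x$scores),
    x$summary["mean"], x$summary["sd"], x$summary["min"], x$summary["max"]))
  invisible(x)
}
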