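#' Labeled expression dataset
#'
#' The package's central container: a cells x genes matrix of non-negative
#' expression values with cell and gene identifiers and (optionally) a
#' per-cell type label. Cells are always rows in memory; files stored in the
#' 10X genes x cells orientation are transposed at read time.
#'
#' @param matrix numeric matrix (cells x genes), all values >= 0. Sparse
#'   `Matrix` objects are densified.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#' @param gene_ids character vector of gene identifiers, one per column.
#'   Duplicates are disambiguated by suffixing `.1`, `.2`, ... in input order,
#'   with a warning.
#' @param labels optional per-cell cell-type labels (character or factor).
#'   Stored as a factor; the level order fixes the class order used for
#'   tie-breaking throughout the package.
#' @param class_levels optional explicit class level order for `labels`.
#' @return An object of class `expression_dataset` with elements `matrix`,
#'   `cell_ids`, `gene_ids`, `labels`.
#' @export
expression_dataset <- function(matrix, cell_ids, gene_ids, labels = NULL,
                               class_levels = NULL) {
  if (inherits(matrix, "Matrix")) matrix <- as.matrix(matrix)
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix")
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(matrix) != length(cell_ids)) {
    stop(sprintf("format error: matrix has %d rows but %d cell ids supplied",
                 nrow(matrix), length(cell_ids)))
  }
  if (ncol(matrix) != length(gene_ids)) {
    stop(sprintf("format error: matrix has %d columns but %d gene ids supplied",
                 ncol(matrix), length(gene_ids)))
  }
  if (anyDuplicated(cell_ids)) stop("cell ids must be unique")
  if (any(matrix < 0)) stop("expression values must be non-negative")
  gene_ids <- dedupe_gene_ids(gene_ids)
  if (!is.null(labels)) {
    if (length(labels) != nrow(matrix)) {
      stop("labels must have one entry per cell")
    }
    if (is.null(class_levels)) {
      class_levels <- if (is.factor(labels)) levels(labels) else unique(as.character(labels))
    }
    labels <- factor(as.character(labels), levels = class_levels)
    if (anyNA(labels)) stop("labels contain values outside the class levels")
  }
  dimnames(matrix) <- list(cell_ids, gene_ids)
  structure(
    list(matrix = matrix, cell_ids = cell_ids, gene_ids = gene_ids,
         labels = labels),
    class = "expression_dataset"
  )
}

dedupe_gene_ids <- function(gene_ids) {
  dup <- duplicated(gene_ids)
  if (!any(dup)) return(gene_ids)
  warning(sprintf("%d duplicate gene id(s) disambiguated by suffixing .1, .2, ...",
                  sum(dup)))
  new_ids <- gene_ids
  for (g in unique(gene_ids[dup])) {
    at <- which(gene_ids == g)
    new_ids[at[-1]] <- paste0(g, ".", seq_along(at[-1]))
  }
  # re-check: suffixing could collide with a pre-existing id
  if (anyDuplicated(new_ids)) new_ids <- make.unique(gene_ids, sep = ".")
  new_ids
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d cells x %d genes\n",
              nrow(x$matrix), ncol(x$matrix)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(sprintf("labels: %d classes (%s)\n", length(tab),
                paste0(utils::head(names(tab), 4), collapse = ", ")))
  } else {
    cat("labels: none\n")
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Number of cells / genes
#' @param data an `expression_dataset`.
#' @return integer count.
#' @export
n_cells <- function(data) nrow(data$matrix)

#' @rdname n_cells
#' @export
n_genes <- function(data) ncol(data$matrix)

#' Restrict a dataset to a subset of genes and/or cells
#'
#' @param data an `expression_dataset`.
#' @param genes character vector of gene ids to keep (order preserved as
#'   given). Unknown ids are an error.
#' @param cells integer or logical index of cells to keep.
#' @return an `expression_dataset`.
#' @export
subset_dataset <- function(data, genes = NULL, cells = NULL) {
  m <- data$matrix
  labels <- data$labels
  if (!is.null(genes)) {
    missing <- setdiff(genes, data$gene_ids)
    if (length(missing)) {
      stop(sprintf("unknown feature id(s): %s",
                   paste(utils::head(missing, 5), collapse = ", ")))
    }
    m <- m[, genes, drop = FALSE]
  }
  if (!is.null(cells)) {
    m <- m[cells, , drop = FALSE]
    if (!is.null(labels)) labels <- labels[cells]
  }
  expression_dataset(m, rownames(m), colnames(m), labels = labels,
                     class_levels = if (!is.null(labels)) levels(labels))
}

#' Class level order of a labeled dataset
#' @param data an `expression_dataset` with labels.
#' @return character vector of class names.
#' @export
class_names <- function(data) {
  if (is.null(data$labels)) stop("dataset has no labels")
  levels(data$labels)
}
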