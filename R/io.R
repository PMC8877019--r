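#' Read an expression matrix with identifiers and optional labels
#'
#' Supports two on-disk layouts:
#' * Matrix Market coordinate format (`.mtx`), stored genes x cells as in 10X
#'   Genomics exports, together with one-id-per-line gene and cell files
#'   (features.tsv / barcodes.tsv style). The matrix is transposed to
#'   cells x rows on read.
#' * Dense CSV/TSV with a header row of gene ids; rows are cells. Cell ids are
#'   taken from a leading `cell_id` column when present, otherwise from
#'   `cells_path`.
#'
#' @param matrix_path path to the `.mtx` or dense CSV/TSV file.
#' @param genes_path path to a gene-id file (one id per line). Optional for
#'   dense input with a header.
#' @param cells_path path to a cell-id file (one id per line). Optional for
#'   dense input with a `cell_id` column.
#' @param labels_path optional TSV with columns `cell_id`, `cell_type`; joined
#'   by cell id. A label for an unknown cell id is an error.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(matrix_path, genes_path = NULL, cells_path = NULL,
                            labels_path = NULL) {
  is_mtx <- grepl("\\.mtx$", matrix_path, ignore.case = TRUE)
  if (is_mtx) {
    if (is.null(genes_path) || is.null(cells_path)) {
      stop("Matrix Market input requires genes_path and cells_path")
    }
    m <- as.matrix(Matrix::readMM(matrix_path))
    gene_ids <- read_id_file(genes_path)
    cell_ids <- read_id_file(cells_path)
    if (nrow(m) != length(gene_ids) || ncol(m) != length(cell_ids)) {
      stop(sprintf(
        "format error: matrix is %d x %d (genes x cells) but id files have %d genes, %d cells",
        nrow(m), ncol(m), length(gene_ids), length(cell_ids)))
    }
    m <- t(m)  # 10X convention: stored genes x cells
  } else {
    df <- data.table::fread(matrix_path, header = TRUE, data.table = FALSE)
    if (ncol(df) > 0 && identical(names(df)[1], "cell_id")) {
      cell_ids <- as.character(df[[1]])
      df <- df[, -1, drop = FALSE]
    } else if (!is.null(cells_path)) {
      cell_ids <- read_id_file(cells_path)
    } else {
      stop("dense input needs a cell_id column or cells_path")
    }
    gene_ids <- if (!is.null(genes_path)) read_id_file(genes_path) else names(df)
    m <- as.matrix(df)
    if (nrow(m) != length(cell_ids) || ncol(m) != length(gene_ids)) {
      stop(sprintf(
        "format error: matrix is %d x %d (cells x genes) but ids give %d cells, %d genes",
        nrow(m), ncol(m), length(cell_ids), length(gene_ids)))
    }
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- data.table::fread(labels_path, header = TRUE, data.table = FALSE,
                             colClasses = "character")
    if (!all(c("cell_id", "cell_type") %in% names(lab))) {
      stop("labels file must have columns cell_id, cell_type")
    }
    unknown <- setdiff(lab$cell_id, cell_ids)
    if (length(unknown)) {
      stop(sprintf("join error: label(s) for unknown cell id(s): %s",
                   paste(utils::head(unknown, 10), collapse = ", ")))
    }
    missing <- setdiff(cell_ids, lab$cell_id)
    if (length(missing)) {
      stop(sprintf("join error: no label for cell id(s): %s",
                   paste(utils::head(missing, 10), collapse = ", ")))
    }
    labels <- lab$cell_type[match(cell_ids, lab$cell_id)]
  }
  expression_dataset(m, cell_ids, gene_ids, labels = labels)
}

read_id_file <- function(path) {
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  as.character(ids)
}

#' Write an expression dataset to disk
#'
#' Writes the matrix in Matrix Market coordinate format (genes x cells, 10X
#' convention), the id files, and the label TSV when labels are present.
#'
#' @param data an `expression_dataset`.
#' @param dir output directory (created if absent).
#' @param format `"mtx"` or `"csv"` (dense, cells x genes with `cell_id`
#'   column).
#' @return invisibly, the paths written.
#' @export
write_expression <- function(data, dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (format == "mtx") {
    mpath <- file.path(dir, "matrix.mtx")
    sp <- Matrix::Matrix(t(data$matrix), sparse = TRUE, doDiag = FALSE)
    Matrix::writeMM(sp, mpath)
    writeLines(data$gene_ids, file.path(dir, "genes.tsv"))
    writeLines(data$cell_ids, file.path(dir, "cells.tsv"))
    paths <- c(mpath, file.path(dir, c("genes.tsv", "cells.tsv")))
  } else {
    mpath <- file.path(dir, "matrix.csv")
    df <- data.frame(cell_id = data$cell_ids, data$matrix,
                     check.names = FALSE)
    data.table::fwrite(df, mpath)
    paths <- mpath
  }
  if (!is.null(data$labels)) {
    lpath <- file.path(dir, "labels.tsv")
    data.table::fwrite(
      data.frame(cell_id = data$cell_ids,
                 cell_type = as.character(data$labels)),
      lpath, sep = "\t")
    paths <- c(paths, lpath)
  }
  invisible(paths)
}

#' Write / read a ranked feature list as TSV
#'
#' Columns `rank`, `gene_id`, `importance`; one line per feature plus a
#' header. Importances are serialized with full double precision.
#'
#' @param ranked a `ranked_feature_list`.
#' @param path output path.
#' @return `write_ranked_list` returns the path invisibly; `read_ranked_list`
#'   returns a `ranked_feature_list`.
#' @export
write_ranked_list <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_feature_list"))
  df <- data.frame(rank = ranked$rank, gene_id = ranked$gene_id,
                   importance = format_num(ranked$importance))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("rank", "gene_id", "importance") %in% names(df))) {
    stop("parse error: ranked list needs columns rank, gene_id, importance")
  }
  ranked_feature_list(gene_id = as.character(df$gene_id),
                      importance = as.numeric(df$importance))
}

#' Write / read an IFS curve as TSV
#'
#' Columns `k`, `weighted_f1`, `macro_f1`, `accuracy`, `mcc`, one line per
#' evaluated subset size plus a header.
#'
#' @param curve an `ifs_curve`.
#' @param path output path.
#' @return `write_ifs_curve` returns the path invisibly; `read_ifs_curve`
#'   returns an `ifs_curve`.
#' @export
write_ifs_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ifs_curve"))
  rec <- curve$records
  df <- data.frame(k = rec$k,
                   weighted_f1 = format_num(rec$weighted_f1),
                   macro_f1 = format_num(rec$macro_f1),
                   accuracy = format_num(rec$accuracy),
                   mcc = format_num(rec$mcc))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_ifs_curve
#' @param classifier_name classifier label to attach on read.
#' @export
read_ifs_curve <- function(path, classifier_name = NA_character_) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("k", "weighted_f1", "macro_f1", "accuracy", "mcc")
  if (!all(need %in% names(df))) {
    stop("parse error: IFS curve needs columns k, weighted_f1, macro_f1, accuracy, mcc")
  }
  for (cl in need) df[[cl]] <- as.numeric(df[[cl]])
  df$k <- as.integer(df$k)
  ifs_curve(df, classifier_name = classifier_name)
}

format_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write / read a rule set as JSON
#'
#' Schema: `{n_training_cells, class_names, rules: [{predicates: [{gene, op,
#' threshold}], predicted_class, passed_count}]}` with `op` one of `"<="`,
#' `">"`. Thresholds survive a round trip bit-exactly.
#'
#' @param rules a `rule_set`.
#' @param path output path.
#' @return `write_ruleset` returns the path invisibly; `read_ruleset` returns
#'   a `rule_set`.
#' @export
write_ruleset <- function(rules, path) {
  stopifnot(inherits(rules, "rule_set"))
  obj <- list(
    n_training_cells = rules$n_training_cells,
    class_names = as.list(rules$class_names),
    rules = lapply(rules$rules, function(r) {
      list(
        predicates = lapply(seq_along(r$predicates$gene), function(i) {
          list(gene = r$predicates$gene[i], op = r$predicates$op[i],
               threshold = r$predicates$threshold[i])
        }),
        predicted_class = r$predicted_class,
        passed_count = r$passed_count)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       always_decimal = FALSE)
  invisible(path)
}

#' @rdname write_ruleset
#' @export
read_ruleset <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("parse error: ", conditionMessage(e)))
  for (nm in c("n_training_cells", "class_names", "rules")) {
    if (is.null(obj[[nm]])) stop(sprintf("parse error: missing field '%s'", nm))
  }
  rules <- lapply(seq_along(obj$rules), function(i) {
    r <- obj$rules[[i]]
    if (is.null(r$predicted_class) || is.null(r$passed_count)) {
      stop(sprintf("parse error: rule %d lacks predicted_class/passed_count", i))
    }
    preds <- r$predicates
    gene <- character(0); op <- character(0); thr <- numeric(0)
    for (j in seq_along(preds)) {
      p <- preds[[j]]
      if (is.null(p$op) || !(p$op %in% c("<=", ">"))) {
        stop(sprintf("parse error: rule %d predicate %d has invalid comparator '%s'",
                     i, j, if (is.null(p$op)) "" else p$op))
      }
      gene <- c(gene, as.character(p$gene))
      op <- c(op, p$op)
      thr <- c(thr, as.numeric(p$threshold))
    }
    decision_rule(gene, op, thr, predicted_class = as.character(r$predicted_class),
                  passed_count = as.integer(r$passed_count))
  })
  rule_set(rules, n_training_cells = as.integer(obj$n_training_cells),
           class_names = unlist(obj$class_names, use.names = FALSE))
}

#' Write an evaluation report as JSON and its confusion matrix as TSV
#'
#' @param report an `evaluation_report`.
#' @param json_path path for the metric JSON.
#' @param confusion_path optional path for the confusion-matrix TSV
#'   (true classes as rows, predicted as columns).
#' @return the JSON path, invisibly.
#' @export
write_report <- function(report, json_path, confusion_path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  obj <- list(accuracy = report$accuracy, mcc = report$mcc,
              macro_f1 = report$macro_f1, weighted_f1 = report$weighted_f1,
              per_class_f1 = as.list(report$per_class_f1),
              confusion = apply(report$confusion, 1, as.list))
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = I(17))
  if (!is.null(confusion_path)) {
    df <- data.frame(true_class = rownames(report$confusion),
                     report$confusion, check.names = FALSE)
    data.table::fwrite(df, confusion_path, sep = "\t")
  }
  invisible(json_path)
}
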