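#' Decision rule
#'
#' An ordered conjunction of threshold predicates on gene expression with a
#' predicted cell type and the number of training cells satisfying every
#' predicate (the rule's "passed count").
#'
#' @param gene character vector of gene ids, one per predicate.
#' @param op comparator per predicate, `"<="` or `">"`.
#' @param threshold numeric threshold per predicate.
#' @param predicted_class the cell type the rule assigns.
#' @param passed_count non-negative integer.
#' @return an object of class `decision_rule`.
#' @export
decision_rule <- function(gene, op, threshold, predicted_class, passed_count) {
  if (!all(op %in% c("<=", ">"))) {
    stop("parse error: predicate comparators must be '<=' or '>'")
  }
  if (length(gene) != length(op) || length(op) != length(threshold)) {
    stop("predicate fields must have equal length")
  }
  passed_count <- as.integer(passed_count)
  if (is.na(passed_count) || passed_count < 0) {
    stop("passed_count must be a non-negative integer")
  }
  structure(
    list(predicates = list(gene = as.character(gene), op = as.character(op),
                           threshold = as.numeric(threshold)),
         predicted_class = as.character(predicted_class),
         passed_count = passed_count),
    class = "decision_rule")
}

#' Rule set
#'
#' The complete set of root-to-leaf rules of a decision tree. The rules
#' partition the feature space: exactly one rule matches any row, and the
#' passed counts sum to the number of training cells.
#'
#' @param rules list of [decision_rule()]s.
#' @param n_training_cells number of cells the tree was trained on.
#' @param class_names class order used by the tree.
#' @return an object of class `rule_set`.
#' @export
rule_set <- function(rules, n_training_cells, class_names) {
  stopifnot(all(vapply(rules, inherits, logical(1), "decision_rule")))
  structure(list(rules = rules,
                 n_training_cells = as.integer(n_training_cells),
                 class_names = as.character(class_names)),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("rule_set: %d rules over %d classes, %d training cells\n",
              length(x$rules), length(x$class_names), x$n_training_cells))
  invisible(x)
}

#' @export
length.rule_set <- function(x) length(x$rules)

#' Extract IF-THEN rules from a fitted decision tree
#'
#' One rule per leaf: the predicates are the root-to-leaf split conditions in
#' path order (`gene <= threshold` on a left branch, `gene > threshold` on a
#' right branch), the predicted class is the leaf's majority training class,
#' and the passed count is the number of training rows reaching the leaf.
#' Rules are numbered in depth-first (left-first) leaf order.
#'
#' @param tree a [cart_fit()] tree, or an `optimal_classifier` whose fitted
#'   model is a decision tree.
#' @param simplify drop dominated predicates on the same gene along a path
#'   (e.g. keep only the tightest `<=`); off by default since it changes rule
#'   text but not semantics.
#' @return a [rule_set()]; passed counts sum to the training size.
#' @export
extract_rules <- function(tree, simplify = FALSE) {
  if (inherits(tree, "optimal_classifier")) {
    if (!inherits(tree$fit$model, "cart_tree")) {
      stop("state error: rules can only be extracted from a decision tree")
    }
    tree <- tree$fit$model
  }
  if (!inherits(tree, "cart_tree")) stop("state error: not a fitted tree")

  rules <- list()
  walk <- function(node, gene, op, thr) {
    if (tree$feature[node] < 0) {  # leaf (0-based arrays, node is 1-based)
      cls <- tree$classes[tree$pred[node] + 1L]
      r <- decision_rule(gene, op, thr, predicted_class = cls,
                         passed_count = tree$n_node[node])
      rules[[length(rules) + 1L]] <<- r
      return(invisible())
    }
    g <- tree$feature_names[tree$feature[node] + 1L]
    t <- tree$threshold[node]
    walk(tree$left[node] + 1L, c(gene, g), c(op, "<="), c(thr, t))
    walk(tree$right[node] + 1L, c(gene, g), c(op, ">"), c(thr, t))
  }
  walk(1L, character(0), character(0), numeric(0))

  if (simplify) rules <- lapply(rules, simplify_rule)
  rule_set(rules, n_training_cells = tree$n_train,
           class_names = tree$classes)
}

simplify_rule <- function(r) {
  p <- r$predicates
  keep <- rep(TRUE, length(p$gene))
  for (g in unique(p$gene)) {
    le <- which(p$gene == g & p$op == "<=")
    gt <- which(p$gene == g & p$op == ">")
    if (length(le) > 1) keep[le[-which.min(p$threshold[le])]] <- FALSE
    if (length(gt) > 1) keep[gt[-which.max(p$threshold[gt])]] <- FALSE
  }
  decision_rule(p$gene[keep], p$op[keep], p$threshold[keep],
                r$predicted_class, r$passed_count)
}

#' Apply a rule set as a classifier
#'
#' Evaluates every rule on every row and checks the partition property:
#' exactly one rule must match each row (a corrupted rule set raises a
#' consistency error).
#'
#' @param rules a [rule_set()].
#' @param X numeric matrix whose column names contain every gene referenced
#'   by the rules.
#' @return factor of predicted classes with the rule set's class order.
#' @export
apply_rules <- function(rules, X) {
  stopifnot(inherits(rules, "rule_set"))
  if (!is.matrix(X)) X <- as.matrix(X)
  needed <- unique(unlist(lapply(rules$rules, function(r) r$predicates$gene)))
  missing <- setdiff(needed, colnames(X))
  if (length(missing)) {
    stop(sprintf("input error: missing gene(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  n <- nrow(X)
  match_count <- integer(n)
  assigned <- character(n)
  for (r in rules$rules) {
    p <- r$predicates
    ok <- rep(TRUE, n)
    for (j in seq_along(p$gene)) {
      v <- X[, p$gene[j]]
      ok <- ok & if (p$op[j] == "<=") v <= p$threshold[j] else v > p$threshold[j]
    }
    assigned[ok] <- r$predicted_class
    match_count <- match_count + ok
  }
  if (any(match_count != 1L)) {
    bad <- which(match_count != 1L)
    stop(sprintf(
      "consistency error: %d row(s) matched by %s rules (first offender: row %d, %d matches)",
      length(bad), paste(sort(unique(match_count[bad])), collapse = "/"),
      bad[1], match_count[bad[1]]))
  }
  factor(assigned, levels = rules$class_names)
}

#' Per-class rule counts and top rules by passed count
#'
#' @param rules a [rule_set()].
#' @return named integer vector over all classes of the rule set (classes
#'   with no rule report 0); the counts partition the rule list.
#' @export
rules_per_class <- function(rules) {
  stopifnot(inherits(rules, "rule_set"))
  cls <- vapply(rules$rules, function(r) r$predicted_class, character(1))
  tab <- table(factor(cls, levels = rules$class_names))
  stats::setNames(as.integer(tab), names(tab))
}

#' @rdname rules_per_class
#' @param class cell type whose rules to return.
#' @param n maximum number of rules.
#' @return `top_rules` returns up to `n` rules of the class, sorted by passed
#'   count descending (ties by rule index ascending); fewer when the class
#'   has fewer rules.
#' @export
top_rules <- function(rules, class, n = 3L) {
  stopifnot(inherits(rules, "rule_set"))
  if (!class %in% rules$class_names) {
    stop(sprintf("input error: unknown class '%s'", class))
  }
  idx <- which(vapply(rules$rules, function(r) r$predicted_class,
                      character(1)) == class)
  if (!length(idx)) return(list())
  counts <- vapply(rules$rules[idx], function(r) r$passed_count, integer(1))
  ord <- idx[order(-counts, idx)]
  rules$rules[utils::head(ord, n)]
}

#' Render rules as human-readable IF-THEN text
#'
#' @param rules a [rule_set()].
#' @param digits significant digits for thresholds in the rendering.
#' @return character vector, one IF-THEN line per rule.
#' @export
format_rules <- function(rules, digits = 6) {
  stopifnot(inherits(rules, "rule_set"))
  vapply(seq_along(rules$rules), function(i) {
    r <- rules$rules[[i]]
    p <- r$predicates
    cond <- if (length(p$gene)) {
      paste(sprintf("%s %s %s", p$gene, p$op,
                    formatC(p$threshold, digits = digits, format = "g")),
            collapse = " AND ")
    } else "TRUE"
    sprintf("Rule_%d: IF %s THEN %s  [passed: %d]", i - 1L, cond,
            r$predicted_class, r$passed_count)
  }, character(1))
}
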