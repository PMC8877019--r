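test_that("a pure single-leaf tree yields one empty-predicate rule covering everything", {
  X <- matrix(runif(10), 10, 1, dimnames = list(NULL, "g"))
  y <- factor(rep("T1", 10))
  rs <- extract_rules(cart_fit(X, y))
  expect_length(rs, 1L)
  expect_length(rs$rules[[1]]$predicates$gene, 0L)
  expect_equal(rs$rules[[1]]$passed_count, 10L)
  expect_equal(rs$rules[[1]]$predicted_class, "T1")
  expect_equal(as.character(apply_rules(rs, X)), rep("T1", 10))
})

test_that("a stump yields two rules with the split partition's passed counts", {
  X <- matrix(c(1, 2, 3, 4, 6, 7, 8, 9, 10, 11), ncol = 1,
              dimnames = list(NULL, "g"))
  y <- factor(rep(c("low", "high"), times = c(4, 6)))
  rs <- extract_rules(cart_fit(X, y))
  expect_length(rs, 2L)
  r_left <- rs$rules[[1]]
  r_right <- rs$rules[[2]]
  expect_equal(r_left$predicates$op, "<=")
  expect_equal(r_left$predicates$threshold, 5)
  expect_equal(r_left$passed_count, 4L)
  expect_equal(r_left$predicted_class, "low")
  expect_equal(r_right$predicates$op, ">")
  expect_equal(r_right$passed_count, 6L)
  expect_equal(r_right$predicted_class, "high")
})

test_that("rule sets reproduce tree predictions on training data and probes", {
  for (seed in c(1, 2, 3)) {
    d <- random_tree_data(n = 250, p = 6, n_class = 3, seed = seed)
    tr <- cart_fit(d$X, d$y)
    rs <- extract_rules(tr)
    expect_equal(sum(vapply(rs$rules, function(r) r$passed_count, integer(1))),
                 nrow(d$X))
    expect_identical(apply_rules(rs, d$X), predict(tr, d$X))
    withr::with_seed(seed + 100, {
      probe <- matrix(runif(500 * 6, -2, 12), 500, 6,
                      dimnames = list(NULL, colnames(d$X)))
    })
    expect_identical(apply_rules(rs, probe), predict(tr, probe))
  }
})

test_that("per-class rule counts partition the rule list and top rules sort by passed count", {
  d <- random_tree_data(n = 300, p = 5, n_class = 3, seed = 7)
  rs <- extract_rules(cart_fit(d$X, d$y))
  counts <- rules_per_class(rs)
  expect_equal(sum(counts), length(rs))
  expect_setequal(names(counts), levels(d$y))

  cls <- names(counts)[which.max(counts)]
  top <- top_rules(rs, cls, n = 3)
  pc <- vapply(top, function(r) r$passed_count, integer(1))
  expect_true(all(diff(pc) <= 0))
  expect_true(all(vapply(top, function(r) r$predicted_class, character(1)) ==
                    cls))
  # no padding beyond available rules
  rare <- names(counts)[which.min(counts)]
  expect_lte(length(top_rules(rs, rare, n = 10^3)), counts[[rare]])
  expect_error(top_rules(rs, "no-such-type"), "unknown class")
})

test_that("corrupted rule sets are detected when applied", {
  d <- random_tree_data(n = 100, p = 4, n_class = 2, seed = 5)
  tr <- cart_fit(d$X, d$y)
  rs <- extract_rules(tr)
  broken <- rs
  broken$rules <- broken$rules[-1]  # a region now matches no rule
  expect_error(apply_rules(broken, d$X), "consistency error")
  dupl <- rs
  dupl$rules <- c(dupl$rules, dupl$rules[1])  # a region matches twice
  expect_error(apply_rules(dupl, d$X), "consistency error")
  expect_error(apply_rules(rs, d$X[, -1, drop = FALSE]), "missing gene")
})

test_that("predicate simplification changes text, not semantics", {
  d <- random_tree_data(n = 300, p = 3, n_class = 3, seed = 11)
  tr <- cart_fit(d$X, d$y)
  full <- extract_rules(tr, simplify = FALSE)
  slim <- extract_rules(tr, simplify = TRUE)
  npred <- function(rs) sum(vapply(rs$rules,
                                   function(r) length(r$predicates$gene),
                                   integer(1)))
  expect_lte(npred(slim), npred(full))
  withr::with_seed(99, {
    probe <- matrix(runif(400 * 3, 0, 10), 400, 3,
                    dimnames = list(NULL, colnames(d$X)))
  })
  expect_identical(apply_rules(slim, probe), apply_rules(full, probe))
})

test_that("rules can only be extracted from decision trees", {
  ds <- separable_dataset(n_per_class = 10)
  opt_rf <- fit_optimal(ds, ranked_feature_list(ds$gene_ids, c(4, 3, 2, 1)), 2,
                        classifier_spec("RF", seed = 1))
  expect_error(extract_rules(opt_rf), "state error")
  expect_error(extract_rules(lm(1 ~ 1)), "state error")
})

test_that("the human-readable rendering lists one IF-THEN line per rule", {
  d <- random_tree_data(n = 60, p = 3, n_class = 2, seed = 13)
  rs <- extract_rules(cart_fit(d$X, d$y))
  txt <- format_rules(rs)
  expect_length(txt, length(rs))
  expect_true(all(grepl("^Rule_\\d+: IF .* THEN .*\\[passed: \\d+\\]$", txt)))
})
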