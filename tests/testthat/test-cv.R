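test_that("a perfectly separating feature yields weighted F1 of 1 under DT", {
  ds <- separable_dataset(n_per_class = 30)
  rep <- cross_validate(ds, "sep01", classifier_spec("DT"), n_folds = 10,
                        balance = balancing_config(seed = 2), seed = 3)
  expect_equal(rep$weighted_f1, 1)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$mcc, 1)
})

test_that("folds are stratified: per-class counts differ by at most one", {
  y <- factor(rep(c("A", "B"), times = c(30, 12)))
  folds <- stratified_folds(y, n_folds = 10, seed = 4)
  tab <- table(y, folds)
  expect_true(all(tab["A", ] == 3))
  expect_true(all(tab["B", ] %in% 1:2))
  expect_equal(sum(tab), 42)
})

test_that("SMOTE never touches the held-out split: fold assignment is identical with and without balancing", {
  ds <- separable_dataset(n_per_class = 20)
  with_bal <- cross_validate(ds, ds$gene_ids, classifier_spec("DT"),
                             n_folds = 5, balance = balancing_config(seed = 9),
                             seed = 11)
  without <- cross_validate(ds, ds$gene_ids, classifier_spec("DT"),
                            n_folds = 5, balance = NULL, seed = 11)
  expect_identical(with_bal$meta$held_out_folds, without$meta$held_out_folds)
})

test_that("unknown feature ids and degenerate classes raise the documented errors", {
  ds <- separable_dataset(n_per_class = 10)
  expect_error(cross_validate(ds, c("sep01", "ghost_gene"),
                              classifier_spec("DT"), n_folds = 5,
                              seed = 1),
               "unknown feature")
  # a single-member class cannot be present in its own fold's training split
  m <- ds$matrix
  labels <- as.character(ds$labels)
  labels[1] <- "solo"
  ds2 <- expression_dataset(m, ds$cell_ids, ds$gene_ids, labels = labels)
  expect_error(cross_validate(ds2, "sep01", classifier_spec("DT"),
                              n_folds = 5, balance = NULL, seed = 1),
               "fold error.*solo")
})

test_that("pooled confusion matrix covers every cell exactly once", {
  ds <- separable_dataset(n_per_class = 25)
  rep <- cross_validate(ds, ds$gene_ids, classifier_spec("DT"), n_folds = 10,
                        balance = balancing_config(seed = 1), seed = 2)
  expect_equal(sum(rep$confusion), n_cells(ds))
})

test_that("cross-validation is deterministic given its seeds", {
  gd <- generate_dataset(synthetic_spec(200, c(A = 0.6, B = 0.25, C = 0.15),
                                        n_genes = 25, markers_per_class = 3,
                                        seed = 2))
  run <- function() {
    cross_validate(gd$data, gd$data$gene_ids[1:10],
                   classifier_spec("RF", seed = 5), n_folds = 5,
                   balance = balancing_config(seed = 6), seed = 7)
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$weighted_f1, r2$weighted_f1)
})

test_that("balancing the whole dataset before splitting is available as an explicit flag", {
  gd <- generate_dataset(synthetic_spec(120, c(A = 0.7, B = 0.3),
                                        n_genes = 15, markers_per_class = 3,
                                        seed = 4))
  r <- cross_validate(gd$data, gd$data$gene_ids[1:10],
                      classifier_spec("DT"), n_folds = 5,
                      balance = balancing_config(seed = 1), seed = 2,
                      smote_before_cv = TRUE)
  # evaluation now covers original + synthetic rows: 2 x majority count
  expect_equal(sum(r$confusion), 2 * max(table(gd$data$labels)))
})
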