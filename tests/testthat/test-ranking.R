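make_encoded_dataset <- function(n = 60, seed = 3) {
  # g0 deterministically encodes the class; all other genes are constant
  withr::with_seed(seed, {
    labels <- sample(c("A", "B", "C"), n, replace = TRUE)
  })
  m <- cbind(g0 = as.numeric(factor(labels)) * 10,
             g1 = rep(5, n), g2 = rep(2, n))
  expression_dataset(m, sprintf("c%03d", 1:n), colnames(m), labels = labels)
}

test_that("the only usable split variable is ranked first by both backends", {
  ds <- make_encoded_dataset()
  for (method in c("xgboost", "stump")) {
    rk <- rank_features(ds, seed = 1, method = method,
                        params = if (method == "xgboost") list(nrounds = 10)
                                 else list(nrounds = 10))
    expect_equal(rk$gene_id[1], "g0")
    expect_gt(rk$importance[1], 0)
    expect_equal(rk$importance[2:3], c(0, 0))
    expect_equal(rk$gene_id[2:3], c("g1", "g2"))  # ties keep column order
  }
})

test_that("an all-constant matrix gives zero importances in input column order", {
  m <- matrix(3, 20, 4, dimnames = list(NULL, paste0("g", 1:4)))
  ds <- expression_dataset(m, sprintf("c%02d", 1:20), colnames(m),
                           labels = rep(c("A", "B"), 10))
  for (method in c("xgboost", "stump")) {
    rk <- rank_features(ds, seed = 1, method = method)
    expect_equal(rk$importance, rep(0, 4))
    expect_equal(rk$gene_id, paste0("g", 1:4))
  }
})

test_that("single-class labels are a ranking error", {
  m <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("g1", "g2")))
  ds <- expression_dataset(m, sprintf("c%02d", 1:10), colnames(m),
                           labels = rep("only", 10))
  expect_error(rank_features(ds, seed = 1), "ranking error")
})

test_that("split counts sum to the number of internal nodes of the ensemble", {
  gd <- generate_dataset(synthetic_spec(150, c(A = 0.4, B = 0.3, C = 0.3),
                                        n_genes = 30, markers_per_class = 3,
                                        seed = 6))
  model <- cellrules:::fit_xgb_booster(gd$data$matrix, gd$data$labels,
                                       params = list(nrounds = 8), seed = 2)
  tab <- importance_table(model)
  dump <- xgboost::xgb.model.dt.tree(model = model)
  expect_equal(sum(tab$split_count), sum(dump$Feature != "Leaf"))
  expect_true(all(tab$split_count == floor(tab$split_count)))
  expect_true(all(tab$split_count >= 0))
})

test_that("stump-booster importance counts stumps exactly", {
  # hand-built ensemble: three stumps on g2, one on g1
  model <- structure(
    list(stumps = list(
      A = list(list(feature = 2L, threshold = 1, left_value = -1,
                    right_value = 1, gain = 3),
               list(feature = 2L, threshold = 2, left_value = -1,
                    right_value = 1, gain = 2)),
      B = list(list(feature = 2L, threshold = 1, left_value = 1,
                    right_value = -1, gain = 4),
               list(feature = 1L, threshold = 0, left_value = 0,
                    right_value = 1, gain = 1))),
      feature_names = c("g1", "g2", "g3")),
    class = "stump_booster")
  tab <- importance_table(model)
  expect_equal(tab$split_count, c(1, 3, 0))
  expect_equal(tab$total_gain, c(1, 9, 0))

  # a single fitted stump concentrates importance on the informative gene
  ds <- make_encoded_dataset(n = 40, seed = 8)
  m1 <- fit_stump_booster(ds$matrix, ds$labels, params = list(nrounds = 1))
  t1 <- importance_table(m1)
  expect_equal(t1$split_count[t1$gene == "g0"], 3)  # one stump per class
  expect_gt(t1$total_gain[t1$gene == "g0"], 0)
  expect_equal(t1$split_count[t1$gene != "g0"], c(0, 0))
})

test_that("unfitted objects are a state error", {
  expect_error(importance_table(list()), "state error")
})

test_that("permuting gene columns permutes importances identically (stump backend)", {
  gd <- generate_dataset(synthetic_spec(120, c(A = 0.5, B = 0.5),
                                        n_genes = 12, markers_per_class = 2,
                                        seed = 10))
  rk1 <- rank_features(gd$data, seed = 1, method = "stump",
                       params = list(nrounds = 15))
  perm <- rev(seq_len(n_genes(gd$data)))
  ds2 <- expression_dataset(gd$data$matrix[, perm],
                            gd$data$cell_ids, gd$data$gene_ids[perm],
                            labels = gd$data$labels)
  rk2 <- rank_features(ds2, seed = 1, method = "stump",
                       params = list(nrounds = 15))
  imp1 <- stats::setNames(rk1$importance, rk1$gene_id)
  imp2 <- stats::setNames(rk2$importance, rk2$gene_id)
  expect_equal(imp1[sort(names(imp1))], imp2[sort(names(imp2))])
})

test_that("ranking is reproducible under a fixed seed", {
  gd <- generate_dataset(synthetic_spec(150, c(A = 0.5, B = 0.5),
                                        n_genes = 20, markers_per_class = 2,
                                        seed = 3))
  r1 <- rank_features(gd$data, seed = 5, params = list(nrounds = 10))
  r2 <- rank_features(gd$data, seed = 5, params = list(nrounds = 10))
  expect_identical(r1$gene_id, r2$gene_id)
  expect_identical(r1$importance, r2$importance)
})
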