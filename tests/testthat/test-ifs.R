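rl <- function(n) {
  ranked_feature_list(sprintf("g%04d", seq_len(n)), rev(seq_len(n)))
}

test_that("subset generation follows the step/cap prefix rule", {
  s <- generate_subsets(rl(3), step = 5, cap = 1000)
  expect_length(s, 1L)
  expect_length(s[[1]], 3L)

  s <- generate_subsets(rl(12), step = 5, cap = 1000)
  expect_equal(lengths(s), c(5L, 10L, 12L))

  s <- generate_subsets(rl(2000), step = 5, cap = 1000)
  expect_equal(lengths(s), seq(5L, 1000L, by = 5L))

  expect_error(generate_subsets(ranked_feature_list(character(0), numeric(0)),
                                step = 5),
               "empty ranked list")
})

test_that("subsets are strictly nested prefixes", {
  s <- generate_subsets(rl(43), step = 7, cap = 40)
  expect_equal(lengths(s), c(7L, 14L, 21L, 28L, 35L, 40L))
  for (i in seq_len(length(s) - 1)) {
    expect_identical(s[[i]], s[[i + 1]][seq_along(s[[i]])])
  }
})

test_that("a single-subset run puts the optimum at that subset's size", {
  ds <- separable_dataset(n_per_class = 20)
  ranked <- ranked_feature_list(ds$gene_ids, c(4, 3, 2, 1))
  curve <- run_ifs(ds, ranked,
                   ifs_config(step = 10, cap = 10,
                              classifier = classifier_spec("DT"),
                              balance = balancing_config(seed = 1),
                              n_folds = 5, cv_seed = 2))
  expect_equal(nrow(curve$records), 1L)
  expect_equal(curve$optimum_k, 4L)  # terminal partial subset of all 4 genes
})

test_that("ties in weighted F1 resolve to the smallest subset size", {
  # sep01 separates perfectly, so k = 1 and k = 4 both reach weighted F1 = 1
  ds <- separable_dataset(n_per_class = 20)
  ranked <- ranked_feature_list(ds$gene_ids, c(4, 3, 2, 1))
  curve <- run_ifs(ds, ranked,
                   ifs_config(step = 1, cap = 4,
                              classifier = classifier_spec("DT"),
                              balance = balancing_config(seed = 1),
                              n_folds = 5, cv_seed = 2))
  expect_equal(max(curve$records$weighted_f1), 1)
  expect_equal(curve$optimum_k, 1L)
})

test_that("optimal refit uses the top-k features and reproduces training behaviour", {
  ds <- separable_dataset(n_per_class = 15)
  ranked <- ranked_feature_list(ds$gene_ids, c(4, 3, 2, 1))
  expect_error(fit_optimal(ds, ranked, 99), "out of range")

  opt_all <- fit_optimal(ds, ranked, 4, classifier_spec("DT"))
  expect_identical(dim(opt_all$X_train),
                   dim(ds$matrix))  # k = N keeps the full training matrix
  expect_identical(sort(colnames(opt_all$X_train)), sort(ds$gene_ids))

  opt1 <- fit_optimal(ds, ranked, 1, classifier_spec("DT"))
  expect_equal(opt1$feature_ids, "sep01")
  pred <- predict_classifier(opt1$fit, opt1$X_train)
  expect_equal(as.character(pred), as.character(opt1$y_train))  # training acc 1
})

test_that("resubstitution performance is at least the cross-validated optimum", {
  fx <- synth_with_ranking(1)
  sizes <- c(50L, 100L)
  curve <- suppressWarnings(run_ifs(
    fx$data, fx$ranked,
    ifs_config(step = 50, cap = 100, classifier = classifier_spec("DT", seed = 2),
               balance = balancing_config(seed = 3), cv_seed = 4)))
  opt <- fit_optimal(fx$data, fx$ranked, curve$optimum_k,
                     classifier_spec("DT", seed = 2))
  resub <- weighted_f1(opt$y_train, predict_classifier(opt$fit, opt$X_train))
  expect_gte(resub, curve$optimum_weighted_f1)
  expect_true(curve$optimum_k %in% sizes)
})

test_that("rerunning IFS with identical seeds reproduces the curve bit-identically", {
  ds <- separable_dataset(n_per_class = 20)
  ranked <- ranked_feature_list(ds$gene_ids, c(4, 3, 2, 1))
  cfg <- ifs_config(step = 2, cap = 4, classifier = classifier_spec("RF", seed = 5),
                    balance = balancing_config(seed = 6), n_folds = 5,
                    cv_seed = 7)
  c1 <- run_ifs(ds, ranked, cfg)
  c2 <- run_ifs(ds, ranked, cfg)
  expect_identical(c1$records, c2$records)
})
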