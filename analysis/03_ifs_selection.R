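#!/usr/bin/env Rscript
# Incremental feature selection over nested prefixes of the ranked list
# (sizes 50/100/150 at this benchmark scale), evaluated by stratified
# 10-fold cross-validation with in-fold SMOTE, for both classifiers.

suppressMessages(library(cellrules))

seed <- 1L
data <- read_expression("results/data/matrix.mtx", "results/data/genes.tsv",
                        "results/data/cells.tsv", "results/data/labels.tsv")
ranked <- read_ranked_list("results/ranked_list.tsv")

optima <- list()
for (cl in c("RF", "DT")) {
  curve <- suppressWarnings(run_ifs(
    data, ranked,
    ifs_config(step = 50, cap = 150,
               classifier = classifier_spec(cl, seed = seed + 2L),
               balance = balancing_config(seed = seed + 3L),
               n_folds = 10, cv_seed = seed + 4L),
    progress = TRUE))
  write_ifs_curve(curve, sprintf("results/ifs_%s.tsv", tolower(cl)))
  optima[[cl]] <- list(optimum_k = curve$optimum_k,
                       weighted_f1 = curve$optimum_weighted_f1)
  message(sprintf("%s optimum: k = %d, weighted F1 = %.4f", cl,
                  curve$optimum_k, curve$optimum_weighted_f1))
}
jsonlite::write_json(optima, "results/ifs_optima.json", auto_unbox = TRUE,
                     digits = I(17))
message("wrote results/ifs_rf.tsv, results/ifs_dt.tsv, results/ifs_optima.json")
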