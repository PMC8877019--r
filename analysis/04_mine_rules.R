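#!/usr/bin/env Rscript
# Refit the optimal decision tree on the full (unbalanced) dataset, extract
# its IF-THEN rules with passed counts, and tabulate rules per cell type and
# the top rules by passed count.

suppressMessages(library(cellrules))

seed <- 1L
data <- read_expression("results/data/matrix.mtx", "results/data/genes.tsv",
                        "results/data/cells.tsv", "results/data/labels.tsv")
ranked <- read_ranked_list("results/ranked_list.tsv")
optima <- jsonlite::read_json("results/ifs_optima.json")

opt <- fit_optimal(data, ranked, optima$DT$optimum_k,
                   classifier = classifier_spec("DT", seed = seed + 2L))
rules <- extract_rules(opt)
write_ruleset(rules, "results/ruleset.json")
writeLines(format_rules(rules), "results/rules.txt")

counts <- rules_per_class(rules)
data.table::fwrite(data.frame(cell_type = names(counts),
                              n_rules = as.integer(counts)),
                   "results/rules_per_class.tsv", sep = "\t")

message(sprintf("%d rules from the optimal DT (k = %d); passed counts sum to %d cells",
                length(rules), optima$DT$optimum_k,
                sum(vapply(rules$rules, function(r) r$passed_count,
                           integer(1)))))
message("rules per cell type:")
for (cl in names(counts)) message(sprintf("  %-26s %4d", cl, counts[[cl]]))
message("top rule per cell type by passed count:")
for (cl in rules$class_names) {
  top <- top_rules(rules, cl, n = 1)
  if (length(top)) {
    message(sprintf("  %-26s passed %4d", cl, top[[1]]$passed_count))
  }
}
message("wrote results/ruleset.json, results/rules.txt, results/rules_per_class.tsv")
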