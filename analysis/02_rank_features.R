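#!/usr/bin/env Rscript
# Rank all genes by gradient-boosted-tree split-count importance and check
# how many of the planted markers surface near the top of the list.

suppressMessages(library(cellrules))

seed <- 1L
dir.create("results", showWarnings = FALSE)

data <- read_expression("results/data/matrix.mtx", "results/data/genes.tsv",
                        "results/data/cells.tsv", "results/data/labels.tsv")
truth <- jsonlite::read_json("results/data/ground_truth.json")
markers <- unlist(truth$marker_map)

ranked <- rank_features(data, seed = seed + 1L)
write_ranked_list(ranked, "results/ranked_list.tsv")

message("top 10 ranked genes: ",
        paste(ranked$gene_id[1:10], collapse = ", "))
for (top in c(55, 110, 220)) {
  message(sprintf("planted markers in top %3d ranks: %2d / %d", top,
                  sum(markers %in% ranked$gene_id[seq_len(top)]),
                  length(markers)))
}
message("wrote results/ranked_list.tsv")
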