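#!/usr/bin/env Rscript
# Stage 6: subsampled consensus K-means over the panel (all tumors),
# CDF-area table across K = 2..9, cluster labels at the selected K and at
# the planted K = 7, and their cross-tabulation against the planted truth.

library(vegfsema)

expr <- read_expression("results/cohort/expression.tsv")
ann <- read_annotation("results/cohort/annotation.tsv")
truth <- jsonlite::read_json("results/cohort/truth.json")
tumors <- ann$sample_id[ann$group == "tumor"]

X <- t(subset_panel(expr)[, tumors])
ks <- 2:9
results <- lapply(ks, function(k) {
  message("consensus clustering at k = ", k)
  consensus_cluster(X, k, iterations = 100, subsample_fraction = 0.8,
                    restarts = 50, seed = 600L + k)
})
sel <- select_k(results)
write.table(data.frame(k = sel$k_range, cdf_area = sel$cdf_areas,
                       relative_change = sel$relative_area_changes),
            "results/consensus_k_selection.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("CDF-area table written; area-rule selection: k = ", sel$chosen_k,
        " (inspect the consensus matrices before trusting any automated K)")

truth_cl <- unlist(truth$cluster[tumors])
for (k in c(sel$chosen_k, 7)) {
  res <- results[[match(k, ks)]]
  write.table(data.frame(sample_id = names(res$labels),
                         cluster = unname(res$labels)),
              sprintf("results/consensus_labels_k%d.tsv", k), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ari <- adjusted_rand_index(res$labels[tumors], truth_cl)
  message(sprintf("k = %d: ARI vs planted clusters = %.3f", k, ari))
  ct <- crosstab(truth_cl, res$labels[tumors])
  message("modal capture per planted cluster (%):")
  print(round(apply(ct$row_pct, 1, max), 1))
}
write_expression(results[[match(7, ks)]]$consensus,
                 "results/consensus_matrix_k7.tsv", id_column = "sample_id")
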