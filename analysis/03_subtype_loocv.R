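#!/usr/bin/env Rscript
# Stage 3: Spearman nearest-centroid classification of the planted
# expression clusters, evaluated by leave-one-out cross validation
# (centroids refit per fold; unclassified counts as wrong).

library(vegfsema)

expr <- read_expression("results/cohort/expression.tsv")
ann <- read_annotation("results/cohort/annotation.tsv")
truth <- jsonlite::read_json("results/cohort/truth.json")
tumors <- ann$sample_id[ann$group == "tumor"]

panel <- subset_panel(expr)[, tumors]
labels <- unlist(truth$cluster[tumors])

cv <- loocv_centroid(panel, labels)
write.table(
  data.frame(sample_id = tumors, truth = labels, predicted = cv$predicted),
  "results/subtype_loocv.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("LOOCV accuracy: %.1f%% (%d/%d)", 100 * cv$accuracy,
                cv$n_correct, cv$n))
print(cv$confusion)
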