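#!/usr/bin/env Rscript
# Stage 2: call triple-negative status from ESR1/PGR/ERBB2 expression.
# IHC decides where informative; the class-conditional Gaussian model
# covers the rest. Calls are compared against the generator's truth.

library(vegfsema)

expr <- read_expression("results/cohort/expression.tsv")
ann <- read_annotation("results/cohort/annotation.tsv")
truth <- jsonlite::read_json("results/cohort/truth.json")
tumors <- ann[ann$group == "tumor", ]

calls <- call_tn_status(expr, tumors)
write.table(calls, "results/tn_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth_tn <- ifelse(unlist(truth$tn_true[calls$sample_id]), "TN", "RP")
err <- status_error_rate(calls$tn_call, truth_tn)
message(sprintf("TN calls: %d/%d by IHC, %d by model",
                sum(calls$source == "ihc"), nrow(calls),
                sum(calls$source == "model")))
message(sprintf("misclassification vs truth: %.2f%% (%d/%d)",
                100 * err$error_rate, err$n_wrong, err$n))
print(err$table)
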