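#!/usr/bin/env Rscript
# Stage 1: generate the synthetic breast-tumor cohort all later stages use.
# 800 tumors + 40 normals; 31-gene VEGF/semaphorin panel with 7 planted
# expression clusters; bimodal ESR1/PGR/ERBB2; exponential PH survival.

library(vegfsema)

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
cfg <- cohort_config(seed = 20130508L)
cohort <- generate_cohort(cfg)

write_expression(cohort$expression, "results/cohort/expression.tsv")
write_annotation(cohort$annotation, "results/cohort/annotation.tsv")
jsonlite::write_json(
  list(cluster = as.list(cohort$truth$cluster),
       tn_true = as.list(cohort$truth$tn_true),
       signature_score = as.list(cohort$truth$signature_score),
       coefficients = cohort$truth$coefficients),
  "results/cohort/truth.json", auto_unbox = TRUE)

tab <- table(cohort$truth$cluster, useNA = "no")
message("planted cluster sizes: ",
        paste(names(tab), tab, sep = "=", collapse = " "))
message(sprintf("true TN fraction: %.1f%%",
                100 * mean(cohort$truth$tn_true[
                  cohort$annotation$group == "tumor"])))
message("cohort written under results/cohort/")
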