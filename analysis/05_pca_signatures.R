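#!/usr/bin/env Rscript
# Stage 5: PCA expression signatures over the panel (all tumors), their
# association with TN status (logistic regression on the first 8 scores;
# Wilks' lambda on the leading score plane), and the TN-only PCA for
# signature comparison across sample sets.

library(vegfsema)

expr <- read_expression("results/cohort/expression.tsv")
ann <- read_annotation("results/cohort/annotation.tsv")
calls <- read.delim("results/tn_calls.tsv")
tumors <- ann$sample_id[ann$group == "tumor"]

panel <- subset_panel(expr)
pca_all <- fit_pca(panel[, tumors], label_suffix = "a")
write.table(data.frame(gene = rownames(pca_all$loadings), pca_all$loadings,
                       check.names = FALSE),
            "results/pca_loadings_all.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(sample_id = rownames(pca_all$scores), pca_all$scores,
                       check.names = FALSE),
            "results/pca_scores_all.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

tn <- calls$tn_call[match(tumors, calls$sample_id)] == "TN"
assoc <- logistic_association(pca_all$scores, as.numeric(tn))
write.table(assoc, "results/pca_tn_logistic.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
top <- assoc$component[which.max(abs(assoc$coef))]
message(sprintf("strongest TN association: %s (coef %.2f, p %.2g)",
                top, assoc$coef[which.max(abs(assoc$coef))],
                assoc$p[which.max(abs(assoc$coef))]))

wk <- manova_wilks(pca_all$scores[, 1:2], ifelse(tn, "TN", "RP"))
message(sprintf("Wilks' lambda on (PC1a, PC2a) by TN: %.3f, chi2 = %.1f, p = %.2g",
                wk$lambda, wk$chi2, wk$p))

# TN-only PCA and cross-fit loading comparison
pca_tn <- fit_pca(panel[, tumors[tn]], label_suffix = "t")
cmp <- sapply(1:4, function(j) {
  sapply(1:4, function(i) compare_loadings(pca_all, i, pca_tn, j)$r)
})
dimnames(cmp) <- list(paste0("PC", 1:4, "a"), paste0("PC", 1:4, "t"))
write.table(data.frame(component = rownames(cmp), round(cmp, 3),
                       check.names = FALSE),
            "results/pca_loading_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("loading correlation (all-tumor vs TN-only components):")
print(round(cmp, 2))

genes_big <- top_loading_genes(pca_all, 1, 2, radius = 0.2)
message("genes with |loading| > 0.2 on the (PC1a, PC2a) plane: ",
        paste(genes_big$gene, collapse = ", "))
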