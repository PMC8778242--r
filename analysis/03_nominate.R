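#!/usr/bin/env Rscript
# Stage 03 -- intersect REC evidence with basal-expression/sensitivity
# correlations and nominate candidate compounds.
#
# A compound is nominated iff it shows negative REC with FDR <= 1e-3 and
# top-30 membership for BOTH target genes at BOTH timepoints, and its
# sensitivity AUC correlates negatively (p <= 0.05) with basal expression of
# both target genes (lower AUC = more sensitive).

library(recscreen)

cfg <- run_config(seed = 1L)
target_genes <- c("MCM2", "MCM10")

rec <- read_output_tsv("results/rec_scores.tsv")
expr <- read_labeled_matrix("results/data/basal_expression.tsv")
sens <- read_labeled_matrix("results/data/sensitivity_auc.tsv")

corr <- sensitivity_correlation_table(expr, sens, target_genes)
cand <- nominate(rec, corr, cfg, target_genes)
write_output_tsv(as.data.frame(cand), "results/candidates.tsv", cfg)
writeLines(cand$compound[cand$nominated], "results/nominated.txt")

cat("Correlations computed for", nrow(corr), "compound x gene pairs\n")
cat("Nominated compounds:",
    if (any(cand$nominated)) paste(cand$compound[cand$nominated], collapse = ", ")
    else "(none)", "\n")
show <- cand[cand$nominated, c("compound", "rec_MCM2_6h", "fdr_MCM2_6h",
                               "rec_MCM10_24h", "fdr_MCM10_24h",
                               "r_MCM2", "p_MCM2", "r_MCM10", "p_MCM10")]
print(show, row.names = FALSE, digits = 3)
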