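#!/usr/bin/env Rscript
# Stage 04 -- preranked GSEA on the nominated compound's REC gene list.
#
# The full per-gene REC slice of the nominated compound (choose the
# timepoint below) is the ranked list; sets come from the demo GMT. In the
# demo world the gene sets are random draws, so enrichment should be null --
# a calibration exhibit rather than a discovery: with planted member sets
# this stage reports them at q < 0.25.

library(recscreen)

cfg <- run_config(seed = 1L)
timepoint <- "6h" # d6 slice; switch to "24h" for the d24 list

compound <- readLines("results/nominated.txt")[1]
tensor <- read_signature_tensor("results/data/signatures.tsv")
sub <- signature_tensor(tensor$z[compound, , , , drop = FALSE])
rec_all <- rec_table(sub, timepoints = timepoint, p_method = "exact")
rlist <- ranked_gene_list(rec_all$gene, rec_all$rec)

collection <- read_gmt("results/data/gene_sets.gmt")
res <- gsea(rlist, collection, cfg)
write_output_tsv(res[, setdiff(names(res), "leading_edge")],
                 "results/gsea_results.tsv", cfg)

cat("Ranked list:", length(rlist), "genes from the", compound, timepoint,
    "REC slice; scored", nrow(res), "sets (",
    length(attr(res, "skipped")), "skipped by size)\n")
cat("Sets with FDR q <", cfg$gsea_q_max, ":", sum(res$fdr_q < cfg$gsea_q_max), "\n")
print(utils::head(res[, c("set", "size_used", "es", "nes", "p", "fdr_q")], 5),
      row.names = FALSE, digits = 3)
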