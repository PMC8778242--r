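#' Emit a complete synthetic demo dataset
#'
#' Writes every input the pipeline consumes -- tall signature TSV, basal
#' expression and sensitivity matrices, a survival cohort CSV, a GMT gene
#' set collection (random sets plus one planted in the top REC decile is
#' left to the GSEA driver), fused/fission TIFF pairs and a dose-response
#' CSV -- into `dir`, all derived from `cfg$seed`.
#'
#' @param dir output directory (created if needed).
#' @param spec a [plant_spec()].
#' @param cfg a [run_config()].
#' @return invisibly, a named list of the written paths.
#' @export
generate_demo_dataset <- function(dir, spec = plant_spec(), cfg = run_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  tensor <- make_signature_tensor(spec, cfg$seed)
  paths$signatures <- file.path(dir, "signatures.tsv")
  write_signature_tensor(tensor, paths$signatures, cfg)
  panel <- make_sensitivity_panel(spec, cfg$seed)
  paths$expression <- file.path(dir, "basal_expression.tsv")
  write_labeled_matrix(panel$expression, paths$expression, "cell_line", cfg)
  paths$sensitivity <- file.path(dir, "sensitivity_auc.tsv")
  write_labeled_matrix(panel$sensitivity, paths$sensitivity, "compound", cfg)
  cohort <- make_survival_cohort(n = 498, hr = 4, cutoff_q = 0.5,
                                 censor_rate = 0.2, seed = cfg$seed,
                                 gene = spec$target_genes[1])
  paths$survival <- file.path(dir, "survival_cohort.csv")
  write_survival_csv(cohort, paths$survival)
  # gene sets: random draws from the tensor's gene universe
  set.seed(derive_seed(cfg$seed, "demo-gmt"))
  max_size <- min(40L, length(spec$genes) - 1L)
  sets <- lapply(1:20, function(i) {
    sample(spec$genes, sample(seq(min(5L, max_size), max_size), 1))
  })
  names(sets) <- sprintf("RANDOM_SET_%02d", 1:20)
  paths$gmt <- file.path(dir, "gene_sets.gmt")
  write_gmt(sets, paths$gmt)
  pair <- make_mito_condition_pair(seed = cfg$seed)
  for (cond in c("fused", "fission")) {
    for (ch in c("mito", "nucleus")) {
      p <- file.path(dir, sprintf("%s_%s.tif", cond, ch))
      write_tiff16(pair[[cond]][[ch]], p)
      paths[[paste(cond, ch, sep = "_")]] <- p
    }
  }
  dr <- make_dose_response(ic50 = 20, hill = 1.2, noise_sd = 5, seed = cfg$seed)
  paths$dose_response <- file.path(dir, "dose_response.csv")
  utils::write.csv(dr, paths$dose_response, row.names = FALSE, quote = FALSE)
  rs_log("generate", "demo dataset written to ", dir)
  invisible(paths)
}
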