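#' Basal expression versus drug sensitivity correlation
#'
#' Correlates a gene's basal (log2) expression with a compound's sensitivity
#' AUC across the cell lines shared by both tables. Sensitivity is stored as
#' AUC with lower = more sensitive (the CTRP convention), so "high
#' expression goes with sensitivity" corresponds to a negative r against
#' AUC. Pearson is the default; Spearman is available.
#'
#' @param expr cell line x gene numeric matrix (log2 expression).
#' @param sens compound x cell line AUC matrix.
#' @param gene,compound labels to correlate.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame with `gene`, `compound`, `n`, `r`, `p` (two-sided).
#' @export
sensitivity_correlation <- function(expr, sens, gene, compound,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!gene %in% colnames(expr)) stop("gene not in expression matrix: ", gene)
  if (!compound %in% rownames(sens)) stop("compound not in sensitivity table: ", compound)
  shared <- intersect(rownames(expr), colnames(sens))
  x <- expr[shared, gene]
  y <- sens[compound, shared]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("fewer than 3 shared cell lines for (", gene, ", ", compound, ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate correlation: zero variance for (", gene, ", ", compound, ")")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  data.frame(gene = gene, compound = compound, n = length(x),
             r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
}

#' Correlations for every compound against a set of target genes
#'
#' @inheritParams sensitivity_correlation
#' @param genes target gene labels.
#' @param compounds compound labels (default: all rows of `sens`).
#' @return row-bound data.frame of [sensitivity_correlation()] results.
#' @export
sensitivity_correlation_table <- function(expr, sens, genes,
                                          compounds = rownames(sens),
                                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  do.call(rbind, lapply(compounds, function(cp) {
    do.call(rbind, lapply(genes, function(g) {
      sensitivity_correlation(expr, sens, g, cp, method)
    }))
  }))
}

#' Nominate candidate compounds
#'
#' Intersects the recurrence evidence with the sensitivity-correlation
#' evidence. A compound is nominated iff, for EVERY target gene and EVERY
#' timepoint, its REC score is negative, its FDR passes `cfg$rec_fdr_max`
#' and it sits within the `cfg$rec_top_k` most negative REC scores of that
#' slice; and, for every target gene, the expression/AUC correlation has
#' r < 0 with p <= `cfg$corr_p_max`. Conjunctive ("both genes, both
#' timepoints") by design -- relaxing any threshold can only add nominees.
#'
#' @param rec a [rec_table()] data.frame covering all target slices.
#' @param corr a [sensitivity_correlation_table()] data.frame covering every
#'   compound x target gene pair.
#' @param cfg a [run_config()].
#' @param target_genes genes whose reversal is screened for.
#' @param timepoints timepoints required (default: all in `rec`).
#' @return `candidate_table` data.frame, one row per compound: per-slice
#'   `rec_*`, `fdr_*` and top-k membership columns, per-gene `r_*`/`p_*`
#'   columns, and a logical `nominated`.
#' @export
nominate <- function(rec, corr, cfg, target_genes,
                     timepoints = unique(rec$timepoint)) {
  if (is.null(corr) || !nrow(corr)) stop("empty correlation table")
  compounds <- sort(unique(rec$compound))
  out <- data.frame(compound = compounds, stringsAsFactors = FALSE)
  pass_rec <- rep(TRUE, length(compounds))
  for (g in target_genes) {
    for (tp in timepoints) {
      sl <- rec[rec$gene == g & rec$timepoint == tp, , drop = FALSE]
      if (!nrow(sl)) stop("missing REC slice for (", g, ", ", tp, ")")
      i <- match(compounds, sl$compound)
      if (anyNA(i)) stop("missing REC slice for (", g, ", ", tp, ")")
      topk <- rank_rec(sl, g, tp, top_k = min(cfg$rec_top_k, nrow(sl)))
      tag <- paste0(g, "_", tp)
      out[[paste0("rec_", tag)]] <- sl$rec[i]
      out[[paste0("fdr_", tag)]] <- sl$fdr[i]
      out[[paste0("top_", tag)]] <- compounds %in% topk
      pass_rec <- pass_rec & sl$rec[i] < 0 & sl$fdr[i] <= cfg$rec_fdr_max &
        compounds %in% topk
    }
  }
  pass_corr <- rep(TRUE, length(compounds))
  for (g in target_genes) {
    cg <- corr[corr$gene == g, , drop = FALSE]
    i <- match(compounds, cg$compound)
    if (anyNA(i)) stop("missing correlation results for gene ", g)
    out[[paste0("r_", g)]] <- cg$r[i]
    out[[paste0("p_", g)]] <- cg$p[i]
    pass_corr <- pass_corr & cg$r[i] < 0 & cg$p[i] <= cfg$corr_p_max
  }
  out$nominated <- pass_rec & pass_corr
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Run the full expression-reversal screen on synthetic inputs
#'
#' Generates a signature tensor and sensitivity panel from a [plant_spec()],
#' scores every compound on the target genes, computes sensitivity
#' correlations, and nominates candidates -- the end-to-end screening
#' workflow on one synthetic world.
#'
#' @param spec a [plant_spec()].
#' @param cfg a [run_config()]; its seed drives all generation.
#' @param outdir optional directory; when given, `rec_scores.tsv`,
#'   `candidates.tsv` and `nominated.txt` are written there.
#' @return list with `tensor`, `panel`, `rec`, `corr`, `candidates`,
#'   `nominated` (character vector of nominated compounds).
#' @export
run_reversal_screen <- function(spec, cfg = run_config(), outdir = NULL) {
  tensor <- make_signature_tensor(spec, cfg$seed)
  panel <- make_sensitivity_panel(spec, cfg$seed)
  rec <- rec_table(tensor, genes = spec$target_genes,
                   z_thr = cfg$rec_z_threshold, p_method = "exact")
  corr <- sensitivity_correlation_table(panel$expression, panel$sensitivity,
                                        spec$target_genes)
  cand <- nominate(rec, corr, cfg, spec$target_genes)
  nominated <- cand$compound[cand$nominated]
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_output_tsv(rec, file.path(outdir, "rec_scores.tsv"), cfg)
    write_output_tsv(as.data.frame(cand), file.path(outdir, "candidates.tsv"), cfg)
    writeLines(nominated, file.path(outdir, "nominated.txt"))
  }
  list(tensor = tensor, panel = panel, rec = rec, corr = corr,
       candidates = cand, nominated = nominated)
}
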