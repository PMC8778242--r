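#' Pipeline run configuration
#'
#' Central container for every tunable threshold of the screen. Defaults are
#' the screen's published operating point: a |z| >= 2 call threshold for the
#' recurrence score, FDR <= 1e-3 on the REC permutation test, p <= 0.05 for
#' the basal-expression/sensitivity correlation, membership in the top 30
#' most-negative REC scores, 1000 permutations and set sizes 10..500 with
#' q < 0.25 for preranked GSEA, and a 3-pixel minimum object size for
#' mitochondrial morphometry.
#'
#' @param seed integer master seed; every stochastic stage derives a named
#'   substream from it via [derive_seed()].
#' @param rec_z_threshold z-score magnitude above which a cell line counts as
#'   up-/downregulated in the REC score.
#' @param rec_fdr_max BH FDR cutoff for the REC screen.
#' @param corr_p_max two-sided p cutoff for the sensitivity correlation.
#' @param rec_top_k a nominated compound must sit within the `rec_top_k` most
#'   negative REC scores of every target slice.
#' @param gsea_permutations number of gene-label permutations for GSEA.
#' @param gsea_set_min,gsea_set_max admissible gene-set sizes (after
#'   intersection with the ranked list).
#' @param gsea_q_max GSEA FDR q-value significance cutoff.
#' @param scan_min_group minimum patients per arm in the survival cutoff scan;
#'   `NA` means the per-cohort default `max(8, ceiling(0.05 * n))`.
#' @param mito_blur_sigma_px Gaussian blur sigma (pixels) before thresholding.
#' @param mito_min_object_px minimum object size in pixels.
#' @return object of class `rec_config` (a validated named list).
#' @export
run_config <- function(seed = 1L,
                       rec_z_threshold = 2.0,
                       rec_fdr_max = 1e-3,
                       corr_p_max = 0.05,
                       rec_top_k = 30L,
                       gsea_permutations = 1000L,
                       gsea_set_min = 10L,
                       gsea_set_max = 500L,
                       gsea_q_max = 0.25,
                       scan_min_group = NA_integer_,
                       mito_blur_sigma_px = 1.2,
                       mito_min_object_px = 3L) {
  cfg <- list(
    seed = as.integer(seed),
    rec_z_threshold = as.numeric(rec_z_threshold),
    rec_fdr_max = as.numeric(rec_fdr_max),
    corr_p_max = as.numeric(corr_p_max),
    rec_top_k = as.integer(rec_top_k),
    gsea_permutations = as.integer(gsea_permutations),
    gsea_set_min = as.integer(gsea_set_min),
    gsea_set_max = as.integer(gsea_set_max),
    gsea_q_max = as.numeric(gsea_q_max),
    scan_min_group = if (is.na(scan_min_group)) NA_integer_ else as.integer(scan_min_group),
    mito_blur_sigma_px = as.numeric(mito_blur_sigma_px),
    mito_min_object_px = as.integer(mito_min_object_px)
  )
  stopifnot(
    length(cfg$seed) == 1L, !is.na(cfg$seed),
    cfg$rec_z_threshold > 0,
    cfg$rec_fdr_max > 0, cfg$rec_fdr_max < 1,
    cfg$corr_p_max > 0, cfg$corr_p_max < 1,
    cfg$rec_top_k >= 1L,
    cfg$gsea_permutations >= 1L,
    cfg$gsea_set_min >= 1L,
    cfg$gsea_set_min <= cfg$gsea_set_max,
    cfg$gsea_q_max > 0, cfg$gsea_q_max < 1,
    is.na(cfg$scan_min_group) || cfg$scan_min_group >= 1L,
    cfg$mito_blur_sigma_px > 0,
    cfg$mito_min_object_px >= 1L
  )
  class(cfg) <- "rec_config"
  cfg
}

#' @export
print.rec_config <- function(x, ...) {
  cat("<rec_config> hash", config_hash(x), "\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# 32-bit FNV-1a over a character string; returned as double in [0, 2^32).
# Used for config stamping and seed-substream derivation only -- not
# cryptographic, just stable across platforms with no extra dependency.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    # XOR with a byte only touches the low 8 bits; keeps h a double in [0, 2^32)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619; 16-bit split keeps
    # every intermediate below 2^53 so double arithmetic stays exact
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Short reproducibility hash of a run configuration
#'
#' @param cfg a `rec_config`.
#' @return 8-hex-digit string, stamped into every output table header.
#' @export
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) format(v, digits = 15L), ""),
             sep = "=", collapse = ";")
  h <- fnv1a32(s)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Derive a named seed substream
#'
#' All randomness in the pipeline flows from one master seed through named
#' substreams, so stages can be re-run independently yet reproducibly and
#' adding a stage never perturbs another stage's draws.
#'
#' @param seed master integer seed.
#' @param stream character stream name (e.g. `"signature"`).
#' @return an integer seed in `[1, 2^31 - 2]`, a pure function of the inputs.
#' @export
derive_seed <- function(seed, stream) {
  h <- fnv1a32(paste0(stream, ":", format(seed)))
  as.integer(h %% 2147483645) + 1L
}

# Lightweight structured log line; silenced unless options(recscreen.verbose).
rs_log <- function(stage, ...) {
  if (isTRUE(getOption("recscreen.verbose", FALSE))) {
    message(sprintf("[recscreen|%s] %s", stage, paste0(...)))
  }
  invisible(NULL)
}
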