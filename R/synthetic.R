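#' Cell line panel used throughout the screen
#'
#' The ten-line LINCS-style panel over which recurrence is scored.
#' @export
LINCS_CELL_LINES <- c("A357", "A549", "HA1E", "HCC515", "HEPG2",
                      "HT29", "MCF7", "NPC", "PC3", "VCAP")

#' Specification of planted structure for synthetic inputs
#'
#' Describes the "stated world" from which all synthetic pipeline inputs are
#' drawn: background signatures are standard-normal-like z-scores; each
#' reversal compound shifts each target gene by `reversal_effect` in a random
#' `reversal_cell_fraction` of cell lines (the same lines at both
#' timepoints); basal expression and sensitivity AUC of target-gene /
#' reversal-compound pairs share a planted correlation of `-|corr_r|`
#' (lower AUC = more sensitive, high expression = more sensitive).
#'
#' `n_compounds` and `n_genes` are TOTAL axis sizes; `reversal_compounds`
#' and `target_genes` name (and replace) the final labels of each axis, so
#' "one planted compound among 200 nulls" is `n_compounds = 201`.
#'
#' @param n_compounds total number of compounds (incl. reversal compounds).
#' @param n_genes total number of genes (incl. target genes).
#' @param cell_lines cell line labels (default the 10-line panel).
#' @param timepoints timepoint labels (default 6h and 24h).
#' @param target_genes genes carrying planted effects.
#' @param reversal_compounds compounds carrying planted effects.
#' @param reversal_effect mean z shift (negative = downregulation).
#' @param reversal_cell_fraction fraction of cell lines shifted, in (0, 1].
#' @param corr_r magnitude of the planted expression/sensitivity
#'   correlation, in `[-1, 1]` (the sign against AUC is always negative).
#' @param noise_sd background z standard deviation.
#' @return validated `plant_spec` list.
#' @export
plant_spec <- function(n_compounds = 201L,
                       n_genes = 200L,
                       cell_lines = LINCS_CELL_LINES,
                       timepoints = c("6h", "24h"),
                       target_genes = c("MCM2", "MCM10"),
                       reversal_compounds = "BI-2536",
                       reversal_effect = -4,
                       reversal_cell_fraction = 1.0,
                       corr_r = 0.9,
                       noise_sd = 1) {
  stopifnot(
    n_compounds >= 1L, n_genes >= 1L,
    length(cell_lines) >= 1L, length(timepoints) >= 1L,
    length(target_genes) <= n_genes,
    length(reversal_compounds) <= n_compounds,
    reversal_cell_fraction > 0, reversal_cell_fraction <= 1,
    abs(corr_r) <= 1, noise_sd >= 0
  )
  compounds <- sprintf("CPD%04d", seq_len(n_compounds))
  if (length(reversal_compounds)) {
    compounds[n_compounds - rev(seq_along(reversal_compounds)) + 1L] <- reversal_compounds
  }
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (length(target_genes)) {
    genes[n_genes - rev(seq_along(target_genes)) + 1L] <- target_genes
  }
  stopifnot(!anyDuplicated(compounds), !anyDuplicated(genes))
  structure(list(
    compounds = compounds, genes = genes,
    cell_lines = cell_lines, timepoints = timepoints,
    target_genes = target_genes, reversal_compounds = reversal_compounds,
    reversal_effect = reversal_effect,
    reversal_cell_fraction = reversal_cell_fraction,
    corr_r = corr_r, noise_sd = noise_sd
  ), class = "plant_spec")
}

#' Generate a synthetic perturbation signature tensor
#'
#' Background z ~ Normal(0, noise_sd); planted shifts per the spec. Pure
#' function of `(spec, seed)`.
#'
#' @param spec a [plant_spec()].
#' @param seed integer seed (substream `"signature"` is derived from it).
#' @return a [signature_tensor()].
#' @export
make_signature_tensor <- function(spec, seed) {
  stopifnot(inherits(spec, "plant_spec"))
  set.seed(derive_seed(seed, "signature"))
  dn <- list(compound = spec$compounds, gene = spec$genes,
             cell_line = spec$cell_lines, timepoint = spec$timepoints)
  z <- array(stats::rnorm(prod(lengths(dn)), 0, spec$noise_sd),
             dim = unname(lengths(dn)), dimnames = dn)
  n_shift <- max(1L, round(spec$reversal_cell_fraction * length(spec$cell_lines)))
  for (cp in spec$reversal_compounds) {
    for (g in spec$target_genes) {
      lines <- if (n_shift == length(spec$cell_lines)) spec$cell_lines
               else sample(spec$cell_lines, n_shift)
      z[cp, g, lines, ] <- z[cp, g, lines, ] + spec$reversal_effect
    }
  }
  signature_tensor(z)
}

#' Generate a basal-expression / drug-sensitivity panel
#'
#' For each (target gene, reversal compound) pair, log2 basal expression and
#' sensitivity AUC are driven by a shared latent factor so that their
#' correlation is `-|corr_r|` (lower AUC = more sensitive): with
#' `a = sqrt(|corr_r|)`, `expr_g = a*F + sqrt(1-a^2)*e_g` and
#' `auc = -(a*F + sqrt(1-a^2)*e_c)` (then affinely rescaled to log2- and
#' AUC-like units, which leaves Pearson r untouched). At `corr_r = 1` the
#' construction is degenerate and the sample correlation is exactly -1.
#' Non-target genes and non-reversal compounds are independent.
#'
#' @param spec a [plant_spec()].
#' @param seed integer seed (substream `"sensitivity"`).
#' @return list with `expression` (cell line x gene matrix, log2 scale) and
#'   `sensitivity` (compound x cell line AUC matrix).
#' @export
make_sensitivity_panel <- function(spec, seed) {
  stopifnot(inherits(spec, "plant_spec"))
  nl <- length(spec$cell_lines)
  if (nl < 3L) stop("need at least 3 cell lines for a correlation panel")
  set.seed(derive_seed(seed, "sensitivity"))
  expr <- matrix(stats::rnorm(nl * length(spec$genes), 8, 1),
                 nrow = nl, dimnames = list(spec$cell_lines, spec$genes))
  sens <- matrix(stats::rnorm(length(spec$compounds) * nl, 12, 2),
                 nrow = length(spec$compounds),
                 dimnames = list(spec$compounds, spec$cell_lines))
  a <- sqrt(abs(spec$corr_r))
  f <- stats::rnorm(nl)
  for (g in spec$target_genes) {
    expr[, g] <- 8 + a * f + sqrt(1 - a^2) * stats::rnorm(nl)
  }
  for (cp in spec$reversal_compounds) {
    sens[cp, ] <- 12 - 2 * (a * f + sqrt(1 - a^2) * stats::rnorm(nl))
  }
  list(expression = expr, sensitivity = sens)
}

#' Generate a synthetic survival cohort
#'
#' Expression of the scored gene is log-normal; event hazard is exponential
#' at a baseline rate of 0.05 per month, multiplied by `hr` for patients
#' above the `cutoff_q` expression quantile; censoring is independent
#' exponential with hazard `censor_rate` times the baseline event hazard
#' (`censor_rate = 0` means no censoring).
#'
#' @param n cohort size (>= 10).
#' @param hr hazard ratio for the high-expression group (> 0).
#' @param cutoff_q true cutoff quantile in (0, 1).
#' @param censor_rate censoring hazard relative to the baseline event hazard.
#' @param seed integer seed (substream `"survival"`).
#' @param gene name of the scored gene column.
#' @param n_null_genes extra independent log-normal expression columns.
#' @return `survival_cohort` data.frame with attribute `true_cutoff`.
#' @export
make_survival_cohort <- function(n, hr, cutoff_q, censor_rate, seed,
                                 gene = "MCM2", n_null_genes = 0L) {
  if (n < 10L) stop("cohort size must be at least 10")
  stopifnot(hr > 0, cutoff_q > 0, cutoff_q < 1, censor_rate >= 0)
  set.seed(derive_seed(seed, "survival"))
  base_rate <- 0.05 # per month; median null survival ~ 14 months
  expr <- exp(stats::rnorm(n, 3, 1))
  cutoff <- stats::quantile(expr, cutoff_q, names = FALSE)
  rate <- base_rate * ifelse(expr > cutoff, hr, 1)
  t_event <- stats::rexp(n, rate)
  t_cens <- if (censor_rate > 0) stats::rexp(n, base_rate * censor_rate) else rep(Inf, n)
  df <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    time = pmax(pmin(t_event, t_cens), 1e-3),
    event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE
  )
  df[[gene]] <- expr
  if (n_null_genes > 0L) {
    for (k in seq_len(n_null_genes)) {
      df[[sprintf("NULL%02d", k)]] <- exp(stats::rnorm(n, 3, 1))
    }
  }
  attr(df, "true_cutoff") <- cutoff
  class(df) <- c("survival_cohort", "data.frame")
  df
}

# stamp a disc of radius r (pixels) around each (row, col) point; returns
# a logical canvas mask
stamp_tube <- function(points, r, nr, nc) {
  d <- ceiling(r)
  off <- expand.grid(dr = -d:d, dc = -d:d)
  off <- off[off$dr^2 + off$dc^2 <= r^2, , drop = FALSE]
  rows <- outer(points[, 1], off$dr, `+`)
  cols <- outer(points[, 2], off$dc, `+`)
  keep <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc
  mask <- matrix(FALSE, nr, nc)
  mask[cbind(rows[keep], cols[keep])] <- TRUE
  mask
}

#' Generate a synthetic mitochondria / nucleus micrograph pair
#'
#' Mitochondria are rendered as smooth random curved tubes (angular random
#' walks of the stated length and width), the field is blurred by a Gaussian
#' PSF and Poisson photon noise is applied, emulating a confocal
#' MitoTracker/DAPI acquisition after z-projection. Ground truth per tube
#' (capsule area and perimeter in px units, plus the exact pixel mask) is
#' returned so segmentation accuracy is checkable. A "fused" phenotype is
#' emulated by fewer, longer tubes at the same total curve length as a
#' "fission" phenotype (see [make_mito_condition_pair()]).
#'
#' @param n_tubes number of tubes.
#' @param tube_len_px length-2 vector `c(mean, sd)` of tube length in px.
#' @param width_px tube width in px.
#' @param psf_sigma Gaussian PSF sigma in px (0 = none).
#' @param photon_scale multiplier on expected photon counts.
#' @param seed integer seed (substream `"mito"`).
#' @param canvas canvas side in px (>= 256).
#' @param bg_level,fg_level expected background / tube photon counts.
#' @return list with `mito`, `nucleus` (integer matrices), `truth`
#'   (per-tube data.frame), `truth_mask` (logical matrix), `pixel_size_um`.
#' @export
make_mito_image <- function(n_tubes, tube_len_px = c(60, 10), width_px = 6,
                            psf_sigma = 1.2, photon_scale = 1, seed,
                            canvas = 256L, bg_level = 100, fg_level = 1000) {
  if (canvas < 256L) stop("canvas must be at least 256 px")
  stopifnot(n_tubes >= 1L, width_px > 0)
  set.seed(derive_seed(seed, "mito"))
  nr <- nc <- as.integer(canvas)
  margin <- min(ceiling(tube_len_px[1] / 2) + width_px, floor(canvas / 3))
  truth_mask <- matrix(FALSE, nr, nc)
  rows <- list()
  for (k in seq_len(n_tubes)) {
    len <- max(8, stats::rnorm(1, tube_len_px[1], tube_len_px[2]))
    pos <- c(stats::runif(1, margin, nr - margin), stats::runif(1, margin, nc - margin))
    ang <- stats::runif(1, 0, 2 * pi)
    step <- 0.5
    n_steps <- round(len / step)
    pts <- matrix(NA_real_, n_steps, 2)
    for (s in seq_len(n_steps)) {
      ang <- ang + stats::rnorm(1, 0, 0.08)
      pos <- pos + step * c(sin(ang), cos(ang))
      pos <- pmin(pmax(pos, width_px + 1), c(nr, nc) - width_px)
      pts[s, ] <- pos
    }
    tube_mask <- stamp_tube(round(pts), width_px / 2, nr, nc)
    truth_mask <- truth_mask | tube_mask
    rows[[k]] <- data.frame(
      tube = k, length_px = len,
      area_px2 = len * width_px + pi * (width_px / 2)^2,
      perimeter_px = 2 * len + pi * width_px,
      n_px = sum(tube_mask)
    )
  }
  if (mean(truth_mask) > 0.5) stop("overcrowded: tubes cover more than half the canvas")
  expected <- bg_level + (fg_level - bg_level) * truth_mask
  if (psf_sigma > 0) expected <- gaussian_blur(expected, psf_sigma)
  mito <- matrix(stats::rpois(nr * nc, photon_scale * expected), nr, nc)
  # nucleus: one central disc, analysis only uses it as the channel-2 tag
  ctr <- c(nr, nc) / 2
  dd <- outer(seq_len(nr), seq_len(nc),
              function(i, j) (i - ctr[1])^2 + (j - ctr[2])^2)
  nuc_expected <- bg_level + 3000 * (dd <= (canvas / 6)^2)
  if (psf_sigma > 0) nuc_expected <- gaussian_blur(nuc_expected, psf_sigma)
  nucleus <- matrix(stats::rpois(nr * nc, photon_scale * nuc_expected), nr, nc)
  list(mito = pmin(mito, 65535L), nucleus = pmin(nucleus, 65535L),
       truth = do.call(rbind, rows), truth_mask = truth_mask,
       pixel_size_um = 0.1)
}

#' Fused-vs-fission image pair at matched total tube length
#'
#' The fused condition has `n_fused` long tubes, the fission condition
#' `n_fission` short ones, with equal total curve length, so morphology
#' metrics rather than total intensity separate the conditions.
#'
#' @param total_len_px total tube length per condition.
#' @param n_fused,n_fission tube counts (fused < fission).
#' @param seed integer seed.
#' @param ... further arguments to [make_mito_image()].
#' @return list with `fused` and `fission` image lists.
#' @export
make_mito_condition_pair <- function(total_len_px = 600, n_fused = 5L,
                                     n_fission = 15L, seed = 1L, ...) {
  stopifnot(n_fused < n_fission)
  fused <- make_mito_image(n_fused, c(total_len_px / n_fused, 2),
                           seed = derive_seed(seed, "fused"), ...)
  fission <- make_mito_image(n_fission, c(total_len_px / n_fission, 2),
                             seed = derive_seed(seed, "fission"), ...)
  list(fused = fused, fission = fission)
}

#' Generate a synthetic dose-response viability table
#'
#' Viability follows a Hill curve `100 / (1 + (d / ic50)^hill)` (100% at the
#' dose-0 control) plus Gaussian noise. The default dose grid is the screen's
#' 0, 1, 3, 10, 30, 100 nM gradient.
#'
#' @param ic50 true IC50 (> 0), same units as `doses`.
#' @param hill Hill slope.
#' @param doses dose grid (nonnegative; should include 0).
#' @param noise_sd viability noise SD (percentage points).
#' @param seed integer seed (substream `"dose"`).
#' @param n_replicates replicates per dose.
#' @return data.frame `dose`, `viability`, `replicate`.
#' @export
make_dose_response <- function(ic50, hill = 1, doses = c(0, 1, 3, 10, 30, 100),
                               noise_sd = 0, seed = 1L, n_replicates = 3L) {
  stopifnot(ic50 > 0, all(doses >= 0), n_replicates >= 1L)
  set.seed(derive_seed(seed, "dose"))
  grid <- expand.grid(replicate = seq_len(n_replicates), dose = doses)[, 2:1]
  mu <- ifelse(grid$dose == 0, 100, 100 / (1 + (grid$dose / ic50)^hill))
  grid$viability <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
  grid[order(grid$dose, grid$replicate), ]
}
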