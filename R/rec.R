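#' Robust z-scores from replicate profiles
#'
#' Builds signature-style z-values from raw expression profiles when no
#' precomputed signatures are available:
#' `z = (treated - median(control)) / (1.4826 * MAD(control))`, per gene.
#' Genes whose control MAD is zero cannot be scored and are flagged absent.
#'
#' @param treated numeric vector of treated values per gene, or a gene x
#'   replicate matrix (the row median is used).
#' @param control gene x replicate matrix with at least 3 replicates.
#' @return list with `z` (numeric, `NA` where absent) and `present` (logical).
#' @export
robust_z <- function(treated, control) {
  stopifnot(is.matrix(control))
  if (ncol(control) < 3L) stop("at least 3 control replicates are required")
  if (is.matrix(treated)) treated <- apply(treated, 1L, stats::median)
  stopifnot(length(treated) == nrow(control))
  ctr_med <- apply(control, 1L, stats::median)
  ctr_mad <- apply(control, 1L, stats::mad) # constant 1.4826 is mad()'s default
  present <- ctr_mad > 0
  if (any(!present)) {
    warning(sum(!present), " gene(s) with zero control MAD flagged absent")
  }
  z <- ifelse(present, (treated - ctr_med) / ctr_mad, NA_real_)
  names(z) <- rownames(control)
  list(z = z, present = present)
}

#' Signed recurrence (REC) score for one tensor slice
#'
#' The REC score summarises how recurrently a compound regulates a gene
#' across a cell line panel:
#' `rec = (#\{lines: z >= z_thr\} - #\{lines: z <= -z_thr\}) / n_measured`,
#' so consistent upregulation scores +1, consistent downregulation -1, and
#' the score is antisymmetric under `z -> -z`. Only measured cell lines
#' enter the denominator.
#'
#' @param tensor a [signature_tensor()].
#' @param compound,gene,timepoint slice labels.
#' @param z_thr z magnitude threshold (default 2).
#' @return list with `rec` in `[-1, 1]` and `n_measured`.
#' @export
rec_score <- function(tensor, compound, gene, timepoint, z_thr = 2) {
  dn <- dimnames(tensor$z)
  if (!compound %in% dn$compound) stop("compound not in tensor: ", compound)
  if (!gene %in% dn$gene) stop("gene not in tensor: ", gene)
  if (!timepoint %in% dn$timepoint) stop("timepoint not in tensor: ", timepoint)
  z <- tensor$z[compound, gene, , timepoint]
  z <- z[tensor$present[compound, gene, , timepoint]]
  n <- length(z)
  if (n < 2L) stop("fewer than 2 cell lines measured for (",
                   compound, ", ", gene, ", ", timepoint, ")")
  list(rec = (sum(z >= z_thr) - sum(z <= -z_thr)) / n, n_measured = n)
}

# exact null distribution of the per-line sum of +/-1/0 indicators under
# independent gene-label resampling within each listed cell line:
# convolution of per-line trinomials. Returns probabilities over
# sum = -n..n (length 2n+1).
rec_null_convolve <- function(p_up, p_down) {
  n <- length(p_up)
  dist <- 1
  for (l in seq_len(n)) {
    p0 <- 1 - p_up[l] - p_down[l]
    m <- length(dist)
    nxt <- numeric(m + 2L)
    nxt[1:m] <- nxt[1:m] + dist * p_down[l]
    nxt[2:(m + 1L)] <- nxt[2:(m + 1L)] + dist * p0
    nxt[3:(m + 2L)] <- nxt[3:(m + 2L)] + dist * p_up[l]
    dist <- nxt
  }
  dist
}

# per-line up/down indicator summaries for one (compound, timepoint):
# s[[l]] = +1/-1/0 vector over the genes measured in line l
rec_line_indicators <- function(tensor, compound, timepoint, z_thr) {
  zm <- tensor$z[compound, , , timepoint, drop = TRUE]   # gene x line
  pm <- tensor$present[compound, , , timepoint, drop = TRUE]
  if (is.null(dim(zm))) zm <- matrix(zm, ncol = 1)
  if (is.null(dim(pm))) pm <- matrix(pm, ncol = 1)
  lapply(seq_len(ncol(zm)), function(l) {
    zl <- zm[pm[, l], l]
    (zl >= z_thr) - (zl <= -z_thr)
  })
}

#' Permutation p-value for a REC score
#'
#' The null resamples the gene label independently within each measured cell
#' line of the compound's signature, preserving every line's signature
#' distribution; the test statistic is `|rec|` (two-sided: the screen reads
#' both strong reversal and strong mimicry). Two estimators are available:
#'
#' * `"exact"` -- full enumeration of the null. Per-line draws are
#'   independent, so the null law of the indicator sum is the convolution of
#'   per-line trinomials, which enumerates all `n_genes^n_lines` label
#'   assignments in closed form. Exact p-values can be far below `1/(B+1)`,
#'   which the downstream FDR <= 1e-3 filter requires.
#' * `"montecarlo"` -- `B` sampled assignments with the add-one estimator
#'   `p = (1 + #\{|rec*| >= |rec|\}) / (B + 1)`, never zero.
#'
#' `"auto"` uses exact enumeration for small gene panels (< 20 genes) and
#' Monte-Carlo otherwise.
#'
#' @inheritParams rec_score
#' @param B number of Monte-Carlo permutations (>= 99).
#' @param seed integer seed for the Monte-Carlo path.
#' @param method `"auto"`, `"exact"` or `"montecarlo"`.
#' @return p-value in (0, 1].
#' @export
rec_permutation_p <- function(tensor, compound, gene, timepoint, z_thr = 2,
                              B = 999L, seed = 1L,
                              method = c("auto", "exact", "montecarlo")) {
  method <- match.arg(method)
  n_genes <- dim(tensor$z)[2]
  if (n_genes < 2L) stop("degenerate tensor: need at least 2 genes for a permutation null")
  if (method == "auto") method <- if (n_genes < 20L) "exact" else "montecarlo"
  obs <- rec_score(tensor, compound, gene, timepoint, z_thr)
  gi <- match(gene, dimnames(tensor$z)$gene)
  meas <- which(tensor$present[compound, gi, , timepoint])
  s <- rec_line_indicators(tensor, compound, timepoint, z_thr)[meas]
  n <- length(meas)
  tol <- 1e-9
  if (method == "exact") {
    p_up <- vapply(s, function(v) mean(v == 1), 0)
    p_down <- vapply(s, function(v) mean(v == -1), 0)
    dist <- rec_null_convolve(p_up, p_down)
    k <- (-n):n
    sum(dist[abs(k / n) >= abs(obs$rec) - tol])
  } else {
    if (B < 99L) stop("B must be at least 99")
    set.seed(derive_seed(seed, paste("rec-perm", compound, gene, timepoint)))
    null_sum <- rowSums(vapply(s, function(v) v[sample.int(length(v), B, replace = TRUE)],
                               numeric(B)))
    (1 + sum(abs(null_sum / n) >= abs(obs$rec) - tol)) / (B + 1)
  }
}

#' Benjamini-Hochberg FDR
#'
#' Step-up FDR adjustment of a p-value vector (delegates to
#' [stats::p.adjust()]).
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted FDR values, same length.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Score every compound of a tensor slice
#'
#' Computes the REC score, permutation p-value, BH FDR (across compounds
#' within each (gene, timepoint) slice -- the screen's multiplicity family)
#' and negative-REC rank for every compound of the requested genes and
#' timepoints. The p-value method defaults to exact enumeration (see
#' [rec_permutation_p()]); Monte-Carlo is available for calibration studies.
#'
#' Monte-Carlo and exact nulls depend only on the compound's per-line
#' signature indicator fractions, so they are shared across genes with the
#' same presence pattern, which keeps full-panel scoring fast.
#'
#' The REC statistic is discrete (multiples of `1/n_measured`), so the
#' add-one Monte-Carlo p-value is sub-uniform under the null, with large
#' atoms (notably p = 1 whenever rec = 0). For calibration diagnostics,
#' `randomized_ties = TRUE` adds a `p_rand` column holding the
#' tie-randomized permutation p-value (the observed statistic's rank among
#' the null draws with ties broken uniformly at random), which is exactly
#' uniform on the permutation grid under the null. Screening decisions (FDR)
#' always use the conservative `p`.
#'
#' @param tensor a [signature_tensor()].
#' @param genes gene labels to score (default: all).
#' @param timepoints timepoint labels (default: all).
#' @param z_thr z magnitude threshold.
#' @param p_method `"exact"` or `"montecarlo"`.
#' @param B,seed Monte-Carlo settings.
#' @param randomized_ties also report tie-randomized Monte-Carlo p-values
#'   (`p_rand` column; Monte-Carlo method only).
#' @return data.frame with columns `compound`, `gene`, `timepoint`, `rec`,
#'   `n_measured`, `p`, `fdr`, `rank_neg` (plus `p_rand` when requested).
#' @export
rec_table <- function(tensor, genes = NULL, timepoints = NULL, z_thr = 2,
                      p_method = c("exact", "montecarlo"), B = 999L, seed = 1L,
                      randomized_ties = FALSE) {
  p_method <- match.arg(p_method)
  dn <- dimnames(tensor$z)
  if (is.null(genes)) genes <- dn$gene
  if (is.null(timepoints)) timepoints <- dn$timepoint
  stopifnot(all(genes %in% dn$gene), all(timepoints %in% dn$timepoint))
  tol <- 1e-9
  out <- list()
  for (tp in timepoints) {
    for (cp in dn$compound) {
      s_all <- rec_line_indicators(tensor, cp, tp, z_thr)
      pres <- tensor$present[cp, genes, , tp, drop = TRUE]
      if (is.null(dim(pres))) pres <- matrix(pres, nrow = length(genes),
                                             dimnames = list(genes, dn$cell_line))
      zc <- tensor$z[cp, genes, , tp, drop = TRUE]
      if (is.null(dim(zc))) zc <- matrix(zc, nrow = length(genes),
                                         dimnames = list(genes, dn$cell_line))
      n_up <- rowSums(zc >= z_thr & pres, na.rm = TRUE)
      n_down <- rowSums(zc <= -z_thr & pres, na.rm = TRUE)
      n_meas <- rowSums(pres)
      if (any(n_meas < 2L)) {
        stop("fewer than 2 cell lines measured for (", cp, ", ",
             genes[which(n_meas < 2L)[1]], ", ", tp, ")")
      }
      rec <- (n_up - n_down) / n_meas
      # one null per presence pattern, shared across genes
      pat <- apply(pres, 1L, function(r) paste(which(r), collapse = ","))
      pv <- numeric(length(genes))
      pv_rand <- rep(NA_real_, length(genes))
      for (pt in unique(pat)) {
        lines <- as.integer(strsplit(pt, ",", fixed = TRUE)[[1]])
        gsel <- which(pat == pt)
        n <- length(lines)
        if (p_method == "exact") {
          p_up <- vapply(s_all[lines], function(v) mean(v == 1), 0)
          p_dn <- vapply(s_all[lines], function(v) mean(v == -1), 0)
          dist <- rec_null_convolve(p_up, p_dn)
          tail_ge <- rev(cumsum(rev(dist)))  # P(sum >= k), k = -n..n
          for (g in gsel) {
            k_min <- ceiling(n * (abs(rec[g]) - tol))
            pv[g] <- if (k_min <= 0) 1 else {
              # P(|sum| >= k_min) = P(sum >= k_min) + P(sum <= -k_min)
              tail_ge[n + 1 + k_min] + sum(dist[seq_len(n + 1 - k_min)])
            }
          }
        } else {
          set.seed(derive_seed(seed, paste("rec-table", cp, tp, pt)))
          null_sum <- rowSums(vapply(s_all[lines],
                                     function(v) v[sample.int(length(v), B, replace = TRUE)],
                                     numeric(B)))
          null_abs <- sort(abs(null_sum) / n)
          for (g in gsel) {
            cnt_ge <- B - findInterval(abs(rec[g]) - tol, null_abs)
            pv[g] <- (1 + cnt_ge) / (B + 1)
            if (randomized_ties) {
              cnt_gt <- B - findInterval(abs(rec[g]) + tol, null_abs)
              n_tied <- cnt_ge - cnt_gt + 1L # null ties plus the observation
              pv_rand[g] <- (cnt_gt + sample.int(n_tied, 1L)) / (B + 1)
            }
          }
        }
      }
      block <- data.frame(
        compound = cp, gene = genes, timepoint = tp,
        rec = rec, n_measured = as.integer(n_meas), p = pv,
        stringsAsFactors = FALSE, row.names = NULL
      )
      if (randomized_ties) block$p_rand <- pv_rand
      out[[length(out) + 1L]] <- block
    }
  }
  res <- do.call(rbind, out)
  res$fdr <- NA_real_
  res$rank_neg <- NA_integer_
  for (tp in timepoints) {
    for (g in genes) {
      i <- which(res$gene == g & res$timepoint == tp)
      res$fdr[i] <- bh_fdr(res$p[i])
      o <- order(res$rec[i], res$p[i], res$compound[i])
      res$rank_neg[i[o]] <- seq_along(i)
    }
  }
  rownames(res) <- NULL
  res
}

#' Rank compounds by most-negative REC
#'
#' Returns the `top_k` compounds of one (gene, timepoint) slice sorted by
#' ascending REC (strongest reversal first), ties broken by smaller p-value
#' then lexicographic compound id.
#'
#' @param results a [rec_table()] data.frame covering one slice.
#' @param gene,timepoint slice labels.
#' @param top_k how many compounds to return (>= 1).
#' @return character vector of compound ids.
#' @export
rank_rec <- function(results, gene, timepoint, top_k = 30L) {
  if (top_k < 1L) stop("top_k must be at least 1")
  sl <- results[results$gene == gene & results$timepoint == timepoint, , drop = FALSE]
  if (!nrow(sl)) stop("no results for (", gene, ", ", timepoint, ")")
  sl <- sl[order(sl$rec, sl$p, sl$compound), , drop = FALSE]
  if (top_k > nrow(sl)) {
    warning("top_k (", top_k, ") exceeds the ", nrow(sl), " available compounds")
    top_k <- nrow(sl)
  }
  sl$compound[seq_len(top_k)]
}
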