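#' Build a ranked gene list
#'
#' Sorts scores descending with stable gene-identifier tie-breaking; genes
#' must be unique. REC scores of a chosen compound are the intended input.
#'
#' @param genes character gene ids.
#' @param scores numeric scores (e.g. REC values).
#' @return named numeric vector, descending, of class `ranked_gene_list`.
#' @export
ranked_gene_list <- function(genes, scores) {
  stopifnot(length(genes) == length(scores), all(is.finite(scores)))
  if (anyDuplicated(genes)) stop("duplicate genes in ranked list")
  o <- order(-scores, genes)
  structure(stats::setNames(scores[o], genes[o]), class = "ranked_gene_list")
}

# fast enrichment score from hit positions only: the weighted KS running sum
# changes linearly between hits, so its extrema occur just before or at hit
# positions. positions must be sorted ascending; w are the corresponding
# weights |score|^weight.
es_from_positions <- function(positions, w, N) {
  m <- length(positions)
  NR <- sum(w)
  if (NR == 0) w[] <- 1 / m else w <- w / NR
  if (NR == 0) NR <- 1
  cumw <- cumsum(w)
  if (N == m) return(list(es = 1, i_ext = positions[m])) # all genes are hits
  miss <- 1 / (N - m)
  after <- cumw - (positions - seq_len(m)) * miss
  before <- c(0, cumw[-m]) - (positions - seq_len(m)) * miss
  cand <- unname(c(after, before))
  i <- which.max(abs(cand))
  list(es = cand[i],
       i_ext = if (i <= m) positions[i] else positions[i - m] - 1L)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic preranked GSEA running-sum statistic: walking down the ranked
#' list, hits increment by `|score|^weight` (normalised over hits) and
#' misses decrement by `1/(N - Nh)`; the ES is the signed maximum deviation.
#' The leading edge is the hit subset up to the extremum.
#'
#' @param rlist a [ranked_gene_list()].
#' @param set character vector of member genes.
#' @param weight score weighting exponent (default 1, the GSEA default).
#' @return list with `es` in `[-1, 1]` (`NA` if the set does not intersect
#'   the list), `leading_edge`, `size_used`.
#' @export
enrichment_score <- function(rlist, set, weight = 1) {
  genes <- names(rlist)
  positions <- which(genes %in% set)
  if (!length(positions)) {
    return(list(es = NA_real_, leading_edge = character(0), size_used = 0L))
  }
  w <- abs(rlist[positions])^weight
  r <- es_from_positions(positions, w, length(rlist))
  le <- if (r$es >= 0) positions[positions <= r$i_ext] else positions[positions > r$i_ext]
  list(es = r$es, leading_edge = genes[le], size_used = length(positions))
}

#' Preranked gene set enrichment analysis
#'
#' Scores every admissible set of a collection against a ranked list.
#' Sets are filtered to intersection sizes within
#' `[cfg$gsea_set_min, cfg$gsea_set_max]` (others skipped with a log entry).
#' The null permutes gene labels: `B = cfg$gsea_permutations` random
#' position sets per distinct set size. NES is the ES divided by the mean
#' magnitude of sign-matched null ES; p is the sign-matched add-one tail;
#' the FDR q-value is the standard NES-ratio estimate (fraction of pooled
#' null NES at least as extreme over fraction of observed NES at least as
#' extreme), clipped to `[0, 1]`.
#'
#' @param rlist a [ranked_gene_list()].
#' @param collection a [read_gmt()]-style named list of gene sets.
#' @param cfg a [run_config()].
#' @param seed integer seed (substream `"gsea"`).
#' @param weight ES weighting exponent.
#' @return data.frame sorted by decreasing NES with columns `set`,
#'   `size_used`, `es`, `nes`, `p`, `fdr_q`, `leading_edge`; skipped set
#'   names in attribute `"skipped"`.
#' @export
gsea <- function(rlist, collection, cfg = run_config(), seed = cfg$seed,
                 weight = 1) {
  N <- length(rlist)
  if (N <= cfg$gsea_set_min) stop("ranked list shorter than gsea_set_min")
  obs <- lapply(collection, enrichment_score, rlist = rlist, weight = weight)
  sizes <- vapply(obs, `[[`, 0L, "size_used")
  keep <- sizes >= cfg$gsea_set_min & sizes <= cfg$gsea_set_max
  skipped <- names(collection)[!keep]
  if (length(skipped)) {
    rs_log("gsea", length(skipped), " set(s) skipped by size filter: ",
           paste(utils::head(skipped, 5), collapse = ", "))
  }
  if (!any(keep)) stop("no gene sets remain after size filtering")
  obs <- obs[keep]
  sizes <- sizes[keep]
  B <- cfg$gsea_permutations
  set.seed(derive_seed(seed, "gsea"))
  absr <- abs(rlist)^weight
  null_es <- lapply(sort(unique(sizes)), function(m) {
    vapply(seq_len(B), function(b) {
      pos <- sort.int(sample.int(N, m))
      es_from_positions(pos, absr[pos], N)$es
    }, 0)
  })
  names(null_es) <- as.character(sort(unique(sizes)))
  norm_pos <- vapply(null_es, function(v) mean(v[v > 0]), 0)
  norm_neg <- vapply(null_es, function(v) mean(abs(v[v < 0])), 0)
  res <- data.frame(set = names(obs), size_used = sizes,
                    es = vapply(obs, `[[`, 0, "es"),
                    stringsAsFactors = FALSE, row.names = NULL)
  res$nes <- res$p <- NA_real_
  null_nes <- list()
  for (i in seq_len(nrow(res))) {
    v <- null_es[[as.character(res$size_used[i])]]
    np <- norm_pos[[as.character(res$size_used[i])]]
    nn <- norm_neg[[as.character(res$size_used[i])]]
    es <- res$es[i]
    if (es >= 0) {
      res$nes[i] <- if (is.finite(np) && np > 0) es / np else NA_real_
      res$p[i] <- (1 + sum(v >= es)) / (1 + sum(v >= 0))
    } else {
      res$nes[i] <- if (is.finite(nn) && nn > 0) es / nn else NA_real_
      res$p[i] <- (1 + sum(v <= es)) / (1 + sum(v < 0))
    }
    null_nes[[i]] <- c(v[v > 0] / np, -abs(v[v < 0]) / nn)
  }
  pooled <- unlist(null_nes)
  res$fdr_q <- vapply(res$nes, function(nes) {
    if (!is.finite(nes)) return(NA_real_)
    if (nes >= 0) {
      num <- mean(pooled >= nes, na.rm = TRUE)
      den <- mean(res$nes >= nes, na.rm = TRUE)
    } else {
      num <- mean(pooled <= nes, na.rm = TRUE)
      den <- mean(res$nes <= nes, na.rm = TRUE)
    }
    min(1, max(0, num / max(den, .Machine$double.eps)))
  }, 0)
  res$leading_edge <- vapply(obs, function(o) paste(o$leading_edge, collapse = ","), "")
  res <- res[order(-res$nes), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
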