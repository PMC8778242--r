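# small in-code fixtures shared across test files

# tensor with explicit z values: compounds x genes x lines x timepoints
tiny_tensor <- function(z, compounds, genes, lines, timepoints = "6h") {
  arr <- array(z, dim = c(length(compounds), length(genes), length(lines),
                          length(timepoints)),
               dimnames = list(compound = compounds, gene = genes,
                               cell_line = lines, timepoint = timepoints))
  signature_tensor(arr)
}

# one-compound tensor whose target gene has the given per-line z values and
# whose remaining genes are drawn N(0, 1); used for permutation-null tests
one_compound_tensor <- function(target_z, n_genes, seed = 1) {
  set.seed(seed)
  n_lines <- length(target_z)
  z <- array(rnorm(n_genes * n_lines), dim = c(1, n_genes, n_lines, 1),
             dimnames = list(compound = "C1",
                             gene = c(sprintf("g%03d", seq_len(n_genes - 1)), "TARGET"),
                             cell_line = sprintf("L%02d", seq_len(n_lines)),
                             timepoint = "6h"))
  z[1, n_genes, , 1] <- target_z
  signature_tensor(z)
}

# brute-force |rec| permutation p by enumerating every gene-label assignment
# (one independent choice per cell line) -- the oracle for the exact method
enum_perm_p <- function(tensor, compound, gene, timepoint, z_thr = 2) {
  obs <- rec_score(tensor, compound, gene, timepoint, z_thr)$rec
  dn <- dimnames(tensor$z)
  lines <- dn$cell_line[tensor$present[compound, gene, , timepoint]]
  n_genes <- length(dn$gene)
  sgn <- sapply(lines, function(l) {
    zl <- tensor$z[compound, , l, timepoint]
    zl <- zl[tensor$present[compound, , l, timepoint]]
    (zl >= z_thr) - (zl <= -z_thr)
  }) # genes x lines
  grid <- do.call(expand.grid, rep(list(seq_len(n_genes)), length(lines)))
  recs <- apply(grid, 1, function(ix) {
    mean(vapply(seq_along(lines), function(l) sgn[ix[l], l], 0))
  })
  mean(abs(recs) >= abs(obs) - 1e-9)
}

# brute-force running-sum GSEA enrichment score (full walk down the list)
es_brute <- function(rlist, set, weight = 1) {
  hit <- names(rlist) %in% set
  N <- length(rlist); Nh <- sum(hit)
  if (Nh == 0) return(NA_real_)
  w <- abs(rlist)^weight
  NR <- sum(w[hit])
  inc <- ifelse(hit, if (NR > 0) w / NR else 1 / Nh,
                if (N > Nh) -1 / (N - Nh) else 0)
  inc[hit & NR == 0] <- 1 / Nh
  run <- cumsum(inc)
  run[which.max(abs(run))]
}
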