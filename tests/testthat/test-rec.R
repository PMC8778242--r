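test_that("robust z-scores match the direct formula and flag zero-MAD genes", {
  # treated equal to the control median scores exactly zero
  ctrl <- matrix(c(1, 2, 3, 4, 5), nrow = 1)[rep(1, 3), ]
  ctrl <- matrix(c(1, 2, 3, 4, 5,  2, 4, 6, 8, 10,  1, 1, 2, 3, 3), nrow = 3,
                 byrow = TRUE, dimnames = list(c("gA", "gB", "gC"), NULL))
  rz <- robust_z(c(3, 20, 2), ctrl)
  expect_equal(unname(rz$z["gA"]), 0)
  # hand-computed oracle: z = (t - median) / (1.4826 * median(|x - median|))
  med <- apply(ctrl, 1, median)
  mad_raw <- apply(ctrl, 1, function(x) median(abs(x - median(x))))
  expect_equal(unname(rz$z), unname((c(3, 20, 2) - med) / (1.4826 * mad_raw)),
               tolerance = 1e-12)
  # zero-MAD gene flagged absent with a warning
  ctrl0 <- rbind(ctrl, gD = rep(7, 5))
  expect_warning(rz0 <- robust_z(c(3, 20, 2, 9), ctrl0), "zero control MAD")
  expect_false(rz0$present[4])
  expect_true(is.na(rz0$z["gD"]))
  expect_error(robust_z(1:3, ctrl[, 1:2]), "3 control replicates")
})

test_that("REC score counts threshold exceedances over measured lines", {
  tn <- tiny_tensor(rep(-3, 10), "C1", "G1", sprintf("L%02d", 1:10))
  expect_equal(rec_score(tn, "C1", "G1", "6h")$rec, -1)
  tn0 <- tiny_tensor(runif(10, -1.9, 1.9), "C1", "G1", sprintf("L%02d", 1:10))
  expect_equal(rec_score(tn0, "C1", "G1", "6h")$rec, 0)
  # 6 lines >= 2, 2 lines <= -2, 2 neutral: rec = (6 - 2) / 10 = 0.4
  tn4 <- tiny_tensor(c(rep(2.5, 6), rep(-2.5, 2), 0, 1), "C1", "G1",
                     sprintf("L%02d", 1:10))
  r <- rec_score(tn4, "C1", "G1", "6h")
  expect_equal(r$rec, 0.4)
  expect_identical(r$n_measured, 10L)
  expect_error(rec_score(tn4, "C9", "G1", "6h"), "compound not in tensor")
  expect_error(rec_score(tn4, "C1", "G9", "6h"), "gene not in tensor")
})

test_that("absent cell lines never enter the REC denominator", {
  z <- c(rep(-3, 4), 99) # the 99 will be marked absent
  arr <- array(z, dim = c(1, 1, 5, 1),
               dimnames = list(compound = "C1", gene = "G1",
                               cell_line = paste0("L", 1:5), timepoint = "6h"))
  pres <- array(TRUE, dim = dim(arr), dimnames = dimnames(arr))
  pres[1, 1, 5, 1] <- FALSE
  tn <- signature_tensor(arr, pres)
  r <- rec_score(tn, "C1", "G1", "6h")
  expect_identical(r$n_measured, 4L)
  expect_equal(r$rec, -1)
  # dropping the absent line entirely changes nothing
  tn4 <- tiny_tensor(z[1:4], "C1", "G1", paste0("L", 1:4))
  expect_equal(rec_score(tn4, "C1", "G1", "6h")$rec, r$rec)
})

test_that("exact permutation p equals brute-force enumeration on tiny tensors", {
  # 3 genes x 2 cell lines: all 9 gene-label assignments
  tn <- tiny_tensor(c(3, -2.5, 0.5, 2.2, -3, 0.1), "C1", c("g1", "g2", "g3"),
                    c("L1", "L2"))
  for (g in c("g1", "g2", "g3")) {
    expect_equal(rec_permutation_p(tn, "C1", g, "6h", method = "exact"),
                 enum_perm_p(tn, "C1", g, "6h"), tolerance = 1e-12)
  }
  # 4 genes x 3 lines: 64 assignments
  set.seed(31)
  tn2 <- tiny_tensor(rnorm(12, 0, 2), "C1", paste0("g", 1:4), paste0("L", 1:3))
  for (g in paste0("g", 1:4)) {
    expect_equal(rec_permutation_p(tn2, "C1", g, "6h", method = "exact"),
                 enum_perm_p(tn2, "C1", g, "6h"), tolerance = 1e-12)
  }
})

test_that("permutation p behaves at the boundaries", {
  # rec_obs = 0: |rec*| >= 0 always, so p = 1 under both estimators
  tn <- one_compound_tensor(runif(6, -1, 1), n_genes = 25, seed = 2)
  expect_equal(rec_permutation_p(tn, "C1", "TARGET", "6h", method = "exact"), 1)
  expect_equal(rec_permutation_p(tn, "C1", "TARGET", "6h", B = 199,
                                 method = "montecarlo"), 1)
  # Monte-Carlo respects the add-one floor and agrees with exact to MC error
  tn2 <- one_compound_tensor(c(rep(-3, 5), 2.5), n_genes = 50, seed = 3)
  p_ex <- rec_permutation_p(tn2, "C1", "TARGET", "6h", method = "exact")
  p_mc <- rec_permutation_p(tn2, "C1", "TARGET", "6h", B = 1999, seed = 5,
                            method = "montecarlo")
  expect_gte(p_mc, 1 / 2000)
  expect_lt(abs(p_mc - p_ex), 4 * sqrt(p_ex * (1 - p_ex) / 2000) + 1e-3)
  expect_error(rec_permutation_p(tn2, "C1", "TARGET", "6h", B = 50,
                                 method = "montecarlo"), "at least 99")
  # degenerate single-gene tensor
  tn1 <- tiny_tensor(c(3, 2), "C1", "G1", c("L1", "L2"))
  expect_error(rec_permutation_p(tn1, "C1", "G1", "6h"), "degenerate")
})

test_that("BH FDR matches an independent step-up implementation", {
  bh_oracle <- function(p) { # textbook step-up, written independently
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)),
               bh_oracle(c(0.01, 0.02, 0.03, 0.04)))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.3, 5)), rep(0.3, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
})

test_that("negative-REC ranking orders by score, then p, then compound id", {
  res <- data.frame(compound = c("B", "A", "C", "D"),
                    gene = "G1", timepoint = "6h",
                    rec = c(-1.0, -0.5, -0.5, 0.2),
                    p = c(0.001, 0.01, 0.001, 0.5))
  expect_identical(rank_rec(res, "G1", "6h", 2), c("B", "C"))
  expect_identical(rank_rec(res, "G1", "6h", 3), c("B", "C", "A"))
  expect_warning(full <- rank_rec(res, "G1", "6h", 10), "exceeds")
  expect_identical(full, c("B", "C", "A", "D"))
  expect_error(rank_rec(res, "G1", "6h", 0), "at least 1")
  expect_error(rank_rec(res, "G9", "6h", 2), "no results")
})

test_that("rec_table agrees with the per-slice operations and ranks consistently", {
  sp <- plant_spec(n_compounds = 8, n_genes = 15, cell_lines = paste0("L", 1:6),
                   reversal_effect = -4)
  tn <- make_signature_tensor(sp, 21)
  rt <- rec_table(tn, genes = c("MCM2", "G0003"))
  for (i in sample(nrow(rt), 6)) {
    row <- rt[i, ]
    expect_equal(row$rec,
                 rec_score(tn, row$compound, row$gene, row$timepoint)$rec)
    expect_equal(row$p,
                 rec_permutation_p(tn, row$compound, row$gene, row$timepoint,
                                   method = "exact"), tolerance = 1e-12)
  }
  # rank_neg is a permutation of 1..N within each slice
  sl <- rt[rt$gene == "MCM2" & rt$timepoint == "6h", ]
  expect_setequal(sl$rank_neg, seq_len(nrow(sl)))
  expect_identical(sl$compound[sl$rank_neg == 1], "BI-2536")
  # fdr within a slice is BH of that slice's p-values
  expect_equal(sl$fdr, bh_fdr(sl$p))
})

test_that("REC scoring is antisymmetric under z negation with unchanged p", {
  set.seed(77)
  for (i in 1:25) {
    tn <- one_compound_tensor(rnorm(8, 0, 2), n_genes = 12, seed = i)
    neg <- signature_tensor(-tn$z, tn$present)
    expect_equal(rec_score(neg, "C1", "TARGET", "6h")$rec,
                 -rec_score(tn, "C1", "TARGET", "6h")$rec)
    expect_equal(rec_permutation_p(neg, "C1", "TARGET", "6h", method = "exact"),
                 rec_permutation_p(tn, "C1", "TARGET", "6h", method = "exact"),
                 tolerance = 1e-12)
  }
})
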