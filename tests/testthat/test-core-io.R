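test_that("tall signature TSV reading builds the right tensor and rejects bad input", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound\tgene\tcell_line\ttimepoint\tz",
               "C1\tG1\tL1\t6h\t1.5",
               "C1\tG1\tL2\t6h\t-0.5",
               "C1\tG2\tL1\t6h\t0.0",
               "C1\tG2\tL2\t6h\t2.5"), p)
  tn <- read_signature_tensor(p)
  expect_identical(dim(tn$z), c(1L, 2L, 2L, 1L))
  expect_equal(tn$z["C1", "G2", "L2", "6h"], 2.5)
  expect_true(all(tn$present))

  # missing cells are absent, not zero
  writeLines(c("compound\tgene\tcell_line\ttimepoint\tz",
               "C1\tG1\tL1\t6h\t1.5",
               "C1\tG2\tL2\t6h\t2.5"), p)
  tn2 <- read_signature_tensor(p)
  expect_false(tn2$present["C1", "G1", "L2", "6h"])
  expect_true(is.na(tn2$z["C1", "G1", "L2", "6h"]))

  writeLines("compound\tgene\tcell_line\ttimepoint\tz", p)
  expect_error(read_signature_tensor(p), "no records")

  writeLines(c("compound\tgene\tcell_line\ttimepoint\tz",
               "C1\tG1\tL1\t6h\t1.0",
               "C1\tG1\tL1\t6h\t2.0"), p)
  expect_error(read_signature_tensor(p), "duplicate.*C1.*G1.*L1.*6h")

  writeLines(c("compound\tgene\tcell_line\ttimepoint\tz",
               "C1\tG1\tL1\t6h\t1.0",
               "C1\tG1\tL2\t6h\tabc"), p)
  expect_error(read_signature_tensor(p), "non-numeric z.*line 2")
})

test_that("signature tensor write/read round-trips exactly", {
  sp <- plant_spec(n_compounds = 4, n_genes = 6, cell_lines = c("L1", "L2", "L3"),
                   target_genes = "MCM2", reversal_compounds = "BI-2536")
  tn <- make_signature_tensor(sp, 11)
  tn$present["CPD0001", "G0001", "L2", "6h"] <- FALSE
  tn$z["CPD0001", "G0001", "L2", "6h"] <- NA
  p <- withr::local_tempfile(fileext = ".tsv")
  write_signature_tensor(tn, p, run_config())
  back <- read_signature_tensor(p)
  # the reader normalizes axis label order; compare against the sorted tensor
  dn <- lapply(dimnames(tn$z), sort)
  tn_sorted <- signature_tensor(tn$z[dn$compound, dn$gene, dn$cell_line,
                                     dn$timepoint, drop = FALSE])
  expect_identical(dimnames(back$z), dimnames(tn_sorted$z))
  expect_equal(back$z, tn_sorted$z, tolerance = 1e-12)
  expect_identical(back$present, tn_sorted$present)
  # byte-identical on rewrite (determinism of outputs)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_signature_tensor(tn, p2, run_config())
  expect_identical(readLines(p), readLines(p2))
})

test_that("GMT parsing collapses duplicate members and flags malformed lines", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tG1\tG2", "S2\tdesc\tG1\tG1"), p)
  gs <- read_gmt(p)
  expect_identical(lengths(gs), c(S1 = 2L, S2 = 1L))
  writeLines(c("S1\tdesc\tG1", "S1\tdesc\tG2"), p)
  expect_error(read_gmt(p), "duplicate gene set name")
  writeLines(c("S1\tdesc\tG1", "S2\tonlytwo"), p)
  expect_error(read_gmt(p), "line 2")
  # round trip
  sets <- list(A = c("G1", "G3"), B = c("G2"))
  class(sets) <- "gene_set_collection"
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, p2)
  expect_identical(unclass(read_gmt(p2))[1:2], list(A = c("G1", "G3"), B = "G2"))
})

test_that("survival CSV validates and excludes incomplete records", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,time,event,MCM2",
               "P1,10,1,5.2", "P2,20,1,3.1", "P3,5,1,8.8"), p)
  co <- read_survival_csv(p)
  expect_identical(nrow(co), 3L)
  expect_identical(sum(co$event == 0), 0L)

  writeLines(c("patient_id,time,event,MCM2", "P1,-1,1,5.2"), p)
  expect_error(read_survival_csv(p), "positive")
  writeLines(c("patient_id,time,event,MCM2", "P1,1,2,5.2"), p)
  expect_error(read_survival_csv(p), "0/1")
  writeLines(c("patient_id,time,event,MCM2",
               "P1,10,1,5.2", "P2,20,0,", "P3,5,1,8.8"), p)
  expect_identical(nrow(read_survival_csv(p)), 2L)
})

test_that("16-bit TIFF writer/reader round-trips pixel-exactly", {
  set.seed(4)
  m <- matrix(sample(0:65535, 64 * 48, TRUE), nrow = 48, ncol = 64)
  p <- withr::local_tempfile(fileext = ".tif")
  write_tiff16(m, p)
  expect_identical(read_tiff16(p), m)
  expect_error(read_tiff16(withr::local_tempfile(fileext = ".bin",
                                                 lines = "not a tiff")), "not a TIFF")
})

test_that("config hashing and seed substreams are deterministic and discriminating", {
  cfg <- run_config(seed = 3)
  expect_identical(config_hash(cfg), config_hash(run_config(seed = 3)))
  expect_false(config_hash(cfg) == config_hash(run_config(seed = 4)))
  expect_identical(derive_seed(7, "a"), derive_seed(7, "a"))
  expect_false(derive_seed(7, "a") == derive_seed(7, "b"))
  expect_true(derive_seed(7, "a") >= 1 && derive_seed(7, "a") <= 2^31 - 1)
  expect_error(run_config(rec_fdr_max = 1.5))
  expect_error(run_config(gsea_set_min = 600, gsea_set_max = 500))
  expect_error(run_config(rec_z_threshold = -1))
})
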