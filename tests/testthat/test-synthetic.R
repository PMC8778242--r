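test_that("signature generator is a pure function of (spec, seed) with correct null mean", {
  sp <- plant_spec(n_compounds = 10, n_genes = 40, reversal_compounds = character(0),
                   target_genes = character(0), reversal_effect = 0)
  t1 <- make_signature_tensor(sp, 5)
  t2 <- make_signature_tensor(sp, 5)
  expect_identical(t1$z, t2$z)
  t3 <- make_signature_tensor(sp, 6)
  expect_false(identical(t1$z, t3$z))
  # null world: overall mean within 4 standard errors of zero
  n <- length(t1$z)
  expect_lt(abs(mean(t1$z)), 4 / sqrt(n))
})

test_that("planted reversal shifts the target gene as specified", {
  sp <- plant_spec(n_compounds = 20, n_genes = 30, reversal_effect = -4,
                   reversal_cell_fraction = 1, noise_sd = 1)
  tn <- make_signature_tensor(sp, 2)
  # mean z of the target gene across the 10 lines: -4 +/- 1/sqrt(10), so
  # below -2 with overwhelming probability under the stated world
  for (tp in c("6h", "24h")) {
    expect_lt(mean(tn$z["BI-2536", "MCM2", , tp]), -2)
    expect_lt(mean(tn$z["BI-2536", "MCM10", , tp]), -2)
  }
  # non-planted compounds stay null
  expect_lt(abs(mean(tn$z["CPD0001", , , ])), 0.5)
})

test_that("sensitivity panel plants the negative expression/AUC correlation", {
  # degenerate: |corr_r| = 1 gives sample correlation exactly -1
  sp1 <- plant_spec(n_compounds = 3, n_genes = 5, corr_r = 1)
  pan <- make_sensitivity_panel(sp1, 9)
  r <- cor(pan$expression[, "MCM2"], pan$sensitivity["BI-2536", ])
  expect_equal(r, -1, tolerance = 1e-12)
  # corr_r = 0: mean sample r over 500 seeds is 0 within 0.05
  sp0 <- plant_spec(n_compounds = 3, n_genes = 5, corr_r = 0)
  rs <- vapply(1:500, function(s) {
    p <- make_sensitivity_panel(sp0, s)
    cor(p$expression[, "MCM2"], p$sensitivity["BI-2536", ])
  }, 0)
  expect_lt(abs(mean(rs)), 0.05)
  # fewer than 3 cell lines is an error
  sp2 <- plant_spec(n_compounds = 3, n_genes = 5, cell_lines = c("L1", "L2"))
  expect_error(make_sensitivity_panel(sp2, 1), "3 cell lines")
})

test_that("survival cohort generator obeys censoring and size rules", {
  co <- make_survival_cohort(100, hr = 2, cutoff_q = 0.5, censor_rate = 0,
                             seed = 3)
  expect_identical(sum(co$event == 0), 0L)
  expect_true(all(co$time > 0))
  co2 <- make_survival_cohort(300, hr = 1, cutoff_q = 0.5, censor_rate = 0.2,
                              seed = 3)
  expect_gt(sum(co2$event == 0), 0)
  expect_error(make_survival_cohort(5, 1, 0.5, 0, 1), "at least 10")
  expect_identical(make_survival_cohort(50, 2, 0.5, 0.1, seed = 8),
                   make_survival_cohort(50, 2, 0.5, 0.1, seed = 8))
})

test_that("mito image generator records ground truth and flags overcrowding", {
  img <- make_mito_image(1, c(40, 0), seed = 2)
  expect_identical(nrow(img$truth), 1L)
  expect_identical(attr(label_components(img$truth_mask), "n"), 1L)
  expect_identical(dim(img$mito), c(256L, 256L))
  img2 <- make_mito_image(1, c(40, 0), seed = 2)
  expect_identical(img$mito, img2$mito)
  # fused condition has strictly larger true per-object area at equal total length
  pair <- make_mito_condition_pair(total_len_px = 600, n_fused = 5,
                                   n_fission = 15, seed = 4)
  expect_gt(mean(pair$fused$truth$area_px2), mean(pair$fission$truth$area_px2))
  expect_gt(mean(pair$fused$truth$perimeter_px), mean(pair$fission$truth$perimeter_px))
  expect_error(make_mito_image(80, c(100, 10), width_px = 40, seed = 1),
               "overcrowded")
})

test_that("dose-response generator follows the Hill curve on the stated grid", {
  dr <- make_dose_response(ic50 = 10, hill = 1, noise_sd = 0, seed = 1)
  expect_setequal(unique(dr$dose), c(0, 1, 3, 10, 30, 100))
  expect_equal(dr$viability[dr$dose == 10][1], 50)
  expect_equal(dr$viability[dr$dose == 0][1], 100)
  mu <- tapply(dr$viability, dr$dose, mean)
  expect_true(all(diff(mu[order(as.numeric(names(mu)))]) <= 0))
  # steeper hill, same midpoint
  dr2 <- make_dose_response(ic50 = 10, hill = 3, noise_sd = 0, seed = 1)
  expect_equal(dr2$viability[dr2$dose == 10][1], 50)
  expect_lt(dr2$viability[dr2$dose == 30][1], dr$viability[dr$dose == 30][1])
})

test_that("demo dataset writer emits every pipeline input", {
  dir <- withr::local_tempdir()
  paths <- generate_demo_dataset(dir, plant_spec(n_compounds = 5, n_genes = 12),
                                 run_config(seed = 2))
  expect_true(all(file.exists(unlist(paths))))
  tn <- read_signature_tensor(paths$signatures)
  expect_identical(dim(tn$z), c(5L, 12L, 10L, 2L))
  expect_identical(dim(read_tiff16(paths$fused_mito)), c(256L, 256L))
  expect_s3_class(read_survival_csv(paths$survival), "survival_cohort")
  expect_gt(length(read_gmt(paths$gmt)), 0)
})
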