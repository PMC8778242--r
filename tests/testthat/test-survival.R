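test_that("Kaplan-Meier estimate matches hand product-limit computations", {
  # no censoring: empirical survival
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0))
  # single censored patient: flat at 1 with a warning
  expect_warning(km1 <- km_estimate(5, 0), "censored")
  expect_true(all(km1$surv == 1))
  # textbook 5-patient mixed example: events at 2, 5, 8; censored at 3, 6
  # S(2) = 4/5; S(5) = 4/5 * 2/3; S(8) = 4/5 * 2/3 * 0
  km5 <- km_estimate(c(2, 3, 5, 6, 8), c(1, 0, 1, 0, 1))
  ev <- km5[km5$n_event > 0, ]
  expect_equal(ev$surv, c(4/5, 4/5 * 2/3, 0), tolerance = 1e-12)
})

test_that("KM with no censoring equals the empirical survival function exactly", {
  set.seed(14)
  times <- round(rexp(60, 0.1), 2) + 0.01
  km <- km_estimate(times, rep(1, 60))
  emp <- vapply(km$time, function(t) mean(times > t), 0)
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("log-rank statistic matches hand arithmetic and survival::survdiff", {
  # identical groups: no separation
  r0 <- logrank(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)
  # 3 vs 3 example against an independent observed-expected/variance loop
  tA <- c(1, 4, 6); eA <- c(1, 1, 0)
  tB <- c(2, 3, 5); eB <- c(1, 1, 1)
  hand <- local({
    tt <- c(tA, tB); ee <- c(eA, eB); gg <- rep(0:1, each = 3)
    oe <- 0; v <- 0
    for (t in sort(unique(tt[ee == 1]))) {
      at <- tt >= t
      n <- sum(at); n1 <- sum(at & gg == 1)
      d <- sum(tt == t & ee == 1); d1 <- sum(tt == t & ee == 1 & gg == 1)
      oe <- oe + d1 - d * n1 / n
      if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    oe^2 / v
  })
  r <- logrank(tA, eA, tB, eB)
  expect_equal(r$chi2, hand, tolerance = 1e-12)
  sd <- survival::survdiff(survival::Surv(c(tA, tB), c(eA, eB)) ~ rep(0:1, each = 3))
  expect_equal(r$chi2, sd$chisq, tolerance = 1e-10)
  # label swap leaves the statistic unchanged
  expect_equal(logrank(tB, eB, tA, eA)$chi2, r$chi2, tolerance = 1e-12)
  expect_error(logrank(numeric(0), numeric(0), tB, eB), "non-empty")
  expect_error(logrank(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "at least one event")
})

test_that("the cutoff scan is Bonferroni-consistent and rank-based", {
  co <- make_survival_cohort(120, hr = 3, cutoff_q = 0.5, censor_rate = 0.2,
                             seed = 42)
  sc <- kaplan_scan(co, "MCM2")
  expect_equal(sc$bonf_p, min(1, sc$raw_p * sc$n_cutoffs_tested))
  expect_gte(sc$bonf_p, sc$raw_p)
  expect_identical(sc$n_high + sc$n_low, nrow(co))
  expect_identical(nrow(sc$scan), sc$n_cutoffs_tested)
  # every tested cutoff leaves min_group patients on each side
  mg <- max(8, ceiling(0.05 * nrow(co)))
  expect_gte(min(sapply(sc$scan$cutoff, function(ct) min(sum(co$MCM2 > ct), sum(co$MCM2 <= ct)))), mg)
  # monotone transform of expression changes the cutoff but not the p-values
  co_log <- co
  co_log$MCM2 <- log(co_log$MCM2)
  sc_log <- kaplan_scan(co_log, "MCM2")
  expect_equal(sc_log$raw_p, sc$raw_p, tolerance = 1e-12)
  expect_equal(sc_log$bonf_p, sc$bonf_p, tolerance = 1e-12)
  expect_equal(sc_log$best_cutoff, log(sc$best_cutoff), tolerance = 1e-9)
  # scan result agrees with a direct log-rank at the best cutoff
  high <- co$MCM2 > sc$best_cutoff
  lr <- logrank(co$time[!high], co$event[!high], co$time[high], co$event[high])
  expect_equal(sc$raw_p, lr$p, tolerance = 1e-12)
})

test_that("a single admissible cutoff needs no correction", {
  set.seed(2)
  co <- data.frame(patient_id = paste0("P", 1:16),
                   time = rexp(16, 0.1) + 0.1, event = rep(1, 16),
                   MCM2 = sample(seq(1, 16)))
  class(co) <- c("survival_cohort", "data.frame")
  sc <- kaplan_scan(co, "MCM2", min_group = 8)
  expect_identical(sc$n_cutoffs_tested, 1L)
  expect_equal(sc$bonf_p, sc$raw_p)
  expect_error(kaplan_scan(co, "MCM2", min_group = 9), "too small")
})

test_that("the cutoff scan recovers a strong planted cutoff", {
  # planted hazard ratio 4 at the median, cohort size of the larger
  # tumor data set; recovered cutoff quantile within 0.15 of truth
  hits <- vapply(1:10, function(s) {
    co <- make_survival_cohort(498, hr = 4, cutoff_q = 0.5, censor_rate = 0.2,
                               seed = 300 + s)
    sc <- kaplan_scan(co, "MCM2")
    q_found <- mean(co$MCM2 <= sc$best_cutoff)
    abs(q_found - 0.5) <= 0.15 && sc$bonf_p < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("stage summary reports group means and one-way ANOVA", {
  set.seed(3)
  vals <- c(rnorm(20, 5), rnorm(20, 7))
  grp <- rep(c("stage3", "stage4"), each = 20)
  ss <- stage_summary(vals, grp)
  expect_identical(ss$groups$n, c(20L, 20L))
  expect_equal(ss$anova_p,
               stats::anova(stats::lm(vals ~ factor(grp)))[["Pr(>F)"]][1],
               tolerance = 1e-10)
})
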