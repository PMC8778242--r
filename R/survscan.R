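#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] returning the step function as a
#' plain table. With no censoring it equals the empirical survival function.
#'
#' @param times positive event/censoring times.
#' @param events 0 = censored, 1 = event.
#' @return data.frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `surv` (right-continuous, `S(0) = 1` implicit).
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) > 0, all(times > 0), all(events %in% c(0, 1)))
  if (all(events == 0)) warning("all records censored; estimator is flat at 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

# log-rank chi-square, computed directly (observed - expected over the
# hypergeometric variance at each distinct event time). Implemented
# in-package because the cutoff scan calls it for every admissible cutoff,
# so it is fully vectorised over event times; cross-checked against
# survival::survdiff in the test suite.
logrank_stat <- function(times, events, high) {
  o <- order(times)
  prep <- logrank_prep(times[o], events[o] == 1)
  logrank_core(prep, high[o])
}

# grouping-independent event-table quantities, computed once per cohort
# (the cutoff scan reuses them for every cutoff); expects time-sorted input
logrank_prep <- function(ts, ev) {
  n <- length(ts)
  et <- ts[ev]
  u <- unique(et)                            # distinct event times, ascending
  first <- match(u, ts)                      # first at-risk index per event time
  list(n = n, ev = ev, first = first, n_at = n - first + 1,
       grp = match(et, u), d = tabulate(match(et, u), nbins = length(u)),
       n_times = length(u))
}

logrank_core <- function(prep, hi) {
  suffix_hi <- rev(cumsum(rev(hi)))          # high at risk at each sorted index
  n1_at <- suffix_hi[prep$first]
  d1 <- tabulate(prep$grp[hi[prep$ev]], nbins = prep$n_times)
  frac <- n1_at / prep$n_at
  o_minus_e <- sum(d1 - prep$d * frac)
  vterm <- prep$d * frac * (1 - frac) * (prep$n_at - prep$d) / pmax(prep$n_at - 1, 1)
  v <- sum(vterm[prep$n_at > 1])
  if (v <= 0) return(list(chi2 = 0, p = 1))
  chi2 <- o_minus_e^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square with p from the upper chi-square tail.
#'
#' @param timesA,eventsA,timesB,eventsB per-group times and 0/1 event codes.
#' @return list with `chi2` and `p`.
#' @export
logrank <- function(timesA, eventsA, timesB, eventsB) {
  if (!length(timesA) || !length(timesB)) stop("both groups must be non-empty")
  stopifnot(length(timesA) == length(eventsA), length(timesB) == length(eventsB))
  if (sum(eventsA) + sum(eventsB) < 1) stop("at least one event is required")
  logrank_stat(c(timesA, timesB), c(eventsA, eventsB),
               c(rep(FALSE, length(timesA)), rep(TRUE, length(timesB))))
}

#' Expression-cutoff scan for survival stratification
#'
#' The "Kaplan scan": every distinct expression value that leaves at least
#' `min_group` patients on each side (high = expression strictly above the
#' cutoff) is tested with the log-rank statistic; the cutoff with minimal
#' raw p is reported together with the Bonferroni-corrected
#' `bonf_p = min(1, raw_p * n_cutoffs_tested)`. The raw minimum p over a
#' scan is anti-conservative; Bonferroni over the number of cutoffs actually
#' tested restores control. Ties on raw p resolve to the smallest cutoff.
#' The scan depends on expression only through ranks, so it is invariant to
#' monotone transforms.
#'
#' @param cohort a `survival_cohort` data.frame.
#' @param gene expression column to scan.
#' @param min_group minimum group size; default `max(8, ceiling(0.05 * n))`.
#' @return list of class `scan_result`: `gene`, `best_cutoff`, `n_high`,
#'   `n_low`, `raw_p`, `chi2`, `bonf_p`, `n_cutoffs_tested`, `km_high`,
#'   `km_low`, and the per-cutoff table `scan`.
#' @export
kaplan_scan <- function(cohort, gene, min_group = NULL) {
  if (!gene %in% names(cohort)) stop("gene not in cohort: ", gene)
  expr <- cohort[[gene]]
  ok <- is.finite(expr)
  expr <- expr[ok]
  times <- cohort$time[ok]
  events <- cohort$event[ok]
  n <- length(expr)
  if (is.null(min_group) || is.na(min_group)) min_group <- max(8L, ceiling(0.05 * n))
  if (n < 2L * min_group) stop("cohort too small for min_group = ", min_group)
  vals <- sort(unique(expr))
  n_above <- n - findInterval(vals, sort(expr)) # patients with expr > cutoff
  admissible <- vals[n_above >= min_group & (n - n_above) >= min_group]
  if (!length(admissible)) stop("no admissible cutoff for gene ", gene)
  o <- order(times)
  prep <- logrank_prep(times[o], events[o] == 1)
  expr_sorted <- expr[o]
  chi2 <- p <- numeric(length(admissible))
  for (i in seq_along(admissible)) {
    r <- logrank_core(prep, expr_sorted > admissible[i])
    chi2[i] <- r$chi2
    p[i] <- r$p
  }
  best <- which.min(p) # first index, i.e. smallest cutoff on ties
  high <- expr > admissible[best]
  out <- list(
    gene = gene,
    best_cutoff = admissible[best],
    n_high = sum(high), n_low = sum(!high),
    raw_p = p[best], chi2 = chi2[best],
    bonf_p = min(1, p[best] * length(admissible)),
    n_cutoffs_tested = length(admissible),
    km_high = km_estimate(times[high], events[high]),
    km_low = km_estimate(times[!high], events[!high]),
    scan = data.frame(cutoff = admissible, chi2 = chi2, p = p)
  )
  class(out) <- "scan_result"
  out
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %s: best cutoff %.4g (%d high / %d low), raw p = %.3g, Bonferroni p = %.3g over %d cutoffs\n",
              x$gene, x$best_cutoff, x$n_high, x$n_low, x$raw_p, x$bonf_p,
              x$n_cutoffs_tested))
  invisible(x)
}

#' Per-stage descriptive summary (reporting helper)
#'
#' Group means with a one-way ANOVA p-value, for stage-wise expression
#' summaries accompanying the survival analysis. Descriptive only.
#'
#' @param values numeric vector (e.g. expression).
#' @param groups group labels (e.g. tumor stage).
#' @return list with per-group `n`/`mean` table and `anova_p`.
#' @export
stage_summary <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  tab <- data.frame(group = levels(groups),
                    n = as.integer(table(groups)),
                    mean = as.numeric(tapply(values, groups, mean)))
  list(groups = tab,
       anova_p = stats::oneway.test(values ~ groups, var.equal = TRUE)$p.value)
}
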