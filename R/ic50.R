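# 4-parameter logistic in log10-dose:
# v(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)
fourpl <- function(d, top, bottom, log10_ic50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(d) - log10_ic50)))
}

#' Estimate IC50 from a dose-response table
#'
#' Two routes are provided, matching common practice with plate-reader
#' viability panels on a small dose gradient:
#'
#' * `"4PL"` (default): least-squares fit of a four-parameter logistic
#'   (top and bottom free) on log10 dose, excluding the dose-0 control
#'   (which only anchors the 100% scale). The optimiser is deterministic:
#'   three fixed initialisations (IC50 at the lower quartile, geometric
#'   mean, and upper quartile of the positive doses), best residual wins,
#'   followed by a Nelder-Mead polish. The IC50 is the fitted half-effect
#'   concentration `10^log10_ic50`.
#' * `"interpolation"`: log-linear interpolation of mean viability between
#'   the two doses bracketing 50%.
#'
#' The fit is flagged `extrapolated` when the estimate leaves
#' `[min positive dose / 10, max dose * 10]`.
#'
#' @param table data.frame with `dose`, `viability` (percent of control) and
#'   optionally `replicate` (see [read_dose_response_csv()]).
#' @param method `"4PL"` or `"interpolation"`.
#' @return list of class `ic50_fit`: `ic50`, `hill`, `method`,
#'   `residual_sse`, `extrapolated`, `params`.
#' @export
fit_ic50 <- function(table, method = c("4PL", "interpolation")) {
  method <- match.arg(method)
  stopifnot(all(c("dose", "viability") %in% names(table)))
  pos <- table[table$dose > 0, , drop = FALSE]
  if (stats::sd(table$viability) < 1e-9) stop("IC50 not identifiable: flat viability")
  dose_rng <- range(pos$dose)
  if (method == "interpolation") {
    mu <- tapply(pos$viability, pos$dose, mean)
    d <- as.numeric(names(mu))
    o <- order(d); d <- d[o]; mu <- as.numeric(mu)[o]
    cross <- which(mu[-length(mu)] >= 50 & mu[-1] <= 50)
    if (!length(cross)) stop("IC50 not identifiable: mean viability does not cross 50%")
    i <- cross[1]
    if (mu[i] == mu[i + 1]) {
      lic <- log10(d[i])
    } else {
      lic <- log10(d[i]) + (mu[i] - 50) / (mu[i] - mu[i + 1]) *
        (log10(d[i + 1]) - log10(d[i]))
    }
    ic50 <- 10^lic
    fit <- list(ic50 = ic50, hill = NA_real_, method = method,
                residual_sse = NA_real_,
                extrapolated = ic50 < dose_rng[1] / 10 || ic50 > dose_rng[2] * 10,
                params = NULL)
    class(fit) <- "ic50_fit"
    return(fit)
  }
  if (length(unique(pos$dose)) < 4L) stop("4PL fit needs at least 4 distinct positive doses")
  d <- pos$dose; v <- pos$viability
  sse <- function(par) {
    pred <- fourpl(d, par[1], par[2], par[3], par[4])
    sum((v - pred)^2)
  }
  qs <- stats::quantile(log10(d), c(0.25, 0.5, 0.75), names = FALSE)
  starts <- lapply(qs, function(lq) c(max(v), min(v), lq, 1))
  fits <- lapply(starts, function(p0) {
    f <- stats::optim(p0, sse, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    stats::optim(f$par, sse, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-15))
  })
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  par <- best$par
  if (!all(is.finite(par)) || abs(par[1] - par[2]) < 1e-6) {
    stop("IC50 not identifiable: 4PL fit did not converge to a dose effect")
  }
  # half-maximal-INHIBITION convention requires a decreasing curve
  if (par[4] < 0) {
    par <- c(par[2], par[1], par[3], -par[4])
  }
  ic50 <- 10^par[3]
  fit <- list(ic50 = ic50, hill = par[4], method = method,
              residual_sse = best$value,
              extrapolated = ic50 < dose_rng[1] / 10 || ic50 > dose_rng[2] * 10,
              params = stats::setNames(par, c("top", "bottom", "log10_ic50", "hill")))
  class(fit) <- "ic50_fit"
  fit
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("<ic50_fit> IC50 = %.4g (%s%s), hill = %.3g, SSE = %.3g\n",
              x$ic50, x$method, if (x$extrapolated) ", extrapolated" else "",
              x$hill, x$residual_sse))
  invisible(x)
}
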