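#' Hill dose-response fit of channel modification
#'
#' Least-squares fit of `M(c) = m_max * c^h / (c^h + ec50^h)` by
#' Levenberg-Marquardt with multi-start initialization (EC50 starts spread
#' over the tested concentration range, Hill slopes 0.5/1/2, plateau near
#' the observed maximum). EC50 is parameterised on the log scale; the
#' plateau is bounded by 100%.
#'
#' @param concentration Concentrations (> 0), >= 3 distinct values.
#' @param m Observed M percentages (same length).
#' @return A `hill_fit`: `ec50`, `hill`, `m_max`, standard errors
#'   (`se_ec50`, `se_hill`, `se_m_max`), `rss`, `residuals`, `fitted`,
#'   `converged`, `n`.
#' @export
fit_hill <- function(concentration, m) {
  stopifnot(length(concentration) == length(m), all(concentration > 0))
  if (length(unique(concentration)) < 3)
    stop("need >= 3 distinct concentrations")
  dat <- data.frame(conc = concentration, m = m)
  lc_range <- range(log(concentration))
  starts <- expand.grid(
    lec50 = seq(lc_range[1], lc_range[2], length.out = 5),
    h = c(0.5, 1, 2),
    mmax = max(m) * c(1.05, 1.3))
  starts$mmax <- pmin(starts$mmax, 100)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        m ~ mmax / (1 + (exp(lec50) / conc)^h),
        data = dat,
        start = list(mmax = starts$mmax[s], h = starts$h[s],
                     lec50 = starts$lec50[s]),
        lower = c(mmax = 1e-6, h = 0.05,
                  lec50 = lc_range[1] - log(1e4)),
        upper = c(mmax = 100, h = 20, lec50 = lc_range[2] + log(1e4)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    out <- list(ec50 = NA_real_, hill = NA_real_, m_max = NA_real_,
                converged = FALSE, n = nrow(dat))
    class(out) <- "hill_fit"
    return(out)
  }
  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))),
                 error = function(e) rep(NA_real_, 3))
  names(se) <- names(cf)
  ec50 <- exp(unname(cf["lec50"]))
  out <- list(
    ec50 = ec50, hill = unname(cf["h"]), m_max = unname(cf["mmax"]),
    se_ec50 = ec50 * unname(se["lec50"]), se_hill = unname(se["h"]),
    se_m_max = unname(se["mmax"]), se_log_ec50 = unname(se["lec50"]),
    rss = best$rss, residuals = as.numeric(residuals(best$fit)),
    fitted = as.numeric(fitted(best$fit)), converged = TRUE, n = nrow(dat))
  class(out) <- "hill_fit"
  out
}

#' @importFrom stats residuals
NULL

#' EC50 fold shift between two channel variants
#'
#' `fold = ec50_variant / ec50_reference`, with a 95% CI by error
#' propagation on log EC50 (the two fits are independent, so the log-scale
#' variances add).
#'
#' @param fit_variant,fit_reference Converged `hill_fit` objects.
#' @return A `sensitivity_shift`: `fold`, `ci95`, `se_log`.
#' @export
sensitivity_shift <- function(fit_variant, fit_reference) {
  for (f in list(fit_variant, fit_reference)) {
    stopifnot(inherits(f, "hill_fit"))
    if (!isTRUE(f$converged))
      stop("cannot form a fold shift from a non-converged Hill fit")
  }
  se_log <- sqrt((fit_variant$se_log_ec50 %||% NA_real_)^2 +
                 (fit_reference$se_log_ec50 %||% NA_real_)^2)
  lf <- log(fit_variant$ec50) - log(fit_reference$ec50)
  z <- qnorm(0.975)
  out <- list(fold = exp(lf),
              ci95 = exp(lf + c(-1, 1) * z * se_log),
              se_log = se_log)
  class(out) <- "sensitivity_shift"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("Hill fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Hill fit: EC50 %.4g (se %.2g), slope %.3g (se %.2g), plateau %.3g%%\n",
    x$ec50, x$se_ec50, x$hill, x$se_hill, x$m_max))
  invisible(x)
}

#' @export
print.sensitivity_shift <- function(x, ...) {
  cat(sprintf("EC50 fold shift: %.3g (95%% CI %.3g - %.3g)\n",
              x$fold, x$ci95[1], x$ci95[2]))
  invisible(x)
}
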