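#' Abbott correction for natural (control) mortality
#'
#' Rescales treated mortality by the control mortality,
#' `p' = max(0, (p - pc) / (1 - pc))`, carried as effective death counts, and
#' drops the control row. A no-op when control mortality is zero.
#'
#' @param table A `conc_mort_table` containing a control row at
#'   concentration 0.
#' @return The corrected table without the control row. Corrected death
#'   counts are fractional in general.
#' @export
abbott_correct <- function(table) {
  tb <- as.data.frame(table)
  ctrl <- tb$concentration <= 0
  if (!any(ctrl)) stop("no control row (concentration 0) found")
  pc <- sum(tb$n_dead[ctrl]) / sum(tb$n_exposed[ctrl])
  if (pc >= 1) stop("control mortality is 1; correction undefined")
  out <- tb[!ctrl, , drop = FALSE]
  if (pc > 0) {
    p <- out$n_dead / out$n_exposed
    out$n_dead <- out$n_exposed * pmax(0, (p - pc) / (1 - pc))
  }
  rownames(out) <- NULL
  attr(out, "unit") <- attr(table, "unit")
  attr(out, "control_mortality") <- pc
  class(out) <- c("conc_mort_table", "data.frame")
  out
}

#' Probit concentration-mortality fit
#'
#' Maximum-likelihood probit regression of mortality on log10 concentration,
#' `Phi^-1(p) = alpha + beta * log10(c)`, fitted by iteratively reweighted
#' least squares (deviance tolerance 1e-10). Replicates at the same
#' concentration are pooled. The LC50 is `10^(-alpha/beta)` with a 95%
#' Fieller interval; lack of fit is assessed by the Pearson chi-square on the
#' pooled concentration groups (df = k - 2). When the chi-square p-value is
#' below 0.05 the parameter covariance is inflated by the heterogeneity
#' factor chi2/df and the normal quantile is replaced by the t quantile with
#' k - 2 df, following standard probit-analysis practice.
#'
#' Control rows are not modelled: a concentration-0 row with zero deaths is
#' dropped silently; with non-zero deaths, [abbott_correct()] should be
#' applied first (a warning is issued and the row dropped).
#'
#' @param table A `conc_mort_table` with at least 3 distinct positive
#'   concentrations and at least one partial (0 < p < 1) response.
#' @param conf_level Confidence level for the LC50 interval.
#' @return A `probit_fit` with elements `alpha`, `beta`, `se_alpha`,
#'   `se_beta`, `vcov` (heterogeneity-scaled when applicable), `lc50`,
#'   `lc50_ci`, `chi2`, `df`, `p_value`, `heterogeneity`, `n_total`, `k`,
#'   `flag` (`NULL`, `"separation"` or `"non-monotone"`) and the pooled data.
#' @export
fit_probit <- function(table, conf_level = 0.95) {
  tb <- as.data.frame(table)
  ctrl <- tb$concentration <= 0
  if (any(ctrl)) {
    if (sum(tb$n_dead[ctrl]) > 0)
      warning("control row with deaths present; apply abbott_correct() ",
              "first. Control row dropped.")
    tb <- tb[!ctrl, , drop = FALSE]
  }
  agg <- aggregate(cbind(n_exposed, n_dead) ~ concentration, data = tb,
                   FUN = sum)
  agg <- agg[order(agg$concentration), ]
  k <- nrow(agg)
  if (k < 3) stop("need >= 3 distinct positive concentrations, got ", k)
  p_obs <- agg$n_dead / agg$n_exposed
  base <- list(k = k, n_total = sum(agg$n_exposed), data = agg,
               unit = attr(table, "unit"), conf_level = conf_level)
  if (!any(p_obs > 0 & p_obs < 1)) {
    # complete separation: every pooled group is all-dead or all-alive
    fit <- c(base, list(flag = "separation", alpha = NA_real_,
                        beta = NA_real_, lc50 = NA_real_,
                        lc50_ci = c(NA_real_, NA_real_)))
    class(fit) <- "probit_fit"
    return(fit)
  }
  x <- log10(agg$concentration)
  gfit <- suppressWarnings(glm(
    cbind(n_dead, n_exposed - n_dead) ~ x,
    family = binomial(link = "probit"),
    data = agg,
    control = glm.control(epsilon = 1e-10, maxit = 200)))
  cf <- coef(gfit)
  alpha <- unname(cf[1]); beta <- unname(cf[2])
  if (!is.finite(beta) || beta <= 0) {
    fit <- c(base, list(flag = "non-monotone", alpha = alpha, beta = beta,
                        lc50 = NA_real_, lc50_ci = c(NA_real_, NA_real_)))
    class(fit) <- "probit_fit"
    return(fit)
  }
  V <- unname(vcov(gfit))
  p_hat <- pnorm(alpha + beta * x)
  e <- agg$n_exposed * p_hat
  chi2 <- sum((agg$n_dead - e)^2 / (e * (1 - p_hat)))
  df <- k - 2L
  p_value <- if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  het <- 1
  q <- qnorm(1 - (1 - conf_level) / 2)
  if (df > 0 && !is.na(p_value) && p_value < 0.05) {
    het <- chi2 / df
    V <- V * het
    q <- qt(1 - (1 - conf_level) / 2, df)
  }
  fit <- c(base, list(
    flag = NULL, alpha = alpha, beta = beta,
    se_alpha = sqrt(V[1, 1]), se_beta = sqrt(V[2, 2]), vcov = V,
    chi2 = chi2, df = df, p_value = p_value, heterogeneity = het, q = q,
    loglik = as.numeric(logLik(gfit))))
  class(fit) <- "probit_fit"
  lc <- lc_at(fit, 0.5)
  fit$lc50 <- lc$dose
  fit$lc50_ci <- lc$ci
  fit
}

#' @importFrom stats logLik
NULL

#' Lethal concentration at an arbitrary mortality quantile
#'
#' Inverts a probit fit: `LCp = 10^((qnorm(p) - alpha)/beta)`, with a
#' confidence interval from Fieller's theorem on the ratio
#' `(qnorm(p) - alpha)/beta`, using the fit's (possibly
#' heterogeneity-scaled) covariance and critical quantile.
#'
#' @param fit A converged `probit_fit`.
#' @param p Mortality proportion in (0, 1).
#' @return List with `dose` and `ci` (lower, upper). CI bounds are `NA` when
#'   the Fieller set is unbounded (slope not distinguishable from 0).
#' @export
lc_at <- function(fit, p) {
  stopifnot(inherits(fit, "probit_fit"))
  if (!is.null(fit$flag)) stop("fit is flagged ('", fit$flag,
                               "'); no finite lethal concentrations")
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("`p` must be a single proportion strictly inside (0, 1)")
  zp <- qnorm(p)
  a <- zp - fit$alpha
  b <- fit$beta
  rho <- a / b
  V <- fit$vcov
  vaa <- V[1, 1]; vab <- -V[1, 2]; vbb <- V[2, 2]
  q <- fit$q
  A <- b^2 - q^2 * vbb
  B <- -2 * (a * b - q^2 * vab)
  C <- a^2 - q^2 * vaa
  disc <- B^2 - 4 * A * C
  ci <- if (A > 0 && disc >= 0) {
    sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  } else c(NA_real_, NA_real_)
  list(dose = 10^rho, ci = 10^ci)
}

#' Resistance ratio between two probit fits
#'
#' `RR = LC50_resistant / LC50_susceptible` with a 95% CI from the delta
#' method on log10 LC50: `var(log10 LC50) = g' V g` with
#' `g = (-1/beta, alpha/beta^2)`, variances summed across the two independent
#' fits, CI `10^(log10 RR +/- z * SE)`. The ratio is declared significant
#' when the CI excludes 1 — the standard lethal-dose-ratio test.
#'
#' @param fit_resistant,fit_susceptible Converged `probit_fit` objects.
#' @param conf_level Confidence level.
#' @return A `resistance_ratio`: list with `rr`, `ci95`, `se_log10`,
#'   `significant`.
#' @export
resistance_ratio <- function(fit_resistant, fit_susceptible,
                             conf_level = 0.95) {
  for (f in list(fit_resistant, fit_susceptible)) {
    stopifnot(inherits(f, "probit_fit"))
    if (!is.null(f$flag))
      stop("cannot form a resistance ratio from a flagged fit ('",
           f$flag, "')")
  }
  vlog <- function(f) {
    g <- c(-1 / f$beta, f$alpha / f$beta^2)
    as.numeric(t(g) %*% f$vcov %*% g)
  }
  l10 <- function(f) -f$alpha / f$beta
  d <- l10(fit_resistant) - l10(fit_susceptible)
  se <- sqrt(vlog(fit_resistant) + vlog(fit_susceptible))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- 10^(d + c(-1, 1) * z * se)
  out <- list(rr = 10^d, ci95 = ci, se_log10 = se,
              significant = ci[1] > 1 || ci[2] < 1)
  class(out) <- "resistance_ratio"
  out
}

#' Resistance ratio from published LC50 summaries
#'
#' When only an LC50 and its 95% CI are reported (no parameter covariance),
#' the log10-scale standard error is recovered as
#' `(log10(upper) - log10(lower)) / (2 * 1.96)` and the ratio test proceeds
#' as in [resistance_ratio()]. This is how ratios between published strain
#' summaries are recomputed.
#'
#' @param lc50_r,ci_r Resistant LC50 and its (lower, upper) 95% CI.
#' @param lc50_s,ci_s Susceptible LC50 and its (lower, upper) 95% CI.
#' @return A `resistance_ratio`.
#' @export
resistance_ratio_from_summary <- function(lc50_r, ci_r, lc50_s, ci_s) {
  stopifnot(lc50_r > 0, lc50_s > 0, all(ci_r > 0), all(ci_s > 0))
  z <- qnorm(0.975)
  se_r <- (log10(ci_r[2]) - log10(ci_r[1])) / (2 * z)
  se_s <- (log10(ci_s[2]) - log10(ci_s[1])) / (2 * z)
  d <- log10(lc50_r) - log10(lc50_s)
  se <- sqrt(se_r^2 + se_s^2)
  ci <- 10^(d + c(-1, 1) * z * se)
  out <- list(rr = 10^d, ci95 = ci, se_log10 = se,
              significant = ci[1] > 1 || ci[2] < 1)
  class(out) <- "resistance_ratio"
  out
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Probit concentration-mortality fit\n")
  if (!is.null(x$flag)) {
    cat("  flagged:", x$flag, "- no finite fit\n")
    return(invisible(x))
  }
  cat(sprintf("  slope %.3g +/- %.3g, intercept %.3g\n",
              x$beta, x$se_beta, x$alpha))
  cat(sprintf("  LC50 %.4g (%.4g - %.4g) %s\n", x$lc50, x$lc50_ci[1],
              x$lc50_ci[2], x$unit %||% ""))
  cat(sprintf("  chi2 %.3g on %d df, P = %.3g (heterogeneity %.3g)\n",
              x$chi2, x$df, x$p_value, x$heterogeneity))
  cat(sprintf("  n = %d over %d concentrations\n", x$n_total, x$k))
  invisible(x)
}

#' @export
print.resistance_ratio <- function(x, ...) {
  cat(sprintf("RR = %.4g (%.4g - %.4g)%s\n", x$rr, x$ci95[1], x$ci95[2],
              if (x$significant) " *" else " (n.s.)"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bioassay summary table across strains and insecticides
#'
#' Builds a combined summary (slope +/- SE, LC50 with CI, chi-square, P,
#' RR with CI) from a named list of probit fits, pairing each resistant fit
#' with the susceptible fit of the same stage and insecticide.
#'
#' @param fits Named list of `probit_fit` objects.
#' @param meta Data frame with one row per fit (same order) and columns
#'   `stage`, `insecticide`, `strain` where `strain` is `"susceptible"` or
#'   `"resistant"`.
#' @return Data frame, one row per fit, resistant rows carrying RR columns.
#' @export
bioassay_summary <- function(fits, meta) {
  stopifnot(length(fits) == nrow(meta))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    out <- data.frame(
      stage = meta$stage[i], insecticide = meta$insecticide[i],
      strain = meta$strain[i], n = f$n_total,
      slope = f$beta, slope_se = f$se_beta,
      lc50 = f$lc50, lc50_lo = f$lc50_ci[1], lc50_hi = f$lc50_ci[2],
      chi2 = f$chi2, p_value = f$p_value,
      rr = NA_real_, rr_lo = NA_real_, rr_hi = NA_real_,
      stringsAsFactors = FALSE)
    if (meta$strain[i] == "resistant") {
      j <- which(meta$stage == meta$stage[i] &
                 meta$insecticide == meta$insecticide[i] &
                 meta$strain == "susceptible")
      if (length(j) == 1L) {
        rr <- resistance_ratio(f, fits[[j]])
        out$rr <- rr$rr; out$rr_lo <- rr$ci95[1]; out$rr_hi <- rr$ci95[2]
      }
    }
    out
  })
  do.call(rbind, rows)
}
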