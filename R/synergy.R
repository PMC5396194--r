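#' One-way analysis of variance on replicate mortality proportions
#'
#' Classical fixed-effects decomposition computed directly from sums of
#' squares: `SSB = sum n_i (ybar_i - ybar)^2`, `SSW = sum (y_ij - ybar_i)^2`,
#' `F = (SSB/(k-1)) / (SSW/(N-k))`, with the p-value from the F distribution.
#' Each replicate jar/vial mortality proportion is one observation;
#' proportions are analysed untransformed by default (`transform = "asin"`
#' applies the arcsine-square-root variance-stabilising transform first).
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with >= 2
#'   replicates, values in `[0, 1]` for mortality data; other responses such
#'   as per-oocyte M percentages are accepted and range-checking skipped).
#' @param transform `"none"` (default) or `"asin"`.
#' @return An `anova_result`: `f_stat`, `df_between`, `df_within`,
#'   `p_value`, group `means`, sizes `n`, `msw`, `ssb`, `ssw`.
#' @export
one_way_anova <- function(groups, transform = c("none", "asin")) {
  transform <- match.arg(transform)
  groups <- validate_groups(groups)
  if (transform == "asin")
    groups <- lapply(groups, function(y) asin(sqrt(pmin(pmax(y, 0), 1))))
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(seq_len(k),
                    function(i) sum((groups[[i]] - means[i])^2), numeric(1)))
  df_b <- k - 1L
  df_w <- N - k
  msw <- ssw / df_w
  rng <- range(unlist(groups))
  if (rng[2] - rng[1] == 0) {
    # all observations identical: no variation to partition
    f <- 0; p <- 1; ssb <- 0; ssw <- 0
  } else {
    f <- (ssb / df_b) / msw
    p <- pf(f, df_b, df_w, lower.tail = FALSE)
  }
  out <- list(f_stat = f, df_between = df_b, df_within = df_w, p_value = p,
              means = means, n = n, msw = msw, ssb = ssb, ssw = ssw,
              groups = groups, transform = transform)
  class(out) <- "anova_result"
  out
}

validate_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("`groups` must be a list of >= 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  lens <- vapply(groups, length, integer(1))
  if (any(lens < 2)) stop("every group needs >= 2 replicates")
  groups
}

#' Scheffe post hoc contrasts for all group pairs
#'
#' For each pair (i, j) the mean difference is compared with the Scheffé
#' bound `sqrt((k-1) * qf(1-alpha, k-1, N-k)) * sqrt(MSW * (1/n_i + 1/n_j))`;
#' a pair is significant when `|mean_i - mean_j|` exceeds its bound. The
#' procedure controls the family-wise error rate over all contrasts, so with
#' k = 2 it reduces exactly to the ANOVA F test.
#'
#' @param groups Named list of replicate vectors (see [one_way_anova()]), or
#'   an `anova_result`.
#' @param alpha Family-wise significance level in (0, 1).
#' @return Data frame with one row per pair: `group_a`, `group_b`,
#'   `difference`, `critical`, `significant`.
#' @export
scheffe_posthoc <- function(groups, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie strictly inside (0, 1)")
  an <- if (inherits(groups, "anova_result")) groups else one_way_anova(groups)
  k <- an$df_between + 1L
  fc <- qf(1 - alpha, an$df_between, an$df_within)
  pairs <- utils::combn(names(an$means), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    d <- an$means[[i]] - an$means[[j]]
    crit <- sqrt((k - 1) * fc) *
      sqrt(an$msw * (1 / an$n[[i]] + 1 / an$n[[j]]))
    data.frame(group_a = i, group_b = j, difference = d, critical = crit,
               significant = abs(d) > crit, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Synergism summary against the unsynergized insecticide
#'
#' Flags which synergist treatments change mortality relative to the
#' insecticide-alone reference group, using the Scheffé contrasts from the
#' full one-way ANOVA (asterisk-style flags as in synergist bioassay
#' figures).
#'
#' @param groups Named list of replicate mortality vectors.
#' @param reference Name of the insecticide-alone group.
#' @param alpha Family-wise significance level.
#' @return A `synergism_report`: the `anova_result` plus a data frame
#'   `contrasts` with `synergist`, `mean`, `difference` (synergist minus
#'   reference), `significant` and `direction`
#'   (`"increase"`/`"decrease"`/`"none"`).
#' @export
synergism_report <- function(groups, reference, alpha = 0.05) {
  groups <- validate_groups(groups)
  if (missing(reference) || !reference %in% names(groups))
    stop("`reference` must name one of the groups")
  an <- one_way_anova(groups)
  sch <- scheffe_posthoc(an, alpha)
  ref_rows <- sch[sch$group_a == reference | sch$group_b == reference, ]
  contrasts <- do.call(rbind, lapply(seq_len(nrow(ref_rows)), function(r) {
    row <- ref_rows[r, ]
    syn <- if (row$group_a == reference) row$group_b else row$group_a
    d <- an$means[[syn]] - an$means[[reference]]
    data.frame(synergist = syn, mean = an$means[[syn]], difference = d,
               significant = row$significant,
               direction = if (!row$significant) "none"
                           else if (d > 0) "increase" else "decrease",
               stringsAsFactors = FALSE)
  }))
  rownames(contrasts) <- NULL
  out <- list(anova = an, reference = reference,
              reference_mean = an$means[[reference]], contrasts = contrasts)
  class(out) <- "synergism_report"
  out
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g on (%d, %d) df, P = %.3g\n",
              x$f_stat, x$df_between, x$df_within, x$p_value))
  invisible(x)
}

#' @export
print.synergism_report <- function(x, ...) {
  print(x$anova)
  cat("reference:", x$reference,
      sprintf("(mean %.3g)\n", x$reference_mean))
  for (r in seq_len(nrow(x$contrasts))) {
    cc <- x$contrasts[r, ]
    cat(sprintf("  %-12s mean %.3g  diff %+.3g  %s\n", cc$synergist,
                cc$mean, cc$difference,
                if (cc$significant) paste0("* (", cc$direction, ")")
                else "n.s."))
  }
  invisible(x)
}
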