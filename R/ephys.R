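trace_baseline <- function(trace) {
  # mean holding current over the pre-pulse window
  mean(trace$current[trace$time < trace$pre_ms - 1e-9])
}

#' Peak sodium current during the first depolarization
#'
#' Baseline-subtracted extremum of the current within the first pulse
#' window; the baseline is the mean holding current before pulse 1. By the
#' inward-negative sign convention the peak is a negative excursion; its
#' magnitude is returned.
#'
#' @param trace A `current_trace` covering at least one depolarizing pulse.
#' @param noise_floor Multiple of the baseline-window noise sd below which
#'   the trace is flagged as flat (`NA` returned with a warning).
#' @return Peak current magnitude (uA), or `NA` for a flat trace.
#' @export
peak_current <- function(trace, noise_floor = 5) {
  stopifnot(inherits(trace, "current_trace"))
  pr <- trace$protocol
  base <- trace_baseline(trace)
  w <- trace$time >= trace$pre_ms &
    trace$time <= trace$pre_ms + pr$pulse_ms
  if (!any(w)) stop("trace does not cover the first depolarizing pulse")
  dev <- abs(trace$current[w] - base)
  noise <- sd(trace$current[trace$time < trace$pre_ms - 1e-9])
  if (noise > 0 && max(dev) < noise_floor * noise) {
    warning("no pulse response above the noise floor; trace flagged flat")
    return(NA_real_)
  }
  max(dev)
}

#' Maximal tail-current amplitude after the final repolarization
#'
#' Baseline-subtracted maximal amplitude in the window following the final
#' pulse's repolarization, excluding the first `blank_ms` (capacitive
#' blanking). A short running-mean filter (`smooth_ms`) suppresses the
#' upward bias that point noise would otherwise add to the maximum; it is
#' negligible relative to the slow tail decay.
#'
#' @param trace A `current_trace` covering the final repolarization.
#' @param blank_ms Capacitive blanking window (ms).
#' @param smooth_ms Running-mean window (ms); 0 disables smoothing.
#' @return Tail amplitude magnitude (uA).
#' @export
tail_amplitude <- function(trace, blank_ms = 0.3, smooth_ms = 0.25) {
  stopifnot(inherits(trace, "current_trace"))
  pr <- trace$protocol
  repol <- trace$pre_ms + pr$n_pulses * pr$pulse_ms +
    (pr$n_pulses - 1) * pr$inter_ms
  t_end <- max(trace$time)
  if (t_end - repol <= blank_ms)
    stop("tail window (", signif(t_end - repol, 3),
         " ms) is shorter than the blanking period (", blank_ms, " ms)")
  base <- trace_baseline(trace)
  w <- trace$time >= repol + blank_ms
  y <- trace$current[w] - base
  if (smooth_ms > 0) {
    # smooth inside the blanked window only, so the fast pre-blank decay
    # cannot leak into the window through the filter
    k <- max(1L, round(smooth_ms / trace$sample_interval))
    if (k > 1L) {
      sm <- stats::filter(y, rep(1 / k, k), sides = 2)
      y <- ifelse(is.na(sm), y, as.numeric(sm))
    }
  }
  max(abs(y))
}

#' Reversal potential from a current-voltage curve
#'
#' Linear interpolation between the two sampled potentials bracketing the
#' zero crossing of the peak current.
#'
#' @param iv Data frame or list with `potential` (mV, strictly increasing)
#'   and `current` (uA), >= 2 points.
#' @return Reversal potential (mV); `NA` with a warning when the currents
#'   never change sign.
#' @export
reversal_potential <- function(iv) {
  v <- iv$potential; i <- iv$current
  stopifnot(length(v) >= 2, length(v) == length(i))
  if (is.unsorted(v, strictly = TRUE))
    stop("potentials must be strictly increasing")
  z <- which(i == 0)
  if (length(z) > 0) return(v[z[1]])
  s <- which(diff(sign(i)) != 0)
  if (length(s) == 0) {
    warning("currents do not change sign; reversal potential undefined")
    return(NA_real_)
  }
  j <- s[1]
  v[j] + (v[j + 1] - v[j]) * (0 - i[j]) / (i[j + 1] - i[j])
}

#' Percentage of pyrethroid-modified channels (the M statistic)
#'
#' `M = {[I_tail/(E_h - E_Na)] / [I_Na/(E_t - E_Na)]} x 100`: the ratio of
#' tail conductance to peak conductance. With signed driving forces (both
#' negative for a sodium channel repolarized below and stepped below E_Na),
#' M is non-negative for physically consistent inputs whether currents are
#' supplied signed or as magnitudes.
#'
#' @param i_tail Maximal tail-current amplitude (uA).
#' @param i_na Peak current during depolarization before pyrethroid exposure
#'   (uA); must be non-zero.
#' @param e_h Repolarization (holding) potential (mV).
#' @param e_na Sodium reversal potential (mV).
#' @param e_t Step-depolarization potential (mV).
#' @return M, a percentage.
#' @export
percent_modified <- function(i_tail, i_na, e_h, e_na, e_t) {
  if (e_h == e_na) stop("zero denominator: e_h equals e_na")
  if (e_t == e_na) stop("zero denominator: e_t equals e_na")
  if (i_na == 0) stop("zero denominator: i_na is 0")
  100 * (i_tail / (e_h - e_na)) / (i_na / (e_t - e_na))
}

#' M statistic extracted from a trace
#'
#' Convenience wrapper: [tail_amplitude()] over [peak_current()] through the
#' M formula, with `E_h` and `E_t` taken from the trace's protocol. When a
#' paired pre-drug trace is available its peak should be supplied as
#' `i_na`; by default the peak of the same trace is used.
#'
#' @param trace A `current_trace`.
#' @param e_na Sodium reversal potential (mV), e.g. from
#'   [reversal_potential()].
#' @param i_na Optional pre-drug peak current magnitude (uA).
#' @param blank_ms,smooth_ms Passed to [tail_amplitude()].
#' @return M (percentage).
#' @export
percent_modified_trace <- function(trace, e_na, i_na = NULL,
                                   blank_ms = 0.3, smooth_ms = 0.25) {
  pr <- trace$protocol
  if (is.null(i_na)) i_na <- peak_current(trace)
  percent_modified(tail_amplitude(trace, blank_ms, smooth_ms), i_na,
                   e_h = pr$v_hold, e_na = e_na, e_t = pr$v_step)
}

#' Per-trace M values of a simulated experiment
#'
#' Runs the extraction pipeline over every record of a
#' [simulate_vc_experiment()] result.
#'
#' @param experiment A `vc_experiment`.
#' @return Data frame with `concentration`, `oocyte`, `m` (extracted) and
#'   `expected_m` (generator closed form).
#' @export
extract_m_table <- function(experiment) {
  stopifnot(inherits(experiment, "vc_experiment"))
  rows <- lapply(experiment$records, function(r) {
    data.frame(concentration = r$concentration, oocyte = r$oocyte,
               m = percent_modified_trace(r$trace,
                                          e_na = experiment$spec$e_na),
               expected_m = r$expected_m)
  })
  do.call(rbind, rows)
}

#' Compare M values across channel variants
#'
#' One-way ANOVA with Scheffé post hoc contrasts over per-oocyte M values
#' grouped by variant (e.g. wild type, V410L, F1534C, double mutant).
#'
#' @param m_by_variant Named list of numeric M vectors, one per variant.
#' @param alpha Family-wise significance level for the contrasts.
#' @return List with `anova` (an `anova_result`) and `contrasts` (the
#'   Scheffé table).
#' @export
compare_variants <- function(m_by_variant, alpha = 0.05) {
  an <- one_way_anova(m_by_variant)
  list(anova = an, contrasts = scheffe_posthoc(an, alpha))
}
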