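#' Specification of a simulated concentration-mortality bioassay
#'
#' Describes the true dose-response and design of a simulated bioassay:
#' mortality follows a probit model on log10 concentration,
#' `p(c) = pi0 + (1 - pi0) * pnorm(alpha + beta * log10(c))`, where
#' `alpha = -beta * log10(true_lc50)`, `beta = true_slope` and `pi0` is the
#' natural (control) mortality.
#'
#' @param true_lc50 True LC50, in the concentration unit of the assay
#'   (micrograms a.i./mL for larvae, micrograms a.i./cm2 for adult vials).
#' @param true_slope True probit slope (probits per log10 concentration unit);
#'   must be positive.
#' @param concentrations Strictly positive, strictly increasing vector of
#'   tested concentrations.
#' @param n_per_conc Number of individuals exposed per concentration (>= 1).
#' @param control_mortality Natural mortality proportion in `[0, 1)`.
#' @param n_control Number of individuals in the untreated control group.
#' @param seed Integer seed making the simulated table reproducible.
#' @return An object of class `mortality_sim_spec`.
#' @seealso [simulate_mortality()], [design_concentrations()]
#' @export
mortality_sim_spec <- function(true_lc50, true_slope, concentrations,
                               n_per_conc, control_mortality = 0,
                               n_control = n_per_conc, seed = 1L) {
  stopifnot(is.numeric(true_lc50), length(true_lc50) == 1L, true_lc50 > 0)
  if (!is.numeric(true_slope) || true_slope <= 0)
    stop("`true_slope` must be positive")
  if (any(concentrations <= 0))
    stop("concentrations must be strictly positive; offending value(s): ",
         paste(concentrations[concentrations <= 0], collapse = ", "))
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  stopifnot(n_per_conc >= 1, n_control >= 0)
  if (control_mortality < 0 || control_mortality >= 1)
    stop("`control_mortality` must lie in [0, 1)")
  structure(
    list(true_lc50 = true_lc50, true_slope = true_slope,
         concentrations = as.numeric(concentrations),
         n_per_conc = as.integer(n_per_conc),
         control_mortality = control_mortality,
         n_control = as.integer(n_control), seed = as.integer(seed)),
    class = "mortality_sim_spec")
}

#' Concentration series spanning a target mortality range
#'
#' Log-spaced concentrations placed so the probit model predicts mortality
#' from `p_range[1]` to `p_range[2]`, mirroring the usual bioassay practice
#' of choosing concentrations that bracket 5-95% mortality.
#'
#' @param lc50,slope True LC50 and probit slope.
#' @param k Number of concentrations.
#' @param p_range Mortality proportions at the lowest and highest
#'   concentration.
#' @return Numeric vector of `k` concentrations.
#' @export
design_concentrations <- function(lc50, slope, k = 5,
                                  p_range = c(0.05, 0.95)) {
  stopifnot(k >= 2, all(p_range > 0), all(p_range < 1))
  lo <- log10(lc50) + qnorm(p_range[1]) / slope
  hi <- log10(lc50) + qnorm(p_range[2]) / slope
  10^seq(lo, hi, length.out = k)
}

#' Simulate a concentration-mortality table
#'
#' Draws binomial death counts under the probit dose-response of a
#' [mortality_sim_spec()], with natural mortality mixed in as
#' `p = pi0 + (1 - pi0) * pnorm(alpha + beta * log10(c))`. A control row at
#' concentration 0 is included (with mortality `pi0`) whenever
#' `n_control > 0`.
#'
#' @param spec A [mortality_sim_spec()].
#' @param strain,stage,insecticide,synergist Label columns carried through to
#'   downstream summaries.
#' @param unit Concentration unit tag.
#' @return A `conc_mort_table`: a data frame with columns `concentration`,
#'   `n_exposed`, `n_dead`, `strain`, `stage`, `insecticide`, `synergist`
#'   and a `unit` attribute.
#' @export
simulate_mortality <- function(spec, strain = "strain", stage = "larvae",
                               insecticide = "insecticide",
                               synergist = "none",
                               unit = "ug a.i./mL") {
  stopifnot(inherits(spec, "mortality_sim_spec"))
  set.seed(spec$seed)
  alpha <- -spec$true_slope * log10(spec$true_lc50)
  p_trt <- spec$control_mortality + (1 - spec$control_mortality) *
    pnorm(alpha + spec$true_slope * log10(spec$concentrations))
  conc <- spec$concentrations
  n <- rep(spec$n_per_conc, length(conc))
  p <- p_trt
  if (spec$n_control > 0) {
    conc <- c(0, conc)
    n <- c(spec$n_control, n)
    p <- c(spec$control_mortality, p)
  }
  dead <- rbinom(length(n), n, p)
  out <- data.frame(concentration = conc, n_exposed = n, n_dead = dead,
                    strain = strain, stage = stage,
                    insecticide = insecticide, synergist = synergist,
                    stringsAsFactors = FALSE)
  attr(out, "unit") <- unit
  class(out) <- c("conc_mort_table", "data.frame")
  out
}
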