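#' Probit recovery study on the adult susceptible deltamethrin design
#'
#' Simulates replicate bioassays under the published design for the adult
#' susceptible strain challenged with deltamethrin (true slope 5.3, true
#' LC50 7.6e-6 ug a.i./cm2, five log-spaced concentrations spanning 5-95%
#' mortality, ~134 mosquitoes per concentration for a total n of ~670) and
#' refits each with [fit_probit()].
#'
#' @param seed Integer seed.
#' @param n_reps Number of replicate bioassays.
#' @param true_lc50,true_slope True dose-response parameters.
#' @param n_per_conc Individuals per concentration.
#' @return List with `mean_lc50`, `mean_slope`, `true_lc50`, `true_slope`,
#'   per-replicate vectors `lc50` and `slope`, and `n_total`.
#' @export
probit_recovery_study <- function(seed, n_reps = 200, true_lc50 = 7.6e-6,
                                  true_slope = 5.3, n_per_conc = 134L) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 1, n_reps)
  conc <- design_concentrations(true_lc50, true_slope)
  lc50 <- slope <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    spec <- mortality_sim_spec(true_lc50, true_slope, conc,
                               n_per_conc = n_per_conc, n_control = 0,
                               seed = seeds[i])
    fit <- fit_probit(simulate_mortality(spec))
    lc50[i] <- fit$lc50
    slope[i] <- fit$beta
  }
  list(mean_lc50 = mean(lc50), mean_slope = mean(slope),
       true_lc50 = true_lc50, true_slope = true_slope,
       lc50 = lc50, slope = slope,
       n_total = length(conc) * n_per_conc, n_reps = n_reps)
}

#' Two-variant sensitivity fold-shift study
#'
#' Simulates the full voltage-clamp pipeline for a reference channel and a
#' resistant variant whose true EC50 is `true_fold` times larger: tail
#' currents under the 100-pulse protocol at `n_conc` log-spaced
#' concentrations (spanning 1.5 decades either side of each variant's EC50,
#' as a dose-response experiment would be designed), `n_oocytes` noisy
#' traces per concentration, per-trace M extraction, per-variant Hill fits
#' and the EC50 fold shift.
#'
#' @param seed Integer seed.
#' @param ec50_reference True EC50 of the reference channel (uM).
#' @param true_fold True EC50 ratio of variant over reference.
#' @param m_max Plateau modified percentage.
#' @param hill True Hill slope.
#' @param n_conc Concentrations per variant.
#' @param n_oocytes Oocytes per concentration.
#' @param noise_frac Trace noise as a fraction of the M plateau (see
#'   [noise_sd_for_m()]).
#' @return List with `fold` (a `sensitivity_shift`), the per-variant
#'   `hill_fit`s and M tables, and `true_fold`.
#' @export
fold_shift_study <- function(seed, ec50_reference = 1, true_fold = 10,
                             m_max = 70, hill = 1, n_conc = 6,
                             n_oocytes = 5, noise_frac = 0.02) {
  protocol <- voltage_protocol()
  run_variant <- function(ec50, sub_seed, label) {
    spec <- channel_sim_spec(m_max = m_max, ec50_true = ec50,
                             hill_true = hill, seed = sub_seed)
    spec$noise_sd <- noise_sd_for_m(spec, protocol, frac = noise_frac)
    conc <- 10^seq(log10(ec50) - 1.5, log10(ec50) + 1.5,
                   length.out = n_conc)
    ex <- simulate_vc_experiment(spec, conc, n_oocytes = n_oocytes,
                                 protocol = protocol, variant = label)
    mt <- extract_m_table(ex)
    list(m_table = mt, fit = fit_hill(mt$concentration, mt$m))
  }
  set.seed(seed)
  sub <- sample.int(2^31 - 1, 2)
  ref <- run_variant(ec50_reference, sub[1], "reference")
  var <- run_variant(ec50_reference * true_fold, sub[2], "variant")
  list(fold = sensitivity_shift(var$fit, ref$fit),
       fit_reference = ref$fit, fit_variant = var$fit,
       m_reference = ref$m_table, m_variant = var$m_table,
       true_fold = true_fold)
}
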