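#' Voltage-clamp pulse-train protocol
#'
#' The standard tail-current protocol: a train of brief step depolarizations
#' from a hyperpolarized holding potential, with equal interpulse intervals
#' at the holding potential. Defaults match the 100-pulse train of 5-ms steps
#' from -120 to 0 mV with 5-ms interpulse intervals used for
#' pyrethroid-modification assays.
#'
#' @param v_hold Holding/repolarization potential (mV).
#' @param v_step Step (test) potential (mV).
#' @param n_pulses Number of pulses (>= 1).
#' @param pulse_ms,inter_ms Pulse and interpulse durations (ms, > 0).
#' @return A `voltage_protocol`.
#' @export
voltage_protocol <- function(v_hold = -120, v_step = 0, n_pulses = 100,
                             pulse_ms = 5, inter_ms = 5) {
  stopifnot(pulse_ms > 0, inter_ms > 0, n_pulses >= 1)
  structure(list(v_hold = v_hold, v_step = v_step,
                 n_pulses = as.integer(n_pulses),
                 pulse_ms = pulse_ms, inter_ms = inter_ms),
            class = "voltage_protocol")
}

#' Default sodium-channel gating parameters
#'
#' An m3h gating scheme with Boltzmann steady states and voltage-dependent
#' time constants: activation `m` has a bell-shaped tau (fast everywhere,
#' ~0.12 ms deactivation at -120 mV); inactivation `h` has a logistic tau
#' that is slow at depolarized potentials (~25 ms at 0 mV) and fast at the
#' holding potential (~0.4 ms), so recovery is complete within each 5-ms
#' interpulse interval and the first-pulse peak conductance is dominated by
#' activation rather than inactivation. That choice keeps the extracted M
#' nearly proportional to the planted modified fraction, so a Hill curve
#' planted in the modified fraction is recovered as a Hill curve in M. Only
#' the tail-to-peak conductance ratio matters for the M statistic, so the
#' parameter set is a documented convention, not a fitted model of any
#' particular channel.
#'
#' @return Named list of gating parameters (mV and ms).
#' @export
default_gating <- function() {
  list(m_vhalf = -30, m_k = 7,
       m_tau_base = 0.1, m_tau_amp = 0.3, m_tau_vmid = -30, m_tau_width = 25,
       h_vhalf = -55, h_k = 6,
       h_tau_base = 0.4, h_tau_amp = 24.6, h_tau_vmid = -45, h_tau_width = 8)
}

gating_at <- function(v, g) {
  list(
    m_inf = 1 / (1 + exp(-(v - g$m_vhalf) / g$m_k)),
    tau_m = g$m_tau_base + g$m_tau_amp / cosh((v - g$m_tau_vmid) /
                                                g$m_tau_width),
    h_inf = 1 / (1 + exp((v - g$h_vhalf) / g$h_k)),
    tau_h = g$h_tau_base + g$h_tau_amp /
      (1 + exp(-(v - g$h_tau_vmid) / g$h_tau_width)))
}

#' Specification of a simulated channel/oocyte experiment
#'
#' Parameters of the deterministic conductance model plus the planted
#' concentration dependence of pyrethroid modification. Unmodified channels
#' gate as m3h (see [default_gating()]); a fraction of channels modified by
#' pyrethroid loses inactivation, activates normally, and deactivates with
#' the slow time constant `tau_slow`, producing the diagnostic tail current
#' after the final repolarization. The modified fraction at concentration c
#' is the Hill curve `(m_max/100) * c^h / (c^h + ec50_true^h)`.
#'
#' @param g_max Maximal conductance (uS).
#' @param e_na Sodium reversal potential (mV).
#' @param gating Gating parameter list, see [default_gating()].
#' @param tau_slow Slow deactivation time constant of modified channels (ms);
#'   must be much larger than the unmodified deactivation tau at the holding
#'   potential.
#' @param m_max Plateau modified percentage (0 < m_max <= 100).
#' @param ec50_true True EC50 of the modification curve (uM).
#' @param hill_true True Hill slope.
#' @param noise_sd Additive Gaussian current noise sd (uA); see
#'   [noise_sd_for_m()] to express it as a fraction of the M plateau.
#' @param sample_interval Sampling interval (ms, <= 0.1).
#' @param seed Integer seed.
#' @return A `channel_sim_spec`.
#' @export
channel_sim_spec <- function(g_max = 0.15, e_na = 50, gating = default_gating(),
                             tau_slow = 50, m_max = 70, ec50_true = 1,
                             hill_true = 1, noise_sd = 0,
                             sample_interval = 0.05, seed = 1L) {
  stopifnot(g_max > 0, tau_slow > 0, ec50_true > 0, hill_true > 0,
            noise_sd >= 0)
  if (m_max <= 0 || m_max > 100) stop("`m_max` must lie in (0, 100]")
  if (sample_interval > 0.1)
    stop("`sample_interval` must be <= 0.1 ms to resolve fast gating")
  tau_deact <- gating_at(-120, gating)$tau_m
  if (tau_slow < 20 * tau_deact)
    stop("`tau_slow` must be much larger than the unmodified deactivation ",
         "time constant (", signif(tau_deact, 3), " ms at -120 mV)")
  structure(list(g_max = g_max, e_na = e_na, gating = gating,
                 tau_slow = tau_slow, m_max = m_max, ec50_true = ec50_true,
                 hill_true = hill_true, noise_sd = noise_sd,
                 sample_interval = sample_interval, seed = as.integer(seed)),
            class = "channel_sim_spec")
}

protocol_epochs <- function(protocol, pre_ms, tail_ms) {
  v <- c(protocol$v_hold,
         rep(c(protocol$v_step, protocol$v_hold), protocol$n_pulses))
  dur <- c(pre_ms,
           rep(c(protocol$pulse_ms, protocol$inter_ms), protocol$n_pulses))
  dur[length(dur)] <- dur[length(dur)] + tail_ms
  data.frame(v = v, dur = dur)
}

# relax a state exponentially toward its target; returns values at times tt
relax <- function(x0, x_inf, tau, tt) x_inf + (x0 - x_inf) * exp(-tt / tau)

#' Simulate a voltage-clamp current trace
#'
#' Deterministic piecewise-exponential evaluation of the gating model over
#' the protocol epochs (the gating ODEs are linear at constant voltage, so
#' states relax exactly as single exponentials within each epoch — no
#' numerical integrator is involved). Unmodified channels contribute
#' `(1 - f) * m^3 * h`; modified channels contribute `f * m_mod^3` where
#' `m_mod` activates with the normal fast time constant but deactivates with
#' `tau_slow`. Gaussian noise of sd `noise_sd` is added to the sampled
#' current. Alongside the trace, the expected M statistic is computed in
#' closed form from the same model: maximal tail conductance after the
#' capacitive blanking window divided by the first-pulse peak conductance,
#' times 100.
#'
#' @param protocol A [voltage_protocol()]; durations must be integer
#'   multiples of the sample interval.
#' @param spec A [channel_sim_spec()].
#' @param modified_fraction Fraction of channels modified, in `[0, 1]`.
#' @param pre_ms Pre-pulse holding period recorded before pulse 1 (baseline
#'   window).
#' @param tail_ms Extra recording appended to the final repolarization (the
#'   tail window).
#' @param blank_ms Capacitive blanking window used in the expected-M closed
#'   form (matches the extraction default).
#' @param seed Noise seed; defaults to the spec seed.
#' @return A list with `trace` (a `current_trace`: `time`, `current`,
#'   `sample_interval`, `protocol`, `pre_ms`, `tail_ms`, `meta`) and
#'   `expected_m` (percentage).
#' @export
simulate_trace <- function(protocol, spec, modified_fraction,
                           pre_ms = 5, tail_ms = 25, blank_ms = 0.3,
                           seed = spec$seed, meta = list()) {
  stopifnot(inherits(protocol, "voltage_protocol"),
            inherits(spec, "channel_sim_spec"))
  if (modified_fraction < 0 || modified_fraction > 1)
    stop("`modified_fraction` must lie in [0, 1]")
  dt <- spec$sample_interval
  durs <- c(pre_ms, protocol$pulse_ms, protocol$inter_ms, tail_ms)
  if (any(abs(durs / dt - round(durs / dt)) > 1e-8))
    stop("protocol durations are not integer multiples of the sample ",
         "interval (", dt, " ms)")
  ep <- protocol_epochs(protocol, pre_ms, tail_ms)
  f <- modified_fraction
  g <- spec$gating
  hold <- gating_at(protocol$v_hold, g)
  # start from steady state at the holding potential
  m_u <- hold$m_inf; h_u <- hold$h_inf; m_md <- hold$m_inf
  cur <- vector("list", nrow(ep))
  for (i in seq_len(nrow(ep))) {
    gv <- gating_at(ep$v[i], g)
    n_i <- round(ep$dur[i] / dt)
    tt <- dt * seq_len(n_i)
    mu_t <- relax(m_u, gv$m_inf, gv$tau_m, tt)
    hu_t <- relax(h_u, gv$h_inf, gv$tau_h, tt)
    tau_md <- if (gv$m_inf >= m_md) gv$tau_m else spec$tau_slow
    md_t <- relax(m_md, gv$m_inf, tau_md, tt)
    cur[[i]] <- spec$g_max * (ep$v[i] - spec$e_na) *
      ((1 - f) * mu_t^3 * hu_t + f * md_t^3)
    m_u <- mu_t[n_i]; h_u <- hu_t[n_i]; m_md <- md_t[n_i]
  }
  current <- c(0, unlist(cur))  # sample at t = 0 included
  # t = 0 current from the initial steady state
  current[1] <- spec$g_max * (protocol$v_hold - spec$e_na) *
    ((1 - f) * hold$m_inf^3 * hold$h_inf + f * hold$m_inf^3)
  if (spec$noise_sd > 0) {
    set.seed(seed)
    current <- current + rnorm(length(current), 0, spec$noise_sd)
  }
  trace <- structure(
    list(time = dt * (seq_along(current) - 1), current = current,
         sample_interval = dt, protocol = protocol, pre_ms = pre_ms,
         tail_ms = tail_ms, meta = meta),
    class = "current_trace")
  list(trace = trace,
       expected_m = expected_m(protocol, spec, f, pre_ms = pre_ms,
                               tail_ms = tail_ms, blank_ms = blank_ms))
}

#' Closed-form expected M of the generator model
#'
#' Evolves the gating states analytically epoch by epoch (end-of-epoch
#' values only), evaluates the first-pulse conductance on a fine grid to
#' locate the peak, and takes the tail conductance at the blanking edge
#' (the tail decays monotonically, so its maximum after blanking sits at the
#' window start). `expected_M = 100 * g_tail / g_peak`. This is the oracle
#' the trace-extraction pipeline is checked against; it shares the model but
#' none of the extraction code.
#'
#' @inheritParams simulate_trace
#' @return Expected M (percentage).
#' @export
expected_m <- function(protocol, spec, modified_fraction, pre_ms = 5,
                       tail_ms = 25, blank_ms = 0.3) {
  f <- modified_fraction
  g <- spec$gating
  hold <- gating_at(protocol$v_hold, g)
  step <- gating_at(protocol$v_step, g)
  m_u <- hold$m_inf; h_u <- hold$h_inf; m_md <- hold$m_inf
  # first-pulse peak conductance on a fine grid
  ttf <- seq(0, protocol$pulse_ms, by = spec$sample_interval / 10)
  mu_t <- relax(m_u, step$m_inf, step$tau_m, ttf)
  hu_t <- relax(h_u, step$h_inf, step$tau_h, ttf)
  md_t <- relax(m_md, step$m_inf, step$tau_m, ttf)
  g_peak <- max((1 - f) * mu_t^3 * hu_t + f * md_t^3)
  # state recursion over the pulse train
  for (i in seq_len(protocol$n_pulses)) {
    m_u <- relax(m_u, step$m_inf, step$tau_m, protocol$pulse_ms)
    h_u <- relax(h_u, step$h_inf, step$tau_h, protocol$pulse_ms)
    m_md <- relax(m_md, step$m_inf, step$tau_m, protocol$pulse_ms)
    if (i < protocol$n_pulses) {
      m_u <- relax(m_u, hold$m_inf, hold$tau_m, protocol$inter_ms)
      h_u <- relax(h_u, hold$h_inf, hold$tau_h, protocol$inter_ms)
      m_md <- relax(m_md, hold$m_inf, spec$tau_slow, protocol$inter_ms)
    }
  }
  # tail conductance at the blanking edge of the final repolarization
  mu_b <- relax(m_u, hold$m_inf, hold$tau_m, blank_ms)
  hu_b <- relax(h_u, hold$h_inf, hold$tau_h, blank_ms)
  md_b <- relax(m_md, hold$m_inf, spec$tau_slow, blank_ms)
  g_tail <- (1 - f) * mu_b^3 * hu_b + f * md_b^3
  100 * g_tail / g_peak
}

#' Trace noise sd matching a target M-scale noise level
#'
#' Maps a noise level expressed as a fraction of the M plateau into current
#' units through the M formula: an error `dI` in the tail amplitude perturbs
#' M by `100 * dI / (E_h - E_Na) * (E_t - E_Na) / I_Na`. Using a noiseless
#' reference peak current, the trace-level sd producing an M-scale sd of
#' `frac * m_max` is `frac * (m_max/100) * |I_Na * (E_h - E_Na)/(E_t - E_Na)|`.
#'
#' @param spec A [channel_sim_spec()].
#' @param protocol A [voltage_protocol()].
#' @param frac Target noise sd as a fraction of the plateau `m_max`.
#' @return Current noise sd (uA).
#' @export
noise_sd_for_m <- function(spec, protocol = voltage_protocol(), frac = 0.02) {
  ref <- spec
  ref$noise_sd <- 0
  tr <- simulate_trace(protocol, ref, modified_fraction = 0)$trace
  i_na <- peak_current(tr)
  frac * (spec$m_max / 100) *
    abs(i_na * (protocol$v_hold - spec$e_na) / (protocol$v_step - spec$e_na))
}

#' Simulate a full voltage-clamp dose-response experiment
#'
#' For each concentration the planted modified fraction is
#' `(m_max/100) * c^h / (c^h + ec50_true^h)`; `n_oocytes` independent noisy
#' traces are generated per concentration, each with its expected M.
#'
#' @param spec A [channel_sim_spec()].
#' @param concentrations Positive concentrations (uM).
#' @param n_oocytes Oocytes (independent traces) per concentration.
#' @param protocol A [voltage_protocol()].
#' @param variant Label carried in each trace's metadata.
#' @return A `vc_experiment`: list with `records` (per-trace list of
#'   `concentration`, `oocyte`, `trace`, `expected_m`, `modified_fraction`)
#'   and the generating `spec`/`protocol`.
#' @export
simulate_vc_experiment <- function(spec, concentrations, n_oocytes = 5,
                                   protocol = voltage_protocol(),
                                   variant = "variant") {
  if (length(concentrations) == 0) stop("empty concentration list")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  fr <- (spec$m_max / 100) * concentrations^spec$hill_true /
    (concentrations^spec$hill_true + spec$ec50_true^spec$hill_true)
  set.seed(spec$seed)
  seeds <- sample.int(2^31 - 1, length(concentrations) * n_oocytes)
  records <- list()
  idx <- 0
  for (i in seq_along(concentrations)) {
    for (j in seq_len(n_oocytes)) {
      idx <- idx + 1
      sim <- simulate_trace(protocol, spec, fr[i], seed = seeds[idx],
                            meta = list(oocyte = j, variant = variant,
                                        concentration = concentrations[i]))
      records[[idx]] <- list(concentration = concentrations[i], oocyte = j,
                             trace = sim$trace, expected_m = sim$expected_m,
                             modified_fraction = fr[i])
    }
  }
  structure(list(records = records, spec = spec, protocol = protocol,
                 variant = variant),
            class = "vc_experiment")
}
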