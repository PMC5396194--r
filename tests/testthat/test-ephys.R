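test_that("the M formula reproduces direct arithmetic and its edge cases", {
  # direct arithmetic: (2/-170)/(10/-50)*100
  expect_equal(percent_modified(2, 10, e_h = -120, e_na = 50, e_t = 0),
               100 * (2 / -170) / (10 / -50), tolerance = 1e-12)
  expect_equal(percent_modified(2, 10, -120, 50, 0), 5.882353,
               tolerance = 1e-6)
  # equal tail and peak conductances -> 100%
  expect_equal(percent_modified(17, 5, -120, 50, 0) *
                 ((5 / -50) / (17 / -170)), 100)
  expect_equal(percent_modified(3.4, 1, -120, 50, 0), 100)
  expect_equal(percent_modified(0, 10, -120, 50, 0), 0)
  expect_error(percent_modified(1, 10, 50, 50, 0), "e_h")
  expect_error(percent_modified(1, 10, -120, 50, 50), "e_t")
  expect_error(percent_modified(1, 0, -120, 50, 0), "i_na")
})

test_that("reversal potential interpolates the zero crossing", {
  expect_equal(reversal_potential(list(potential = c(40, 60),
                                       current = c(-1, 1))), 50)
  expect_equal(reversal_potential(list(potential = c(30, 45, 60),
                                       current = c(-2, 0, 1))), 45)
  # ohmic IV with known reversal is recovered exactly
  v <- seq(-40, 80, by = 20)
  expect_equal(reversal_potential(list(potential = v,
                                       current = 0.2 * (v - 52))), 52)
  expect_warning(
    out <- reversal_potential(list(potential = c(0, 20), current = c(1, 2))),
    "sign")
  expect_true(is.na(out))
  expect_error(reversal_potential(list(potential = c(20, 0),
                                       current = c(1, -1))), "increasing")
})

test_that("trace generation is deterministic and validates its inputs", {
  spec <- channel_sim_spec(noise_sd = 0.3, seed = 12)
  pr <- short_protocol()
  a <- simulate_trace(pr, spec, 0.4)
  b <- simulate_trace(pr, spec, 0.4)
  expect_identical(a$trace$current, b$trace$current)
  expect_error(simulate_trace(pr, spec, 1.2), "modified_fraction")
  expect_error(simulate_trace(voltage_protocol(pulse_ms = 5.013), spec, 0.4),
               "sample")
  expect_error(channel_sim_spec(sample_interval = 0.5), "sample_interval")
  expect_error(channel_sim_spec(tau_slow = 0.5), "tau_slow")
})

test_that("without modified channels the tail vanishes and M is 0", {
  spec <- channel_sim_spec(noise_sd = 0)
  sim <- simulate_trace(short_protocol(), spec, 0)
  expect_lt(percent_modified_trace(sim$trace, e_na = spec$e_na), 0.1)
  expect_lt(sim$expected_m, 0.1)
})

test_that("peak and tail extraction match the generator closed form", {
  spec <- channel_sim_spec(noise_sd = 0)
  pr <- voltage_protocol()  # full 100-pulse protocol
  for (f in c(0.1, 0.5, 0.9)) {
    sim <- simulate_trace(pr, spec, f)
    m <- percent_modified_trace(sim$trace, e_na = spec$e_na)
    expect_equal(m, sim$expected_m, tolerance = 0.01)
  }
})

test_that("expected M increases strictly with the modified fraction", {
  spec <- channel_sim_spec(noise_sd = 0)
  pr <- voltage_protocol()
  em <- vapply(seq(0, 1, by = 0.1),
               function(f) expected_m(pr, spec, f), numeric(1))
  expect_true(!is.unsorted(em, strictly = TRUE))
})

test_that("tail amplitude is monotone in the modified fraction (noiseless)", {
  spec <- channel_sim_spec(noise_sd = 0)
  pr <- short_protocol()
  tails <- vapply(c(0.2, 0.5, 0.8), function(f)
    tail_amplitude(simulate_trace(pr, spec, f)$trace), numeric(1))
  expect_true(!is.unsorted(tails, strictly = TRUE))
})

test_that("M is invariant to uniform trace scaling and baseline offsets", {
  spec <- channel_sim_spec(noise_sd = 0)
  sim <- simulate_trace(short_protocol(), spec, 0.5)
  m0 <- percent_modified_trace(sim$trace, e_na = spec$e_na)
  scaled <- sim$trace
  scaled$current <- scaled$current * 3.7
  expect_equal(percent_modified_trace(scaled, e_na = spec$e_na), m0,
               tolerance = 1e-9)
  offset <- sim$trace
  offset$current <- offset$current + 0.8
  expect_equal(peak_current(offset), peak_current(sim$trace),
               tolerance = 1e-9)
  expect_equal(percent_modified_trace(offset, e_na = spec$e_na), m0,
               tolerance = 1e-9)
})

test_that("a flat trace is flagged and short tail windows are rejected", {
  spec <- channel_sim_spec(noise_sd = 0.05)
  sim <- simulate_trace(short_protocol(), spec, 0)
  flat <- sim$trace
  set.seed(8)
  flat$current <- rnorm(length(flat$current), 0, 0.05)
  expect_warning(out <- peak_current(flat), "flat")
  expect_true(is.na(out))
  # a brief interpulse plus a clipped tail leaves less than the blanking
  sim2 <- simulate_trace(voltage_protocol(n_pulses = 2, inter_ms = 0.1),
                         channel_sim_spec(), 0.3, tail_ms = 0.15)
  expect_error(tail_amplitude(sim2$trace, blank_ms = 0.3), "blanking")
})

test_that("the Hill midpoint and plateau behave as planted", {
  spec <- channel_sim_spec(ec50_true = 0.8, m_max = 70, noise_sd = 0)
  ex <- simulate_vc_experiment(spec, c(0.8), n_oocytes = 1,
                               protocol = voltage_protocol())
  # at c = EC50 the planted modified fraction is exactly m_max/200
  expect_equal(ex$records[[1]]$modified_fraction, 0.35)
  expect_equal(ex$records[[1]]$expected_m, 35, tolerance = 0.05)
  ex_hi <- simulate_vc_experiment(spec, 0.8 * 1e5, n_oocytes = 1)
  expect_equal(ex_hi$records[[1]]$expected_m, 70, tolerance = 0.05)
  expect_error(simulate_vc_experiment(spec, numeric(0), 2), "empty")
  expect_error(simulate_vc_experiment(spec, c(-1, 2), 2), "positive")
})

test_that("exact Hill data are recovered to numerical precision", {
  conc <- 10^seq(-2, 2, length.out = 9)
  m <- 62 * conc^1.3 / (conc^1.3 + 0.7^1.3)
  fit <- fit_hill(conc, m)
  expect_equal(fit$ec50, 0.7, tolerance = 1e-6)
  expect_equal(fit$hill, 1.3, tolerance = 1e-6)
  expect_equal(fit$m_max, 62, tolerance = 1e-6)
  expect_error(fit_hill(c(1, 1, 2), c(1, 1, 2)), "distinct")
})

test_that("Hill fits are equivariant under concentration rescaling", {
  set.seed(9)
  conc <- 10^seq(-2, 1, length.out = 7)
  m <- 55 * conc / (conc + 0.3) + rnorm(7, 0, 0.5)
  f1 <- fit_hill(conc, m)
  f2 <- fit_hill(conc * 1000, m)  # e.g. uM -> nM
  expect_equal(f2$ec50, 1000 * f1$ec50, tolerance = 1e-4)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-4)
  expect_equal(f2$m_max, f1$m_max, tolerance = 1e-4)
})

test_that("fold shifts are reciprocal and 1 for identical fits", {
  conc <- 10^seq(-2, 2, length.out = 8)
  fa <- fit_hill(conc, 60 * conc / (conc + 0.5))
  fb <- fit_hill(conc, 60 * conc / (conc + 4))
  expect_equal(sensitivity_shift(fa, fa)$fold, 1, tolerance = 1e-9)
  expect_equal(sensitivity_shift(fa, fb)$fold *
                 sensitivity_shift(fb, fa)$fold, 1, tolerance = 1e-9)
})

test_that("variant comparison delegates to ANOVA with Scheffe contrasts", {
  set.seed(10)
  null_groups <- replicate(4, rnorm(5, 30, 2), simplify = FALSE)
  names(null_groups) <- c("wild_type", "V410L", "F1534C", "double")
  cv <- compare_variants(null_groups)
  expect_equal(cv$anova$df_between, 3L)
  expect_false(any(cv$contrasts$significant))
  shifted <- null_groups
  shifted$V410L <- shifted$V410L - 20  # planted large sensitivity loss
  cv2 <- compare_variants(shifted)
  vs_ref <- cv2$contrasts[
    (cv2$contrasts$group_a == "V410L" | cv2$contrasts$group_b == "V410L"), ]
  expect_true(all(vs_ref$significant))
})
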