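make_table <- function(conc, n, dead) {
  out <- data.frame(concentration = conc, n_exposed = n, n_dead = dead)
  class(out) <- c("conc_mort_table", "data.frame")
  out
}

test_that("Abbott correction rescales by control mortality", {
  tb <- make_table(c(0, 1, 10), c(100, 100, 100), c(0, 30, 80))
  out <- abbott_correct(tb)
  expect_equal(out$n_dead, c(30, 80))  # no-op when control mortality is 0
  tb2 <- make_table(c(0, 1), c(100, 100), c(20, 60))
  out2 <- abbott_correct(tb2)
  expect_equal(out2$n_dead / out2$n_exposed, 0.5)  # (0.6-0.2)/0.8
  expect_error(abbott_correct(make_table(c(0, 1), c(10, 10), c(10, 5))),
               "control mortality is 1")
  expect_error(abbott_correct(make_table(1, 10, 5)), "no control row")
})

test_that("corrected mortality is never negative on random tables", {
  set.seed(41)
  for (i in 1:50) {
    pc <- runif(1, 0, 0.5)
    conc <- sort(10^runif(4, -3, 0))
    p <- runif(4)
    tb <- make_table(c(0, conc), 100,
                     c(rbinom(1, 100, pc), rbinom(4, 100, p)))
    out <- abbott_correct(tb)
    expect_true(all(out$n_dead >= 0))
    expect_true(all(out$n_dead <= out$n_exposed))
  }
})

test_that("a symmetric design puts the LC50 at the middle concentration", {
  tb <- make_table(c(0.1, 1, 10), c(100, 100, 100), c(5, 50, 95))
  fit <- fit_probit(tb)
  expect_equal(fit$lc50, 1, tolerance = 1e-8)
  expect_true(fit$lc50_ci[1] < 1 && fit$lc50_ci[2] > 1)
  expect_equal(fit$df, 1L)
})

test_that("the fitted optimum beats a parameter grid on log-likelihood", {
  spec <- adult_delta_spec(seed = 5)
  tb <- simulate_mortality(spec)
  fit <- fit_probit(tb)
  x <- log10(fit$data$concentration)
  ll <- function(a, b) {
    p <- pnorm(a + b * x)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(fit$data$n_dead * log(p) +
        (fit$data$n_exposed - fit$data$n_dead) * log(1 - p))
  }
  grid <- expand.grid(a = fit$alpha + seq(-2, 2, length.out = 100),
                      b = fit$beta + seq(-1, 1, length.out = 100))
  grid_best <- max(mapply(ll, grid$a, grid$b))
  expect_gte(ll(fit$alpha, fit$beta), grid_best - 1e-6)
})

test_that("degenerate response patterns are flagged, not fitted", {
  sep <- make_table(c(0.1, 1, 10), 50, c(0, 0, 50))
  fit <- fit_probit(sep)
  expect_equal(fit$flag, "separation")
  expect_true(is.na(fit$lc50))
  expect_error(lc_at(fit, 0.5), "flagged")
  ok <- fit_probit(make_table(c(0.1, 1, 10), 100, c(5, 50, 95)))
  expect_error(resistance_ratio(fit, ok), "flagged")
  # decreasing mortality with dose -> negative slope at the optimum
  nonmono <- make_table(c(0.1, 1, 10), 100, c(90, 50, 10))
  expect_equal(fit_probit(nonmono)$flag, "non-monotone")
})

test_that("lc_at inverts the fit and is monotone in the quantile", {
  fit <- fit_probit(make_table(c(0.1, 0.5, 1, 5, 10), 100,
                               c(4, 25, 52, 88, 97)))
  expect_equal(lc_at(fit, 0.5)$dose, fit$lc50)
  doses <- vapply(c(0.1, 0.25, 0.5, 0.75, 0.9),
                  function(p) lc_at(fit, p)$dose, numeric(1))
  expect_true(!is.unsorted(doses, strictly = TRUE))
  expect_error(lc_at(fit, 1.2), "proportion")
  expect_error(lc_at(fit, 0), "proportion")
})

test_that("LC50 and its CI are scale-equivariant; the RR is invariant", {
  spec_r <- adult_delta_spec(seed = 21)
  spec_s <- adult_delta_spec(seed = 22)
  tb_r <- simulate_mortality(spec_r)
  tb_s <- simulate_mortality(spec_s)
  k <- 37.5
  scale_tb <- function(tb) {
    tb$concentration <- tb$concentration * k
    tb
  }
  f1 <- fit_probit(tb_r); f2 <- fit_probit(scale_tb(tb_r))
  expect_equal(f2$lc50, k * f1$lc50, tolerance = 1e-8)
  expect_equal(f2$lc50_ci, k * f1$lc50_ci, tolerance = 1e-8)
  rr1 <- resistance_ratio(f1, fit_probit(tb_s))
  rr2 <- resistance_ratio(f2, fit_probit(scale_tb(tb_s)))
  expect_equal(rr2$rr, rr1$rr, tolerance = 1e-8)
  expect_equal(rr2$ci95, rr1$ci95, tolerance = 1e-8)
})

test_that("probit fitting is consistent on generator output at large n", {
  lc50 <- 5e-4; slope <- 3.2
  spec <- mortality_sim_spec(lc50, slope,
                             design_concentrations(lc50, slope),
                             n_per_conc = 1e5, n_control = 0, seed = 17)
  fit <- fit_probit(simulate_mortality(spec))
  expect_equal(fit$lc50, lc50, tolerance = 0.01)
  expect_equal(fit$beta, slope, tolerance = 0.01)
})

test_that("a strain compared with itself gives RR 1, not significant", {
  spec <- adult_delta_spec(seed = 30)
  fit <- fit_probit(simulate_mortality(spec))
  rr <- resistance_ratio(fit, fit)
  expect_equal(rr$rr, 1)
  expect_false(rr$significant)
})
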