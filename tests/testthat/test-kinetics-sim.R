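test_that("exact closed form matches the mass-action integrator", {
  cases <- list(
    list(rates = rate_constants(1, 0.5), E0 = 2),
    list(rates = rate_constants(8, 0.216), E0 = 4),
    list(rates = rate_constants(0.5, 2.37), E0 = 8)
  )
  for (cs in cases) {
    mix <- mix_config(E0 = cs$E0)   # E0 >= 10 * R0 throughout
    trace <- simulate_association(cs$rates, mix)
    expected <- 0.1 + association_closed_form(cs$rates, mix,
                                              trace$time) / mix$R0
    rel <- max(abs(trace$signal - expected)) / max(expected)
    expect_lt(rel, 1e-4)
  }
})

test_that("pseudo-first-order curve deviates at low effector excess", {
  rates <- rate_constants(1, 0.5)
  mix <- mix_config(E0 = 0.4, duration = 4)   # only 2 x R0
  expect_warning(trace <- simulate_association(rates, mix),
                 "pseudo-first-order")
  pfo <- 0.1 + association_closed_form(rates, mix, trace$time,
                                       exact = FALSE) / mix$R0
  rel <- max(abs(trace$signal - pfo)) / diff(range(trace$signal))
  expect_gt(rel, 0.01)
})

test_that("noiseless association fits recover the expected kobs", {
  rates <- rate_constants(1, 0.5)
  # at the protocol concentrations the fitted rate sits within a couple
  # of percent of the idealised kon*E0 + koff
  trace <- simulate_association(rates, mix_config(E0 = 2))
  fit <- fit_single_exponential(trace, "rising")
  expect_equal(fit$kobs, 2.5, tolerance = 0.02)
  # in the strict pseudo-first-order limit the match becomes exact
  tiny <- mix_config(R0 = 1e-4, E0 = 2)
  fit2 <- fit_single_exponential(simulate_association(rates, tiny),
                                 "rising")
  expect_equal(fit2$kobs, 2.5, tolerance = 1e-3)
})

test_that("zero effector gives a flat baseline trace", {
  trace <- simulate_association(rate_constants(1, 0.5),
                                mix_config(E0 = 0, duration = 1))
  expect_true(all(abs(trace$signal - 0.1) < 1e-12))
})

test_that("species are conserved at every integrator step", {
  rates <- rate_constants(5, 0.1)
  comp <- rate_constants(50, 0.001)
  mix <- mix_config(E0 = 2, C0 = 20)
  trace <- simulate_competition(rates, comp, mix)
  sp <- attr(trace, "species")
  expect_true(all(abs(sp$R + sp$RE + sp$RC - mix$R0) < 1e-8))
  expect_true(all(abs(sp$E + sp$RE - mix$E0) < 1e-8))
  expect_true(all(abs(sp$C + sp$RC - mix$C0) < 1e-8))
})

test_that("displacement decays at koff under displacer excess", {
  rates <- rate_constants(8, 0.216)
  mix <- mix_config(E0 = 0.2, U0 = 10)  # equimolar pre-formed complex
  trace <- simulate_displacement(rates, mix)
  fit <- fit_single_exponential(trace, "falling")
  expect_equal(fit$kobs, 0.216, tolerance = 0.05)
})

test_that("koff of zero gives a flat displacement trace", {
  trace <- simulate_displacement(rate_constants(1, 0),
                                 mix_config(E0 = 0.2, duration = 5))
  expect_lt(diff(range(trace$signal)), 1e-9)
})

test_that("recovered koff approaches truth as displacer excess grows", {
  rates <- rate_constants(8, 0.216)
  errs <- vapply(c(10, 30, 100), function(U0) {
    mix <- mix_config(E0 = 0.2, U0 = U0)
    fit <- fit_single_exponential(simulate_displacement(rates, mix),
                                  "falling")
    abs(fit$kobs - rates$koff)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("insufficient displacer excess warns", {
  expect_warning(
    simulate_displacement(rate_constants(1, 0.5),
                          mix_config(R0 = 2, E0 = 2, U0 = 4,
                                     duration = 5)),
    "excess")
})

test_that("competition with no competitor equals plain association", {
  ratesE <- rate_constants(1.88, 1.73)
  ratesC <- rate_constants(50, 0.001)
  mix0 <- mix_config(E0 = 2, C0 = 0)
  a <- simulate_association(ratesE, mix0)
  b <- simulate_competition(ratesE, ratesC, mix0)
  expect_equal(b$signal, a$signal, tolerance = 1e-10)
})

test_that("competitor kinetics reproduce the qualitative outcome classes", {
  ratesE <- make_kinetics_fixture()$rac1$rates
  mix <- mix_config(E0 = 2, C0 = 20)
  # fast, tight competitor: complete suppression
  fast <- run_competition_experiment(ratesE, rate_constants(50, 0.001),
                                     mix)
  expect_lt(fast$amplitude_ratio, 0.1)
  expect_equal(fast$class, "complete")
  # slow competitor of comparable affinity: no effect on the trace
  slow <- run_competition_experiment(ratesE,
                                     rate_constants(0.005, 0.0135),
                                     mix)
  expect_gt(slow$amplitude_ratio, 0.8)
  expect_equal(slow$class, "not_affected")
  # fast competitor of moderate affinity: partial suppression
  mid <- run_competition_experiment(ratesE, rate_constants(5, 10), mix)
  expect_gt(mid$amplitude_ratio, 0.1)
  expect_lt(mid$amplitude_ratio, 0.8)
  expect_equal(mid$class, "partial")
})

test_that("competition amplitude is monotone in competitor dose and speed", {
  ratesE <- make_kinetics_fixture()$rac1$rates
  rho_c0 <- vapply(c(0, 5, 20, 50), function(C0) {
    run_competition_experiment(ratesE, rate_constants(5, 10),
                               mix_config(E0 = 2, C0 = C0))$amplitude_ratio
  }, numeric(1))
  expect_true(all(diff(rho_c0) <= 1e-9))
  rho_kon <- vapply(c(0.5, 2, 8, 32), function(konC) {
    run_competition_experiment(ratesE, rate_constants(konC, 10),
                               mix_config(E0 = 2, C0 = 20))$amplitude_ratio
  }, numeric(1))
  expect_true(all(diff(rho_kon) <= 1e-9))
})

test_that("GAP reaction rate reflects effector protection", {
  eff <- rate_constants(100, 100)  # rapid equilibrium, Kd = 1
  k_gap <- 0.05
  # no effector: observed rate equals k_gap
  none <- simulate_gap_reaction(eff, k_gap, mix_config(E0 = 0))
  expect_equal(fit_single_exponential(none, "falling")$kobs, k_gap,
               tolerance = 1e-4)
  # at E0 = Kd the rate is halved
  half <- simulate_gap_reaction(eff, k_gap, mix_config(E0 = 1))
  expect_equal(fit_single_exponential(half, "falling")$kobs, k_gap / 2,
               tolerance = 0.1)
  # protection is monotone in effector concentration
  rates_obs <- vapply(c(0, 0.5, 1, 2, 8), function(E0) {
    tr <- simulate_gap_reaction(eff, k_gap, mix_config(E0 = E0))
    fit_single_exponential(tr, "falling")$kobs
  }, numeric(1))
  expect_true(all(diff(rates_obs) < 0))
  # saturating effector approaches the rapid-equilibrium limit
  sat <- simulate_gap_reaction(eff, k_gap, mix_config(E0 = 20))
  expect_equal(fit_single_exponential(sat, "falling")$kobs,
               k_gap * 1 / (1 + 20), tolerance = 0.1)
})

test_that("GEF exchange is blind to a GTP-form-specific effector", {
  k_gef <- 0.2
  none <- simulate_gef_reaction(k_gef)
  expect_equal(fit_single_exponential(none, "falling")$kobs, k_gef,
               tolerance = 1e-6)
  eff <- make_kinetics_fixture()$rac1$rates
  blind <- simulate_gef_reaction(k_gef, effector = eff,
                                 effector_binds_gdp = FALSE,
                                 mix = mix_config(E0 = 2))
  expect_equal(fit_single_exponential(blind, "falling")$kobs, k_gef,
               tolerance = 0.01 * k_gef)
  # a hypothetical GDP-form binder slows the observed exchange
  binder <- simulate_gef_reaction(k_gef, effector = rate_constants(100, 10),
                                  effector_binds_gdp = TRUE,
                                  mix = mix_config(E0 = 2))
  expect_lt(fit_single_exponential(binder, "falling")$kobs, 0.8 * k_gef)
})

test_that("trace noise is seeded and reproducible", {
  rates <- rate_constants(1, 0.5)
  mix <- mix_config(E0 = 2)
  a <- simulate_association(rates, mix, sigma = 0.02, seed = 7)
  b <- simulate_association(rates, mix, sigma = 0.02, seed = 7)
  c <- simulate_association(rates, mix, sigma = 0.02, seed = 8)
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, c$signal))
})
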