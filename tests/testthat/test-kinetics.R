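test_that("partition fractions follow the linear three-phase formula", {
  # no sorbents: everything dissolved
  pf <- partition_fractions(1, tss = 100, dom = 10, kd_solid = 0, kd_dom = 0)
  expect_equal(unlist(pf), c(f_dissolved = 1, f_particulate = 0,
                             f_dom_bound = 0))
  # kd_solid * tss = 1 splits half/half with no DOM binding
  pf <- partition_fractions(1, tss = 100, dom = 10, kd_solid = 0.01,
                            kd_dom = 0)
  expect_equal(pf$f_dissolved, 0.5)
  expect_equal(pf$f_particulate, 0.5)
  # published default coefficients: check against independent arithmetic
  pf <- partition_fractions(1, tss = 100, dom = 10, kd_solid = 0.0002,
                            kd_dom = 0.002)
  denom <- 1 + 0.0002 * 100 + 0.002 * 10
  expect_equal(pf$f_dissolved, 1 / denom)
  expect_equal(pf$f_particulate, 0.02 / denom)
  expect_equal(pf$f_dom_bound, 0.02 / denom)
  expect_equal(pf$f_dissolved + pf$f_particulate + pf$f_dom_bound, 1)
  expect_error(partition_fractions(1, tss = -1, dom = 0, kd_solid = 0,
                                   kd_dom = 0), ">= 0")
})

test_that("Monod rate has the half-saturation identity and ceiling", {
  expect_equal(monod_mu(0.1083, 0, 9.1), 0)
  expect_equal(monod_mu(0.1083, 9.1, 9.1), 0.1083 / 2)
  expect_equal(monod_mu(0.1083, 1e9, 9.1), 0.1083, tolerance = 1e-6)
  s <- seq(0, 50, by = 0.5)
  expect_true(all(diff(monod_mu(0.1083, s, 9.1)) >= 0))
  expect_true(all(monod_mu(0.1083, s, 9.1) <= 0.1083))
})

test_that("antibiotic inhibition is linear to zero at MIC, resistant exempt", {
  expect_equal(antibiotic_inhibition(0, 4, "f"), 1)
  expect_equal(antibiotic_inhibition(4, 4, "f"), 0)
  expect_equal(antibiotic_inhibition(2, 4, "f"), 0.5)
  expect_equal(antibiotic_inhibition(10, 4, "p"), 1)
  expect_equal(antibiotic_inhibition(10, 4, "cp"), 1)
  expect_error(antibiotic_inhibition(1, 0, "f"), "mic")
})

test_that("metal factor is 1 below the threshold and hyperbolic above", {
  expect_equal(metal_growth_factor(0, 3.049), 1)
  expect_equal(metal_growth_factor(3.049, 3.049), 1)
  expect_equal(metal_growth_factor(2 * 3.049, 3.049), 0.5)
  m <- seq(0, 20, by = 0.1)
  expect_true(all(diff(metal_growth_factor(m, 3.049)) <= 0))
})

test_that("fitness costs compose additively and clamp at zero", {
  p <- default_parameters()
  expect_equal(cost_multiplier("f", p), 1)
  expect_equal(cost_multiplier("p", p), 1 - 0.05 - 0.01)
  expect_equal(cost_multiplier("c", p), 1 - 0.02)
  expect_equal(cost_multiplier("cp", p), 0.92)
  p$c_c <- 1.2
  expect_equal(cost_multiplier("cp", p), 0)
})

test_that("effective growth rate composes its factors", {
  p <- default_parameters()
  expect_equal(effective_growth_rate("f", "wc", dom = 0, a_dissolved = 0,
                                     m = 0, p), 0)
  expect_equal(effective_growth_rate("f", "wc", dom = 10, a_dissolved = 4,
                                     m = 0, p), 0)
  mu <- effective_growth_rate("cp", "sed", dom = 9.1, a_dissolved = 10,
                              m = 0, p)
  expect_equal(mu, 0.92 * 0.0108 / 2)
})

test_that("conjugation is frequency-dependent, symmetric and bounded", {
  expect_equal(conjugation_term(0.1, 3, 0), 0)
  expect_equal(conjugation_term(0.1, 0, 3), 0)
  expect_equal(conjugation_term(0.1, 2, 2), 0.1 * 1)
  expect_equal(conjugation_term(0.000045, 3, 1), 0.000045 * 0.75)
  expect_equal(conjugation_term(0.1, 3, 1), conjugation_term(0.1, 1, 3))
  d <- runif(50, 0, 10); r <- runif(50, 0, 10)
  expect_true(all(conjugation_term(0.3, d, r) <= 0.3 * pmin(d, r) + 1e-12))
})

test_that("first-order terms integrate to exponential decay", {
  expect_equal(first_order_term(0.05, 0), 0)
  expect_equal(first_order_term(0.05, 2), 0.1)
  k <- 0.05; dt <- 0.001 / k; c0 <- 3
  c_num <- c0
  for (i in 1:1000) c_num <- c_num + dt * first_order_term(k, -1) * c_num
  expect_equal(c_num, c0 * exp(-k * 1000 * dt), tolerance = 1e-3)
})

test_that("reaction terms vanish on an empty river", {
  sc <- tiny_scenario()
  S <- river_state(sc)
  S[] <- 0
  expect_true(all(reaction_rhs(S, "wc", sc) == 0))
  expect_true(all(reaction_rhs(S, "sed", sc) == 0))
  expect_error(reaction_rhs(S - 1, "wc", sc), "negative")
})

test_that("logistic cap stops growth at carrying capacity, death persists", {
  p <- inert_params(a_death = 0.0006, mu_max_wc = 0.1083)
  sc <- tiny_scenario(parameters = p, n_max_wc = 10)
  S <- river_state(sc)
  S[, "n_f_wc"] <- 10 # N = N_max exactly
  S[, c("n_p_wc", "n_c_wc", "n_cp_wc")] <- 0
  S[, "DOM_wc"] <- 20
  r <- reaction_rhs(S, "wc", sc)
  expect_equal(r[, "n_f"], rep(-0.0006 * 10, sc$n_cells))
  expect_true(all(r[, "DOM"] == 0)) # no realised growth, no consumption
})

test_that("yield bookkeeping: biomass growth equals yield times consumption", {
  p <- inert_params(mu_max_wc = 0.1083, mu_max_sed = 0.0108,
                    eta_metal = 0.01)
  sc <- tiny_scenario(parameters = p)
  S <- river_state(sc)
  S[, "n_f_wc"] <- 0.8; S[, "n_p_wc"] <- 0.3
  S[, "n_c_wc"] <- 0.2; S[, "n_cp_wc"] <- 0.1
  S[, "DOM_wc"] <- 7
  r <- reaction_rhs(S, "wc", sc)
  consumed <- r[, "n_f"] / p$y_f + r[, "n_p"] / p$y_p +
    r[, "n_c"] / p$y_c + r[, "n_cp"] / p$y_cp
  expect_equal(r[, "DOM"], -consumed)
  expect_equal(r[, "M"], -p$eta_metal * consumed)
})

test_that("gene flow moves biomass between pools with zero net creation", {
  # growth, death and hydrolysis off: only conjugation and segregation act
  p <- inert_params(beta_conjugation = 0.02, sa_segregation = 0.004)
  sc <- tiny_scenario(parameters = p)
  S <- river_state(sc)
  S[, "n_f_wc"] <- 1.2; S[, "n_p_wc"] <- 0.4
  S[, "n_c_wc"] <- 0.3; S[, "n_cp_wc"] <- 0.15
  r <- reaction_rhs(S, "wc", sc)
  total <- r[, "n_f"] + r[, "n_p"] + r[, "n_c"] + r[, "n_cp"]
  expect_equal(max(abs(total)), 0) # exact cancellation
  # segregation direction: p feeds f, cp feeds c
  p2 <- inert_params(sa_segregation = 0.004)
  sc2 <- tiny_scenario(parameters = p2)
  r2 <- reaction_rhs(S, "wc", sc2)
  expect_equal(r2[, "n_f"], 0.004 * S[, "n_p_wc"])
  expect_equal(r2[, "n_c"], 0.004 * S[, "n_cp_wc"])
})

test_that("growth rate responds monotonically to substrate and stressors", {
  p <- default_parameters()
  dom <- seq(0, 30, by = 0.5)
  expect_true(all(diff(effective_growth_rate("f", "wc", dom, 0, 0, p)) >= 0))
  a <- seq(0, 4, by = 0.1)
  expect_true(all(diff(effective_growth_rate("f", "wc", 10, a, 0, p)) <= 0))
  m <- seq(3.1, 30, by = 0.5)
  expect_true(all(diff(effective_growth_rate("p", "wc", 10, 0, m, p)) <= 0))
})

test_that("all rate constants zero silences every reaction", {
  p <- inert_params()
  sc <- tiny_scenario(parameters = p)
  S <- river_state(sc) # fully loaded water column
  expect_true(all(reaction_rhs(S, "wc", sc) == 0))
  expect_true(all(reaction_rhs(S, "sed", sc) == 0))
})
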