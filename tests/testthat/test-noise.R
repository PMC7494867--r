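test_that("noise draws scale as 1/sqrt(dt) and are reproducible", {
  set.seed(42)
  expect_equal(stats::sd(draw_noise(1, 1e5)), 1, tolerance = 0.02)
  set.seed(42)
  expect_equal(stats::sd(draw_noise(0.25, 1e5)), 2, tolerance = 0.02)
  set.seed(7); a <- draw_noise(0.5, 100)
  set.seed(7); b <- draw_noise(0.5, 100)
  expect_identical(a, b)
  expect_error(draw_noise(0), "dt")
  expect_error(draw_noise(-1), "dt")
})

test_that("stochastic increments carry the Poisson variance", {
  expect_equal(stochastic_increment(0, 1, xi = 5), 0)
  expect_equal(stochastic_increment(-3, 1, xi = 5), 0) # clamped rate
  set.seed(1)
  inc <- stochastic_increment(rep(4, 1e5), 1)
  expect_equal(stats::var(inc), 4, tolerance = 0.05)
  # integrated variance is invariant to the step size
  set.seed(2)
  acc <- numeric(2e4)
  for (i in 1:100) acc <- acc + stochastic_increment(rep(4, 2e4), 0.01)
  expect_equal(stats::var(acc), 4 * 1, tolerance = 0.05)
})

test_that("categories activate their documented process sets", {
  expect_length(noise_spec("none")$processes, 0)
  expect_setequal(noise_spec("demographic")$processes,
                  c("death", "conjugation", "segregation", "substrate_use"))
  expect_setequal(noise_spec("environmental")$processes,
                  c("settling_abiotic", "degradation_A_wc"))
  expect_setequal(noise_spec("anthropogenic")$processes,
                  c("boundary_A", "boundary_DOM"))
  expect_setequal(noise_spec("demographic")$parameters,
                  c("a_death", "k_s", "mic", "mu_max_wc", "sa_segregation",
                    "y_f", "beta_conjugation"))
  expect_setequal(noise_spec("environmental")$parameters,
                  c("kd_dom_a", "kd_solid_a", "k_set", "k_xa_wc"))
  expect_error(noise_spec("cosmic"))
  expect_error(noise_spec("demographic", amplitude = -1), "amplitude")
})

test_that("boundary perturbation touches only A and DOM under
           anthropogenic noise", {
  bc <- boundary_conditions(A = 0, DOM = 10)
  set.seed(3)
  out <- perturb_boundary(bc, noise_spec("demographic", 3), dt = 1)
  expect_identical(out, bc)
  set.seed(3)
  out <- perturb_boundary(bc, noise_spec("anthropogenic", 3), dt = 1)
  expect_equal(out[["A"]], 0) # sqrt(0) amplitude
  expect_false(out[["DOM"]] == 10)
  expect_equal(out[["TSS"]], 100)
  # zero-mean: the average perturbed value matches the unperturbed one
  set.seed(4)
  vals <- replicate(1e4, perturb_boundary(
    boundary_conditions(), noise_spec("anthropogenic", 1), dt = 1)[["DOM"]])
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 10), 3 * se + 0.02) # clamp bias at DOM=10 is tiny
})

test_that("assembled stochastic part respects the category wiring", {
  sc <- tiny_scenario()
  st <- river_state(sc)
  st[, "n_p_sed"] <- 0.2; st[, "TSS_sed"] <- 500; st[, "POM_sed"] <- 100

  parts <- assemble_rhs(st, sc, noise = noise_spec("none", 1))
  expect_true(all(parts$stoch == 0))

  set.seed(11)
  parts <- assemble_rhs(st, sc, noise = noise_spec("demographic", 11))
  # degradation and settling noise are not demographic: A and TSS untouched
  expect_true(all(parts$stoch[, c("A_wc", "A_sed", "TSS_wc", "TSS_sed")] == 0))
  expect_false(all(parts$stoch[, "n_f_wc"] == 0))

  set.seed(12)
  parts <- assemble_rhs(st, sc, noise = noise_spec("environmental", 12))
  # biological process noise is not environmental: bacteria untouched
  bact <- c("n_f_wc", "n_p_wc", "n_c_wc", "n_cp_wc",
            "n_f_sed", "n_p_sed", "n_c_sed", "n_cp_sed")
  expect_true(all(parts$stoch[, bact] == 0))
  expect_false(all(parts$stoch[, "A_wc"] == 0))
  expect_false(all(parts$stoch[, "TSS_sed"] == 0))
})

test_that("paired noise draws conserve mass and biomass", {
  sc <- tiny_scenario()
  st <- river_state(sc)
  st[, "n_p_wc"] <- 0.3; st[, "n_cp_wc"] <- 0.1
  st[, "n_p_sed"] <- 0.2; st[, "n_c_sed"] <- 0.4

  # environmental settling pairs: volume-weighted sum is exactly zero
  set.seed(21)
  parts <- assemble_rhs(st, sc, noise = noise_spec("environmental", 21))
  for (v in c("A", "M", "TSS", "POM")) {
    paired <- parts$stoch[, paste0(v, "_wc")] +
      parts$stoch[, paste0(v, "_sed")] / sc$gamma
    # A_wc also carries its own degradation draw; subtract pairs only
    if (v != "A") expect_equal(max(abs(paired)), 0)
  }

  # demographic gene-flow pairs: total biomass noise equals the death and
  # growth-free processes only (conjugation/segregation cancel exactly)
  p <- inert_params(beta_conjugation = 0.05, sa_segregation = 0.01)
  sc2 <- tiny_scenario(parameters = p)
  set.seed(22)
  parts <- assemble_rhs(st, sc2, noise = noise_spec("demographic", 22))
  bact_wc <- parts$stoch[, "n_f_wc"] + parts$stoch[, "n_p_wc"] +
    parts$stoch[, "n_c_wc"] + parts$stoch[, "n_cp_wc"]
  expect_equal(max(abs(bact_wc)), 0) # death rate zero here, so exact
})
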