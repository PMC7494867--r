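test_that("a uniform profile at the boundary value is at rest", {
  prof <- rep(3, 20)
  r <- advection_dispersion(prof, u = 360, d = 3600, dx = 1000,
                            upstream_value = 3)
  expect_equal(max(abs(r)), 0)
})

test_that("pure upwind advection translates a front at speed u", {
  n <- 200; dx <- 10; u <- 50; dt <- 0.1
  prof <- c(rep(1, 50), rep(0, n - 50))
  t_total <- 20 # front should move u * t = 1000 m = 100 cells
  for (i in seq_len(t_total / dt)) {
    prof <- prof + dt * advection_dispersion(prof, u, d = 0, dx,
                                             upstream_value = 1)
  }
  front <- max(which(prof > 0.5))
  expect_lt(abs(front * dx - (500 + u * t_total)), dx * 10)
  expect_true(all(prof >= -1e-12 & prof <= 1 + 1e-12))
})

test_that("dispersion spreads a pulse like the analytic Gaussian", {
  n <- 401; dx <- 5; d <- 100; dt <- 0.1
  x <- (seq_len(n) - 0.5) * dx
  x0 <- x[201]
  sigma0 <- 40
  prof <- exp(-(x - x0)^2 / (2 * sigma0^2))
  m0 <- sum(prof) * dx
  t_total <- 10
  for (i in seq_len(t_total / dt)) {
    prof <- prof + dt * advection_dispersion(prof, u = 0, d = d, dx,
                                             closed = TRUE)
  }
  sigma_t <- sqrt(sigma0^2 + 2 * d * t_total)
  analytic <- sigma0 / sigma_t * exp(-(x - x0)^2 / (2 * sigma_t^2))
  expect_lt(max(abs(prof - analytic)), 5e-3)
  # closed boundaries conserve mass
  expect_equal(sum(prof) * dx, m0, tolerance = 1e-12)
})

test_that("settling and resuspension exchange the published amounts and
           conserve volume-weighted mass", {
  ex <- settling_exchange(100, k_set = 0.02, gamma = 10)
  expect_equal(ex$wc, -2)
  expect_equal(ex$sed, 20)
  expect_equal(ex$wc + ex$sed / 10, 0)
  ex <- settling_exchange(0, 0.02, 10)
  expect_equal(c(ex$wc, ex$sed), c(0, 0))

  ex <- resuspension_exchange(10, k_resus = 0.1, gamma = 10)
  expect_equal(ex$wc, 0.1)
  expect_equal(ex$sed, -1)
  expect_equal(ex$wc + ex$sed / 10, 0)

  # settling balanced by resuspension at the two-box fixed point
  k_set <- 0.02; k_resus <- 0.05; gamma <- 10; c_wc <- 4
  c_sed <- k_set * gamma * c_wc / k_resus
  s <- settling_exchange(c_wc, k_set, gamma)
  r <- resuspension_exchange(c_sed, k_resus, gamma)
  expect_equal(s$wc + r$wc, 0)
  expect_equal(s$sed + r$sed, 0)
})

test_that("diffusive exchange equilibrates porewater with the column", {
  ex <- diffusion_exchange(2, 2 * 0.3, k_diff = 0.000208, h_o = 0.1,
                           porosity = 0.3, gamma = 10)
  expect_equal(c(ex$wc, ex$sed), c(0, 0))
  ex <- diffusion_exchange(0, 1, 0.000208, 0.1, 0.3, 10)
  expect_gt(ex$wc, 0)
  expect_lt(ex$sed, 0)
  expect_equal(ex$wc + ex$sed / 10, 0)
  # two-box integration reaches the porewater equilibrium ratio
  c_wc <- 0; c_sed <- 1; dt <- 1
  for (i in 1:20000) {
    ex <- diffusion_exchange(c_wc, c_sed, 0.000208, 0.1, 0.3, 10)
    c_wc <- c_wc + dt * ex$wc
    c_sed <- c_sed + dt * ex$sed
  }
  expect_equal(c_sed / 0.3, c_wc, tolerance = 1e-6)
})

test_that("transport is silent when every transport constant vanishes", {
  p <- inert_params()
  sc <- river_scenario(reach_length = 10000, n_cells = 10,
                       velocity_u = 1, dispersion_d = 1, dt = 0.5,
                       parameters = p, validate = FALSE)
  sc$velocity_u <- 0; sc$dispersion_d <- 0
  S <- river_state(sc)
  expect_equal(max(abs(transport_rhs(S, sc))), 0)
})

test_that("a conservative tracer conserves volume-weighted mass under
           closed boundaries", {
  p <- default_parameters() # full settling/resuspension/diffusion active
  sc <- tiny_scenario(n_cells = 20, dt = 0.5, parameters = p)
  state <- river_state(sc)
  S <- unclass(state)
  S[, "TSS_wc"] <- 50 + 30 * sin(seq_len(20)) # structured profile
  S[, "A_wc"] <- 0.05; S[, "A_sed"] <- 0.01
  mass <- function(S) sum(S[, 1:9]) + sum(S[, 10:18]) / sc$gamma
  m0 <- mass(S)
  st <- state; st[] <- S
  for (i in 1:1000) {
    det <- transport_rhs(st, sc, closed = TRUE)
    st <- st + sc$dt * det
  }
  expect_lt(abs(mass(unclass(st)) - m0) / m0, 1e-6)
})

test_that("only settling active moves bacteria to the bed gamma-fold", {
  p <- inert_params(k_set = 0.02)
  sc <- river_scenario(reach_length = 5000, n_cells = 5, dt = 0.5,
                       velocity_u = 1e-6, dispersion_d = 1e-6,
                       parameters = p,
                       boundary = boundary_conditions(n_p = 0.5))
  st <- river_state(sc)
  tr <- transport_rhs(st, sc)
  expect_equal(tr[, "n_p_wc"], rep(-0.02 * 0.5, 5), tolerance = 1e-6)
  expect_equal(tr[, "n_p_sed"], rep(0.02 * 10 * 0.5, 5), tolerance = 1e-6)
})
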