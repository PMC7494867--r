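# Shared fixture builders. All fixtures are generated in code.

# parameter set with every first-order/transport rate switched off but the
# structurally required positives (yields, half-saturation, thresholds,
# porosity) kept at their defaults
inert_params <- function(...) {
  p <- default_parameters()
  for (nm in c("k_set", "k_resus", "k_diff", "k_xa_wc", "k_xa_sed",
               "k_h_wc", "k_h_sed", "a_death", "sa_segregation",
               "beta_conjugation", "eta_metal", "mu_max_wc", "mu_max_sed")) {
    p[[nm]] <- 0
  }
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}

# small reach for fast unit tests
tiny_scenario <- function(n_cells = 10, dt = 0.5, t_end = 200, ...) {
  river_scenario(reach_length = n_cells * 1000, n_cells = n_cells,
                 dt = dt, t_end = t_end, ...)
}

# 0-D batch configuration: one cell, negligible through-flow, boundary
# equal to the initial water column so advection exchanges nothing at t = 0
batch_scenario <- function(dt = 1, t_end = 100,
                           parameters = default_parameters(),
                           boundary = boundary_conditions()) {
  river_scenario(reach_length = 1000, n_cells = 1, dt = dt, t_end = t_end,
                 velocity_u = 1e-6, dispersion_d = 1e-6,
                 parameters = parameters, boundary = boundary)
}

# independent explicit-Euler oracle used to cross-check the engine: the
# same update rule written directly against the exported operators
euler_oracle <- function(scenario, n_steps) {
  state <- river_state(scenario)
  for (i in seq_len(n_steps)) {
    det <- transport_rhs(state, scenario) +
      cbind(reaction_rhs(state, "wc", scenario),
            reaction_rhs(state, "sed", scenario))
    S <- unclass(state) + scenario$dt * det
    if (min(S) < 0) S[S < 0] <- 0
    attr(S, "time_h") <- attr(state, "time_h") + scenario$dt
    class(S) <- class(state)
    state <- S
  }
  state
}
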