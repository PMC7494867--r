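#' Advection-dispersion operator on a concentration profile
#'
#' Conservative finite-volume discretisation of
#' \deqn{-u \partial c/\partial x + D \partial^2 c/\partial x^2}
#' with first-order upwind advective fluxes and central-difference
#' dispersive fluxes. With `closed = FALSE` the upstream boundary is a
#' Dirichlet ghost cell at `upstream_value` (advective inflow `u*c_up`,
#' dispersive exchange against the gradient) and the downstream boundary is
#' advective outflow with a zero dispersive gradient. With `closed = TRUE`
#' both edge fluxes vanish and total mass is conserved exactly.
#'
#' @param profile Concentration series over the grid, mg/l.
#' @param u Velocity, m/h (> 0; upwind direction is increasing x).
#' @param d Dispersion coefficient, m2/h (>= 0).
#' @param dx Cell width, m.
#' @param upstream_value Dirichlet boundary concentration, mg/l.
#' @param closed Use zero-flux (closed) boundaries instead.
#' @return Rate series, mg/l/h, same length as `profile`.
#' @export
advection_dispersion <- function(profile, u, d, dx, upstream_value = 0,
                                 closed = FALSE) {
  n <- length(profile)
  if (n < 1) stop("empty profile")
  # fluxes at the n+1 cell edges
  left <- c(upstream_value, profile) # ghost + cells
  f_adv <- u * left[1:n]             # edge i carries upwind cell i-1
  f_adv <- c(f_adv, u * profile[n])  # downstream outflow
  grad <- c(profile[1] - upstream_value, diff(profile), 0) / dx
  f_disp <- -d * grad
  f <- f_adv + f_disp
  if (closed) {
    f[1] <- 0
    f[n + 1] <- 0
  }
  (f[1:n] - f[2:(n + 1)]) / dx
}

#' Settling exchange between water column and sediment
#'
#' The water column loses particulate mass at `k_set * c`; the sediment
#' layer, `gamma` times smaller in volume, gains `k_set * gamma * c`.
#' Volume-weighted mass is conserved exactly.
#'
#' @param c_particulate_wc Particulate concentration in the water column,
#'   mg/l.
#' @param k_set Settling rate constant, 1/h.
#' @param gamma Water-to-sediment volume ratio.
#' @return List with rate components `wc` (loss) and `sed` (gain), mg/l/h.
#' @export
settling_exchange <- function(c_particulate_wc, k_set, gamma) {
  flux <- k_set * c_particulate_wc
  list(wc = -flux, sed = gamma * flux)
}

#' Resuspension exchange between sediment and water column
#'
#' Mirror of [settling_exchange()]: the sediment loses `k_resus * c`, the
#' water column gains `k_resus * c / gamma`.
#'
#' @param c_sed Sediment concentration, mg/l.
#' @param k_resus Resuspension rate constant, 1/h.
#' @param gamma Water-to-sediment volume ratio.
#' @return List with rate components `wc` (gain) and `sed` (loss), mg/l/h.
#' @export
resuspension_exchange <- function(c_sed, k_resus, gamma) {
  flux <- k_resus * c_sed
  list(wc = flux / gamma, sed = -flux)
}

#' Diffusive exchange of a dissolved species across the bed interface
#'
#' Two-film exchange with transfer coefficient `k_diff / h_o` acting on the
#' difference between the sediment porewater concentration
#' (`c_diss_sed / porosity`, converting bulk sediment concentration to
#' porewater) and the water-column concentration. Rates are antisymmetric
#' under the volume convention (sediment rate is `-gamma` times the
#' water-column rate), so volume-weighted mass is conserved exactly.
#'
#' @param c_diss_wc Dissolved concentration in the water column, mg/l.
#' @param c_diss_sed Dissolved concentration in bulk sediment, mg/l.
#' @param k_diff Diffusion mass-transfer constant, m/h.
#' @param h_o Active sediment layer thickness, m.
#' @param porosity Sediment porosity (0, 1].
#' @param gamma Water-to-sediment volume ratio.
#' @return List with rate components `wc` and `sed`, mg/l/h.
#' @export
diffusion_exchange <- function(c_diss_wc, c_diss_sed, k_diff, h_o,
                               porosity, gamma) {
  k <- k_diff / h_o
  delta <- c_diss_sed / porosity - c_diss_wc
  list(wc = k * delta, sed = -gamma * k * delta)
}

# Internal: full transport operator; returns the 18-column rate matrix and
# the per-variable settling flux magnitudes reused by the noise model.
# Hot path: fixed integer column indices, no name lookups.
.transport_terms <- function(S, scenario, bc = scenario$boundary,
                             closed = FALSE) {
  p <- scenario$parameters
  n <- nrow(S)
  u <- scenario$velocity_u; d <- scenario$dispersion_d; dx <- scenario$dx
  gamma <- scenario$gamma
  rates <- matrix(0, n, 18, dimnames = list(NULL, .STATE_COLS))

  # along-river advection + dispersion, water column only (all nine
  # profiles at once; same finite-volume fluxes as advection_dispersion)
  bcv <- if (closed) numeric(9) else as.numeric(bc[state_variables()])
  W <- S[, 1:9, drop = FALSE]
  left <- rbind(bcv, W)                       # upwind cell at each edge
  right <- rbind(W, W[n, , drop = FALSE])     # downstream cell at each edge
  f <- u * left - d * ((right - left) / dx)
  if (closed) {
    f[1, ] <- 0
    f[n + 1, ] <- 0
  }
  rates[, 1:9] <- (f[1:n, , drop = FALSE] - f[2:(n + 1), , drop = FALSE]) / dx

  # particulate / dissolved splits of the sorbing chemicals
  den_a_wc <- 1 + p$kd_solid_a * S[, 3L] + p$kd_dom_a * S[, 5L]
  den_m_wc <- 1 + p$kd_solid_m * S[, 3L] + p$kd_dom_m * S[, 5L]
  den_a_sed <- 1 + p$kd_solid_a * S[, 12L] + p$kd_dom_a * S[, 14L]
  den_m_sed <- 1 + p$kd_solid_m * S[, 12L] + p$kd_dom_m * S[, 14L]
  A_part_wc <- p$kd_solid_a * S[, 3L] / den_a_wc * S[, 1L]
  M_part_wc <- p$kd_solid_m * S[, 3L] / den_m_wc * S[, 2L]
  A_part_sed <- p$kd_solid_a * S[, 12L] / den_a_sed * S[, 10L]
  M_part_sed <- p$kd_solid_m * S[, 12L] / den_m_sed * S[, 11L]
  A_diss_wc <- S[, 1L] / den_a_wc
  M_diss_wc <- S[, 2L] / den_m_wc
  A_diss_sed <- S[, 10L] / den_a_sed
  M_diss_sed <- S[, 11L] / den_m_sed

  # settling: bacteria, TSS and POM settle whole; A and M settle via their
  # particulate fraction (wc columns 1..9 pair with sed columns 10..18)
  k_set <- p$k_set
  settle_conc <- list(A = A_part_wc, M = M_part_wc,
                      TSS = S[, 3L], POM = S[, 4L],
                      n_f = S[, 6L], n_p = S[, 7L],
                      n_c = S[, 8L], n_cp = S[, 9L])
  settle_cols <- c(1L, 2L, 3L, 4L, 6L, 7L, 8L, 9L)
  settle_flux <- vector("list", 8L)
  names(settle_flux) <- names(settle_conc)
  for (k in 1:8) {
    iw <- settle_cols[k]
    flux <- k_set * settle_conc[[k]]
    settle_flux[[k]] <- flux
    rates[, iw] <- rates[, iw] - flux
    rates[, iw + 9L] <- rates[, iw + 9L] + gamma * flux
  }

  # resuspension: mirror, acting on the sediment pools
  k_res <- p$k_resus
  resus_conc <- list(A_part_sed, M_part_sed, S[, 12L], S[, 13L],
                     S[, 15L], S[, 16L], S[, 17L], S[, 18L])
  for (k in 1:8) {
    iw <- settle_cols[k]
    flux <- k_res * resus_conc[[k]]
    rates[, iw] <- rates[, iw] + flux / gamma
    rates[, iw + 9L] <- rates[, iw + 9L] - flux
  }

  # sediment-water diffusion of the dissolved phases (A, M, DOM)
  kd <- p$k_diff / scenario$h_o
  poro <- p$porosity
  diff_wc <- list(A_diss_wc, M_diss_wc, S[, 5L])
  diff_sed <- list(A_diss_sed, M_diss_sed, S[, 14L])
  diff_cols <- c(1L, 2L, 5L)
  for (k in 1:3) {
    iw <- diff_cols[k]
    delta <- diff_sed[[k]] / poro - diff_wc[[k]]
    rates[, iw] <- rates[, iw] + kd * delta
    rates[, iw + 9L] <- rates[, iw + 9L] - gamma * (kd * delta)
  }

  list(rates = rates, settle_flux = settle_flux)
}

#' Full transport operator for a river state
#'
#' Applies along-river advection and dispersion to every water-column
#' variable, settling and resuspension exchange to the particle-associated
#' pools (TSS, POM, all bacteria, and the particulate fractions of
#' antibiotic and metal), and sediment-water diffusive exchange to the
#' dissolved phases (antibiotic, metal, DOM). Sediment pools have no
#' along-river transport: the bed is a stationary well-mixed active layer
#' per cell.
#'
#' @param state A `river_state` matrix.
#' @param scenario A `river_scenario`.
#' @param bc Boundary conditions to apply this step (defaults to the
#'   scenario's; the stochastic engine passes perturbed values here).
#' @param closed Use closed (zero-flux) along-river boundaries, for
#'   conservation tests.
#' @return Matrix (`n_cells` x 18) of transport rates, mg/l/h.
#' @export
transport_rhs <- function(state, scenario, bc = scenario$boundary,
                          closed = FALSE) {
  S <- unclass(state)
  if (any(!is.finite(S))) stop("transport_rhs: non-finite state")
  .transport_terms(S, scenario, bc = bc, closed = closed)$rates
}
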