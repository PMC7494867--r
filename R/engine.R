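#' Explicit-scheme stability check
#'
#' The explicit upwind/central scheme is stable when the time step respects
#' both the advective Courant bound `dt <= dx/u` and the dispersive bound
#' `dt <= dx^2/(2 D)`.
#'
#' @param u Velocity, m/h.
#' @param d Dispersion, m2/h.
#' @param dx Cell width, m.
#' @param dt Time step, h.
#' @return List with `ok` (logical), `dt_max` (binding bound, h), `binding`
#'   (`"advective"` or `"dispersive"`), and both individual bounds.
#' @export
#' @examples
#' cfl_check(u = 360, d = 3600, dx = 1000, dt = 1)
cfl_check <- function(u, d, dx, dt) {
  if (any(c(u, d, dx, dt) <= 0)) stop("cfl_check: arguments must be > 0")
  adv <- dx / u
  disp <- dx^2 / (2 * d)
  dt_max <- min(adv, disp)
  list(ok = dt <= dt_max,
       dt_max = dt_max,
       binding = if (adv <= disp) "advective" else "dispersive",
       advective_bound = adv, dispersive_bound = disp)
}

# Internal: deterministic rates plus (optionally) stochastic increments.
# The deterministic part is computed identically whether or not noise is
# active, so the zero-noise trajectory is bit-identical to a deterministic
# integration.
.assemble <- function(S, scenario, noise = NULL, bc = scenario$boundary) {
  tr <- .transport_terms(S, scenario, bc = bc)
  rwc <- .reaction_terms(S, scenario, "wc")
  rsed <- .reaction_terms(S, scenario, "sed")
  det <- tr$rates + cbind(rwc$rates, rsed$rates)

  active <- !is.null(noise) && length(noise$processes) > 0 &&
    noise$category %in% c("demographic", "environmental")
  if (!active) {
    return(list(det = det, stoch = NULL))
  }

  dt <- scenario$dt
  n <- nrow(S)
  gamma <- scenario$gamma
  stoch <- matrix(0, n, 18, dimnames = list(NULL, .STATE_COLS))
  amp <- if (is.null(noise$amplitude)) 1 else noise$amplitude
  inc <- function(rate) amp * sqrt(pmax(rate, 0) * dt) * stats::rnorm(n)

  if (noise$category == "environmental") {
    # settling of the abiotic pools: shared draw per wc/sed pair
    for (v in c("A", "M", "TSS", "POM")) {
      iw <- .IX[[paste0(v, "_wc")]]
      z <- inc(tr$settle_flux[[v]])
      stoch[, iw] <- stoch[, iw] - z
      stoch[, iw + 9L] <- stoch[, iw + 9L] + gamma * z
    }
    # water-column antibiotic degradation
    stoch[, 1L] <- stoch[, 1L] - inc(rwc$degrade_A)
  }

  if (noise$category == "demographic") {
    reac <- list(wc = rwc, sed = rsed)
    offs <- c(wc = 0L, sed = 9L)
    for (comp in c("wc", "sed")) {
      r <- reac[[comp]]
      off <- offs[[comp]]
      # death of each phenotype, with the POM gain drawn on the summed
      # death rate as its own process
      for (k in 1:4) {
        j <- off + 5L + k # n_f, n_p, n_c, n_cp columns
        stoch[, j] <- stoch[, j] - inc(r$death[[k]])
      }
      stoch[, off + 4L] <- stoch[, off + 4L] + inc(r$death_total)
    }
    for (comp in c("wc", "sed")) {
      r <- reac[[comp]]
      off <- offs[[comp]]
      jf <- off + 6L; jp <- off + 7L; jc <- off + 8L; jcp <- off + 9L
      # conjugation channels: donor-pool loss and recipient-pool gain
      # share one draw, so gene flow creates no biomass
      z <- inc(r$conj$fp); stoch[, jf] <- stoch[, jf] - z
      stoch[, jp] <- stoch[, jp] + z
      z <- inc(r$conj$fcp); stoch[, jf] <- stoch[, jf] - z
      stoch[, jp] <- stoch[, jp] + z
      z <- inc(r$conj$cp_); stoch[, jc] <- stoch[, jc] - z
      stoch[, jcp] <- stoch[, jcp] + z
      z <- inc(r$conj$ccp); stoch[, jc] <- stoch[, jc] - z
      stoch[, jcp] <- stoch[, jcp] + z
      # segregation: p -> f and cp -> c
      z <- inc(r$seg$p)
      stoch[, jp] <- stoch[, jp] - z
      stoch[, jf] <- stoch[, jf] + z
      z <- inc(r$seg$cp)
      stoch[, jcp] <- stoch[, jcp] - z
      stoch[, jc] <- stoch[, jc] + z
      # substrate-linked consumption noise (susceptible yield pathway):
      # DOM and metal each with an independent draw
      stoch[, off + 5L] <- stoch[, off + 5L] - inc(r$cons_f)
      stoch[, off + 2L] <- stoch[, off + 2L] -
        scenario$parameters$eta_metal * inc(r$cons_f)
    }
  }

  list(det = det, stoch = stoch)
}

#' Assemble deterministic rates and stochastic increments for one step
#'
#' The deterministic part is the sum of [transport_rhs()] and the two
#' compartments' [reaction_rhs()]. The stochastic part adds, for every
#' process active under the noise category, an increment
#' `sqrt(process rate) * xi * dt` carrying the sign of that process's
#' deterministic contribution, with an independent draw per process per
#' cell per step (paired exchange and gene-flow terms share their draw;
#' see [noise_spec()]). Category `none` yields a zero stochastic part.
#'
#' @param state A `river_state`.
#' @param scenario A `river_scenario`.
#' @param noise A `noise_spec` or NULL.
#' @param bc Boundary conditions for this step (already perturbed under
#'   anthropogenic noise).
#' @return List with `det` (rates, mg/l/h, `n_cells` x 18) and `stoch`
#'   (increments, mg/l; zero matrix when no process noise is active).
#' @export
assemble_rhs <- function(state, scenario, noise = NULL,
                         bc = scenario$boundary) {
  parts <- .assemble(unclass(state), scenario, noise = noise, bc = bc)
  if (is.null(parts$stoch)) {
    parts$stoch <- matrix(0, nrow(state), 18,
                          dimnames = list(NULL, state_columns()))
  }
  parts
}

#' Advance the state by one Euler-Maruyama step
#'
#' `state + dt * deterministic + stochastic increments`, with anthropogenic
#' boundary perturbation applied before the transport operator, any
#' negative concentration clamped to zero afterwards (clamp events are
#' counted in the `clamp_events` attribute), and the clock advanced by
#' `dt`. With no active noise the update is a pure explicit Euler step.
#'
#' @param state A `river_state`.
#' @param scenario A `river_scenario` whose `dt` passes [cfl_check()].
#' @param noise A `noise_spec` or NULL (deterministic).
#' @return The advanced `river_state`.
#' @export
step_state <- function(state, scenario, noise = NULL) {
  S <- unclass(state)
  dt <- scenario$dt
  bc <- scenario$boundary
  if (!is.null(noise) && noise$category == "anthropogenic") {
    bc <- perturb_boundary(bc, noise, dt)
  }
  parts <- .assemble(S, scenario, noise = noise, bc = bc)
  S_new <- S + dt * parts$det
  if (!is.null(parts$stoch)) S_new <- S_new + parts$stoch
  if (any(!is.finite(S_new))) {
    stop(sprintf("solver blow-up: non-finite state at t = %g h",
                 attr(state, "time_h")))
  }
  clamps <- 0L
  if (min(S_new) < 0) {
    neg <- S_new < 0
    clamps <- sum(neg)
    S_new[neg] <- 0
  }
  attr(S_new, "time_h") <- attr(state, "time_h") + dt
  attr(S_new, "clamp_events") <-
    (if (is.null(attr(state, "clamp_events"))) 0 else
      attr(state, "clamp_events")) + clamps
  class(S_new) <- .RIVER_STATE_CLASS
  S_new
}

#' Steady-state detector
#'
#' Operates on a history of equally spaced state snapshots (rows). The
#' system is declared steady when, over the last `window` intervals, the
#' largest relative rate of change
#' `|c(t+span) - c(t)| / (span * max(|c(t)|, floor))` stays below `tol`
#' for every field. The same criterion applied to windowed means of
#' station series serves stochastic runs, whose instantaneous rates never
#' settle because of the noise floor.
#'
#' @param history Numeric matrix: consecutive snapshots in rows.
#' @param tol Relative drift tolerance, 1/h.
#' @param window Number of consecutive intervals that must pass.
#' @param span_h Time spacing between rows, h.
#' @param floor Concentration floor for the relative normalisation, mg/l.
#' @return TRUE iff at least `window + 1` rows exist and the last `window`
#'   intervals all pass.
#' @export
detect_steady_state <- function(history, tol = 1e-4, window = 4,
                                span_h = 1, floor = 0.01) {
  history <- as.matrix(history)
  if (nrow(history) < window + 1) return(FALSE)
  h <- history[(nrow(history) - window):nrow(history), , drop = FALSE]
  for (i in seq_len(window)) {
    rate <- abs(h[i + 1, ] - h[i, ]) / (span_h * pmax(abs(h[i, ]), floor))
    if (max(rate) >= tol) return(FALSE)
  }
  TRUE
}

#' Integrate a scenario to steady state or to the horizon
#'
#' Runs the Euler-Maruyama (or, without noise, explicit Euler) integration
#' from the scenario's initial state, recording the concentration of every
#' field at the requested stations, until either the steady-state criterion
#' fires (`stop = "steady"`, deterministic drift below `steady_tol` for
#' `steady_window` consecutive checks) or the horizon `t_end` is reached.
#' A "generation" of the stochastic ensemble experiment is one call of this
#' function with its own seed.
#'
#' @param scenario A `river_scenario`.
#' @param noise A `noise_spec` or NULL. The engine seeds R's RNG from
#'   `noise$seed`, so equal seeds give identical trajectories.
#' @param stations_km Station positions, km (default the five reporting
#'   stations 2, 5, 10, 99, 100 km).
#' @param stop `"steady"` (steady state, capped at `t_end`) or `"t_end"`.
#' @param steady_tol,steady_window,check_every Steady-state criterion: see
#'   [detect_steady_state()]; the state is inspected every `check_every`
#'   steps.
#' @param record_every Record station values every this many steps.
#' @return Object of class `river_run`: final state, station series (long
#'   data.frame), clamp-event count, seed, scenario hash, stop reason.
#' @export
run_simulation <- function(scenario, noise = NULL,
                           stations_km = c(2, 5, 10, 99, 100),
                           stop = c("steady", "t_end"),
                           steady_tol = 1e-4, steady_window = 4,
                           check_every = 25, record_every = 24) {
  stop_rule <- match.arg(stop)
  validate_scenario(scenario)
  if (!is.null(noise)) set.seed(noise$seed)
  state <- river_state(scenario)
  dt <- scenario$dt
  n_steps <- ceiling(scenario$t_end / dt - 1e-9)
  cells <- station_cell(scenario, stations_km)
  n_rec <- floor(n_steps / record_every) + 1L
  rec <- array(NA_real_, dim = c(n_rec, length(cells), 18))
  rec_t <- rep(NA_real_, n_rec)
  rec[1, , ] <- unclass(state)[cells, , drop = FALSE]
  rec_t[1] <- 0
  k_rec <- 1L

  snap <- unclass(state)
  passes <- 0L
  steady <- FALSE
  steps_done <- 0L

  for (s in seq_len(n_steps)) {
    state <- step_state(state, scenario, noise)
    steps_done <- s
    if (s %% record_every == 0L) {
      k_rec <- k_rec + 1L
      rec[k_rec, , ] <- unclass(state)[cells, , drop = FALSE]
      rec_t[k_rec] <- attr(state, "time_h")
    }
    if (stop_rule == "steady" && s %% check_every == 0L) {
      cur <- unclass(state)
      span <- check_every * dt
      rate <- abs(cur - snap) / (span * pmax(abs(snap), 0.01))
      if (max(rate) < steady_tol) passes <- passes + 1L else passes <- 0L
      snap <- cur
      if (passes >= steady_window) {
        steady <- TRUE
        break
      }
    }
  }

  keep <- seq_len(k_rec)
  series <- data.frame(
    time_h = rep(rec_t[keep], times = length(cells) * 18),
    station_km = rep(rep(stations_km, each = k_rec), times = 18),
    field = rep(state_columns(), each = k_rec * length(cells)),
    value = as.numeric(rec[keep, , ]),
    stringsAsFactors = FALSE
  )
  series$variable <- sub("_(wc|sed)$", "", series$field)
  series$compartment <- sub("^.*_(wc|sed)$", "\\1", series$field)
  series$field <- NULL

  structure(list(
    final_state = state,
    time_h = attr(state, "time_h"),
    steps = steps_done,
    steady = steady,
    clamp_events = if (is.null(attr(state, "clamp_events"))) 0 else
      attr(state, "clamp_events"),
    series = series,
    stations_km = stations_km,
    station_cells = cells,
    noise = noise,
    seed = if (is.null(noise)) NA_integer_ else noise$seed,
    scenario_hash = scenario_hash(scenario)
  ), class = "river_run")
}

#' @export
print.river_run <- function(x, ...) {
  cat(sprintf(
    "<river_run> t = %g h in %d steps (%s), clamp events = %d\n",
    x$time_h, x$steps,
    if (x$steady) "steady state" else "horizon reached",
    x$clamp_events))
  cat(sprintf("  noise: %s, seed: %s\n",
              if (is.null(x$noise)) "none (deterministic)" else
                x$noise$category,
              x$seed))
  invisible(x)
}

#' Final value of one field at the reporting stations
#'
#' @param run A `river_run`.
#' @param variable Variable name (default `"n_p"`, the plasmid-borne
#'   resistant population, the study's focal output).
#' @param compartment `"sed"` or `"wc"`.
#' @return Named numeric vector, one value per station.
#' @export
station_final <- function(run, variable = "n_p", compartment = "sed") {
  S <- unclass(run$final_state)
  idx <- match(paste0(variable, "_", compartment), state_columns())
  stats::setNames(S[run$station_cells, idx], paste0(run$stations_km, "km"))
}
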