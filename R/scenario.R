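#' Upstream boundary conditions
#'
#' Constant upstream (Dirichlet) concentrations for the nine water-column
#' state variables, mg/l. The defaults describe a heavily polluted lowland
#' reach under continuous effluent loading: trace antibiotic, ~1 mg/l heavy
#' metal, high suspended solids and organic matter, and a mixed bacterial
#' community that is overwhelmingly susceptible with ~1% resistant seed
#' populations. They are package defaults (the source field data are not
#' published) and every value is overridable.
#'
#' @param A antibiotic (fluoroquinolone), mg/l
#' @param M heavy metal, mg/l
#' @param TSS total suspended solids, mg/l
#' @param POM particulate organic matter, mg/l
#' @param DOM dissolved organic matter, mg/l
#' @param n_f susceptible bacteria, mg biomass/l
#' @param n_p plasmid-borne resistant bacteria, mg biomass/l
#' @param n_c chromosomally resistant bacteria, mg biomass/l
#' @param n_cp doubly resistant bacteria, mg biomass/l
#' @return Named numeric vector of class `boundary_conditions`.
#' @export
boundary_conditions <- function(A = 0.01, M = 1, TSS = 100, POM = 30,
                                DOM = 10, n_f = 1, n_p = 0.01,
                                n_c = 0.01, n_cp = 0.01) {
  bc <- c(A = A, M = M, TSS = TSS, POM = POM, DOM = DOM,
          n_f = n_f, n_p = n_p, n_c = n_c, n_cp = n_cp)
  if (any(!is.finite(bc)) || any(bc < 0)) {
    stop("boundary concentrations must be finite and >= 0")
  }
  class(bc) <- c("boundary_conditions", class(bc))
  bc
}

.scenario_sections <- list(
  geometry = c("reach_length", "n_cells"),
  hydraulics = c("velocity_u", "dispersion_d", "gamma", "h_o", "z_organic",
                 "n_max_wc", "n_max_sed"),
  discretization = c("dt", "t_end"),
  parameters = NULL, # validated against the registry
  boundary = NULL,   # validated against boundary_conditions names
  initial = c("wc", "sed")
)

#' Build a river scenario configuration
#'
#' Assembles and validates the full configuration of a simulation: reach
#' geometry, hydraulics, the water-to-sediment volume ratio, discretization,
#' kinetic parameters, upstream boundary loading and initial state.
#'
#' The hydraulic defaults (velocity 360 m/h = 0.1 m/s, dispersion
#' 3600 m2/h = 1 m2/s) are typical lowland-river magnitudes. `gamma` is the
#' water-column-to-active-sediment-layer volume ratio (default 10: 1 m of
#' water over a 0.1 m active bed layer); sediment-layer rates gain a factor
#' `gamma` when mass settles out of the larger water volume and lose it on
#' resuspension. `z_organic` is the organic (hydrolysable) fraction of TSS.
#' Carrying capacities `n_max_wc`/`n_max_sed` cap total biomass per
#' compartment.
#'
#' @param reach_length Reach length, m.
#' @param n_cells Number of grid cells; `dx = reach_length / n_cells`.
#' @param dt Time step, h. Must satisfy [cfl_check()].
#' @param t_end Simulation horizon, h (default 43800 h = 5 years).
#' @param velocity_u Advection velocity, m/h.
#' @param dispersion_d Longitudinal dispersion, m2/h.
#' @param gamma Water-column to sediment-layer volume ratio (> 0).
#' @param h_o Thickness of the active sediment exchange layer, m.
#' @param z_organic Organic fraction of TSS subject to hydrolysis, in [0,1].
#' @param n_max_wc,n_max_sed Biomass carrying capacities, mg/l.
#' @param parameters A `river_parameters` list (default: published values).
#' @param boundary A [boundary_conditions()] vector.
#' @param initial List with named numeric vectors `wc` and `sed` giving the
#'   spatially uniform initial concentration of each variable in each
#'   compartment. Default: water column starts at the boundary values,
#'   sediment starts empty.
#' @param validate Check invariants and the CFL bound (default TRUE).
#' @return Object of class `river_scenario`.
#' @export
#' @examples
#' sc <- river_scenario(n_cells = 20, dt = 0.5)
#' sc$dx
river_scenario <- function(reach_length = 100000, n_cells = 100,
                           dt = 1, t_end = 43800,
                           velocity_u = 360, dispersion_d = 3600,
                           gamma = 10, h_o = 0.1, z_organic = 0.3,
                           n_max_wc = 10, n_max_sed = 10,
                           parameters = default_parameters(),
                           boundary = boundary_conditions(),
                           initial = NULL,
                           validate = TRUE) {
  vars <- state_variables()
  if (is.null(initial)) {
    initial <- list(
      wc = stats::setNames(as.numeric(boundary[vars]), vars),
      sed = stats::setNames(rep(0, length(vars)), vars)
    )
  }
  sc <- structure(list(
    reach_length = reach_length, n_cells = as.integer(n_cells),
    dx = reach_length / n_cells,
    dt = dt, t_end = t_end,
    velocity_u = velocity_u, dispersion_d = dispersion_d,
    gamma = gamma, h_o = h_o, z_organic = z_organic,
    n_max_wc = n_max_wc, n_max_sed = n_max_sed,
    parameters = parameters, boundary = boundary, initial = initial
  ), class = "river_scenario")
  if (validate) validate_scenario(sc)
  sc
}

#' Validate a scenario configuration
#'
#' Checks structural invariants (positive geometry and capacities, gamma > 0,
#' organic fraction in [0,1], nonnegative boundary and initial values) and
#' the explicit-scheme stability contract of [cfl_check()]. Errors name the
#' offending field; the CFL error names the maximum admissible time step.
#'
#' @param sc A `river_scenario`.
#' @return `sc`, invisibly, if valid.
#' @export
validate_scenario <- function(sc) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(is.finite(sc$reach_length) && sc$reach_length > 0,
      "geometry.reach_length must be > 0")
  chk(is.finite(sc$n_cells) && sc$n_cells >= 1,
      "geometry.n_cells must be >= 1")
  chk(is.finite(sc$dx) && sc$dx > 0, "dx = reach_length/n_cells must be > 0")
  chk(is.finite(sc$dt) && sc$dt > 0, "discretization.dt must be > 0")
  chk(is.finite(sc$t_end) && sc$t_end > 0, "discretization.t_end must be > 0")
  chk(sc$velocity_u > 0, "hydraulics.velocity_u must be > 0")
  chk(sc$dispersion_d > 0, "hydraulics.dispersion_d must be > 0")
  chk(sc$gamma > 0, "hydraulics.gamma must be > 0")
  chk(sc$h_o > 0, "hydraulics.h_o must be > 0")
  chk(sc$z_organic >= 0 && sc$z_organic <= 1,
      "hydraulics.z_organic must lie in [0, 1]")
  chk(sc$n_max_wc > 0 && sc$n_max_sed > 0,
      "hydraulics.n_max_wc and n_max_sed must be > 0")
  vars <- state_variables()
  chk(all(vars %in% names(sc$boundary)),
      "boundary must name all nine water-column variables")
  chk(all(sc$boundary[vars] >= 0), "boundary values must be >= 0")
  for (comp in c("wc", "sed")) {
    chk(all(vars %in% names(sc$initial[[comp]])),
        paste0("initial.", comp, " must name all nine variables"))
    chk(all(sc$initial[[comp]][vars] >= 0),
        paste0("initial.", comp, " values must be >= 0"))
  }
  missing <- setdiff(parameter_registry()$name, names(sc$parameters))
  chk(length(missing) == 0,
      paste0("parameters missing: ", paste(missing, collapse = ", ")))
  cfl <- cfl_check(sc$velocity_u, sc$dispersion_d, sc$dx, sc$dt)
  if (!cfl$ok) {
    stop(sprintf(
      "discretization.dt = %g h violates the %s stability bound; max admissible dt = %g h",
      sc$dt, cfl$binding, cfl$dt_max), call. = FALSE)
  }
  invisible(sc)
}

#' @export
print.river_scenario <- function(x, ...) {
  cat("<river_scenario>\n")
  cat(sprintf("  reach: %g m in %d cells (dx = %g m)\n",
              x$reach_length, x$n_cells, x$dx))
  cat(sprintf("  dt = %g h, t_end = %g h\n", x$dt, x$t_end))
  cat(sprintf("  u = %g m/h, D = %g m2/h, gamma = %g, h_o = %g m\n",
              x$velocity_u, x$dispersion_d, x$gamma, x$h_o))
  cat("  boundary (mg/l):",
      paste(names(x$boundary), signif(as.numeric(x$boundary), 4),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Reference scenario: a polluted 100 km lowland reach
#'
#' The package's reference configuration, patterned on a 100 km stretch of a
#' heavily polluted lowland river (Musi-like conditions): 100 cells of 1 km,
#' published default kinetic constants, default hydraulics and constant
#' upstream loading of antibiotic, metal, solids, organic matter and mixed
#' susceptible/resistant bacterial populations. All numeric boundary and
#' hydraulic values are documented package defaults, not field measurements.
#'
#' @param ... Overrides forwarded to [river_scenario()].
#' @return A `river_scenario`.
#' @export
#' @examples
#' sc <- musi_scenario()
#' sc$reach_length  # 100000 m
musi_scenario <- function(...) {
  river_scenario(...)
}

#' Draw a random but valid synthetic scenario
#'
#' Test-fixture generator: kinetic constants are drawn uniformly within
#' their published min-max envelopes (single-valued rows keep their published
#' value; for the rows with inconsistent published bounds the draw uses the
#' sorted bounds), and boundary concentrations are drawn within documented
#' positive ranges around the reference loading. The same seed reproduces
#' the same scenario.
#'
#' @param seed Integer RNG seed.
#' @param ... Overrides forwarded to [river_scenario()] (e.g. `n_cells`).
#' @return A `river_scenario` whose parameters pass [validate_parameters()].
#' @export
make_synthetic_scenario <- function(seed, ...) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  reg <- parameter_registry()
  p <- default_parameters()
  for (i in seq_len(nrow(reg))) {
    if (reg$single_valued[i]) next
    lo <- min(reg$min[i], reg$max[i])
    hi <- max(reg$min[i], reg$max[i])
    p[[reg$name[i]]] <- stats::runif(1, lo, hi)
  }
  bc <- boundary_conditions(
    A = stats::runif(1, 0.001, 0.1),
    M = stats::runif(1, 0.1, 5),
    TSS = stats::runif(1, 20, 300),
    POM = stats::runif(1, 5, 80),
    DOM = stats::runif(1, 2, 30),
    n_f = stats::runif(1, 0.1, 5),
    n_p = stats::runif(1, 0.001, 0.1),
    n_c = stats::runif(1, 0.001, 0.1),
    n_cp = stats::runif(1, 0.001, 0.1)
  )
  river_scenario(parameters = p, boundary = bc, ...)
}

# ---- scenario JSON I/O -----------------------------------------------------

#' Write a scenario to a JSON file
#'
#' Serialises a `river_scenario` into the sectioned JSON layout
#' `{geometry, hydraulics, discretization, parameters, boundary, initial}`
#' at full numeric precision, so that [load_scenario()] reproduces an equal
#' configuration.
#'
#' @param sc A `river_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  doc <- list(
    geometry = list(reach_length = sc$reach_length, n_cells = sc$n_cells),
    hydraulics = list(
      velocity_u = sc$velocity_u, dispersion_d = sc$dispersion_d,
      gamma = sc$gamma, h_o = sc$h_o, z_organic = sc$z_organic,
      n_max_wc = sc$n_max_wc, n_max_sed = sc$n_max_sed
    ),
    discretization = list(dt = sc$dt, t_end = sc$t_end),
    parameters = unclass(sc$parameters),
    boundary = as.list(stats::setNames(as.numeric(sc$boundary[state_variables()]),
                                       state_variables())),
    initial = list(
      wc = as.list(sc$initial$wc[state_variables()]),
      sed = as.list(sc$initial$sed[state_variables()])
    )
  )
  # digits = I(17): exact IEEE round trip so load_scenario reproduces the
  # configuration bit for bit
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Load and validate a scenario from a JSON file
#'
#' Reads a sectioned scenario document, rejects unknown sections or fields
#' (naming the offending field path), fills unspecified fields with the
#' documented defaults, and validates the result, including the CFL
#' stability contract. A file containing only parameter overrides therefore
#' yields a scenario with published defaults everywhere else.
#'
#' @param path Path to a scenario JSON file.
#' @return A validated `river_scenario`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  known_sections <- names(.scenario_sections)
  bad <- setdiff(names(doc), known_sections)
  if (length(bad) > 0) stop("unknown scenario section: ", bad[[1]])
  for (sec in c("geometry", "hydraulics", "discretization")) {
    bad <- setdiff(names(doc[[sec]]), .scenario_sections[[sec]])
    if (length(bad) > 0) stop("unknown scenario field: ", sec, ".", bad[[1]])
  }
  if (!is.null(doc$parameters)) {
    bad <- setdiff(names(doc$parameters), parameter_registry()$name)
    if (length(bad) > 0) stop("unknown scenario field: parameters.", bad[[1]])
  }
  if (!is.null(doc$boundary)) {
    bad <- setdiff(names(doc$boundary), state_variables())
    if (length(bad) > 0) stop("unknown scenario field: boundary.", bad[[1]])
  }
  if (!is.null(doc$initial)) {
    bad <- setdiff(names(doc$initial), c("wc", "sed"))
    if (length(bad) > 0) stop("unknown scenario field: initial.", bad[[1]])
    for (comp in names(doc$initial)) {
      bad <- setdiff(names(doc$initial[[comp]]), state_variables())
      if (length(bad) > 0) {
        stop("unknown scenario field: initial.", comp, ".", bad[[1]])
      }
    }
  }
  p <- default_parameters()
  for (nm in names(doc$parameters)) p[[nm]] <- as.numeric(doc$parameters[[nm]])
  bc_args <- lapply(doc$boundary, as.numeric)
  bc <- do.call(boundary_conditions, bc_args)
  args <- list(parameters = p, boundary = bc)
  for (sec in c("geometry", "hydraulics", "discretization")) {
    for (nm in names(doc[[sec]])) args[[nm]] <- as.numeric(doc[[sec]][[nm]])
  }
  if (!is.null(doc$initial)) {
    vars <- state_variables()
    init <- list(wc = stats::setNames(as.numeric(bc[vars]), vars),
                 sed = stats::setNames(rep(0, length(vars)), vars))
    for (comp in names(doc$initial)) {
      for (nm in names(doc$initial[[comp]])) {
        init[[comp]][[nm]] <- as.numeric(doc$initial[[comp]][[nm]])
      }
    }
    args$initial <- init
  }
  do.call(river_scenario, args)
}

#' Stable hash of a scenario configuration
#'
#' MD5 digest of the canonical JSON serialisation, used in run manifests so
#' that outputs can be traced to the exact configuration that produced them.
#'
#' @param sc A `river_scenario`.
#' @return Character MD5 string.
#' @export
scenario_hash <- function(sc) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_scenario(sc, tmp)
  unname(tools::md5sum(tmp))
}
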