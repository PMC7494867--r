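#' Registry of model rate constants and coefficients
#'
#' Returns the full registry of the 28 kinetic and transport constants used
#' by the model, one row per constant, with its unit, default value and the
#' published minimum/maximum envelope used both by [validate_parameters()]
#' and by the one-at-a-time sensitivity harness.
#'
#' Three registry rows are internally inconsistent as published (the default
#' lies outside the printed bounds, or the printed minimum exceeds the
#' printed maximum): the sediment antibiotic degradation constant, the
#' sediment hydrolysis constant, and the segregation rate. They are stored
#' exactly as published and flagged with `bounds_consistent = FALSE`;
#' [validate_parameters()] skips bound checks on them. Four rows publish a
#' single value with no range (`single_valued = TRUE`); for those
#' `min = max = default`. The resuspension constant is defined as a velocity
#' ratio but published with a sorption-style unit; the value is stored as
#' published and used as a first-order rate (1/h).
#'
#' @return A data.frame with columns `index`, `name`, `description`, `unit`,
#'   `default`, `min`, `max`, `single_valued`, `bounds_consistent`.
#' @seealso [default_parameters()], [validate_parameters()],
#'   [write_parameter_registry()]
#' @export
#' @examples
#' reg <- parameter_registry()
#' nrow(reg)  # 28
parameter_registry <- function() {
  reg <- data.frame(
    index = 1:28,
    name = c(
      "k_set", "kd_solid_a", "kd_dom_a", "kd_solid_m", "kd_dom_m",
      "k_resus", "k_diff", "k_xa_wc", "k_xa_sed", "k_h_wc", "k_h_sed",
      "porosity", "a_death", "sa_segregation", "beta_conjugation",
      "y_f", "y_p", "y_c", "y_cp", "eta_metal", "mu_max_wc", "mu_max_sed",
      "k_s", "k_im", "c_c", "c_p", "x_cost", "mic"
    ),
    description = c(
      "settling rate constant (settling velocity over mean depth)",
      "solids partition coefficient, antibiotic",
      "DOM partition coefficient, antibiotic",
      "solids partition coefficient, metal",
      "DOM partition coefficient, metal",
      "resuspension rate constant (unit published as l/mg; used as 1/h)",
      "sediment-water diffusion mass-transfer constant (over h_o = 0.1 m)",
      "antibiotic degradation rate, water column",
      "antibiotic degradation rate, sediment",
      "POM hydrolysis rate, water column",
      "POM hydrolysis rate, sediment",
      "sediment porosity",
      "extrinsic density-dependent death rate of cells",
      "plasmid segregation (loss) rate",
      "horizontal plasmid transfer (conjugation) rate",
      "yield coefficient, susceptible cells",
      "yield coefficient, plasmid-borne resistance",
      "yield coefficient, chromosomal resistance",
      "yield coefficient, plasmid plus chromosomal resistance",
      "mg metal reduced per mg substrate utilised",
      "maximum specific growth rate, water column",
      "maximum specific growth rate, sediment",
      "half-saturation (half rate) constant",
      "metal inhibition threshold concentration",
      "fitness cost of chromosomal resistance gene",
      "fitness cost of plasmid-borne resistance gene",
      "fitness cost of plasmid carriage",
      "minimum inhibitory concentration"
    ),
    unit = c(
      "1/h", "l/mg", "l/mg", "l/mg", "l/mg",
      "1/h", "m/h", "1/h", "1/h", "1/h", "1/h",
      "-", "1/h", "1/h", "1/h",
      "mg/mg", "mg/mg", "mg/mg", "mg/mg", "mg/mg", "1/h", "1/h",
      "mg/l", "mg/l", "-", "-", "-", "mg/l"
    ),
    default = c(
      0.02, 0.0002, 0.002, 0.000002, 0.000002,
      0.00000239, 0.000208, 0.05, 0.03, 0.00208, 0.0002,
      0.3, 0.0006, 0.000001, 0.000045,
      0.4, 0.3, 0.3, 0.2, 0.01, 0.1083, 0.0108,
      9.1, 3.049, 0.02, 0.05, 0.01, 4
    ),
    min = c(
      0.002, 0.00007, 0.00007, 0.000002, 0.000002,
      NA, 0.00004167, 0.001917, 0.000958, 0.000416, 0.00416,
      NA, 0.0001, 0.00000104, 0,
      0.2, 0.2, 0.2, 0.2, NA, 0.01083, 0.009,
      0.2, NA, 0, 0, 0, 0.05
    ),
    max = c(
      0.135, 0.005, 0.005, 0.0002, 0.0002,
      NA, 0.0004167, 1.7916, 0.01, 0.0029, 0.0029,
      NA, 0.00625, 0.0054, 1.0,
      0.52, 0.52, 0.52, 0.52, NA, 0.1875, 0.1875,
      18, NA, 1.2, 1.2, 1.2, 8
    ),
    stringsAsFactors = FALSE
  )
  reg$single_valued <- is.na(reg$min) & is.na(reg$max)
  reg$min[reg$single_valued] <- reg$default[reg$single_valued]
  reg$max[reg$single_valued] <- reg$default[reg$single_valued]
  reg$bounds_consistent <- reg$min <= reg$max &
    reg$default >= reg$min & reg$default <= reg$max
  reg
}

#' Default parameter set
#'
#' Named list of the 28 model constants at their published default values.
#'
#' @return An object of class `river_parameters` (a named list of scalars).
#' @export
#' @examples
#' p <- default_parameters()
#' p$mic  # 4 mg/l
default_parameters <- function() {
  reg <- parameter_registry()
  p <- as.list(stats::setNames(reg$default, reg$name))
  class(p) <- "river_parameters"
  p
}

#' @export
print.river_parameters <- function(x, ...) {
  cat("<river_parameters> ", length(x), " constants\n", sep = "")
  reg <- parameter_registry()
  df <- data.frame(
    name = reg$name, unit = reg$unit,
    value = unlist(x[reg$name]),
    default = reg$default,
    row.names = NULL
  )
  print(df, ...)
  invisible(x)
}

#' Check a parameter set against its published bounds
#'
#' Compares each constant with its published minimum/maximum envelope (see
#' [parameter_registry()]). Violations are returned, not raised, so a caller
#' can inspect or report them. Registry rows whose published bounds are
#' internally inconsistent are exempt from the check; single-valued rows are
#' checked for equality with the published value.
#'
#' @param p A `river_parameters` object or named list covering all 28
#'   registry names.
#' @return A data.frame of violations with columns `name`, `value`, `lower`,
#'   `upper`; zero rows when every checked value is inside its envelope.
#' @export
#' @examples
#' nrow(validate_parameters(default_parameters()))  # 0
#' p <- default_parameters(); p$mu_max_wc <- 0.2
#' validate_parameters(p)  # one violation (upper bound 0.1875)
validate_parameters <- function(p) {
  reg <- parameter_registry()
  missing <- setdiff(reg$name, names(p))
  if (length(missing) > 0) {
    stop("parameter set is missing: ", paste(missing, collapse = ", "))
  }
  out <- data.frame(
    name = character(0), value = numeric(0),
    lower = numeric(0), upper = numeric(0),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(reg))) {
    if (!reg$bounds_consistent[i]) next
    v <- as.numeric(p[[reg$name[i]]])
    if (!is.finite(v) || v < reg$min[i] || v > reg$max[i]) {
      out <- rbind(out, data.frame(
        name = reg$name[i], value = v,
        lower = reg$min[i], upper = reg$max[i],
        stringsAsFactors = FALSE
      ))
    }
  }
  out
}

#' Export the parameter registry as CSV
#'
#' @param path File path for the CSV.
#' @return `path`, invisibly.
#' @export
write_parameter_registry <- function(path) {
  utils::write.csv(parameter_registry(), path, row.names = FALSE)
  invisible(path)
}
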