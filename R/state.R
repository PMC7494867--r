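#' Names of the nine transported state variables
#'
#' Antibiotic (A), heavy metal (M), total suspended solids (TSS),
#' particulate organic matter (POM), dissolved organic matter (DOM), and the
#' four bacterial phenotypes: susceptible (n_f), plasmid-borne resistant
#' (n_p), chromosomally resistant (n_c) and doubly resistant (n_cp). Each
#' variable exists in both the water column (`_wc`) and the sediment layer
#' (`_sed`).
#'
#' @return Character vector of length 9.
#' @export
state_variables <- function() {
  c("A", "M", "TSS", "POM", "DOM", "n_f", "n_p", "n_c", "n_cp")
}

#' Column names of the full 18-field state matrix
#' @return Character vector of length 18 (water column first, then sediment).
#' @export
state_columns <- function() .STATE_COLS

#' The four bacterial phenotype identifiers
#' @return `c("f", "p", "c", "cp")`.
#' @export
phenotypes <- function() c("f", "p", "c", "cp")

# fixed column layout of the state matrix, as integer indices (hot path)
.IX <- list(
  A_wc = 1L, M_wc = 2L, TSS_wc = 3L, POM_wc = 4L, DOM_wc = 5L,
  n_f_wc = 6L, n_p_wc = 7L, n_c_wc = 8L, n_cp_wc = 9L,
  A_sed = 10L, M_sed = 11L, TSS_sed = 12L, POM_sed = 13L, DOM_sed = 14L,
  n_f_sed = 15L, n_p_sed = 16L, n_c_sed = 17L, n_cp_sed = 18L
)
.STATE_COLS <- names(.IX)
.RIVER_STATE_CLASS <- c("river_state", "matrix", "array")

#' Initial river state for a scenario
#'
#' Builds the concentration field: a matrix with one row per grid cell and
#' one column per variable-compartment pair (see [state_columns()]), with a
#' simulation clock attribute `time_h`. All concentrations are mg per litre
#' of bulk environmental volume.
#'
#' @param scenario A `river_scenario`.
#' @return A `river_state` matrix (`n_cells` x 18) at `time_h = 0`.
#' @export
river_state <- function(scenario) {
  vars <- state_variables()
  n <- scenario$n_cells
  S <- matrix(0, nrow = n, ncol = 18,
              dimnames = list(NULL, state_columns()))
  for (v in vars) {
    S[, paste0(v, "_wc")] <- scenario$initial$wc[[v]]
    S[, paste0(v, "_sed")] <- scenario$initial$sed[[v]]
  }
  attr(S, "time_h") <- 0
  class(S) <- c("river_state", class(S))
  S
}

#' @export
print.river_state <- function(x, ...) {
  cat(sprintf("<river_state> %d cells x 18 fields, t = %g h\n",
              nrow(x), attr(x, "time_h")))
  rng <- apply(unclass(x), 2, range)
  print(signif(t(rng), 4))
  invisible(x)
}

#' Grid cell containing a river station
#'
#' Cell centres use a 0-based convention where cell `i` spans
#' `[i*dx, (i+1)*dx)`; the station at kilometre `km` is the cell containing
#' `x = 1000*km` m, clamped to the final cell for the downstream end point.
#'
#' @param scenario A `river_scenario`.
#' @param km Station positions in kilometres (vectorised).
#' @return Integer row indices into the state matrix.
#' @export
#' @examples
#' station_cell(river_scenario(n_cells = 100), c(2, 5, 99, 100))
station_cell <- function(scenario, km) {
  idx <- floor(km * 1000 / scenario$dx) + 1
  pmin(pmax(as.integer(idx), 1L), scenario$n_cells)
}

#' Export a state as a tidy profile table
#'
#' @param state A `river_state`.
#' @param scenario The `river_scenario` it belongs to (for coordinates).
#' @return data.frame with columns `x_m`, `variable`, `compartment`,
#'   `concentration`, `time_h`.
#' @export
state_profiles <- function(state, scenario) {
  vars <- state_variables()
  x_m <- (seq_len(scenario$n_cells) - 0.5) * scenario$dx
  out <- expand.grid(x_m = x_m, variable = vars,
                     compartment = c("wc", "sed"),
                     stringsAsFactors = FALSE)
  conc <- numeric(nrow(out))
  for (comp in c("wc", "sed")) {
    for (v in vars) {
      rows <- which(out$variable == v & out$compartment == comp)
      conc[rows] <- unclass(state)[, paste0(v, "_", comp)]
    }
  }
  out$concentration <- conc
  out$time_h <- attr(state, "time_h")
  out
}
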