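#' One-at-a-time parameter sensitivity analysis
#'
#' For each named constant the deterministic model is run twice — once at
#' the published minimum, once at the published maximum, everything else at
#' its default — and the two steady-state profiles of the plasmid-borne
#' resistant population in the sediment (`n_p_sed`, the study's focal
#' output) are compared. The recorded difference is the maximum absolute
#' end-state difference over the grid, a single mg/l number per parameter.
#' Constants published with a single value (no range) are flagged
#' `single_valued` and score a zero difference without running; solver
#' failures are recorded per parameter and do not abort the batch.
#'
#' @param scenario Base `river_scenario` (defaults everywhere else).
#' @param parameters Character vector of constants to perturb; default all
#'   28 registry rows.
#' @param t_max Horizon cap for each deterministic run, h. Sensitivity runs
#'   use a shorter cap than the scenario's `t_end` because the focal
#'   biological fields equilibrate long before the slowest sediment stocks.
#' @param steady_tol,steady_window,check_every Forwarded to
#'   [run_simulation()].
#' @return data.frame of class `oat_sensitivity`, ordered by decreasing
#'   difference, with columns `parameter`, `min`, `max`, `diff_mg_l`,
#'   `status`.
#' @export
run_oat_sensitivity <- function(scenario, parameters = NULL,
                                t_max = 15000,
                                steady_tol = 1e-4, steady_window = 4,
                                check_every = 25) {
  reg <- parameter_registry()
  if (is.null(parameters)) parameters <- reg$name
  unknown <- setdiff(parameters, reg$name)
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  sc <- scenario
  sc$t_end <- min(scenario$t_end, t_max)
  one_run <- function(p_name, value) {
    s <- sc
    s$parameters[[p_name]] <- value
    run <- run_simulation(s, noise = NULL, stop = "steady",
                          steady_tol = steady_tol,
                          steady_window = steady_window,
                          check_every = check_every,
                          record_every = 1000)
    unclass(run$final_state)[, match("n_p_sed", state_columns())]
  }
  rows <- lapply(parameters, function(p_name) {
    i <- match(p_name, reg$name)
    lo <- min(reg$min[i], reg$max[i])
    hi <- max(reg$min[i], reg$max[i])
    if (reg$single_valued[i] || lo == hi) {
      return(data.frame(parameter = p_name, min = lo, max = hi,
                        diff_mg_l = 0, status = "single_valued",
                        stringsAsFactors = FALSE))
    }
    res <- tryCatch({
      prof_lo <- one_run(p_name, lo)
      prof_hi <- one_run(p_name, hi)
      data.frame(parameter = p_name, min = lo, max = hi,
                 diff_mg_l = max(abs(prof_hi - prof_lo)), status = "ok",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(parameter = p_name, min = lo, max = hi,
                 diff_mg_l = NA_real_,
                 status = paste0("failed: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$diff_mg_l), -Inf, out$diff_mg_l)), ]
  rownames(out) <- NULL
  class(out) <- c("oat_sensitivity", class(out))
  out
}

#' Flag sensitive parameters against a cutoff
#'
#' A parameter qualifies as sensitive when its end-state difference reaches
#' the cutoff (inclusive, so a difference exactly at the cutoff — the
#' least-sensitive qualifying case — is flagged).
#'
#' @param records An `oat_sensitivity` data.frame (or any frame with a
#'   `diff_mg_l` column).
#' @param cutoff Sensitivity cutoff, mg/l (default 0.05).
#' @return The records with a logical `sensitive` column added.
#' @export
classify_sensitive <- function(records, cutoff = 0.05) {
  if (cutoff < 0) stop("cutoff must be >= 0")
  records$sensitive <- !is.na(records$diff_mg_l) &
    records$diff_mg_l >= cutoff
  records
}

#' Multi-generation stochastic ensemble
#'
#' Runs `n_generations` independent stochastic realisations
#' ("generations") of the scenario under one noise category, generation
#' `g` seeded with `base_seed + g - 1`, each integrated to its stop rule,
#' and records the final plasmid-borne resistant sediment population
#' (`n_p_sed`) at each reporting station. Per-station ensemble means and
#' standard deviations summarise the spread the noise induces.
#'
#' @param scenario A `river_scenario`.
#' @param category Noise category (see [noise_spec()]).
#' @param n_generations Number of realisations (default 100).
#' @param stations_km Reporting stations, km.
#' @param base_seed Base RNG seed.
#' @param stop Stop rule per generation (default `"t_end"`: stochastic
#'   trajectories fluctuate around their equilibrium, so the horizon, not
#'   the deterministic drift criterion, ends a generation).
#' @param amplitude Noise amplitude multiplier (see [noise_spec()]).
#' @return Object of class `ensemble_summary`: category, stations, the
#'   generations-by-stations matrix of final values, per-station `mean`
#'   and `sd`, counts and seed bookkeeping.
#' @export
run_ensemble <- function(scenario, category, n_generations = 100,
                         stations_km = c(2, 5, 10, 99, 100),
                         base_seed = 1, stop = "t_end", amplitude = 1) {
  finals <- matrix(NA_real_, n_generations, length(stations_km),
                   dimnames = list(NULL, paste0(stations_km, "km")))
  failures <- character(0)
  for (g in seq_len(n_generations)) {
    ns <- noise_spec(category, seed = base_seed + g - 1,
                     amplitude = amplitude)
    res <- tryCatch(
      run_simulation(scenario, noise = ns, stations_km = stations_km,
                     stop = stop, record_every = 1000),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures,
                    sprintf("generation %d: %s", g, conditionMessage(res)))
      next
    }
    finals[g, ] <- station_final(res, "n_p", "sed")
  }
  ok <- stats::complete.cases(finals)
  structure(list(
    category = category,
    stations_km = stations_km,
    finals = finals,
    mean = apply(finals[ok, , drop = FALSE], 2, mean),
    sd = apply(finals[ok, , drop = FALSE], 2, stats::sd),
    n_generations = n_generations,
    n_ok = sum(ok),
    base_seed = base_seed,
    failures = failures
  ), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %s noise, %d/%d generations\n",
              x$category, x$n_ok, x$n_generations))
  print(data.frame(station_km = x$stations_km,
                   mean = x$mean, sd = x$sd, row.names = NULL))
  invisible(x)
}

#' Tabular comparison of noise categories
#'
#' Long-format table of per-station ensemble mean and standard deviation
#' for each category, with the spread expressed relative to the first
#' summary supplied (`sd_ratio`).
#'
#' @param summaries List of `ensemble_summary` objects sharing stations and
#'   generation counts.
#' @return data.frame with columns `category`, `station_km`, `mean`, `sd`,
#'   `sd_ratio`.
#' @export
compare_categories <- function(summaries) {
  if (length(summaries) < 1) stop("need at least one summary")
  st <- summaries[[1]]$stations_km
  ng <- summaries[[1]]$n_generations
  for (s in summaries) {
    if (!identical(s$stations_km, st)) {
      stop("summaries do not share stations")
    }
    if (s$n_generations != ng) {
      stop("summaries do not share the number of generations")
    }
  }
  ref_sd <- summaries[[1]]$sd
  out <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(category = s$category, station_km = st,
               mean = as.numeric(s$mean), sd = as.numeric(s$sd),
               sd_ratio = as.numeric(s$sd / ref_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
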