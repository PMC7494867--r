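#' Equilibrium partitioning of a sorbing chemical
#'
#' Linear equilibrium three-phase partitioning of a chemical between the
#' truly dissolved phase, the solids-sorbed phase and the DOM-bound phase:
#' \deqn{f_{part} = K_{d,solid} TSS / (1 + K_{d,solid} TSS + K_{d,DOM} DOM)}
#' and analogously for the DOM-bound fraction; the three fractions sum to 1.
#' Only the particulate fraction settles and only the dissolved fraction
#' takes part in sediment-water diffusion and is considered bioactive.
#'
#' @param total Total concentration, mg/l (carried for interface symmetry;
#'   fractions do not depend on it).
#' @param tss Suspended solids, mg/l.
#' @param dom Dissolved organic matter, mg/l.
#' @param kd_solid Solids partition coefficient, l/mg.
#' @param kd_dom DOM partition coefficient, l/mg.
#' @return List with numeric components `f_dissolved`, `f_particulate`,
#'   `f_dom_bound`, each in [0, 1]; vectorised over the inputs.
#' @export
#' @examples
#' partition_fractions(1, tss = 100, dom = 10, kd_solid = 2e-4, kd_dom = 2e-3)
partition_fractions <- function(total = 1, tss, dom, kd_solid, kd_dom) {
  if (any(c(total, tss, dom, kd_solid, kd_dom) < 0, na.rm = TRUE)) {
    stop("partition_fractions: all inputs must be >= 0")
  }
  denom <- 1 + kd_solid * tss + kd_dom * dom
  list(
    f_dissolved = 1 / denom,
    f_particulate = kd_solid * tss / denom,
    f_dom_bound = kd_dom * dom / denom
  )
}

#' Monod (substrate-saturating) specific growth rate
#'
#' \deqn{\mu = \mu_{max} S / (K_s + S)} Monotone nondecreasing in `S`,
#' equal to `mu_max/2` at `S = k_s`, bounded by `mu_max`.
#'
#' @param mu_max Maximum specific growth rate, 1/h.
#' @param substrate Substrate (DOM) concentration, mg/l.
#' @param k_s Half-saturation constant, mg/l.
#' @return Specific growth rate, 1/h (vectorised).
#' @export
monod_mu <- function(mu_max, substrate, k_s) {
  denom <- k_s + substrate
  out <- ifelse(denom > 0, mu_max * substrate / denom, 0)
  out
}

#' Antibiotic growth-inhibition factor
#'
#' Susceptible cells (`phenotype = "f"`) grow at a rate linearly reduced by
#' the dissolved antibiotic concentration, reaching full inhibition at the
#' minimum inhibitory concentration: `max(0, 1 - a/mic)`. Resistant
#' phenotypes (`p`, `c`, `cp`) are unaffected.
#'
#' @param a_dissolved Dissolved antibiotic, mg/l.
#' @param mic Minimum inhibitory concentration, mg/l.
#' @param phenotype One of `"f"`, `"p"`, `"c"`, `"cp"`.
#' @return Factor in [0, 1] (vectorised over `a_dissolved`).
#' @export
antibiotic_inhibition <- function(a_dissolved, mic, phenotype) {
  phenotype <- match.arg(phenotype, phenotypes())
  if (phenotype != "f") {
    return(rep(1, length(a_dissolved)))
  }
  if (any(mic <= 0)) stop("mic must be > 0 for the susceptible phenotype")
  pmax(0, 1 - a_dissolved / mic)
}

#' Metal growth factor
#'
#' Metal serves bacterial growth up to the inhibition threshold `k_im` and
#' acts as an inhibitor above it: `min(1, k_im / m)`, continuous and
#' nonincreasing in `m`.
#'
#' @param m Metal concentration, mg/l.
#' @param k_im Metal inhibition threshold, mg/l.
#' @return Factor in (0, 1] (vectorised).
#' @export
metal_growth_factor <- function(m, k_im) {
  if (any(k_im <= 0)) stop("k_im must be > 0")
  ifelse(m <= k_im, 1, k_im / m)
}

#' Fitness-cost multiplier of a resistance phenotype
#'
#' Costs compose additively on the growth rate: carrying the resistance gene
#' on the chromosome costs `c_c`; on the plasmid `c_p` plus the plasmid
#' carriage cost `x_cost`; the doubly resistant phenotype pays all three.
#' The multiplier is clamped at zero.
#'
#' @param phenotype One of `"f"`, `"p"`, `"c"`, `"cp"`.
#' @param params Parameter list with `c_c`, `c_p`, `x_cost`.
#' @return Scalar multiplier in [0, 1].
#' @export
cost_multiplier <- function(phenotype, params) {
  phenotype <- match.arg(phenotype, phenotypes())
  m <- switch(phenotype,
    f = 1,
    p = 1 - params$c_p - params$x_cost,
    c = 1 - params$c_c,
    cp = 1 - params$c_c - params$c_p - params$x_cost
  )
  max(0, m)
}

#' Effective specific growth rate of a phenotype
#'
#' Composes the compartment's maximum growth rate with the fitness-cost
#' multiplier, Monod substrate limitation on DOM, antibiotic inhibition of
#' the susceptible phenotype (dissolved fraction only) and the metal growth
#' factor:
#' \deqn{\mu = \mu_{max} \cdot cost \cdot \frac{S}{K_s+S} \cdot
#'   inhib(A_{diss}) \cdot min(1, K_{im}/M)}
#'
#' @param phenotype One of `"f"`, `"p"`, `"c"`, `"cp"`.
#' @param compartment `"wc"` or `"sed"` (selects `mu_max_wc`/`mu_max_sed`).
#' @param dom DOM concentration, mg/l.
#' @param a_dissolved Dissolved antibiotic, mg/l.
#' @param m Metal concentration, mg/l.
#' @param params Parameter list (see [default_parameters()]).
#' @return Specific growth rate, 1/h (vectorised over concentrations).
#' @export
effective_growth_rate <- function(phenotype, compartment, dom, a_dissolved,
                                  m, params) {
  compartment <- match.arg(compartment, c("wc", "sed"))
  mu_max <- if (compartment == "wc") params$mu_max_wc else params$mu_max_sed
  cost_multiplier(phenotype, params) *
    monod_mu(mu_max, dom, params$k_s) *
    antibiotic_inhibition(a_dissolved, params$mic, phenotype) *
    metal_growth_factor(m, params$k_im)
}

#' Plasmid conjugation rate between a donor and a recipient pool
#'
#' Frequency-dependent horizontal gene transfer
#' \deqn{\beta \, n_d n_r / (n_d + n_r)}: zero when either pool is empty,
#' symmetric in its arguments, bounded by `beta * min(donor, recipient)`.
#'
#' @param beta Conjugation rate constant, 1/h.
#' @param donor,recipient Biomass concentrations, mg/l.
#' @return Transfer rate, mg/l/h (vectorised).
#' @export
conjugation_term <- function(beta, donor, recipient) {
  s <- donor + recipient
  ifelse(s > 0, beta * donor * recipient / s, 0)
}

#' First-order process rate
#'
#' `k * c`; covers antibiotic decay, bacterial death, plasmid segregation
#' and organic-matter hydrolysis.
#'
#' @param k Rate constant, 1/h.
#' @param c Concentration, mg/l.
#' @return Rate, mg/l/h.
#' @export
first_order_term <- function(k, c) k * c

# Internal: all reaction terms for one compartment, vectorised over cells.
# Returns the 9-column rate matrix plus the per-process magnitudes the
# noise model reuses. This is the hot path: branch-free arithmetic, no
# name lookups per cell.
.reaction_terms <- function(S, scenario, compartment) {
  p <- scenario$parameters
  wc <- compartment == "wc"
  off <- if (wc) 0L else 9L
  A <- S[, off + 1L]; M <- S[, off + 2L]; TSS <- S[, off + 3L]
  POM <- S[, off + 4L]; DOM <- S[, off + 5L]
  nf <- S[, off + 6L]; np <- S[, off + 7L]
  nc <- S[, off + 8L]; ncp <- S[, off + 9L]
  k_xa <- if (wc) p$k_xa_wc else p$k_xa_sed
  k_h <- if (wc) p$k_h_wc else p$k_h_sed
  n_max <- if (wc) scenario$n_max_wc else scenario$n_max_sed
  mu_max <- if (wc) p$mu_max_wc else p$mu_max_sed

  # dissolved antibiotic fraction (linear three-phase partitioning)
  a_diss <- A / (1 + p$kd_solid_a * TSS + p$kd_dom_a * DOM)
  N <- nf + np + nc + ncp
  logistic <- 1 - N / n_max

  denom <- p$k_s + DOM
  monod <- mu_max * DOM / (denom + (denom == 0))
  metal <- pmin(1, p$k_im / pmax(M, p$k_im))
  inhib_f <- pmax(0, 1 - a_diss / p$mic)
  mu_base <- monod * metal
  cost_p <- max(0, 1 - p$c_p - p$x_cost)
  cost_c <- max(0, 1 - p$c_c)
  cost_cp <- max(0, 1 - p$c_c - p$c_p - p$x_cost)

  g_f <- logistic * (mu_base * inhib_f) * nf
  g_p <- logistic * (cost_p * mu_base) * np
  g_c <- logistic * (cost_c * mu_base) * nc
  g_cp <- logistic * (cost_cp * mu_base) * ncp

  a_dth <- p$a_death
  d_f <- a_dth * nf; d_p <- a_dth * np
  d_c <- a_dth * nc; d_cp <- a_dth * ncp
  beta <- p$beta_conjugation
  s1 <- nf + np; r_fp <- beta * nf * np / (s1 + (s1 == 0))
  s2 <- nf + ncp; r_fcp <- beta * nf * ncp / (s2 + (s2 == 0))
  s3 <- nc + np; r_cp_ <- beta * nc * np / (s3 + (s3 == 0))
  s4 <- nc + ncp; r_ccp <- beta * nc * ncp / (s4 + (s4 == 0))
  s_p <- p$sa_segregation * np
  s_cp <- p$sa_segregation * ncp

  cons_f <- g_f / p$y_f
  cons <- cons_f + g_p / p$y_p + g_c / p$y_c + g_cp / p$y_cp

  rates <- cbind(
    A = -k_xa * A,
    M = -p$eta_metal * cons,
    TSS = -scenario$z_organic * k_h * TSS,
    POM = a_dth * N - k_h * POM,
    DOM = k_h * POM - cons,
    n_f = g_f - d_f - r_fp - r_fcp + s_p,
    n_p = g_p - d_p + r_fp + r_fcp - s_p,
    n_c = g_c - d_c - r_cp_ - r_ccp + s_cp,
    n_cp = g_cp - d_cp + r_cp_ + r_ccp - s_cp
  )
  list(rates = rates,
       growth = list(f = g_f, p = g_p, c = g_c, cp = g_cp),
       death = list(f = d_f, p = d_p, c = d_c, cp = d_cp),
       death_total = a_dth * N,
       conj = list(fp = r_fp, fcp = r_fcp, cp_ = r_cp_, ccp = r_ccp),
       seg = list(p = s_p, cp = s_cp),
       cons_f = cons_f, degrade_A = k_xa * A, a_diss = a_diss)
}

#' Reaction rate terms for one compartment
#'
#' Assembles every reaction term of the mass balances for one compartment
#' over the spatial grid: first-order antibiotic decay; metal consumption
#' proportional to substrate-linked growth; hydrolysis of the organic TSS
#' fraction; POM gain from bacterial death and loss to hydrolysis; DOM gain
#' from POM hydrolysis and loss to substrate consumption; and for each
#' bacterial phenotype logistic-capped growth, death, the four conjugation
#' channels (susceptible to plasmid-borne, chromosomal to doubly resistant)
#' and the two segregation channels (plasmid loss, returning `p` to `f` and
#' `cp` to `c`). Substrate (and metal) consumption is tied to realised
#' growth, so the yield bookkeeping `growth = Y * consumption` holds
#' exactly, including the logistic cap.
#'
#' @param state A `river_state` matrix (or any matrix with
#'   [state_columns()] columns).
#' @param compartment `"wc"` or `"sed"`.
#' @param scenario A `river_scenario`.
#' @return Matrix (`n_cells` x 9) of time derivatives, mg/l/h, with columns
#'   named as [state_variables()].
#' @export
reaction_rhs <- function(state, compartment, scenario) {
  compartment <- match.arg(compartment, c("wc", "sed"))
  S <- unclass(state)
  if (any(S < 0)) stop("reaction_rhs: negative concentrations in state")
  out <- .reaction_terms(S, scenario, compartment)$rates
  colnames(out) <- state_variables()
  out
}
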