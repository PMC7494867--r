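#' Specify a stochasticity category
#'
#' Selects which process noise terms the Euler-Maruyama engine activates.
#' The three categories group the sensitive parameters by their origin:
#'
#' * `demographic` — noise on the biological process rates governed by the
#'   death rate, half-saturation constant, MIC, water-column maximum growth
#'   rate, segregation rate, susceptible yield coefficient and conjugation
#'   rate: per-phenotype death (both compartments, with the matching POM
#'   gain), the four conjugation channels, the two segregation channels,
#'   and the substrate/metal consumption pathway, whose magnitude
#'   \eqn{\sqrt{\mu_f n_f / Y_f}} is where the growth-governing constants
#'   (maximum growth rate, half-saturation constant, MIC) enter the noise.
#'   No separate noise attaches to the biomass growth term itself.
#' * `environmental` — noise on the physicochemical fate processes governed
#'   by the settling rate, the antibiotic partition coefficients and the
#'   water-column antibiotic degradation rate: settling of the abiotic
#'   pools (particulate antibiotic and metal, TSS, POM) and water-column
#'   antibiotic decay.
#' * `anthropogenic` — noise on the upstream boundary concentrations of
#'   antibiotic and DOM only (see [perturb_boundary()]).
#' * `none` — no noise; the engine follows the deterministic arithmetic
#'   path exactly.
#'
#' Noise draws are scaled standard-normal deviates (the source text's
#' "standard normal distribution between 0 to 1" is read as N(0,1), which
#' its own notation uses); each active process in each grid cell gets an
#' independent draw at every step, except that a mass-transfer pair (e.g.
#' settling loss in the water column and the matching sediment gain) and a
#' gene-flow pair (conjugation/segregation donor loss and recipient gain)
#' share one draw, so their fluctuation conserves volume-weighted mass and
#' total biomass respectively.
#'
#' @param category One of `"none"`, `"demographic"`, `"environmental"`,
#'   `"anthropogenic"`.
#' @param seed Integer seed for the realisation.
#' @param amplitude Common multiplier on every active noise amplitude
#'   (default 1, the Poisson-diffusion magnitude shared by all processes).
#'   Mainly a diagnostic knob: station spread scales linearly with it.
#' @return Object of class `noise_spec` with fields `category`, `seed`,
#'   `amplitude`, `processes` (active process labels) and `parameters`
#'   (the governing constants).
#' @export
#' @examples
#' noise_spec("demographic", seed = 1)$processes
noise_spec <- function(category = c("none", "demographic", "environmental",
                                    "anthropogenic"),
                       seed = 1L, amplitude = 1) {
  category <- match.arg(category)
  if (!is.finite(amplitude) || amplitude < 0) {
    stop("amplitude must be >= 0")
  }
  processes <- switch(category,
    none = character(0),
    demographic = c("death", "conjugation", "segregation", "substrate_use"),
    environmental = c("settling_abiotic", "degradation_A_wc"),
    anthropogenic = c("boundary_A", "boundary_DOM")
  )
  parameters <- switch(category,
    none = character(0),
    demographic = c("a_death", "k_s", "mic", "mu_max_wc", "sa_segregation",
                    "y_f", "beta_conjugation"),
    environmental = c("kd_dom_a", "kd_solid_a", "k_set", "k_xa_wc"),
    anthropogenic = character(0)
  )
  structure(list(category = category, seed = as.integer(seed),
                 amplitude = amplitude,
                 processes = processes, parameters = parameters),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("<noise_spec> category = %s, seed = %d\n", x$category, x$seed))
  if (length(x$processes)) {
    cat("  processes:", paste(x$processes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Draw scaled noise deviates
#'
#' Standard-normal draws scaled by the time step,
#' \deqn{\xi = z / \sqrt{\Delta t}, \quad z \sim N(0,1),}
#' so that an increment `sqrt(rate) * xi * dt` has variance `rate * dt`
#' regardless of `dt` (the random-walk scaling of the diffusion
#' approximation). Draws come from R's global RNG stream; seed it (e.g. via
#' the engine, which seeds from the `noise_spec`) for reproducibility.
#'
#' @param dt Time step, h (> 0).
#' @param n Number of independent draws.
#' @return Numeric vector of length `n`.
#' @export
draw_noise <- function(dt, n = 1L) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  stats::rnorm(n) / sqrt(dt)
}

#' Stochastic increment of a process under the Poisson diffusion
#' approximation
#'
#' A process with deterministic rate `r` (events contributing mass at mean
#' rate `r` per hour) fluctuates with variance equal to its mean, so its
#' integrated stochastic contribution over one step is
#' \deqn{\sqrt{r}\,\xi\,\Delta t = \sqrt{r \Delta t}\, z.}
#' Summed over an interval `T` the increments have variance `r * T`,
#' independent of the step size. Negative rates are clamped to zero before
#' the square root.
#'
#' @param rate Deterministic process rate, mg/l/h (vectorised).
#' @param dt Time step, h.
#' @param xi Optional pre-drawn deviates from [draw_noise()] (same length
#'   as `rate`); drawn internally when omitted.
#' @return Stochastic increments, mg/l.
#' @export
stochastic_increment <- function(rate, dt, xi = NULL) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (is.null(xi)) xi <- draw_noise(dt, length(rate))
  sqrt(pmax(rate, 0)) * xi * dt
}

#' Perturb upstream boundary values (anthropogenic noise)
#'
#' Under the anthropogenic category the upstream antibiotic and DOM
#' loadings receive an additive zero-mean perturbation with the Poisson
#' diffusion amplitude, `sqrt(value) * xi * dt`, clamped at zero; every
#' other boundary value and every other category leaves the boundary
#' untouched. Two draws (antibiotic first, then DOM) are consumed per call.
#'
#' @param bc A [boundary_conditions()] vector.
#' @param noise A `noise_spec`.
#' @param dt Time step, h.
#' @return A boundary vector of the same shape.
#' @export
perturb_boundary <- function(bc, noise, dt) {
  if (is.null(noise) || noise$category != "anthropogenic") return(bc)
  amp <- if (is.null(noise$amplitude)) 1 else noise$amplitude
  for (v in c("A", "DOM")) {
    bc[[v]] <- max(0, bc[[v]] + amp * stochastic_increment(bc[[v]], dt))
  }
  bc
}
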