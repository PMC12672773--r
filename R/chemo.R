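#' One alternating-direction implicit diffusion step
#'
#' Advances the drug field by one diffusion step of `dC/dt = D_c * lap(C)`
#' using an alternating-direction implicit scheme: a row-implicit sweep
#' followed by a column-implicit sweep, each solving a tridiagonal system per
#' line (fully implicit in its direction, so the update is unconditionally
#' stable and positivity-preserving at any diffusion number). While dosing,
#' the outermost rows and columns are held at the boundary dose `C_b`
#' (Dirichlet, drug influx from the periphery); between doses the boundary is
#' zero-flux (Neumann), under which total mass is conserved exactly, or
#' absorbing (zero Dirichlet) when `rest_bc = "absorbing"`.
#'
#' @param drug Non-negative numeric matrix of concentrations.
#' @param D_c Diffusion coefficient in lattice^2/step.
#' @param dosing_active Logical; apply Dirichlet `C_b` boundaries?
#' @param C_b Boundary concentration during dosing.
#' @param substeps Number of equal substeps the step is split into.
#' @param rest_bc Rest-period boundary condition, `"neumann"` or
#'   `"absorbing"`.
#' @return The diffused concentration matrix (non-negative).
#' @examples
#' u <- matrix(1, 10, 10)
#' identical(diffuse_adi(u, 5, FALSE, 0), u) # uniform field is a fixed point
#' @export
diffuse_adi <- function(drug, D_c, dosing_active = FALSE, C_b = 0,
                        substeps = 1L, rest_bc = c("neumann", "absorbing")) {
  rest_bc <- match.arg(rest_bc)
  if (!all(is.finite(drug)))
    stop("drug field contains non-finite values", call. = FALSE)
  if (D_c < 0) stop("'D_c' must be non-negative", call. = FALSE)
  adi_cpp(drug, D_c, isTRUE(dosing_active), C_b, as.integer(substeps),
          rest_bc == "neumann")
}

#' Per-step drug decay and tumor uptake
#'
#' Applies the operational decay/uptake rule: every site retains
#' `decay_factor` of its drug, and sites occupied by a tumor cell
#' additionally lose `uptake_fraction` of the post-decay local drug
#' (absorbed by the cell). Astrocytes and neutral agents absorb nothing.
#' The result is clipped at zero.
#'
#' @param drug Numeric concentration matrix.
#' @param world An `astro_world` aligned with `drug`.
#' @param params A [chemo_params()] object.
#' @return The updated concentration matrix.
#' @export
decay_and_uptake <- function(drug, world, params) {
  stopifnot(all(dim(drug) == dim(world$states)))
  out <- drug * params$decay_factor
  tum <- world$states == STATE_CODES[["TUMOR"]]
  out[tum] <- out[tum] * (1 - params$uptake_fraction)
  out[out < 0] <- 0
  out
}

#' Effective drug concentration under gap-junction protection
#'
#' The drug concentration a tumor cell senses is reduced in proportion to the
#' number of pro-metastatic astrocytes in its direct Moore neighborhood:
#' `C_eff = C * (1 - G_f * n_pro / 8)`. With `G_f = 1` and all eight
#' neighbors pro-metastatic the blockade is complete.
#'
#' @param C_local Local drug concentration (vectorized).
#' @param n_pro_moore Number of pro-metastatic astrocyte Moore neighbors,
#'   0--8 (vectorized).
#' @param G_f Gap-junction modulation factor in `[0, 1]`.
#' @return Effective concentration in `[C * (1 - G_f), C]`.
#' @examples
#' effective_concentration(1, 4, 0.5) # 0.75
#' @export
effective_concentration <- function(C_local, n_pro_moore, G_f) {
  if (any(n_pro_moore < 0 | n_pro_moore > 8))
    stop("'n_pro_moore' must be between 0 and 8", call. = FALSE)
  C_local * (1 - G_f * n_pro_moore / 8)
}

#' Chemotherapy death probability
#'
#' Sigmoidal kill curve in the effective local concentration:
#' `1 / (1 + exp(-k * (C_eff - T_half)))`. Each tumor cell draws an
#' independent death decision per dosing step; death removes the cell,
#' leaving the site empty. Astrocytes and neutral agents are unaffected by
#' drug.
#'
#' @param C_eff Effective concentration (non-negative; vectorized).
#' @param k Kill-curve steepness.
#' @param T_half Half-maximal concentration.
#' @return Death probability in `(0, 1)`.
#' @examples
#' death_probability(0.5, 20, 0.5) # 0.5 at the half-max concentration
#' @export
death_probability <- function(C_eff, k, T_half) {
  if (any(C_eff < 0)) stop("'C_eff' must be non-negative", call. = FALSE)
  1 / (1 + exp(-k * (C_eff - T_half)))
}

#' Is drug being applied at a given step?
#'
#' Therapy is triggered once the tumor count reaches the start threshold
#' (evaluated at the end of a step; dosing begins the following step) and
#' then follows a repeating cycle of `steps_on` dosing steps and
#' `steps_off` rest steps: offsets 0 to `steps_on - 1` of each cycle are
#' dosing, the remainder rest.
#'
#' @param step_index Step label (vectorized).
#' @param therapy_start_step First dosing step, or `NA` if therapy has not
#'   been triggered.
#' @param steps_on,steps_off Cycle structure (defaults 14 and 7).
#' @return Logical vector.
#' @examples
#' dosing_active(0:22, 1) # TRUE for steps 1..14, FALSE 15..21, TRUE 22
#' @export
dosing_active <- function(step_index, therapy_start_step, steps_on = 14L,
                          steps_off = 7L) {
  if (is.null(therapy_start_step) || is.na(therapy_start_step))
    return(rep(FALSE, length(step_index)))
  cycle <- steps_on + steps_off
  offset <- step_index - therapy_start_step
  offset >= 0 & (offset %% cycle) < steps_on
}
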