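#' Astrocyte-tumor interaction parameters
#'
#' Bundles the six swept interaction parameters together with the fixed
#' distance-kernel constants and the derived normalization constant
#' `i_max`. The same kernel (steepness `S = 3`, half-maximal distance
#' `d = 1.5` lattice units) is shared by the tumor-on-astrocyte and
#' astrocyte-on-tumor influence sums, and `i_max` is the maximum cumulative
#' influence achievable over the full 7x7 neighborhood at unit per-cell
#' magnitude (about 7.23); it normalizes both sums.
#'
#' @param alpha Suppression magnitude of an anti-metastatic astrocyte on
#'   tumor division, in `[0, 1]`.
#' @param beta Promotion magnitude of a pro-metastatic astrocyte on tumor
#'   division, in `[0, 1]`.
#' @param theta Conversion threshold: normalized tumor influence at which the
#'   astrocyte switching probability is 50%, in `[0, 1]`.
#' @param kappa Influence magnitude each tumor cell exerts on a nearby
#'   astrocyte, in `[0, 1]`.
#' @param switch_sensitivity Steepness `S_A` of the switching sigmoid;
#'   canonical levels are 8, 16, 32.
#' @param division_sensitivity Steepness `S_T` of the division sigmoid;
#'   canonical levels are 4, 8, 16.
#' @param kernel_steepness Distance-kernel steepness `S` (fixed at 3).
#' @param kernel_half_distance Distance at which the kernel weight halves
#'   (fixed at 1.5 lattice units; 1 lattice unit = 25 micrometres).
#' @param radius Interaction neighborhood radius in sites (3 gives the 7x7
#'   window).
#'
#' @return A list of class `interaction_params` including the derived
#'   normalization constant `i_max`.
#' @examples
#' p <- interaction_params()
#' p$i_max # ~ 7.23
#' @export
interaction_params <- function(alpha = 0.15, beta = 0.85, theta = 0.25,
                               kappa = 1, switch_sensitivity = 32,
                               division_sensitivity = 8,
                               kernel_steepness = 3,
                               kernel_half_distance = 1.5,
                               radius = 3L) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(theta),
            is.numeric(kappa))
  check_unit <- function(x, name) {
    if (length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop(sprintf("'%s' must be a single value in [0, 1]", name),
           call. = FALSE)
  }
  check_unit(alpha, "alpha"); check_unit(beta, "beta")
  check_unit(theta, "theta"); check_unit(kappa, "kappa")
  if (switch_sensitivity <= 0 || division_sensitivity <= 0)
    stop("sensitivities must be positive", call. = FALSE)
  radius <- as.integer(radius)
  if (radius < 1L) stop("'radius' must be >= 1", call. = FALSE)
  p <- list(alpha = alpha, beta = beta, theta = theta, kappa = kappa,
            switch_sensitivity = switch_sensitivity,
            division_sensitivity = division_sensitivity,
            kernel_steepness = kernel_steepness,
            kernel_half_distance = kernel_half_distance,
            radius = radius)
  p$i_max <- max_cumulative_influence(radius, kernel_steepness,
                                      kernel_half_distance)
  class(p) <- "interaction_params"
  p
}

#' Chemotherapy parameters
#'
#' Drug-field and kill-curve constants for the chemotherapy module. The drug
#' diffuses with coefficient `D_c` (lattice^2 per 17-hour step), decays by the
#' per-step retention factor `decay_factor`, and tumor-occupied sites absorb
#' `uptake_fraction` of the post-decay local drug. During dosing the lattice
#' boundary is held at `C_b` (Dirichlet); between doses a zero-flux boundary
#' is used (or zero-Dirichlet when `rest_bc = "absorbing"`). Therapy starts
#' once the tumor population reaches `start_threshold` cells and then cycles
#' `steps_on` dosing steps followed by `steps_off` rest steps.
#'
#' The numeric defaults are artifact calibrations, not published values: the
#' boundary dose is normalized to 1, the kill curve reaches half-maximum at
#' half the boundary dose (`T = 0.5`, `k = 20`, so a cell bathed at the full
#' boundary dose is almost certainly killed while a cell below ~0.35 dose
#' units is essentially safe), and `D_c = 2500` is the order implied by
#' small-molecule diffusivity (~1e-6 cm^2/s) over a 25-micrometre site and a
#' 17-hour step, reduced for brain-tissue tortuosity.
#'
#' @param D_c Diffusion coefficient, lattice^2/step.
#' @param decay_factor Per-step retention multiplier in `(0, 1]`.
#' @param C_b Boundary drug concentration applied while dosing.
#' @param uptake_fraction Fraction of post-decay local drug absorbed per
#'   tumor cell per step, in `[0, 1]`.
#' @param G_f Gap-junction modulation factor in `[0, 1]`: maximal fractional
#'   reduction of the drug a tumor cell senses when all 8 Moore neighbors are
#'   pro-metastatic astrocytes.
#' @param k Kill-curve steepness.
#' @param T_half Kill-curve half-maximal concentration.
#' @param start_threshold Tumor count that triggers therapy.
#' @param steps_on,steps_off Dosing and rest steps per cycle.
#' @param substeps ADI substeps per agent step (accuracy control; the solver
#'   is unconditionally stable).
#' @param rest_bc Boundary condition between doses: `"neumann"` (zero flux,
#'   default) or `"absorbing"` (zero Dirichlet).
#'
#' @return A list of class `chemo_params`.
#' @export
chemo_params <- function(D_c = 2500, decay_factor = 0.9, C_b = 1,
                         uptake_fraction = 0.05, G_f = 1, k = 20,
                         T_half = 0.5, start_threshold = 3000L,
                         steps_on = 14L, steps_off = 7L, substeps = 1L,
                         rest_bc = c("neumann", "absorbing")) {
  rest_bc <- match.arg(rest_bc)
  if (D_c < 0) stop("'D_c' must be non-negative", call. = FALSE)
  if (decay_factor <= 0 || decay_factor > 1)
    stop("'decay_factor' must be in (0, 1]", call. = FALSE)
  if (C_b < 0) stop("'C_b' must be non-negative", call. = FALSE)
  if (uptake_fraction < 0 || uptake_fraction > 1)
    stop("'uptake_fraction' must be in [0, 1]", call. = FALSE)
  if (G_f < 0 || G_f > 1) stop("'G_f' must be in [0, 1]", call. = FALSE)
  if (k < 0 || T_half < 0)
    stop("kill-curve parameters must be non-negative", call. = FALSE)
  if (steps_on < 1L || steps_off < 0L)
    stop("'steps_on' must be >= 1 and 'steps_off' >= 0", call. = FALSE)
  p <- list(D_c = D_c, decay_factor = decay_factor, C_b = C_b,
            uptake_fraction = uptake_fraction, G_f = G_f, k = k,
            T_half = T_half, start_threshold = as.integer(start_threshold),
            steps_on = as.integer(steps_on), steps_off = as.integer(steps_off),
            substeps = as.integer(substeps), rest_bc = rest_bc)
  class(p) <- "chemo_params"
  p
}

#' Simulation configuration
#'
#' Assembles a full run configuration: grid shape, step count, astrocyte
#' density and seeding pattern, whether phenotype switching is enabled, the
#' interaction parameters, optional chemotherapy parameters, and the RNG seed.
#' The total non-tumor occupancy (astrocytes plus neutral backfill) is fixed
#' at half the grid (45,000 agents on the default 300 x 300 lattice), so
#' density only redistributes occupancy between astrocytes and inert neutral
#' agents.
#'
#' @param rows,cols Lattice dimensions (default 300 x 300).
#' @param n_steps Number of 17-hour steps to simulate (default 150, about 3.5
#'   months).
#' @param density Fraction of the grid initially astrocyte-occupied, in
#'   `[0, 0.5]`.
#' @param pattern Seeding pattern, one of [seeding_patterns()].
#' @param switching_enabled If `FALSE`, astrocytes never leave the
#'   anti-metastatic state.
#' @param interaction An [interaction_params()] object.
#' @param chemo A [chemo_params()] object, or `NULL` for untreated runs.
#' @param seed Integer RNG seed.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(density = 0.3, pattern = "radial", seed = 7)
#' @export
sim_config <- function(rows = 300L, cols = 300L, n_steps = 150L,
                       density = 0.5, pattern = "random",
                       switching_enabled = TRUE,
                       interaction = interaction_params(),
                       chemo = NULL, seed = 1L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 7L || cols < 7L)
    stop("grid must be at least 7 x 7", call. = FALSE)
  if (!is.numeric(density) || length(density) != 1 || is.na(density) ||
      density < 0 || density > 0.5)
    stop("'density' must be in [0, 0.5]", call. = FALSE)
  if (!pattern %in% seeding_patterns())
    stop(sprintf("unknown seeding pattern '%s'; choose one of %s", pattern,
                 paste(seeding_patterns(), collapse = ", ")), call. = FALSE)
  if (!inherits(interaction, "interaction_params"))
    stop("'interaction' must be an interaction_params object", call. = FALSE)
  if (!is.null(chemo) && !inherits(chemo, "chemo_params"))
    stop("'chemo' must be NULL or a chemo_params object", call. = FALSE)
  cfg <- list(rows = rows, cols = cols, n_steps = as.integer(n_steps),
              density = density, pattern = pattern,
              switching_enabled = isTRUE(switching_enabled),
              interaction = interaction, chemo = chemo,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d x %d grid, %d steps, density %.3f (%s)\n",
              x$rows, x$cols, x$n_steps, x$density, x$pattern))
  cat(sprintf("  switching %s | chemo %s | seed %d\n",
              if (x$switching_enabled) "on" else "off",
              if (is.null(x$chemo)) "off" else "on", x$seed))
  ip <- x$interaction
  cat(sprintf("  alpha %.3g beta %.3g theta %.3g kappa %.3g S_A %g S_T %g\n",
              ip$alpha, ip$beta, ip$theta, ip$kappa,
              ip$switch_sensitivity, ip$division_sensitivity))
  invisible(x)
}
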