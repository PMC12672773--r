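#' Sigmoidal distance weight of a single cell's influence
#'
#' The influence a cell exerts at Euclidean distance `distance` decays as a
#' logistic function of distance: `magnitude / (1 + exp(S * (distance - d)))`.
#' The weight is strictly decreasing in distance, bounded by
#' `(0, magnitude]`, and reaches half its magnitude at `distance = d`.
#'
#' @param distance Euclidean distance in lattice units (non-negative;
#'   vectorized).
#' @param magnitude Per-cell influence magnitude (e.g. `kappa`, `alpha`,
#'   `beta`).
#' @param S Kernel steepness (default 3).
#' @param d Half-maximal distance (default 1.5 lattice units).
#' @return Numeric vector of weights.
#' @examples
#' influence_weight(1.5, 1) # exactly 0.5
#' influence_weight(1, 1)   # ~ 0.8176
#' @export
influence_weight <- function(distance, magnitude = 1, S = 3, d = 1.5) {
  if (any(distance < 0))
    stop("'distance' must be non-negative", call. = FALSE)
  magnitude / (1 + exp(S * (distance - d)))
}

# Offsets of the square neighborhood of the given radius, excluding the
# center, with Euclidean distances and unit-magnitude kernel weights.
# Used both by the R-level operations and to feed the compiled step kernel.
kernel_offsets <- function(radius = 3L, S = 3, d = 1.5) {
  o <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  o <- o[!(o$dr == 0 & o$dc == 0), , drop = FALSE]
  o$distance <- sqrt(o$dr^2 + o$dc^2)
  o$weight <- influence_weight(o$distance, 1, S, d)
  rownames(o) <- NULL
  o
}

#' Maximum cumulative influence over the interaction neighborhood
#'
#' Sum of the unit-magnitude distance weights over every site of the
#' `(2*radius+1)^2` square neighborhood excluding the center. This is the
#' theoretical maximum cumulative influence a site can receive (all 48
#' neighbors occupied at unit per-cell magnitude for radius 3) and is used as
#' the normalization constant for both the astrocyte-facing and tumor-facing
#' influence sums. At the default constants it is about 7.23.
#'
#' @param radius Neighborhood radius in sites (default 3).
#' @inheritParams influence_weight
#' @return A single number, `I_max`.
#' @examples
#' max_cumulative_influence() # ~ 7.23
#' @export
max_cumulative_influence <- function(radius = 3L, S = 3, d = 1.5) {
  if (radius < 1L) stop("'radius' must be >= 1", call. = FALSE)
  sum(kernel_offsets(as.integer(radius), S, d)$weight)
}

#' Cumulative tumor influence on an astrocyte
#'
#' Sums the distance-weighted contributions (magnitude `kappa`) of every
#' tumor cell within the radius-`radius` square neighborhood of `site`.
#' Neighborhoods are truncated at the grid edge (no wraparound).
#'
#' @param world An `astro_world` object.
#' @param site Integer `(row, col)` of an astrocyte site (1-based).
#' @param params An [interaction_params()] object.
#' @return The raw cumulative influence `I_total_A` (0 when no tumor cells
#'   are in range).
#' @export
cumulative_tumor_influence <- function(world, site, params = interaction_params()) {
  nb <- neighborhood_sites(site, params$radius, dim(world$states))
  if (nrow(nb) == 0) return(0)
  tum <- world$states[cbind(nb$row, nb$col)] == STATE_CODES[["TUMOR"]]
  sum(influence_weight(nb$distance[tum], params$kappa,
                       params$kernel_steepness, params$kernel_half_distance))
}

#' Astrocyte switching probability
#'
#' Probability that an anti-metastatic astrocyte switches to the
#' pro-metastatic phenotype this step, as a sigmoid of its normalized
#' cumulative tumor influence:
#' `1 / (1 + exp(-S_A * (i_norm - theta)))`. At `i_norm = theta` the
#' probability is exactly 50%. The probability is recomputed from the current
#' neighborhood at every step, and is strictly positive even at zero
#' influence (a small "leak" of `1 / (1 + exp(S_A * theta))`).
#'
#' @param i_norm Normalized influence in `[0, 1]` (vectorized).
#' @param params An [interaction_params()] object supplying
#'   `switch_sensitivity` and `theta`.
#' @return Switching probability in `(0, 1)`.
#' @examples
#' p <- interaction_params(theta = 0.25)
#' switch_probability(0.25, p) # exactly 0.5
#' @export
switch_probability <- function(i_norm, params = interaction_params()) {
  if (any(i_norm < 0 | i_norm > 1))
    stop("'i_norm' must lie in [0, 1]", call. = FALSE)
  1 / (1 + exp(-params$switch_sensitivity * (i_norm - params$theta)))
}

#' Stochastic astrocyte phenotype update
#'
#' Draws one uniform number and returns `"ASTRO_PRO"` if it falls below the
#' switching probability computed from the astrocyte's current normalized
#' tumor influence, else `"ASTRO_ANTI"`. Pro-metastatic astrocytes are
#' irreversible: called on an `ASTRO_PRO` site the function returns
#' `"ASTRO_PRO"` without consuming a draw.
#'
#' @inheritParams cumulative_tumor_influence
#' @return The updated state name, `"ASTRO_ANTI"` or `"ASTRO_PRO"`.
#' @export
update_astrocyte <- function(world, site, params = interaction_params()) {
  st <- world$states[site[1], site[2]]
  if (st == STATE_CODES[["ASTRO_PRO"]]) return("ASTRO_PRO")
  if (st != STATE_CODES[["ASTRO_ANTI"]])
    stop("site does not hold an astrocyte", call. = FALSE)
  i_norm <- min(cumulative_tumor_influence(world, site, params) / params$i_max, 1)
  if (stats::runif(1) < switch_probability(i_norm, params)) "ASTRO_PRO"
  else "ASTRO_ANTI"
}

#' Net astrocyte influence on a tumor cell
#'
#' Signed sum of distance-weighted astrocyte contributions within the
#' interaction neighborhood of a tumor cell: anti-metastatic astrocytes
#' contribute `-alpha` weights, pro-metastatic astrocytes `+beta` weights;
#' neutral agents and other tumor cells contribute nothing.
#'
#' @inheritParams cumulative_tumor_influence
#' @return The signed raw influence `I_total_T`.
#' @export
net_astrocyte_influence <- function(world, site, params = interaction_params()) {
  nb <- neighborhood_sites(site, params$radius, dim(world$states))
  if (nrow(nb) == 0) return(0)
  st <- world$states[cbind(nb$row, nb$col)]
  w <- influence_weight(nb$distance, 1, params$kernel_steepness,
                        params$kernel_half_distance)
  sum(w[st == STATE_CODES[["ASTRO_PRO"]]]) * params$beta -
    sum(w[st == STATE_CODES[["ASTRO_ANTI"]]]) * params$alpha
}

#' Tumor division probability
#'
#' Sigmoid of the normalized net astrocyte influence,
#' `1 / (1 + exp(-S_T * i_norm_T))`. With no astrocytes in range the
#' probability is exactly 0.5 per 17-hour step, matching a ~34-hour doubling
#' time; anti-metastatic neighborhoods push it toward 0 and pro-metastatic
#' neighborhoods toward 1.
#'
#' @param i_norm_T Normalized net influence in `[-1, 1]` (vectorized).
#' @param S_T Division sensitivity (canonical levels 4, 8, 16).
#' @return Division probability in `(0, 1)`.
#' @examples
#' division_probability(0, 8) # 0.5
#' @export
division_probability <- function(i_norm_T, S_T = 8) {
  if (any(i_norm_T < -1 | i_norm_T > 1))
    stop("'i_norm_T' must lie in [-1, 1]", call. = FALSE)
  1 / (1 + exp(-S_T * i_norm_T))
}

#' Stochastic tumor division attempt
#'
#' Draws the division uniform; if it falls below the astrocyte-adjusted
#' division probability and at least one Moore-8 neighbor site is empty, a
#' daughter tumor cell is placed on one empty Moore neighbor chosen uniformly
#' (a second, separate draw). The parent always persists.
#'
#' @inheritParams cumulative_tumor_influence
#' @param p_div Optional override of the division probability (otherwise
#'   computed from the world).
#' @return A list with `divided` (logical), `daughter` (`c(row, col)` or
#'   `NULL`) and the updated `world`.
#' @export
attempt_division <- function(world, site, params = interaction_params(),
                             p_div = NULL) {
  if (world$states[site[1], site[2]] != STATE_CODES[["TUMOR"]])
    stop("site does not hold a tumor cell", call. = FALSE)
  if (is.null(p_div)) {
    i_norm <- clamp(net_astrocyte_influence(world, site, params) / params$i_max,
                    -1, 1)
    p_div <- division_probability(i_norm, params$division_sensitivity)
  }
  u <- stats::runif(1)
  if (u >= p_div)
    return(list(divided = FALSE, daughter = NULL, world = world))
  nb <- moore_neighbors(site, dim(world$states))
  empty <- nb[world$states[cbind(nb$row, nb$col)] == STATE_CODES[["EMPTY"]], ,
              drop = FALSE]
  if (nrow(empty) == 0)
    return(list(divided = FALSE, daughter = NULL, world = world))
  j <- min(floor(stats::runif(1) * nrow(empty)), nrow(empty) - 1) + 1
  daughter <- c(empty$row[j], empty$col[j])
  world$states[daughter[1], daughter[2]] <- STATE_CODES[["TUMOR"]]
  list(divided = TRUE, daughter = daughter, world = world)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
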