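#' Integer codes of the lattice agent states
#'
#' Each lattice site holds exactly one agent state: `EMPTY` (0), `TUMOR` (1),
#' `ASTRO_ANTI` (2), `ASTRO_PRO` (3) or `NEUTRAL` (4). The same codes are
#' used in snapshot files.
#'
#' @format Named integer vector.
#' @export
STATE_CODES <- c(EMPTY = 0L, TUMOR = 1L, ASTRO_ANTI = 2L, ASTRO_PRO = 3L,
                 NEUTRAL = 4L)

#' Sites of a truncated square neighborhood
#'
#' All on-grid sites with `|drow| <= radius` and `|dcol| <= radius` around
#' `site`, excluding `site` itself, each with its Euclidean distance in
#' lattice units. Sites beyond the grid edge are omitted (truncated
#' neighborhood; no wraparound or mirroring).
#'
#' @param site Integer `(row, col)`, 1-based, on the grid.
#' @param radius Neighborhood radius (>= 1); 3 gives the 7x7 window.
#' @param dim Grid dimensions `c(rows, cols)`.
#' @return A data.frame with columns `row`, `col`, `distance`.
#' @examples
#' nrow(neighborhood_sites(c(5, 5), 1, c(10, 10))) # 8 (Moore neighborhood)
#' nrow(neighborhood_sites(c(5, 5), 3, c(10, 10))) # 48
#' nrow(neighborhood_sites(c(1, 1), 3, c(10, 10))) # 15 (corner truncation)
#' @export
neighborhood_sites <- function(site, radius = 3L, dim = c(300L, 300L)) {
  radius <- as.integer(radius)
  if (radius < 1L) stop("'radius' must be >= 1", call. = FALSE)
  if (site[1] < 1 || site[1] > dim[1] || site[2] < 1 || site[2] > dim[2])
    stop("'site' is off the grid", call. = FALSE)
  o <- kernel_offsets(radius)
  r <- site[1] + o$dr
  c <- site[2] + o$dc
  keep <- r >= 1 & r <= dim[1] & c >= 1 & c <= dim[2]
  data.frame(row = r[keep], col = c[keep], distance = o$distance[keep])
}

# Moore-8 neighbors of a site, truncated at the grid edge, in fixed
# row-major offset order (the order used for division placement).
moore_neighbors <- function(site, dim) {
  o <- moore_offsets()
  r <- site[1] + o[, 1]
  c <- site[2] + o[, 2]
  keep <- r >= 1 & r <= dim[1] & c >= 1 & c <= dim[2]
  data.frame(row = r[keep], col = c[keep])
}

moore_offsets <- function() {
  cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
        dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
}

#' Initialize a simulation world
#'
#' Builds the lattice in its initial condition: one tumor cell at the central
#' site, astrocytes placed by the configured seeding pattern at the requested
#' density (all anti-metastatic), neutral agents backfilled uniformly at
#' random so astrocytes plus neutrals total half the grid, a zero drug field,
#' and step counter 0. Placement consumes the current RNG stream; seed it (or
#' use [run_simulation()], which seeds from `config$seed`) for reproducible
#' layouts.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `astro_world`: a list with integer matrix
#'   `states`, numeric matrix `drug`, `step_index`, and
#'   `therapy_start_step` (`NA` until the tumor reaches the therapy
#'   threshold).
#' @examples
#' set.seed(1)
#' w <- create_world(sim_config(rows = 50, cols = 50, density = 0.2))
#' table(w$states)
#' @export
create_world <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- generate_layout(config$pattern, config$density,
                            config$rows, config$cols)
  states <- matrix(STATE_CODES[["EMPTY"]], config$rows, config$cols)
  center <- center_site(config$rows, config$cols)
  states[center[1], center[2]] <- STATE_CODES[["TUMOR"]]
  if (nrow(layout$astrocyte_sites))
    states[as.matrix(layout$astrocyte_sites)] <- STATE_CODES[["ASTRO_ANTI"]]
  if (nrow(layout$neutral_sites))
    states[as.matrix(layout$neutral_sites)] <- STATE_CODES[["NEUTRAL"]]
  w <- list(states = states,
            drug = matrix(0, config$rows, config$cols),
            step_index = 0L,
            therapy_start_step = NA_integer_)
  class(w) <- "astro_world"
  w
}

center_site <- function(rows, cols) c(rows %/% 2L + 1L, cols %/% 2L + 1L)

#' Count agents by state
#'
#' @param world An `astro_world`.
#' @return Named integer vector over the five agent states.
#' @export
state_counts <- function(world) {
  tab <- tabulate(world$states + 1L, nbins = 5L)
  names(tab) <- names(STATE_CODES)
  tab
}

#' @export
print.astro_world <- function(x, ...) {
  cts <- state_counts(x)
  cat(sprintf("<astro_world> %d x %d, step %d\n", nrow(x$states),
              ncol(x$states), x$step_index))
  cat(sprintf("  tumor %d | anti %d | pro %d | neutral %d | empty %d\n",
              cts[["TUMOR"]], cts[["ASTRO_ANTI"]], cts[["ASTRO_PRO"]],
              cts[["NEUTRAL"]], cts[["EMPTY"]]))
  if (!is.na(x$therapy_start_step))
    cat(sprintf("  therapy started at step %d\n", x$therapy_start_step))
  invisible(x)
}

#' Advance the world by one time step
#'
#' Applies one full 17-hour step in the fixed order of the update scheme:
#' (1) astrocyte switching sweep over anti-metastatic sites in a fresh
#' uniformly random order; (2) tumor sweep in a fresh random order, where
#' each tumor cell computes its astrocyte-adjusted division probability,
#' attempts division into an empty Moore neighbor, and (while dosing is
#' active) draws an independent chemotherapy death; (3) drug-field update
#' (ADI diffusion, then decay and tumor uptake) when chemotherapy is
#' configured. Cells born during the step do not act until the next step;
#' astrocytes switched during the step do influence the subsequent tumor
#' sweep. Therapy is triggered on the tumor count at the end of a step and
#' dosing begins at the next step.
#'
#' The update consumes the current R RNG stream; identical
#' `(config, .Random.seed)` give bit-identical results.
#'
#' @param world An `astro_world`.
#' @param config The [sim_config()] the world was created from.
#' @return The updated `astro_world` with `step_index` incremented.
#' @export
advance_step <- function(world, config) {
  stopifnot(inherits(world, "astro_world"), inherits(config, "sim_config"))
  ip <- config$interaction
  ch <- config$chemo
  step_label <- world$step_index + 1L
  dosing <- dosing_active(step_label, world$therapy_start_step,
                          if (is.null(ch)) 14L else ch$steps_on,
                          if (is.null(ch)) 7L else ch$steps_off)
  off <- kernel_offsets(ip$radius, ip$kernel_steepness, ip$kernel_half_distance)
  res <- step_cpp(world$states, world$drug,
                  as.integer(off$dr), as.integer(off$dc), off$weight,
                  ip$alpha, ip$beta, ip$theta, ip$kappa,
                  ip$switch_sensitivity, ip$division_sensitivity, ip$i_max,
                  config$switching_enabled,
                  !is.null(ch), dosing,
                  if (is.null(ch)) 0 else ch$D_c,
                  if (is.null(ch)) 1 else ch$decay_factor,
                  if (is.null(ch)) 0 else ch$C_b,
                  if (is.null(ch)) 0 else ch$uptake_fraction,
                  if (is.null(ch)) 0 else ch$G_f,
                  if (is.null(ch)) 1 else ch$k,
                  if (is.null(ch)) 0 else ch$T_half,
                  if (is.null(ch)) 1L else ch$substeps,
                  if (is.null(ch)) TRUE else ch$rest_bc == "neumann")
  world$states <- res$states
  world$drug <- res$drug
  world$step_index <- step_label
  if (!is.null(ch) && is.na(world$therapy_start_step)) {
    if (sum(world$states == STATE_CODES[["TUMOR"]]) >= ch$start_threshold)
      world$therapy_start_step <- step_label + 1L
  }
  world
}

#' Run a full simulation
#'
#' Creates the world from `config`, seeds the RNG from `config$seed`, and
#' advances `config$n_steps` steps, recording per-step population counts and
#' mean drug concentration (and, optionally, boundary morphometrics).
#' The caller's RNG state is restored on exit.
#'
#' @param config A [sim_config()] object.
#' @param metrics If `TRUE`, compute fractal dimension, lacunarity and
#'   eccentricity at steps selected by `metric_every` and at the final step.
#' @param metric_every Spacing (in steps) of morphometric evaluation; `NA`
#'   (default) computes metrics at the final step only.
#' @param keep_world If `TRUE` (default) the final world is returned.
#' @return An object of class `astro_sim`: list with `timeseries`
#'   (data.frame of step, tumor_count, anti_count, pro_count, mean_drug and
#'   any metric columns), `world`, `config`, and `therapy_start_step`.
#' @examples
#' sim <- run_simulation(sim_config(rows = 60, cols = 60, n_steps = 10,
#'                                  density = 0.2, seed = 3))
#' tail(sim$timeseries)
#' @export
run_simulation <- function(config, metrics = FALSE, metric_every = NA,
                           keep_world = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  world <- create_world(config)
  rows <- vector("list", config$n_steps + 1L)
  rows[[1]] <- record_row(world, 0L, config, metrics && !is.na(metric_every))
  for (s in seq_len(config$n_steps)) {
    world <- advance_step(world, config)
    want_metrics <- metrics &&
      (s == config$n_steps ||
         (!is.na(metric_every) && s %% metric_every == 0L))
    rows[[s + 1L]] <- record_row(world, s, config, want_metrics)
  }
  ts <- do.call(rbind, rows)
  out <- list(timeseries = ts,
              world = if (keep_world) world else NULL,
              config = config,
              therapy_start_step = world$therapy_start_step)
  class(out) <- "astro_sim"
  out
}

record_row <- function(world, step, config, with_metrics) {
  cts <- state_counts(world)
  row <- data.frame(step = step,
                    tumor_count = cts[["TUMOR"]],
                    anti_count = cts[["ASTRO_ANTI"]],
                    pro_count = cts[["ASTRO_PRO"]],
                    mean_drug = mean(world$drug),
                    dosing_active = dosing_active(
                      step, world$therapy_start_step,
                      if (is.null(config$chemo)) 14L else config$chemo$steps_on,
                      if (is.null(config$chemo)) 7L else config$chemo$steps_off))
  if (with_metrics) {
    m <- compute_morphology(world)
    row$fractal_dimension <- m$fractal_dimension
    row$lacunarity <- m$lacunarity
    row$eccentricity <- m$eccentricity
  } else {
    row$fractal_dimension <- NA_real_
    row$lacunarity <- NA_real_
    row$eccentricity <- NA_real_
  }
  row
}

#' @export
print.astro_sim <- function(x, ...) {
  final <- x$timeseries[nrow(x$timeseries), ]
  cat(sprintf("<astro_sim> %d steps on %d x %d grid (seed %d)\n",
              x$config$n_steps, x$config$rows, x$config$cols, x$config$seed))
  cat(sprintf("  final tumor count %d (anti %d, pro %d)\n",
              final$tumor_count, final$anti_count, final$pro_count))
  if (!is.na(x$therapy_start_step))
    cat(sprintf("  therapy started at step %d\n", x$therapy_start_step))
  invisible(x)
}
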