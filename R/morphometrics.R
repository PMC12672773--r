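#' Tumor boundary mask
#'
#' Logical mask that is `TRUE` exactly at tumor sites having at least one
#' EMPTY site in their Moore-8 neighborhood. Occupied neighbors of any kind
#' (astrocyte, neutral, tumor) do not qualify a cell as boundary; only empty
#' space does, so a tumor cell fully enclosed by astrocytes is interior.
#' Fractal dimension and lacunarity are computed on this mask; eccentricity
#' uses the bulk tumor coordinates instead.
#'
#' @param world An `astro_world`.
#' @return Logical matrix of the same shape as the state grid.
#' @export
boundary_mask <- function(world) {
  st <- world$states
  tumor <- st == STATE_CODES[["TUMOR"]]
  # pad with EMPTY so off-grid counts as empty space
  nr <- nrow(st); nc <- ncol(st)
  emp <- matrix(TRUE, nr + 2L, nc + 2L)
  emp[2:(nr + 1L), 2:(nc + 1L)] <- st == STATE_CODES[["EMPTY"]]
  any_empty <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    any_empty <- any_empty |
      emp[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  tumor & any_empty
}

#' Box-counting fractal dimension
#'
#' Tiles the grid with non-overlapping `eps x eps` boxes anchored at the
#' origin for each box size `eps`, counts boxes containing at least one mask
#' cell, and returns the negative slope of the ordinary least squares fit of
#' `log N(eps)` on `log eps`. A one-dimensional boundary gives values near
#' 1, a filled region near 2; a single cell gives 0.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param box_sizes At least three box sizes (default `c(2, 4, 8, 16, 32)`).
#' @return The fractal dimension, or `NA` with a warning for an empty mask.
#' @export
fractal_dimension <- function(mask, box_sizes = c(2L, 4L, 8L, 16L, 32L)) {
  mask <- mask != 0
  if (length(box_sizes) < 3)
    stop("need at least three box sizes", call. = FALSE)
  if (!any(mask)) {
    warning("empty mask: fractal dimension undefined")
    return(NA_real_)
  }
  counts <- vapply(box_sizes, function(eps) box_count(mask, eps), numeric(1))
  fit <- stats::lsfit(log(box_sizes), log(counts))
  -unname(fit$coefficients[2])
}

box_count <- function(mask, eps) {
  eps <- as.integer(eps)
  br <- (seq_len(nrow(mask)) - 1L) %/% eps
  bc <- (seq_len(ncol(mask)) - 1L) %/% eps
  occ <- rowsum(mask + 0, br)          # collapse rows into row-bands
  occ <- t(rowsum(t(occ), bc))         # then columns into boxes
  sum(occ > 0)
}

#' Lacunarity of a binary mask
#'
#' Partitions the grid into non-overlapping `window x window` squares
#' anchored at the origin (windows overhanging the edge are discarded),
#' counts mask cells per window (the mass distribution), and returns
#' `variance / mean^2` of the masses using the population variance. Zero for
#' any uniform mass distribution; large values indicate gappy, heterogeneous
#' masks.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param window Window side length (default 8).
#' @return The lacunarity, or `NA` with a warning if no mask cell falls in a
#'   complete window.
#' @export
lacunarity <- function(mask, window = 8L) {
  masses <- window_masses(mask, window)
  mu <- mean(masses)
  if (mu == 0) {
    warning("all-zero mass distribution: lacunarity undefined")
    return(NA_real_)
  }
  mean((masses - mu)^2) / mu^2
}

window_masses <- function(mask, window) {
  mask <- mask != 0
  window <- as.integer(window)
  nr <- (nrow(mask) %/% window) * window
  nc <- (ncol(mask) %/% window) * window
  if (nr == 0 || nc == 0)
    stop("window larger than the grid", call. = FALSE)
  m <- mask[seq_len(nr), seq_len(nc), drop = FALSE]
  br <- (seq_len(nr) - 1L) %/% window
  bc <- (seq_len(nc) - 1L) %/% window
  occ <- rowsum(m + 0, br)
  occ <- t(rowsum(t(occ), bc))
  as.vector(occ)
}

#' Lacunarity over a set of window sizes
#'
#' @inheritParams lacunarity
#' @param windows Vector of window sizes.
#' @return Named numeric vector of lacunarities.
#' @export
lacunarity_spectrum <- function(mask, windows = c(2L, 4L, 8L, 16L, 32L)) {
  out <- vapply(windows, function(w) suppressWarnings(lacunarity(mask, w)),
                numeric(1))
  names(out) <- paste0("window_", windows)
  out
}

#' Tumor eccentricity
#'
#' Deviation of the bulk tumor shape from circularity:
#' `sqrt(1 - lambda2 / lambda1)` where `lambda1 >= lambda2` are the
#' eigenvalues of the 2 x 2 covariance matrix of all tumor cell coordinates.
#' 0 means circular (equal principal variances), 1 means collinear.
#'
#' @param coordinates Two-column matrix or data.frame of `(row, col)` tumor
#'   cell positions.
#' @return Eccentricity in `[0, 1]`; `NA` with a warning for fewer than two
#'   points or zero total variance; exactly 1 for collinear points.
#' @export
eccentricity <- function(coordinates) {
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) < 2) {
    warning("need at least two points: eccentricity undefined")
    return(NA_real_)
  }
  cv <- stats::cov(coordinates)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0 # guard tiny negative rounding
  if (ev[1] == 0) {
    warning("zero total variance: eccentricity undefined")
    return(NA_real_)
  }
  sqrt(1 - ev[2] / ev[1])
}

#' Tumor coordinates of a world
#'
#' @param world An `astro_world`.
#' @return Integer matrix of `(row, col)` positions of all tumor cells.
#' @export
tumor_coordinates <- function(world) {
  which(world$states == STATE_CODES[["TUMOR"]], arr.ind = TRUE)
}

#' Morphology record for a world snapshot
#'
#' Computes the per-snapshot morphometrics: tumor count, box-counting
#' fractal dimension and lacunarity of the boundary mask, and bulk
#' eccentricity. The scalar lacunarity uses the default window (8 sites);
#' set `spectrum = TRUE` to also obtain the per-window values.
#'
#' @param world An `astro_world`.
#' @param box_sizes Box sizes for the fractal dimension.
#' @param lac_window Window size for the scalar lacunarity.
#' @param spectrum If `TRUE`, attach per-window lacunarities as extra
#'   columns.
#' @return One-row data.frame with columns `step`, `tumor_count`,
#'   `fractal_dimension`, `lacunarity`, `eccentricity`.
#' @export
compute_morphology <- function(world, box_sizes = c(2L, 4L, 8L, 16L, 32L),
                               lac_window = 8L, spectrum = FALSE) {
  bm <- boundary_mask(world)
  coords <- tumor_coordinates(world)
  rec <- data.frame(
    step = world$step_index,
    tumor_count = nrow(coords),
    fractal_dimension = suppressWarnings(fractal_dimension(bm, box_sizes)),
    lacunarity = suppressWarnings(lacunarity(bm, lac_window)),
    eccentricity = suppressWarnings(eccentricity(coords)))
  if (spectrum) {
    sp <- suppressWarnings(lacunarity_spectrum(bm))
    for (nm in names(sp)) rec[[paste0("lacunarity_", nm)]] <- sp[[nm]]
  }
  rec
}
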