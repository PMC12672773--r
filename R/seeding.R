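#' Available astrocyte seeding patterns
#'
#' @return Character vector of the six pattern names.
#' @export
seeding_patterns <- function() {
  c("uniform", "random", "clustered", "radial", "inverse_radial", "gradient")
}

#' Generate an initial astrocyte layout with neutral backfill
#'
#' Places exactly `round(density * rows * cols)` astrocytes according to the
#' requested spatial pattern, then backfills neutral agents uniformly at
#' random over the remaining non-center sites so that astrocytes plus
#' neutrals total half the grid (45,000 agents on the default 300 x 300
#' lattice). The central tumor seed site is reserved before placement. All
#' six patterns at equal density therefore yield identical total occupancy,
#' so downstream differences are attributable to arrangement alone.
#'
#' Patterns (placement law, with `r` the distance to the grid center and
#' `f` the column fraction):
#' * `uniform`: a near-square sublattice of evenly spaced sites, trimmed or
#'   topped up at random to hit the quota exactly;
#' * `random`: uniform without replacement;
#' * `clustered`: `cluster_count` square blocks around uniformly placed
#'   cluster seeds, trimmed/topped up to the quota;
#' * `radial`: weighted sampling with weight `max(r) - r` (astrocytes
#'   concentrate at the tumor core);
#' * `inverse_radial`: weight `r` (density increases outward);
#' * `gradient`: weight `f` (linear horizontal gradient, sparse left, dense
#'   right).
#'
#' The weight functions and cluster geometry are artifact choices exposed as
#' arguments so alternative constants can be dropped in.
#'
#' @param pattern One of [seeding_patterns()].
#' @param density Fraction of grid sites occupied by astrocytes, in
#'   `[0, 0.5]`.
#' @param rows,cols Grid dimensions.
#' @param cluster_count Number of cluster seeds for the clustered pattern.
#' @return A list of class `seeding_layout` with data.frames
#'   `astrocyte_sites` and `neutral_sites` (columns `row`, `col`), plus
#'   `pattern` and `density`. Placement consumes the current RNG stream.
#' @examples
#' set.seed(1)
#' lay <- generate_layout("radial", 0.3, 100, 100)
#' nrow(lay$astrocyte_sites) # 3000
#' @export
generate_layout <- function(pattern, density, rows = 300L, cols = 300L,
                            cluster_count = 30L) {
  if (!pattern %in% seeding_patterns())
    stop(sprintf("unknown seeding pattern '%s'", pattern), call. = FALSE)
  if (density < 0 || density > 0.5)
    stop("'density' must be in [0, 0.5]", call. = FALSE)
  rows <- as.integer(rows); cols <- as.integer(cols)
  n_sites <- rows * cols
  n_astro <- round(density * n_sites)
  n_total <- round(0.5 * n_sites)
  if (n_astro > n_total)
    stop("astrocyte quota exceeds the fixed non-tumor occupancy",
         call. = FALSE)
  center <- center_site(rows, cols)
  center_idx <- (center[2] - 1L) * rows + center[1]

  idx_all <- setdiff(seq_len(n_sites), center_idx)
  astro_idx <- switch(
    pattern,
    random = idx_all[sample.int(length(idx_all), n_astro)],
    uniform = uniform_sublattice(rows, cols, n_astro, center_idx),
    clustered = clustered_sites(rows, cols, n_astro, center_idx,
                                cluster_count),
    radial = weighted_site_sample(rows, cols, n_astro, center_idx,
                                  function(r, f) max(r) - r),
    inverse_radial = weighted_site_sample(rows, cols, n_astro, center_idx,
                                          function(r, f) r),
    gradient = weighted_site_sample(rows, cols, n_astro, center_idx,
                                    function(r, f) f)
  )
  free_idx <- setdiff(idx_all, astro_idx)
  neutral_idx <- if (n_total - n_astro > 0)
    free_idx[sample.int(length(free_idx), n_total - n_astro)] else integer(0)

  layout <- list(astrocyte_sites = idx_to_sites(astro_idx, rows),
                 neutral_sites = idx_to_sites(neutral_idx, rows),
                 pattern = pattern, density = density)
  class(layout) <- "seeding_layout"
  layout
}

idx_to_sites <- function(idx, rows) {
  data.frame(row = ((idx - 1L) %% rows) + 1L,
             col = ((idx - 1L) %/% rows) + 1L)
}

# Weighted sampling without replacement via exponential-race keys
# (Efraimidis-Spirakis): taking the n largest runif(N)^(1/w) is equivalent
# to sequential sampling with probabilities proportional to w. Zero-weight
# sites are only used if the positive-weight pool is exhausted.
weighted_site_sample <- function(rows, cols, n, center_idx, weight_fun) {
  if (n == 0L) return(integer(0))
  site_row <- rep(seq_len(rows), times = cols)
  site_col <- rep(seq_len(cols), each = rows)
  center <- center_site(rows, cols)
  r <- sqrt((site_row - center[1])^2 + (site_col - center[2])^2)
  f <- (site_col - 1) / max(cols - 1, 1)
  w <- weight_fun(r, f)
  w[center_idx] <- -Inf
  keys <- ifelse(w > 0, stats::runif(length(w))^(1 / w), -stats::runif(length(w)))
  keys[center_idx] <- -Inf
  order(keys, decreasing = TRUE)[seq_len(n)]
}

# Evenly spaced sublattice: place sites on a regular grid with spacing close
# to sqrt(sites per astrocyte), then trim or top up at random to hit the
# quota exactly.
uniform_sublattice <- function(rows, cols, n, center_idx) {
  if (n == 0L) return(integer(0))
  spacing <- sqrt(rows * cols / n)
  rr <- unique(pmin(rows, pmax(1L, round(seq(1, rows, by = spacing)))))
  cc <- unique(pmin(cols, pmax(1L, round(seq(1, cols, by = spacing)))))
  idx <- as.vector(outer(rr, (cc - 1L) * rows, `+`))
  idx <- setdiff(idx, center_idx)
  adjust_quota(idx, n, rows, cols, center_idx)
}

clustered_sites <- function(rows, cols, n, center_idx, cluster_count) {
  if (n == 0L) return(integer(0))
  cluster_count <- max(1L, as.integer(cluster_count))
  half <- ceiling(sqrt(n / cluster_count)) %/% 2L + 1L
  seeds <- sample(setdiff(seq_len(rows * cols), center_idx), cluster_count)
  seed_r <- ((seeds - 1L) %% rows) + 1L
  seed_c <- ((seeds - 1L) %/% rows) + 1L
  blocks <- lapply(seq_len(cluster_count), function(i) {
    r <- pmax(1L, seed_r[i] - half):pmin(rows, seed_r[i] + half)
    c <- pmax(1L, seed_c[i] - half):pmin(cols, seed_c[i] + half)
    as.vector(outer(r, (c - 1L) * rows, `+`))
  })
  idx <- setdiff(unique(unlist(blocks)), center_idx)
  adjust_quota(idx, n, rows, cols, center_idx)
}

adjust_quota <- function(idx, n, rows, cols, center_idx) {
  if (length(idx) > n) {
    idx <- idx[sort.int(sample.int(length(idx), n))]
  } else if (length(idx) < n) {
    pool <- setdiff(setdiff(seq_len(rows * cols), center_idx), idx)
    idx <- c(idx, pool[sample.int(length(pool), n - length(idx))])
  }
  idx
}

#' @export
print.seeding_layout <- function(x, ...) {
  cat(sprintf("<seeding_layout> %s, density %.3f: %d astrocytes, %d neutral\n",
              x$pattern, x$density, nrow(x$astrocyte_sites),
              nrow(x$neutral_sites)))
  invisible(x)
}
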