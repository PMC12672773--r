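#' Derive a replicate seed from a base seed
#'
#' Deterministic per-replicate seeds, kept within the 32-bit integer range,
#' so the same `(base_seed, index)` always maps to the same trajectory and
#' matched-seed comparisons across conditions are possible.
#'
#' @param base_seed Integer base seed.
#' @param index Replicate index (1-based; vectorized).
#' @return Integer seed(s).
#' @export
replicate_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) + 7919 * as.numeric(index)) %% 2147483647)
}

#' Run independent replicate simulations
#'
#' Runs `n_replicates` independent trajectories of the same configuration,
#' with per-replicate seeds derived from `(base_seed, index)` via
#' [replicate_seed()], and stacks their per-step records.
#'
#' @param config A [sim_config()] object (its `seed` field is overridden per
#'   replicate).
#' @param n_replicates Number of replicates (>= 1).
#' @param base_seed Base seed; defaults to `config$seed`.
#' @param metrics,metric_every Passed to [run_simulation()].
#' @return A data.frame of per-step records with a leading `replicate`
#'   column and a `seed` column.
#' @export
run_replicates <- function(config, n_replicates, base_seed = config$seed,
                           metrics = FALSE, metric_every = NA) {
  stopifnot(n_replicates >= 1)
  out <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- replicate_seed(base_seed, i)
    sim <- run_simulation(cfg, metrics = metrics, metric_every = metric_every,
                          keep_world = FALSE)
    ts <- sim$timeseries
    ts$replicate <- i
    ts$seed <- cfg$seed
    out[[i]] <- ts
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("replicate", "seed",
          setdiff(names(res), c("replicate", "seed")))]
}

#' Final-step records of a replicate table
#'
#' @param records Output of [run_replicates()].
#' @return One row per replicate, at the maximum step.
#' @export
final_records <- function(records) {
  records[records$step == max(records$step), , drop = FALSE]
}

#' Sobol low-discrepancy sequence on the unit cube
#'
#' Deterministic Gray-code Sobol sequence (direction numbers from the
#' Joe-Kuo tables for up to 7 dimensions). The degenerate all-zero initial
#' point is skipped, so the first point returned is (0.5, 0.5, ...).
#'
#' @param n Number of points.
#' @param dims Number of dimensions (1--7).
#' @return An `n x dims` matrix with entries in (0, 1).
#' @export
sobol_sequence <- function(n, dims = 6L) {
  dims <- as.integer(dims)
  if (dims < 1L || dims > 7L) stop("'dims' must be 1..7", call. = FALSE)
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  L <- 30L
  nbits <- max(1L, ceiling(log2(n + 1)))
  # primitive polynomial degree s, coefficient bits a, initial odd m's
  tab <- list(
    list(s = 0L, a = 0L, m = integer(0)),       # van der Corput
    list(s = 1L, a = 0L, m = c(1L)),
    list(s = 2L, a = 1L, m = c(1L, 3L)),
    list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
    list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
    list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
    list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)))
  V <- matrix(0, nbits, dims) # direction numbers as integers (doubles)
  for (j in seq_len(dims)) {
    e <- tab[[j]]
    if (e$s == 0L) {
      m <- rep(1L, nbits)
    } else {
      m <- numeric(nbits)
      m[seq_len(min(e$s, nbits))] <- e$m[seq_len(min(e$s, nbits))]
      if (nbits > e$s) for (k in (e$s + 1L):nbits) {
        val <- bitwXor(as.integer(m[k - e$s]),
                       as.integer(m[k - e$s] * 2^e$s))
        if (e$s > 1L) for (q in seq_len(e$s - 1L)) {
          a_q <- bitwAnd(bitwShiftR(e$a, e$s - 1L - q), 1L)
          if (a_q == 1L)
            val <- bitwXor(val, as.integer(m[k - q] * 2^q))
        }
        m[k] <- val
      }
    }
    V[, j] <- m[seq_len(nbits)] * 2^(L - seq_len(nbits))
  }
  pts <- matrix(0, n, dims)
  x <- numeric(dims)
  for (i in seq_len(n)) {
    # index of the lowest zero bit of (i - 1)
    c <- 1L; ii <- i - 1L
    while (bitwAnd(ii, 1L) == 1L) { ii <- bitwShiftR(ii, 1L); c <- c + 1L }
    x <- vapply(seq_len(dims),
                function(j) bitwXor(as.integer(x[j]), as.integer(V[c, j])),
                numeric(1))
    pts[i, ] <- x / 2^L
  }
  pts
}

#' Sobol sample of the interaction parameter space
#'
#' Generates `n` parameter sets over the six swept interaction parameters:
#' the four continuous magnitudes (`alpha`, `beta`, `theta`, `kappa`) mapped
#' affinely onto `[0, 1]`, and the two discrete sensitivities mapped by
#' equal thirds of the unit interval onto their level sets
#' (`S_A` in {8, 16, 32}, `S_T` in {4, 8, 16}). Deterministic for fixed `n`.
#'
#' @param n Number of parameter sets.
#' @return A data.frame with columns `sample_id`, `alpha`, `beta`, `theta`,
#'   `kappa`, `S_A`, `S_T`.
#' @examples
#' head(sobol_parameter_sets(8))
#' @export
sobol_parameter_sets <- function(n) {
  u <- sobol_sequence(n, 6L)
  thirds <- function(x, levels) levels[pmin(floor(x * 3) + 1L, 3L)]
  data.frame(sample_id = seq_len(n),
             alpha = u[, 1], beta = u[, 2], theta = u[, 3], kappa = u[, 4],
             S_A = thirds(u[, 5], c(8, 16, 32)),
             S_T = thirds(u[, 6], c(4, 8, 16)))
}

#' Partial rank correlation coefficients
#'
#' For each parameter column, rank-transforms all columns, regresses the
#' parameter's ranks and the output's ranks on the ranks of every other
#' parameter (ordinary least squares with intercept), and reports the
#' Pearson correlation of the two residual vectors. This isolates the
#' monotone association between a parameter and the output with the
#' linear-rank effects of all other parameters removed; values lie in
#' `[-1, 1]` and are invariant to strictly increasing transforms of the
#' output.
#'
#' @param parameters data.frame or matrix of parameter columns (one row per
#'   sample).
#' @param output Numeric vector of per-sample output values.
#' @return A data.frame with columns `parameter` and `prcc`; constant
#'   columns yield `NA` with a warning.
#' @export
prcc <- function(parameters, output) {
  X <- as.data.frame(parameters)
  stopifnot(nrow(X) == length(output))
  if (nrow(X) < 10) stop("need at least 10 samples", call. = FALSE)
  if (!all(is.finite(output))) stop("outputs must be finite", call. = FALSE)
  R <- vapply(X, rank, numeric(nrow(X)))
  ry <- rank(output)
  out <- data.frame(parameter = colnames(R), prcc = NA_real_)
  if (stats::var(ry) == 0) {
    warning("constant output: PRCC undefined")
    return(out)
  }
  for (j in seq_len(ncol(R))) {
    if (stats::var(R[, j]) == 0) {
      warning(sprintf("constant parameter '%s': PRCC undefined",
                      colnames(R)[j]))
      next
    }
    others <- R[, -j, drop = FALSE]
    # constant columns carry no rank information and would only make the
    # regression collinear
    others <- others[, apply(others, 2, stats::var) > 0, drop = FALSE]
    rx <- if (ncol(others)) stats::lsfit(others, R[, j])$residuals
          else R[, j] - mean(R[, j])
    rz <- if (ncol(others)) stats::lsfit(others, ry)$residuals
          else ry - mean(ry)
    out$prcc[j] <- stats::cor(rx, rz)
  }
  out
}

#' Stratify parameter sets into outcome regimes
#'
#' Ranks samples by their mean final tumor count and splits them into
#' tertiles: the bottom third is labeled `Inhibitory`, the middle `Neutral`,
#' the top `Promoting`. Ties are broken by `sample_id` for determinism.
#'
#' @param mean_counts Per-sample mean final tumor counts.
#' @param sample_id Sample identifiers (default sequential).
#' @return Factor of regime labels aligned with the input order.
#' @export
stratify_regimes <- function(mean_counts, sample_id = seq_along(mean_counts)) {
  n <- length(mean_counts)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  ord <- order(mean_counts, sample_id)
  rank_pos <- integer(n)
  rank_pos[ord] <- seq_len(n)
  tert <- ceiling(3 * rank_pos / n)
  factor(c("Inhibitory", "Neutral", "Promoting")[tert],
         levels = c("Inhibitory", "Neutral", "Promoting"))
}

#' Residualize a metric on tumor count, per time step
#'
#' At each time step, fits ordinary least squares of the metric on the tumor
#' count over all pooled observations at that step and returns the
#' residuals, removing the component of the metric explained by tumor size
#' so that group comparisons reflect size-independent morphology. Steps with
#' zero count variance return the centered metric (flagged with a warning).
#'
#' @param metric Numeric metric values.
#' @param tumor_count Tumor counts aligned with `metric`.
#' @param step Time-step labels aligned with `metric`.
#' @return Numeric vector of residuals in input order.
#' @export
residualize_metric <- function(metric, tumor_count, step) {
  stopifnot(length(metric) == length(tumor_count),
            length(metric) == length(step))
  res <- numeric(length(metric))
  for (s in unique(step)) {
    i <- which(step == s)
    if (length(i) < 3)
      stop("need at least 3 pooled observations per step", call. = FALSE)
    if (stats::var(tumor_count[i]) == 0) {
      warning(sprintf("zero count variance at step %s: centering only", s))
      res[i] <- metric[i] - mean(metric[i])
    } else {
      res[i] <- stats::lsfit(tumor_count[i], metric[i])$residuals
    }
  }
  res
}

#' Compare two groups of simulation outputs
#'
#' Delegates to the standard tests: `rank_sum` (two-sided Mann-Whitney U via
#' [stats::wilcox.test()]; the statistic is U for the first group),
#' `anova` (one-way analysis of variance), or `kruskal`
#' ([stats::kruskal.test()]). Rank-based tests are the default since
#' simulation outputs frequently violate normality and equal-variance
#' assumptions.
#'
#' @param values_a,values_b Numeric vectors.
#' @param test One of `"rank_sum"`, `"anova"`, `"kruskal"`.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("rank_sum", "anova", "kruskal")) {
  test <- match.arg(test)
  if (!length(values_a) || !length(values_b))
    stop("groups must be non-empty", call. = FALSE)
  if (test == "rank_sum") {
    ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                              exact = FALSE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "Mann-Whitney U")
  } else if (test == "kruskal") {
    g <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
    ht <- stats::kruskal.test(c(values_a, values_b), g)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "Kruskal-Wallis")
  } else {
    g <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
    fit <- stats::aov(y ~ g, data = data.frame(y = c(values_a, values_b),
                                               g = g))
    sm <- summary(fit)[[1]]
    list(statistic = sm$`F value`[1], p_value = sm$`Pr(>F)`[1],
         method = "one-way ANOVA")
  }
}

#' Sobol sweep over the interaction parameter space
#'
#' Runs `n_replicates` trajectories for each of `n_samples` Sobol parameter
#' sets and collects final-state outputs (tumor count and, optionally,
#' morphometrics), the input table for PRCC and regime stratification.
#'
#' @param n_samples Number of Sobol parameter sets.
#' @param n_replicates Replicates per set.
#' @param config Base configuration; its interaction magnitudes are
#'   overridden per sample.
#' @param base_seed Base seed for replicate derivation.
#' @param metrics Compute morphometrics at the final step?
#' @return A data.frame with one row per (sample, replicate): the sampled
#'   parameters plus `final_count` and metric columns.
#' @export
parameter_sweep <- function(n_samples, n_replicates = 10L,
                            config = sim_config(), base_seed = config$seed,
                            metrics = FALSE) {
  sets <- sobol_parameter_sets(n_samples)
  out <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    cfg <- config
    cfg$interaction <- interaction_params(
      alpha = sets$alpha[s], beta = sets$beta[s], theta = sets$theta[s],
      kappa = sets$kappa[s], switch_sensitivity = sets$S_A[s],
      division_sensitivity = sets$S_T[s],
      kernel_steepness = config$interaction$kernel_steepness,
      kernel_half_distance = config$interaction$kernel_half_distance,
      radius = config$interaction$radius)
    rec <- run_replicates(cfg, n_replicates,
                          base_seed = replicate_seed(base_seed, s * 1000L),
                          metrics = metrics)
    fin <- final_records(rec)
    fin$sample_id <- sets$sample_id[s]
    for (nm in c("alpha", "beta", "theta", "kappa", "S_A", "S_T"))
      fin[[nm]] <- sets[[nm]][s]
    fin$final_count <- fin$tumor_count
    out[[s]] <- fin
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
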