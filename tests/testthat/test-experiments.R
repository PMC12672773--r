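test_that("Sobol sequence reproduces the reference low-discrepancy points", {
  # first eight points of the unscrambled 6-dimensional sequence (zero point
  # skipped), frozen from an independent quasi-Monte-Carlo implementation
  s <- sobol_sequence(8, 6)
  expected <- rbind(
    c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    c(0.75, 0.25, 0.25, 0.25, 0.75, 0.75),
    c(0.25, 0.75, 0.75, 0.75, 0.25, 0.25),
    c(0.375, 0.375, 0.625, 0.875, 0.375, 0.125),
    c(0.875, 0.875, 0.125, 0.375, 0.875, 0.625),
    c(0.625, 0.125, 0.875, 0.625, 0.625, 0.875),
    c(0.125, 0.625, 0.375, 0.125, 0.125, 0.375),
    c(0.1875, 0.3125, 0.9375, 0.4375, 0.5625, 0.3125))
  expect_equal(s, expected, tolerance = 1e-12)
  # dyadic balance: within a full block of 2^k consecutive points (the
  # zero point excluded), each half of [0,1] receives half the points
  s2 <- sobol_sequence(63, 6)
  for (j in 1:6) expect_equal(sum(s2[, j] < 0.5), 31)
})

test_that("parameter sets are deterministic and within their ranges", {
  a <- sobol_parameter_sets(1000)
  b <- sobol_parameter_sets(1000)
  expect_identical(a, b)
  expect_equal(nrow(a), 1000)
  for (nm in c("alpha", "beta", "theta", "kappa")) {
    expect_true(all(a[[nm]] >= 0 & a[[nm]] <= 1))
  }
  expect_true(all(a$S_A %in% c(8, 16, 32)))
  expect_true(all(a$S_T %in% c(4, 8, 16)))
  # each discrete level appears (equal-thirds mapping)
  expect_equal(sort(unique(a$S_A)), c(8, 16, 32))
  expect_equal(sort(unique(a$S_T)), c(4, 8, 16))
})

test_that("discrete mapping splits the unit interval into equal thirds", {
  thirds <- function(x, levels) levels[pmin(floor(x * 3) + 1L, 3L)]
  expect_equal(thirds(c(0, 0.33, 0.34, 0.66, 0.67, 0.999), c(8, 16, 32)),
               c(8, 8, 16, 16, 32, 32))
})

test_that("PRCC recovers a noiseless monotone driver and little else", {
  set.seed(74)
  n <- 200
  X <- as.data.frame(matrix(stats::runif(n * 6), n, 6))
  names(X) <- paste0("x", 1:6)
  y <- X$x1 + 0.001 * stats::rnorm(n) # monotone driver, hairline noise
  res <- prcc(X, y)
  expect_gte(res$prcc[res$parameter == "x1"], 0.99)
  expect_true(all(abs(res$prcc[res$parameter != "x1"]) <= 0.1))
  # invariance under strictly increasing transforms of the output
  res2 <- prcc(X, exp(3 * y))
  expect_equal(res$prcc, res2$prcc, tolerance = 1e-12)
})

test_that("PRCC matches an independent precision-matrix oracle", {
  set.seed(72)
  n <- 150
  X <- as.data.frame(matrix(stats::runif(n * 4), n, 4))
  y <- 2 * X[[1]] - 3 * X[[2]] + 0.5 * stats::rnorm(n)
  res <- prcc(X, y)
  # oracle: partial correlations from the inverse rank-correlation matrix
  R <- stats::cor(cbind(vapply(X, rank, numeric(n)), rank(y)))
  P <- solve(R)
  k <- ncol(R)
  oracle <- -P[seq_len(k - 1), k] / sqrt(diag(P)[seq_len(k - 1)] * P[k, k])
  expect_equal(res$prcc, unname(oracle), tolerance = 1e-10)
})

test_that("PRCC of an unrelated output stays near zero and flags constants", {
  set.seed(73)
  n <- 400
  X <- as.data.frame(matrix(stats::runif(n * 6), n, 6))
  y <- stats::rnorm(n)
  res <- prcc(X, y)
  expect_true(all(abs(res$prcc) < 4 / sqrt(n)))
  X$x_const <- 1
  expect_warning(res2 <- prcc(X, y), "constant parameter")
  expect_true(is.na(res2$prcc[res2$parameter == "x_const"]))
  expect_error(prcc(X[1:5, ], y[1:5]), "at least 10")
})

test_that("regime stratification forms deterministic tertiles", {
  lab <- stratify_regimes(1:9)
  expect_equal(as.character(lab),
               rep(c("Inhibitory", "Neutral", "Promoting"), each = 3))
  # tie-break by sample id is deterministic and splits evenly
  lab2 <- stratify_regimes(rep(5, 9))
  expect_equal(table(lab2)[["Inhibitory"]], 3L)
  expect_equal(table(lab2)[["Promoting"]], 3L)
  expect_identical(lab2, stratify_regimes(rep(5, 9)))
  # tertile monotonicity
  set.seed(74)
  x <- stats::rnorm(30)
  lab3 <- stratify_regimes(x)
  expect_lte(max(x[lab3 == "Inhibitory"]), min(x[lab3 == "Promoting"]))
  expect_error(stratify_regimes(c(1, 2)), "at least 3")
})

test_that("residualization removes the count-explained component", {
  set.seed(75)
  step <- rep(1:5, each = 20)
  count <- stats::rpois(100, 50) + step * 10
  # metric exactly linear in count: residuals vanish
  metric <- 3 + 0.2 * count
  expect_equal(residualize_metric(metric, count, step), rep(0, 100),
               tolerance = 1e-10)
  # metric independent of count: residual variance tracks metric variance
  metric2 <- stats::rnorm(100)
  r2 <- residualize_metric(metric2, count, step)
  expect_gt(stats::var(r2), 0.5 * stats::var(metric2))
  # intercept absorption: constant shifts do not move group differences
  r3 <- residualize_metric(metric2 + 7, count, step)
  expect_equal(r2, r3, tolerance = 1e-10)
  # zero count variance: centered metric with a flag
  expect_warning(r4 <- residualize_metric(metric2[1:6], rep(4, 6),
                                          rep(1, 6)), "zero count variance")
  expect_equal(r4, metric2[1:6] - mean(metric2[1:6]))
})

test_that("group comparisons delegate to the standard tests", {
  set.seed(76)
  x <- stats::rnorm(50)
  res_same <- compare_groups(x, x)
  expect_gt(res_same$p_value, 0.9)
  # complete separation: U = 0 for the lower group
  a <- stats::runif(50); b <- a + 10
  res_sep <- compare_groups(a, b)
  expect_equal(res_sep$statistic, 0)
  # swapping groups flips U to n1*n2 - U
  res_flip <- compare_groups(b, a)
  expect_equal(res_flip$statistic, 50 * 50)
  y <- stats::rnorm(40, mean = 2)
  for (tst in c("anova", "kruskal")) {
    res <- compare_groups(x[1:40], y, test = tst)
    expect_lt(res$p_value, 1e-6)
  }
  expect_error(compare_groups(numeric(0), x), "non-empty")
})

test_that("replicate tables are reproducible and match single runs", {
  cfg <- sim_config(rows = 40, cols = 40, n_steps = 8, density = 0.3,
                    seed = 77)
  r1 <- run_replicates(cfg, 3)
  r2 <- run_replicates(cfg, 3)
  expect_identical(r1, r2)
  expect_equal(length(unique(r1$replicate)), 3)
  # n = 1 equals a direct simulation at the derived seed
  single_cfg <- cfg
  single_cfg$seed <- replicate_seed(cfg$seed, 1)
  direct <- run_simulation(single_cfg)
  one <- run_replicates(cfg, 1)
  expect_equal(one$tumor_count, direct$timeseries$tumor_count)
})

test_that("a small Sobol sweep produces an analyzable table", {
  cfg <- sim_config(rows = 30, cols = 30, n_steps = 5, density = 0.3,
                    seed = 78)
  sw <- parameter_sweep(4, n_replicates = 2, config = cfg)
  expect_equal(nrow(sw), 8)
  expect_true(all(c("sample_id", "alpha", "S_T", "final_count") %in%
                    names(sw)))
  agg <- stats::aggregate(final_count ~ sample_id, sw, mean)
  lab <- stratify_regimes(agg$final_count, agg$sample_id)
  expect_equal(length(lab), 4)
})
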