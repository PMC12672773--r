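test_that("boundary mask marks tumor cells touching empty space only", {
  w <- lone_tumor_world(9)
  expect_true(boundary_mask(w)[5, 5])
  # solid 3x3 block: center excluded, perimeter included
  w2 <- empty_world(9)
  w2$states[4:6, 4:6] <- STATE_CODES[["TUMOR"]]
  bm <- boundary_mask(w2)
  expect_false(bm[5, 5])
  expect_equal(sum(bm), 8)
  # tumor fully enclosed by astrocytes is not boundary
  w3 <- empty_world(9)
  w3$states[4:6, 4:6] <- STATE_CODES[["ASTRO_ANTI"]]
  w3$states[5, 5] <- STATE_CODES[["TUMOR"]]
  expect_false(boundary_mask(w3)[5, 5])
  # ...but neutral or astrocyte neighbors plus one empty neighbor qualify
  w3$states[4, 4] <- STATE_CODES[["EMPTY"]]
  expect_true(boundary_mask(w3)[5, 5])
})

test_that("fractal dimension recovers line and plane dimensions", {
  line <- matrix(FALSE, 64, 64); line[32, 1:64] <- TRUE
  expect_equal(fractal_dimension(line, c(2, 4, 8, 16)), 1, tolerance = 0.05)
  solid <- matrix(TRUE, 64, 64)
  expect_equal(fractal_dimension(solid, c(2, 4, 8, 16)), 2, tolerance = 0.05)
  single <- matrix(FALSE, 64, 64); single[10, 10] <- TRUE
  expect_equal(fractal_dimension(single, c(2, 4, 8, 16)), 0, tolerance = 1e-10)
  expect_warning(out <- fractal_dimension(matrix(FALSE, 8, 8), c(2, 4, 8)),
                 "empty")
  expect_true(is.na(out))
  expect_error(fractal_dimension(line, c(2, 4)), "three box sizes")
})

test_that("box counts match the naive oracle on random masks", {
  set.seed(55)
  for (rep in 1:4) {
    mask <- matrix(stats::runif(48 * 48) < 0.15, 48, 48)
    for (eps in c(2, 3, 4, 8, 16))
      expect_equal(box_count(mask, eps), naive_box_count(mask, eps))
  }
})

test_that("lacunarity matches hand-computed and degenerate cases", {
  # 4x4 grid, one occupied cell, 2x2 windows: masses {1,0,0,0}
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE
  expect_equal(lacunarity(m, 2), 3.0)
  # uniform masses give zero lacunarity
  expect_equal(lacunarity(matrix(TRUE, 8, 8), 4), 0)
  chk <- matrix(c(TRUE, FALSE), 8, 8) # same mass in every window
  expect_equal(lacunarity(chk, 2), 0)
  expect_warning(out <- lacunarity(matrix(FALSE, 8, 8), 2), "all-zero")
  expect_true(is.na(out))
})

test_that("window masses match the naive oracle, dropping partial windows", {
  set.seed(56)
  mask <- matrix(stats::runif(30 * 22) < 0.3, 30, 22)
  for (eps in c(2, 4, 8)) {
    expect_equal(sort(window_masses(mask, eps)),
                 sort(naive_window_masses(mask[seq_len((30 %/% eps) * eps),
                                               seq_len((22 %/% eps) * eps)],
                                          eps)))
  }
})

test_that("eccentricity separates circular, elongated and collinear shapes", {
  # 4-fold symmetric disc: equal eigenvalues
  g <- expand.grid(r = -10:10, c = -10:10)
  disc <- g[g$r^2 + g$c^2 <= 100, ]
  expect_equal(eccentricity(disc), 0, tolerance = 1e-6)
  # collinear points
  expect_equal(eccentricity(cbind(1:12, 2 * (1:12) + 3)), 1)
  # 4:1 variance ratio -> sqrt(1 - 1/4)
  rect <- cbind(c(0, 0, 2, 2), c(0, 1, 0, 1))
  expect_equal(eccentricity(rect), sqrt(1 - 1 / 4), tolerance = 1e-12)
  expect_warning(out <- eccentricity(cbind(1, 1)), "two points")
  expect_true(is.na(out))
  expect_warning(out2 <- eccentricity(cbind(c(1, 1), c(2, 2))), "variance")
  expect_true(is.na(out2))
})

test_that("metrics are translation invariant; eccentricity rotation invariant", {
  set.seed(57)
  base <- matrix(FALSE, 40, 40)
  base[10:20, 12:22] <- matrix(stats::runif(11 * 11) < 0.5, 11, 11)
  # shift by a multiple of every box/window size: the origin-anchored
  # tilings then translate with the mask and the metrics are unchanged
  shifted <- matrix(FALSE, 40, 40)
  shifted[18:28, 4:14] <- base[10:20, 12:22]
  sizes <- c(2, 4, 8)
  expect_equal(fractal_dimension(base, sizes),
               fractal_dimension(shifted, sizes), tolerance = 1e-12)
  expect_equal(lacunarity(base, 8), lacunarity(shifted, 8),
               tolerance = 1e-12)
  pts <- which(base, arr.ind = TRUE)
  rot <- cbind(pts[, 2], -pts[, 1]) # 90-degree rotation
  expect_equal(eccentricity(pts), eccentricity(rot), tolerance = 1e-10)
  shift_pts <- sweep(pts, 2, c(100, -50), `+`)
  expect_equal(eccentricity(pts), eccentricity(shift_pts), tolerance = 1e-10)
})

test_that("morphology records bundle the per-snapshot metrics", {
  set.seed(58)
  w <- empty_world(40)
  w$states[15:25, 15:25] <- STATE_CODES[["TUMOR"]]
  rec <- compute_morphology(w)
  expect_named(rec, c("step", "tumor_count", "fractal_dimension",
                      "lacunarity", "eccentricity"))
  expect_equal(rec$tumor_count, 121)
  expect_gte(rec$fractal_dimension, 0)
  expect_lte(rec$fractal_dimension, 2)
  expect_gte(rec$lacunarity, 0)
  expect_lte(rec$eccentricity, 1)
  sp <- compute_morphology(w, spectrum = TRUE)
  expect_true(any(grepl("lacunarity_window", names(sp))))
})
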