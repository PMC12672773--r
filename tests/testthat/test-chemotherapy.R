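test_that("uniform fields are fixed points of diffusion", {
  u <- matrix(2.5, 12, 12)
  expect_equal(diffuse_adi(u, 10, FALSE, 0), u, tolerance = 1e-12)
})

test_that("Neumann diffusion conserves mass to 1e-10 relative", {
  set.seed(8)
  u <- matrix(stats::runif(40 * 40, 0, 5), 40, 40)
  total <- sum(u)
  for (Dc in c(0.5, 10, 2500)) {
    v <- u
    for (i in 1:5) v <- diffuse_adi(v, Dc, FALSE, 0)
    expect_equal(sum(v), total, tolerance = 1e-10)
    expect_true(all(v >= 0))
  }
})

test_that("all-edge Dirichlet forcing converges to the uniform dose", {
  u <- matrix(0, 24, 24)
  for (i in 1:400) u <- diffuse_adi(u, 5, TRUE, 3)
  expect_lt(max(abs(u - 3)), 1e-8)
})

test_that("diffusion rejects non-finite input and stays non-negative", {
  u <- matrix(1, 5, 5); u[2, 2] <- NaN
  expect_error(diffuse_adi(u, 1, FALSE, 0), "non-finite")
  set.seed(12)
  u <- matrix(stats::rexp(20 * 20), 20, 20)
  expect_true(all(diffuse_adi(u, 4000, TRUE, 1) >= 0))
})

test_that("decay and uptake follow the per-step update rule", {
  w <- empty_world(6)
  drug <- matrix(1, 6, 6)
  p <- chemo_params(decay_factor = 0.9, uptake_fraction = 0.2)
  expect_equal(decay_and_uptake(drug, w, p), matrix(0.9, 6, 6))
  # tumor sites lose the uptake fraction of the post-decay drug
  w$states[3, 3] <- STATE_CODES[["TUMOR"]]
  out <- decay_and_uptake(drug, w, p)
  expect_equal(out[3, 3], 1 * 0.9 * (1 - 0.2))
  expect_equal(out[1, 1], 0.9)
  # zero uptake reduces to pure geometric decay
  p0 <- chemo_params(decay_factor = 0.8, uptake_fraction = 0)
  expect_equal(decay_and_uptake(drug, w, p0), matrix(0.8, 6, 6))
})

test_that("gap-junction protection scales the sensed concentration", {
  expect_equal(effective_concentration(1, 0, 1), 1)
  expect_equal(effective_concentration(1, 8, 1), 0)
  expect_equal(effective_concentration(2, 4, 0.5), 1.5)
  expect_equal(effective_concentration(1.3, 5, 0), 1.3) # protection off
  expect_error(effective_concentration(1, 9, 1), "0 and 8")
})

test_that("kill curve is a monotone sigmoid through its half-max", {
  expect_equal(death_probability(0.5, 20, 0.5), 0.5)
  expect_equal(death_probability(0, 10, 1), 1 / (1 + exp(10)),
               tolerance = 1e-12)
  cc <- seq(0, 2, by = 0.1)
  expect_true(all(diff(death_probability(cc, 12, 0.7)) > 0))
  expect_error(death_probability(-0.1, 10, 1), "non-negative")
})

test_that("dosing schedule follows the 14-on/7-off cycle after the trigger", {
  expect_false(any(dosing_active(1:200, NA)))
  start <- 30L
  expect_true(all(dosing_active(start + c(0, 5, 13), start)))
  expect_false(any(dosing_active(start + c(14, 17, 20), start)))
  expect_true(dosing_active(start + 21, start))
  expect_false(any(dosing_active(1:(start - 1), start)))
  s <- start + 0:100
  expect_equal(dosing_active(s, start), dosing_active(s + 21, start))
})

test_that("therapy triggers on the threshold count and starts next step", {
  # a world already above threshold: the step that reaches it schedules
  # dosing for the following step
  w <- empty_world(21)
  w$states[8:14, 8:14] <- STATE_CODES[["TUMOR"]]
  cfg <- world_config(w, chemo = chemo_params(start_threshold = 49L))
  set.seed(21)
  w1 <- advance_step(w, cfg)
  expect_equal(w1$therapy_start_step, 2L)
  expect_false(unname(dosing_active(1, w1$therapy_start_step)))
  expect_true(unname(dosing_active(2, w1$therapy_start_step)))
})

test_that("astrocytes and neutral agents are unaffected by drug", {
  set.seed(33)
  ch <- chemo_params(start_threshold = 1L, T_half = 0.01, k = 50)
  cfg <- sim_config(rows = 40, cols = 40, n_steps = 40, density = 0.4,
                    chemo = ch, seed = 33)
  sim <- run_simulation(cfg)
  ts <- sim$timeseries
  expect_true(all(ts$anti_count + ts$pro_count ==
                    ts$anti_count[1] + ts$pro_count[1]))
  expect_true(all(sim$world$drug >= 0))
})

test_that("with G_f = 0 the kill probability ignores astrocyte phenotype", {
  ceff_anti <- effective_concentration(0.8, 0, 0)
  ceff_pro <- effective_concentration(0.8, 8, 0)
  expect_equal(ceff_anti, ceff_pro)
  expect_equal(death_probability(ceff_anti, 20, 0.5),
               death_probability(ceff_pro, 20, 0.5))
})

test_that("stronger gap-junction protection lowers the per-cell kill rate", {
  # fixed geometry: a protected cell's death probability is non-increasing
  # in G_f, matching the hot-spot behavior at full blockade
  gf <- seq(0, 1, by = 0.25)
  pd <- death_probability(effective_concentration(1, 6, gf), 20, 0.5)
  expect_true(all(diff(pd) < 0))
})
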