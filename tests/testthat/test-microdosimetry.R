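test_that("the range-energy model is monotone, invertible and in the published band", {
  m <- range_energy_model()
  expect_true(all(diff(m$R) > 0) && all(diff(m$E) > 0))
  E <- seq(0.1, 9.9, by = 0.1)
  expect_equal(alpha_energy_from_range(alpha_range(E, m), m), E,
               tolerance = 1e-3)
  expect_gt(alpha_range(8.3, m), 80)
  expect_lt(alpha_range(8.3, m), 95)
  expect_error(alpha_range(25, m), "above the table span")
})

test_that("residual energy follows the residual-range method", {
  m <- range_energy_model()
  expect_equal(residual_energy(8.3, 0, m), 8.3, tolerance = 1e-12)
  expect_identical(residual_energy(8.3, alpha_range(8.3, m), m), 0)
  expect_identical(residual_energy(8.3, 500, m), 0)

  # midpoint of the track: compare against a dense table scan oracle
  E0 <- 6; R0 <- alpha_range(E0, m)
  Egrid <- seq(0.02, E0, length.out = 40000)
  Rgrid <- alpha_range(Egrid, m)
  oracle <- Egrid[which.min(abs(Rgrid - R0 / 2))]
  expect_equal(residual_energy(E0, R0 / 2, m), oracle, tolerance = 1e-3)

  # continuous and non-increasing in the path
  path <- seq(0, R0 * 1.2, length.out = 500)
  Er <- residual_energy(E0, path, m)
  expect_true(all(diff(Er) <= 1e-12))
  expect_lt(max(abs(diff(Er))), 0.1)  # no jumps at the range end
})

test_that("geometric hit probability matches solid-angle geometry and ray sampling", {
  expect_lt(geometric_hit_probability(1e6, 4), 1e-11)
  expect_equal(geometric_hit_probability(4, 4), 0.5)
  expect_equal(geometric_hit_probability(1, 4), 1)

  p_exact <- (1 - sqrt(3) / 2) / 2
  expect_equal(geometric_hit_probability(8, 4), p_exact, tolerance = 1e-12)

  # brute-force oracle: isotropic directions, count ray-sphere hits
  n <- 1e6
  hits <- aicdosim:::with_seed(123, {
    mu <- runif(n, -1, 1)           # cos of angle to the target axis
    sum(8 * sqrt(1 - mu^2) < 4 & mu > 0)  # perpendicular distance < r_n
  })
  se <- sqrt(p_exact * (1 - p_exact) / n)
  expect_lt(abs(hits / n - p_exact), 3 * se)
  expect_error(geometric_hit_probability(-1, 4), "must be > 0")
})

test_that("single-hit spectra convert deposited energy to specific energy correctly", {
  m <- range_energy_model()
  tg <- target_cell(0, 0, 5, 4)
  expect_equal(tg$m_n, 2.68e-13, tolerance = 1e-3)
  # a fully deposited 8.3 MeV alpha in this nucleus gives 4.96 Gy
  expect_equal(8.3 * 1.602e-13 / tg$m_n, 4.96, tolerance = 1e-3)

  # an emitter at the nucleus centre with range below r_n deposits its
  # full energy in every sample: z is degenerate at E0 * 1.602e-13 / m_n
  sp <- single_hit_spectrum_mc(c(0, 0), tg, E0 = 1.0, n_samples = 2000,
                               seed = 5, model = m)
  expect_equal(sp$z1, 1.0 * 1.602e-13 / tg$m_n, tolerance = 1e-12)
  expect_equal(sp$z1sq, sp$z1^2, tolerance = 1e-12)
  expect_equal(sp$n_stoppers, 2000L)
  expect_equal(sp$p_hit, 1)

  # beyond alpha range: zero moments
  far <- single_hit_spectrum_mc(c(120, 0), tg, E0 = 8.3, n_samples = 1000,
                                seed = 5, model = m)
  expect_identical(far$z1, 0)
  expect_identical(far$z1sq, 0)

  # determinism given the seed
  a <- single_hit_spectrum_mc(c(10, 0), tg, 8.3, 5000, seed = 77, model = m)
  b <- single_hit_spectrum_mc(c(10, 0), tg, 8.3, 5000, seed = 77, model = m)
  expect_identical(a$z1, b$z1)
})

test_that("Monte Carlo moments agree with the quadrature oracle within sampling error", {
  m <- range_energy_model()
  tg <- target_cell(0, 0, 5, 4)
  for (geom in list(c(6, 0, 8.3), c(30, 10, 8.3), c(2, 1, 5.8),
                    c(60, 0, 8.3), c(12, -7, 5.8))) {
    sp <- single_hit_spectrum_mc(geom[1:2], tg, geom[3], 50000, seed = 19,
                                 model = m)
    or <- single_hit_moments_oracle(geom[1:2], tg, geom[3], 4096, model = m)
    se <- sqrt(max(sp$z1sq - sp$z1^2, 0) / sp$n_samples)
    expect_lt(abs(sp$z1 - or$z1), 3 * se + 1e-15)
    expect_gte(sp$z1sq, sp$z1^2)  # variance non-negativity
  }
})

test_that("the quadrature oracle self-converges and vanishes out of range", {
  m <- range_energy_model()
  tg <- target_cell(0, 0, 5, 4)
  expect_identical(single_hit_moments_oracle(c(120, 0), tg, 8.3, 64,
                                             model = m)$z1, 0)
  o1 <- single_hit_moments_oracle(c(9, 3), tg, 8.3, 4096, model = m)
  o2 <- single_hit_moments_oracle(c(9, 3), tg, 8.3, 8192, model = m)
  expect_lt(abs(o1$z1 / o2$z1 - 1), 1e-4)
})

test_that("dose kernel decays with distance except for the stopper peak at end of range", {
  m <- range_energy_model()
  tg <- target_cell(0, 0, 5, 4)
  d <- seq(5, 95, by = 5)
  kern <- vapply(d, function(dd) {
    or <- single_hit_moments_oracle(c(dd, 0), tg, 8.3, 2048, model = m)
    or$z1 * geometric_hit_probability(dd, tg$nucleus_radius_um)
  }, numeric(1))
  # over most of the range the shrinking solid angle dominates and
  # <z1> p_hit decreases monotonically ...
  crosser <- d <= 70
  expect_true(all(diff(kern[crosser]) < 0))
  # ... but near the end of range the per-hit deposit rises steeply
  # (full-energy stoppers), producing a local bump before the hard
  # range cutoff
  expect_gt(max(kern[d >= 75 & d <= 90]), kern[d == 70])
  expect_identical(kern[d == 95], 0)
  # the mean per-hit specific energy itself grows towards end of range
  z1s <- vapply(c(30, 60, 85), function(dd)
    single_hit_moments_oracle(c(dd, 0), tg, 8.3, 2048, model = m)$z1,
    numeric(1))
  expect_true(all(diff(z1s) > 0))
})

test_that("expected hit numbers follow the activity-probability product", {
  expect_identical(expected_hits(1.13, 0.1, 0), 0)
  expect_equal(expected_hits(1.13, 0.1, 0.01, 1), 1.13e-3, tolerance = 1e-12)
  draws <- expected_hits(rep(50, 1e5), 1, 0.04, 1, mode = "poisson",
                         seed = 123)
  expect_equal(mean(draws), 2, tolerance = 0.01)
  expect_error(expected_hits(-1, 1, 0.5), "inputs must be")
})

test_that("dose accumulation is additive and reproduces the closed-form linear growth", {
  acc <- dose_accumulator()
  expect_identical(acc$z, 0)
  acc0 <- accumulate_dose(acc, data.frame(n = c(0, 0), z1 = c(1, 2),
                                          z1sq = c(1, 4)))
  expect_identical(acc0$z, 0)
  expect_identical(acc0$var, 0)

  # two sources in one window equal two single-source windows
  c1 <- data.frame(n = 0.3, z1 = 2, z1sq = 5)
  c2 <- data.frame(n = 0.1, z1 = 7, z1sq = 50)
  both <- accumulate_dose(dose_accumulator(), rbind(c1, c2))
  seq2 <- accumulate_dose(accumulate_dose(dose_accumulator(), c1), c2)
  expect_equal(both$z, seq2$z, tolerance = 1e-15)
  expect_equal(both$var, seq2$var, tolerance = 1e-15)

  # constant-activity single source: z(t) = A Y p <z1> t
  A <- 1.13; p <- 0.02; z1 <- 3.4; dt <- 1e-3; K <- 250
  acc <- dose_accumulator()
  for (k in seq_len(K)) {
    acc <- accumulate_dose(acc, data.frame(n = expected_hits(A, dt, p),
                                           z1 = z1, z1sq = z1^2))
  }
  expect_equal(acc$z, A * p * z1 * dt * K, tolerance = 1e-12)
  expect_error(accumulate_dose(acc, data.frame(n = -1, z1 = 1, z1sq = 1)),
               "negative")
})
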