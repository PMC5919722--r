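test_that("parameter validation and closed-form oracles", {
  expect_error(telegraph_params(k_on = 0), "positive")
  expect_error(telegraph_params(n_copies = 3), "1 or 2")

  p <- telegraph_presets()
  expect_equal(stationary_mean(p$one_dose), 0.5 * 0.01 / 0.008) # 0.625
  expect_equal(stationary_mean(p$two_dose), 1.25)
  expect_equal(stationary_mean(p$one_dose_compensated), 1.25)
  expect_equal(fano_factor(p$one_dose),
               1 + 0.01 * 0.02 / (0.04 * (0.04 + 0.008)))
  # Fano is copy-number independent (independent copies)
  expect_equal(fano_factor(p$two_dose), fano_factor(p$one_dose))
  # constitutive limit: k_off -> 0 gives Poisson
  constitutive <- telegraph_params(k_on = 5, k_off = 1e-9, s_a = 0.01,
                                   delta_m = 0.008)
  expect_equal(stationary_mean(constitutive), 0.01 / 0.008, tolerance = 1e-6)
  expect_equal(fano_factor(constitutive), 1, tolerance = 1e-6)

  # the 14-minute half-life preset swaps only the degradation rate
  alt <- telegraph_presets(degradation = "half_time_14min")
  expect_equal(alt$one_dose$delta_m, log(2) / 840)
  expect_equal(alt$one_dose$k_on, 0.02)
})

test_that("single-cell trajectories satisfy the SSA contract", {
  p <- telegraph_presets()$two_dose
  tr <- simulate_cell(p, t_end = 5000, seed = 4)
  expect_true(all(diff(tr$time) > 0))
  expect_true(all(tr$mrna >= 0))
  expect_true(all(abs(diff(tr$mrna)) <= 1)) # events change counts by <= 1
  expect_true(all(tr$n_active %in% 0:2))
  expect_equal(tr$mrna[1], 0)   # starts with no mRNA
  expect_equal(tr$n_active[1], 0) # all copies repressed at t = 0

  # determinism: same seed reproduces the trajectory, different seed differs
  expect_equal(simulate_cell(p, 5000, seed = 4), tr)
  tr2 <- simulate_cell(p, 5000, seed = 5)
  expect_false(isTRUE(all.equal(tr, tr2)))

  # vanishing transcription: mRNA never appears
  silent <- telegraph_params(s_a = 1e-12)
  trs <- simulate_cell(silent, t_end = 1e4, seed = 1)
  expect_true(all(trs$mrna == 0))
})

test_that("SSA stationary mean and Fano match the closed forms", {
  p <- telegraph_presets()$two_dose
  x <- sample_population(p, 4000, t_obs = 4000, seed = 8,
                         observe = "time_average", burn_in = 1000)
  # time averages are unbiased for the stationary mean
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - stationary_mean(p)), 3 * se)

  # point observation after burn-in: mean and Fano within 3 block-SE
  y <- sample_population(p, 8000, seed = 8)
  se_y <- sd(y) / sqrt(length(y))
  expect_lt(abs(mean(y) - stationary_mean(p)), 3 * se_y)
  blocks <- split(y, rep(1:20, length.out = length(y)))
  fano_b <- vapply(blocks, function(b) var(b) / mean(b), numeric(1))
  se_f <- sd(fano_b) / sqrt(length(fano_b))
  expect_lt(abs(var(y) / mean(y) - fano_factor(p)), 3 * se_f)
})

test_that("population averaging shrinks delta as N^(-1/2)", {
  p <- telegraph_presets()$two_dose
  curve <- delta_vs_popsize(p, sizes = c(1, 10, 100, 1000), repeats = 20,
                            seed = 3)
  expect_true(all(diff(curve$mean_delta) < 0)) # monotone decreasing
  expect_gt(curve$mean_delta[1], 0.3)          # single cells: order 1
  expect_equal(delta_vs_popsize(p, sizes = c(1, 10, 100, 1000),
                                repeats = 20, seed = 3),
               curve) # identical seed, identical curve
  slope <- delta_curve_slope(curve)
  expect_lt(slope, -0.35)
  expect_gt(slope, -0.65)

  # parameter sweeps preserve "fewer cells => larger mean delta"
  for (s in list(telegraph_params(k_on = 0.05, k_off = 0.01),
                 telegraph_params(s_a = 0.05),
                 telegraph_params(delta_m = 0.002))) {
    cs <- delta_vs_popsize(s, sizes = c(10, 1000), repeats = 15, seed = 6,
                           t_obs = 5 / s$delta_m)
    expect_gt(cs$mean_delta[1], cs$mean_delta[2])
  }
})

test_that("compensated one-dose and two-dose genes have equal mean expression", {
  p <- telegraph_presets()
  m1 <- population_mean(p$one_dose_compensated, 6000, seed = 12)
  m2 <- population_mean(p$two_dose, 6000, seed = 13)
  v <- fano_factor(p$two_dose) * stationary_mean(p$two_dose)
  se <- sqrt(2 * v / 6000)
  expect_lt(abs(m1 - m2), 3 * se)
  # uncompensated one-dose genes sit at half that level
  m0 <- population_mean(p$one_dose, 6000, seed = 14)
  expect_lt(abs(m0 / m2 - 0.5), 0.06)
})
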