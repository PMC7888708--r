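test_that("noise-free sizer sits at its deterministic steady state", {
  p <- SimParams(control_model = "sizer", target_length = 14,
                 growth_rate = 0.05, trigger_noise_sd = 0, asym_sd = 0,
                 meas_noise_sd = 0, frame_interval = 0,
                 n_founders = 3L, founder_mean = 7, founder_sd = 0,
                 max_generations = 3L, total_time = 1e6)
  recs <- simulateLineages(p)
  expect_equal(nrow(recs), 3 * (1 + 2 + 4))
  expect_equal(recs$division_length_um, rep(14, nrow(recs)))
  expect_equal(recs$birth_length_um, rep(7, nrow(recs)))
  expect_equal(recs$extension_um, rep(7, nrow(recs)))
  expect_equal(recs$cycle_time_min, rep(140, nrow(recs)))
  # daughters are one generation later than their parents
  expect_equal(sort(unique(recs$generation)), 1:3)
  expect_equal(as.integer(table(recs$generation)), c(3L, 6L, 12L))
})

test_that("noise-free adder holds its fixed point and contracts deviations", {
  base <- list(control_model = "adder", increment = 7, growth_rate = 0.05,
               trigger_noise_sd = 0, asym_sd = 0, meas_noise_sd = 0,
               frame_interval = 0, n_founders = 2L, founder_sd = 0,
               max_generations = 3L, total_time = 1e6)
  at_fp <- simulateLineages(do.call(SimParams, c(base, founder_mean = 7)))
  expect_equal(at_fp$division_length_um, rep(14, nrow(at_fp)))
  expect_equal(at_fp$extension_um, rep(7, nrow(at_fp)))

  # from founder BL = 10 the deviation from D = 2*Delta halves per
  # generation: D_g = 14 + (10 - 7) / 2^(g-1)
  off <- simulateLineages(do.call(SimParams, c(base, founder_mean = 10)))
  d_by_gen <- tapply(off$division_length_um, off$generation, unique)
  expect_equal(unname(d_by_gen[["1"]]), 17)
  expect_equal(unname(d_by_gen[["2"]]), 15.5)
  expect_equal(unname(d_by_gen[["3"]]), 14.75)
})

test_that("sizer division-length CV matches the analytic trigger CV", {
  p <- sizerPreset(n_founders = 150L, seed = 11L)  # 1050 cycles
  recs <- simulateLineages(p)
  expect_gte(nrow(recs), 1000)
  cv <- cvPct(recs$division_length_um)
  se <- 8 / sqrt(2 * nrow(recs))
  expect_lt(abs(cv - 8), 3 * se)
})

test_that("extension conservation E = D - BL is exact for any settings", {
  for (p in list(sizerPreset(n_founders = 20L, seed = 2L),
                 adderPreset(n_founders = 20L, seed = 3L,
                             frame_interval = 10, meas_noise_sd = 0.2),
                 timerPreset(n_founders = 20L, seed = 4L,
                             frame_interval = 10))) {
    recs <- simulateLineages(p)
    expect_identical(recs$extension_um,
                     recs$division_length_um - recs$birth_length_um)
    expect_true(all(recs$birth_length_um > 0))
  }
  # with no frame sampling and no measurement noise, extension is positive
  recs <- simulateLineages(sizerPreset(n_founders = 30L, seed = 5L))
  expect_true(all(recs$extension_um > 0))
})

test_that("identical seeds reproduce bit-identically; different seeds agree in distribution", {
  p <- sizerPreset(n_founders = 72L, seed = 9L)
  expect_identical(simulateLineages(p), simulateLineages(p))
  a <- simulateLineages(sizerPreset(n_founders = 72L, seed = 9L))
  b <- simulateLineages(sizerPreset(n_founders = 72L, seed = 10L))
  expect_gte(nrow(a), 500)
  ks <- suppressWarnings(stats::ks.test(a$division_length_um,
                                        b$division_length_um))
  expect_gt(ks$p.value, 0.01)
})

test_that("frame sampling shortens recorded cycle time by at most two frames", {
  dt <- 10
  cont <- simulateLineages(sizerPreset(n_founders = 40L, seed = 6L))
  framed <- simulateLineages(sizerPreset(n_founders = 40L, seed = 6L,
                                         frame_interval = dt))
  # same seed and draw sequence: records correspond row by row
  expect_equal(nrow(cont), nrow(framed))
  expect_true(all(framed$cycle_time_min <= cont$cycle_time_min + 1e-9))
  expect_true(all(framed$cycle_time_min >= cont$cycle_time_min - 2 * dt))
  # recorded times sit on the frame grid
  expect_true(all(framed$birth_time_min %% dt == 0))
})

test_that("invalid simulation parameters are rejected", {
  expect_error(SimParams(target_length = -1), "trigger")
  expect_error(SimParams(trigger_noise_sd = -0.1), ">= 0")
  expect_error(SimParams(growth_rate = 0), "growth_rate")
  expect_error(MultinucSimParams(division_prob = 1.5), "division_prob")
  expect_error(IntensitySimParams(nuclei_per_cell = 1), "nuclei_per_cell")
})

test_that("synchronous nuclei double each cycle; q = 1 is the same limit", {
  sync <- simulateMultinucleate(MultinucSimParams(mode = "synchronous",
                                                  n_cycles = 3L,
                                                  n_cells = 50L, seed = 1L))
  expect_true(all(sync$nuclei_count[sync$cycle == 3] == 8))
  expect_true(all(sync$nuclei_count == 2^sync$cycle))
  ind1 <- simulateMultinucleate(MultinucSimParams(mode = "independent",
                                                  division_prob = 1,
                                                  n_cycles = 3L,
                                                  n_cells = 50L, seed = 1L))
  expect_equal(ind1$nuclei_count, sync$nuclei_count)
})

test_that("independent division matches the exact branching-process law", {
  n <- 10000L
  sim <- simulateMultinucleate(MultinucSimParams(mode = "independent",
                                                 division_prob = 0.5,
                                                 n_cycles = 2L,
                                                 n_cells = n, seed = 8L))
  final <- sim$nuclei_count[sim$cycle == 2]
  expect_true(all(final %in% 1:4))
  exact <- branchingDist(0.5, 2)
  expect_equal(unname(exact[["4"]]), 0.5 * 0.5^2)  # P(4) = q * q^2
  for (k in names(exact)) {
    phat <- mean(final == as.integer(k))
    se <- sqrt(exact[[k]] * (1 - exact[[k]]) / n)
    expect_lt(abs(phat - exact[[k]]), 3 * se)
  }
})

test_that("nuclear intensity simulation honours its variance structure", {
  p <- IntensitySimParams(n_cells = 5L, nuclei_per_cell = 4L, seed = 2L)
  iv <- simulateNuclearIntensities(p)
  expect_equal(nrow(iv), 20L)
  expect_equal(as.integer(table(iv$cell_id)), rep(4L, 5))

  # no within-cell noise: every per-cell CV is zero
  flat <- simulateNuclearIntensities(
    IntensitySimParams(n_cells = 20L, within_cell_sd = 0, seed = 3L))
  cvs <- perCellIntensityCV(flat)
  expect_equal(cvs$cv_pct, rep(0, 20))

  # no between-cell noise: per-cell CVs cluster at the analytic value
  # (for n = 4 normal draws E[s] = c4 * sigma with c4 ~ 0.9213)
  within <- simulateNuclearIntensities(
    IntensitySimParams(n_cells = 200L, between_cell_sd = 0,
                       within_cell_sd = 5, mean_intensity = 100,
                       seed = 4L))
  mean_cv <- attr(perCellIntensityCV(within), "mean_cv_pct")
  c4 <- sqrt(2 / 3) * gamma(2) / gamma(1.5)
  expect_lt(abs(mean_cv - 100 * 5 / 100 * c4), 0.5)
})
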