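test_that("extension is the exact difference of division and birth length", {
  recs <- makeRecords(bl = c(7.2, 8, 6.5), d = c(14.1, 8, 13))
  recs$extension_um <- NULL
  out <- computeExtension(recs)
  expect_equal(out$extension_um, c(6.9, 0, 6.5))
  expect_equal(out$neg_extension, c(FALSE, FALSE, FALSE))
  expect_equal(mean(out$extension_um),
               mean(out$division_length_um) - mean(out$birth_length_um))
  # negative extensions are flagged and retained
  neg <- computeExtension(makeRecords(bl = c(7, 9), d = c(14, 8.5)))
  expect_equal(attr(neg, "n_negative_extension"), 1L)
  expect_equal(nrow(neg), 2L)
  expect_error(computeExtension(data.frame(birth_length_um = 1)),
               "division_length_um")
})

test_that("cohorting uses half-open 0.5 um bins anchored at zero", {
  recs <- makeRecords(bl = c(6.1, 6.4, 6.9), d = rep(14, 3))
  co <- cohortByBirthLength(recs, width = 0.5)
  expect_equal(co$bin_start, c(6.0, 6.5))
  expect_equal(co$n, c(2L, 1L))
  # boundary value falls in the upper bin (half-open rule)
  b <- cohortByBirthLength(makeRecords(bl = 6.5, d = 14), width = 0.5)
  expect_equal(b$bin_start, 6.5)
  expect_error(
    cohortByBirthLength(data.frame(birth_length_um = numeric(0),
                                   division_length_um = numeric(0))),
    "empty")
})

test_that("noise-free sizer cohort means lie exactly on E = L_T - BL", {
  p <- SimParams(trigger_noise_sd = 0, asym_sd = 0.05, meas_noise_sd = 0,
                 frame_interval = 0, n_founders = 40L, founder_mean = 7,
                 founder_sd = 0.6, target_length = 14, seed = 21L,
                 total_time = 1e6)
  recs <- simulateLineages(p)
  co <- cohortByBirthLength(recs)
  expect_equal(co$mean_e, 14 - co$mean_bl, tolerance = 1e-10)
})

test_that("the BL/E regression reproduces closed-form OLS", {
  line <- makeRecords(bl = seq(4, 9.5, by = 0.5), d = 10 + seq(4, 9.5, 0.5))
  line$division_length_um <- 10  # E = 10 - BL exactly
  line$extension_um <- NULL
  fit <- suppressWarnings(fitBLE(line))  # exact fit: lm warns on zero residuals
  expect_equal(fit@slope, -1, tolerance = 1e-12)
  expect_equal(fit@intercept, 10, tolerance = 1e-12)
  expect_equal(fit@r_squared, 1, tolerance = 1e-12)

  pts <- makeRecords(bl = c(6, 7, 8), d = c(10, 10.5, 10.5))
  fit3 <- suppressWarnings(fitBLE(pts))
  expect_equal(fit3@slope, -0.75, tolerance = 1e-10)
  expect_equal(fit3@intercept, 8.5833, tolerance = 1e-4)

  flat <- makeRecords(bl = 1:12, d = 1:12 + 5)  # constant E
  expect_equal(suppressWarnings(fitBLE(flat))@slope, 0, tolerance = 1e-12)

  const <- makeRecords(bl = rep(7, 12), d = rep(14, 12))
  expect_error(fitBLE(const), "variation in birth length")
})

test_that("slope classification follows the configurable thresholds", {
  expect_equal(classifyControlMode(-0.72), "sizer_like")   # wild-type range
  expect_equal(classifyControlMode(-0.066), "adder_like")
  expect_equal(classifyControlMode(-0.46), "impaired")
  expect_equal(classifyControlMode(0.9), "timer_like")
  expect_equal(classifyControlMode(-0.5, thresholds = c(sizer = -0.4,
                                                        impaired = -0.1,
                                                        timer = 0.2)),
               "sizer_like")
})

test_that("simulated sizer, adder and timer recover their expected slopes", {
  fits <- list(
    sizer = fitBLE(simulateLineages(sizerPreset(129L, seed = 31L))),
    adder = fitBLE(simulateLineages(adderPreset(129L, seed = 32L))),
    timer = fitBLE(simulateLineages(timerPreset(129L, seed = 33L))))
  expect_lt(abs(fits$sizer@slope - (-1)), 3 * fits$sizer@slope_se)
  expect_lt(abs(fits$adder@slope - 0), 3 * fits$adder@slope_se)
  expect_lt(abs(fits$timer@slope - 1), 3 * fits$timer@slope_se)
  expect_equal(fits$sizer@mode_label, "sizer_like")
  expect_equal(fits$adder@mode_label, "adder_like")
  expect_equal(fits$timer@mode_label, "timer_like")
  # cohort sizes partition the sample
  expect_equal(sum(fits$sizer@cohorts$n), fits$sizer@n)
})

test_that("a common additive shift moves only the intercept", {
  recs <- simulateLineages(sizerPreset(30L, seed = 41L))
  shifted <- recs
  shifted$birth_length_um <- recs$birth_length_um + 2.5
  shifted$division_length_um <- recs$division_length_um + 2.5
  shifted$extension_um <- NULL
  f0 <- fitBLE(recs)
  f1 <- fitBLE(shifted)
  expect_equal(f1@slope, f0@slope, tolerance = 1e-10)
  # E is unchanged and BL shifts by c, so the intercept moves by -c * slope
  expect_equal(f1@intercept, f0@intercept - 2.5 * f0@slope,
               tolerance = 1e-8)
})

test_that("cohort-mean regression agrees with the raw regression on sizers", {
  recs <- simulateLineages(sizerPreset(129L, seed = 51L))
  fit <- fitBLE(recs)
  co <- fit@cohorts[fit@cohorts$n >= 5, ]
  cfit <- stats::lm(mean_e ~ mean_bl, data = co)
  expect_lt(abs(unname(stats::coef(cfit)[2]) - fit@slope),
            2 * fit@slope_se)
})

test_that("birth-length measurement noise biases the adder slope toward -1", {
  slopes <- vapply(c(0, 0.2, 0.4), function(sm) {
    fitBLE(simulateLineages(adderPreset(200L, seed = 61L,
                                        meas_noise_sd = sm)))@slope
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))  # monotone decrease toward -1
})
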