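test_that("shedding ratios follow the stated formula and normalisation", {
  plate <- data.frame(
    condition = rep(c("ctrl", "mut"), each = 2),
    compartment = rep(c("supernatant", "cell"), 2),
    fluorescence = c(300, 200, 500, 200))
  bg <- c(supernatant = 100, cell = 100)
  res <- shedding_ratio(plate, "ctrl", bg)
  expect_equal(res$ratio[res$condition == "ctrl"], 2.0)
  expect_equal(res$normalized_ratio[res$condition == "ctrl"], 1.0)
  expect_equal(res$normalized_ratio[res$condition == "mut"], 2.0)
  # corrected cell signal <= 0 is undefined
  bad <- plate; bad$fluorescence[2] <- 100
  expect_error(shedding_ratio(bad, "ctrl", bg), "undefined")
  expect_error(shedding_ratio(plate, "nope", bg), "not present")
})

test_that("shedding ratio is gain-invariant and recovers the generator's truth", {
  for (g in c(1, 10)) {
    sim <- simulate_plate(c(ctrl = 0.1, a = 0.3, b = 0.05),
                          n_wells = 4, gain = g, noise_sd = 0, seed = 41)
    res <- shedding_ratio(sim$plate, "ctrl", sim$background)
    expect_equal(res$normalized_ratio,
                 unname(sim$truth$expected_normalized[res$condition]),
                 tolerance = 1e-9, info = paste("gain", g))
  }
  # with noise the recovery holds within simulation error
  sim <- simulate_plate(c(ctrl = 0.1, a = 0.3), n_wells = 8,
                        total_signal = 1000, noise_sd = 5, seed = 42)
  res <- shedding_ratio(sim$plate, "ctrl", sim$background)
  expect_equal(res$normalized_ratio[res$condition == "a"],
               unname(sim$truth$expected_normalized[["a"]]), tolerance = 0.15)
  # a null condition stays at the control ratio
  sim0 <- simulate_plate(c(ctrl = 0.2, null = 0.2), noise_sd = 0, seed = 43)
  res0 <- shedding_ratio(sim0$plate, "ctrl", sim0$background)
  expect_equal(res0$normalized_ratio, c(1, 1))
})

test_that("FRET normalisation maps anchors to exactly 0 and 100", {
  sim <- simulate_fret_trace(bleed_through = 0.3, noise_sd = 0, seed = 51)
  out <- fret_normalize(sim$trace, sim$ligand_index, sim$stimulus_index,
                        sim$bleed_through, sim$background)
  expect_lt(max(abs(out$response - sim$truth$response_percent)), 1e-6)
  baseline_idx <- (sim$ligand_index - 10):(sim$ligand_index - 1)
  expect_equal(mean(out$response[baseline_idx]), 0, tolerance = 1e-9)
  n <- nrow(out)
  expect_equal(mean(out$response[(n - 9):n]), 100, tolerance = 1e-9)
  # hand-checked affine map: baseline 1, plateau 2, point 1.7 -> 70%
  expect_equal((1.7 - 1) / (2 - 1) * 100, 70)
  expect_error(fret_normalize(sim$trace, ligand_index = 5,
                              stimulus_index = sim$stimulus_index),
               "baseline")
})

test_that("three-parameter fits recover exact model data and are shift-equivariant", {
  conc <- 10^seq(-10.5, -6, length.out = 9)
  resp <- 0 + (100 - 0) / (1 + 10^(-8 - log10(conc)))
  fit <- fit_dose_response(conc, resp)
  expect_true(fit$converged)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_equal(fit$top, 100, tolerance = 1e-6)
  expect_equal(fit$logEC50, -8, tolerance = 1e-6)
  expect_equal(fit$df, 9L - 3L)
  # adding a constant shifts both asymptotes, not the EC50
  fit2 <- fit_dose_response(conc, resp + 37)
  expect_equal(fit2$bottom - fit$bottom, 37, tolerance = 1e-4)
  expect_equal(fit2$top - fit$top, 37, tolerance = 1e-4)
  expect_equal(fit2$logEC50, fit$logEC50, tolerance = 1e-5)
  # constant response is flagged degenerate
  flat <- fit_dose_response(conc, rep(5, 9))
  expect_true(flat$degenerate)
  expect_error(fit_dose_response(c(1e-8, 1e-8, 1e-7, 1e-7), c(1, 2, 3, 4)),
               "distinct")
})

test_that("the extra-sum-of-squares F test detects no gain on identical data", {
  conc <- rep(10^seq(-10, -6, length.out = 6), 2)
  set.seed(61)
  resp <- 10 + 90 / (1 + 10^(-8 - log10(conc))) + rnorm(length(conc), 0, 2)
  cmp <- compare_dose_response(conc, resp, conc, resp)
  expect_lt(cmp$test$F, 1e-6)
  expect_gt(cmp$test$p, 0.999)
  expect_error(ess_f_test(list(residual_ss = 1, df = 3),
                          list(residual_ss = 0.5, df = 5)), "df")
})

test_that("the F test is calibrated under the null and powered under a top shift", {
  conc <- 10^seq(-10, -6, length.out = 8)
  mu <- 0 + 100 / (1 + 10^(-8 - log10(conc)))
  sd_res <- 5
  n_null <- 200L
  rej <- 0L
  set.seed(62)
  for (r in seq_len(n_null)) {
    y1 <- mu + rnorm(8, 0, sd_res)
    y2 <- mu + rnorm(8, 0, sd_res)
    cmp <- compare_dose_response(conc, y1, conc, y2)
    if (cmp$test$p < 0.05) rej <- rej + 1L
  }
  rate <- rej / n_null
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / n_null)
  expect_gt(rate, ci[1] - 1e-9)
  expect_lt(rate, ci[2])

  # tops differing by 5 residual SDs, duplicate wells per concentration
  # (the assays are run in duplicates): overwhelmingly detected
  conc2 <- rep(conc, 2)
  mu_d <- 100 / (1 + 10^(-8 - log10(conc2)))
  mu2_d <- (100 + 5 * sd_res) / (1 + 10^(-8 - log10(conc2)))
  hits <- 0L
  n_pow <- 50L
  for (r in seq_len(n_pow)) {
    y1 <- mu_d + rnorm(16, 0, sd_res)
    y2 <- mu2_d + rnorm(16, 0, sd_res)
    cmp <- compare_dose_response(conc2, y1, conc2, y2)
    if (cmp$test$p < 0.001) hits <- hits + 1L
  }
  expect_gte(hits / n_pow, 0.95)
})

test_that("qPCR efficiency evaluates the printed formula", {
  expect_equal(qpcr_efficiency(-1 / log10(2)), 100, tolerance = 1e-9)
  expect_equal(qpcr_efficiency(-1), 900)
  expect_lt(qpcr_efficiency(-1000), 0.3)   # limiting behaviour toward 0
  expect_error(qpcr_efficiency(0), "non-zero")
})
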