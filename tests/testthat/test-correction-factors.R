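test_that("ratio factors: value, SEM propagation, and invariances", {
  # self-ratio
  same <- rep(2, 20)
  rf <- ratio_factor(same, same, kind = "k_s")
  expect_equal(rf$value, 1)
  expect_equal(rf$u, 0)

  # frozen SEM-propagation case: 2.10 +/- 0.02 over 2.00 +/- 0.02, n = 20
  num <- set_with_moments(2.10, 0.02, 20)
  den <- set_with_moments(2.00, 0.02, 20)
  rf <- ratio_factor(num, den, kind = "k_s")
  expect_equal(rf$value, 1.05, tolerance = 1e-12)
  expect_equal(rf$u, 0.00324, tolerance = 1e-2)

  # scale invariance of value and relative uncertainty
  rf3 <- ratio_factor(3 * num, 3 * den, kind = "k_s")
  expect_equal(rf3$value, rf$value)
  expect_equal(rf3$u / rf3$value, rf$u / rf$value)

  # transitivity: (A/B) * (B/C) = (A/C)
  a <- set_with_moments(2.2, 0.03, 15)
  b <- set_with_moments(2.0, 0.02, 20)
  cc <- set_with_moments(1.9, 0.02, 18)
  expect_equal(
    ratio_factor(a, b)$value * ratio_factor(b, cc)$value,
    ratio_factor(a, cc)$value,
    tolerance = 1e-14
  )

  expect_error(ratio_factor(2, den), "at least two readings")
  expect_error(ratio_factor(c(-1, 2), den), "positive")
})

test_that("analytic ratio uncertainty agrees with a bootstrap oracle", {
  num <- simulate_measurement_set(2.1, cv_pct = 1, n = 20, seed = 11)$reading_Gy
  den <- simulate_measurement_set(2.0, cv_pct = 1, n = 20, seed = 12)$reading_Gy
  rf <- ratio_factor(num, den)
  boot_sd <- withr::with_seed(99, {
    B <- 1e5
    mn <- colMeans(matrix(sample(num, 20 * B, replace = TRUE), nrow = 20))
    md <- colMeans(matrix(sample(den, 20 * B, replace = TRUE), nrow = 20))
    sd(mn / md)
  })
  expect_lt(abs(rf$u - boot_sd) / boot_sd, 0.1)
})

test_that("ratio_factor recovers a known true factor across repetitions", {
  true_f <- 1.05
  hits <- vapply(1:1000, function(i) {
    den <- simulate_measurement_set(2, cv_pct = 1, n = 20, seed = 2 * i)$reading_Gy
    num <- simulate_measurement_set(2 * true_f, cv_pct = 1, n = 20,
                                    seed = 2 * i + 1)$reading_Gy
    rf <- ratio_factor(num, den)
    abs(rf$value - true_f) <= 3 * rf$u
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("total-factor combination reproduces the published audit factors", {
  ir <- combine_total(
    correction_factor(0.993, 0.005, "k_m"),
    correction_factor(0.993, 0.009, "k_m", "mc"),
    correction_factor(1.054, 0.004, "k_s"),
    correction_factor(1.059, 0.008, "k_s", "mc"),
    correction_factor(0.981, 0.005, "k_Q")
  )
  expect_equal(round(ir$value, 3), 1.029)
  expect_equal(round(ir$u, 3), 0.009)

  # Co-60: rounded published inputs land within 0.15 % of the published total
  co <- combine_total(1.004, 1.005, 1.010, 1.009, 1.043)
  expect_equal(round(co$value, 3), 1.058)
  expect_lt(abs(co$value / 1.059 - 1), 0.0015)

  ident <- combine_total(1, 1, 1, 1, 1)
  expect_equal(ident$value, 1)
  expect_equal(ident$u, 0)

  # monotone increasing in every argument
  base <- combine_total(1, 1, 1, 1, 1)$value
  for (i in 1:5) {
    args <- as.list(rep(1, 5))
    args[[i]] <- 1.01
    expect_gt(do.call(combine_total, args)$value, base)
  }
})

test_that("experimental vs reference comparison reports relative agreement", {
  km_exp <- correction_factor(0.993, 0.005, "k_m")
  km_mc <- correction_factor(0.993, 0.009, "k_m", "mc")
  rep1 <- validate_against_reference(km_exp, km_mc, tolerance_pct = 0.5)
  expect_equal(rep1$diff_pct, 0)
  expect_true(rep1$within_tolerance)

  ks_exp <- correction_factor(1.054, 0.004, "k_s")
  ks_mc <- correction_factor(1.059, 0.008, "k_s", "mc")
  rep2 <- validate_against_reference(ks_exp, ks_mc, tolerance_pct = 0.5)
  expect_equal(rep2$diff_pct, 0.47, tolerance = 1e-2)
  expect_true(rep2$within_tolerance)
  expect_true(rep2$within_uncertainty)

  expect_error(validate_against_reference(km_exp, ks_mc), "different kinds")
})

test_that("estimate_factors derives the three factors from a tidy readings table", {
  sets <- dplyr::bind_rows(
    simulate_measurement_set(2.00, 0.5, 20, seed = 1, setup_label = "A"),
    simulate_measurement_set(2.10, 0.5, 20, seed = 2,
                             setup_label = "B_pmma_in_water"),
    simulate_measurement_set(2.09, 0.5, 20, seed = 3,
                             setup_label = "C_plasticwater_in_water"),
    simulate_measurement_set(2.05, 0.5, 20, seed = 4,
                             setup_label = "reference_co60")
  )
  out <- estimate_factors(sets)
  expect_equal(out$kind, c("k_s", "k_m", "k_Q"))
  means <- tapply(sets$reading_Gy, sets$setup_label, mean)
  expect_equal(out$value[out$kind == "k_s"],
               unname(means["B_pmma_in_water"] / means["A"]))
  expect_equal(out$value[out$kind == "k_Q"],
               unname(means["reference_co60"] / means["C_plasticwater_in_water"]))
})
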