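mk_records <- function(ratios, shifts = rep(0, length(ratios)), d_user = 2) {
  tibble::tibble(
    centre_id = sprintf("C%02d", seq_along(ratios)),
    radionuclide = rep(c("Ir-192", "Co-60"), length.out = length(ratios)),
    d_user_Gy = d_user,
    rpld1_Gy = ratios * d_user,
    rpld2_Gy = ratios * d_user,
    shift1_mm = shifts,
    shift2_mm = shifts
  )
}

test_that("per-set endpoints: dose ratio, intra-set difference, shift", {
  rec <- tibble::tibble(d_user_Gy = 2, rpld1_Gy = 2.00, rpld2_Gy = 2.04,
                        shift1_mm = 1, shift2_mm = 2)
  out <- dose_ratio(rec)
  expect_equal(out$dose_ratio, 1.010)
  expect_equal(out$d_iaea_Gy, 2.02)
  expect_equal(out$mean_shift_mm, 1.5)
  expect_equal(out$shift_u_mm, sqrt(0.09 + 0.5))

  # scaling all doses leaves the ratio unchanged
  out3 <- dose_ratio(dplyr::mutate(rec, d_user_Gy = d_user_Gy * 3,
                                   rpld1_Gy = rpld1_Gy * 3,
                                   rpld2_Gy = rpld2_Gy * 3))
  expect_equal(out3$dose_ratio, out$dose_ratio)
  expect_error(dose_ratio(dplyr::mutate(rec, d_user_Gy = 0)), "positive")
})

test_that("cohort summary matches hand computation on a small cohort", {
  summ <- summarize_cohort(mk_records(c(0.97, 1.00, 1.04)))
  expect_equal(summ$n_sets, 3)
  expect_equal(summ$ratio_mean, mean(c(0.97, 1.00, 1.04)))
  expect_equal(summ$n_within_3pct, 2)
  expect_equal(summ$n_within_5pct, 3)
  expect_equal(summ$ratio_min, 0.97)
  expect_equal(summ$ratio_max, 1.04)
  expect_false(summ$insufficient_n)
  by_nuc <- summ$by_radionuclide[[1]]
  expect_equal(sum(by_nuc$n), 3)
})

test_that("single-set cohorts report SD 0 with an insufficient-n flag", {
  summ <- summarize_cohort(mk_records(1.0))
  expect_equal(summ$ratio_sd, 0)
  expect_equal(summ$shift_sd_mm, 0)
  expect_true(summ$insufficient_n)
})

test_that("summary is permutation invariant and counts are nested", {
  rec <- simulate_cohort(n_sets = 30, seed = 4)
  s1 <- summarize_cohort(rec)
  s2 <- summarize_cohort(rec[sample(nrow(rec)), ])
  expect_equal(glance(s1), glance(s2))
  expect_lte(s1$n_within_3pct, s1$n_within_5pct)
  expect_lte(s1$n_within_5pct, s1$n_sets)
  expect_lte(s1$n_within_3mm, s1$n_within_5mm)
})

test_that("classification counts match the generator's normal-tail probabilities", {
  n_cohorts <- 500
  n_sets <- 59
  ratio_mean <- 1.008; ratio_sd <- 0.014
  shift_mean <- 1.2; shift_sd <- 2.5; film_sd <- 0.3
  counts <- vapply(seq_len(n_cohorts), function(i) {
    s <- summarize_cohort(simulate_cohort(
      n_sets = n_sets, ratio_mean = ratio_mean, ratio_sd = ratio_sd,
      shift_mean_mm = shift_mean, shift_sd_mm = shift_sd,
      film_sd_mm = film_sd, seed = i
    ))
    c(s$n_within_3pct, s$n_within_3mm)
  }, numeric(2))

  p_ratio <- pnorm(0.03, ratio_mean - 1, ratio_sd) -
    pnorm(-0.03, ratio_mean - 1, ratio_sd)
  sd_set_shift <- sqrt(shift_sd^2 + film_sd^2 / 2) # mean of two films
  p_shift <- pnorm(3, shift_mean, sd_set_shift) -
    pnorm(-3, shift_mean, sd_set_shift)

  for (k in 1:2) {
    p <- c(p_ratio, p_shift)[k]
    mc_sem <- sqrt(n_sets * p * (1 - p)) / sqrt(n_cohorts)
    expect_lt(abs(mean(counts[k, ]) - n_sets * p), 5 * mc_sem)
  }
})

test_that("cohort report writes per-set CSV and summary JSON", {
  dir <- withr::local_tempdir()
  rec <- simulate_cohort(n_sets = 10, seed = 2)
  summ <- write_cohort_report(rec, dir)
  per_set <- read.csv(file.path(dir, "per_set_results.csv"))
  expect_equal(nrow(per_set), 10)
  js <- jsonlite::fromJSON(file.path(dir, "cohort_summary.json"))
  expect_equal(js$n_sets, 10)
  expect_equal(js$ratio_mean, summ$ratio_mean, tolerance = 1e-12)
})

test_that("cohort plots build without error", {
  rec <- simulate_cohort(n_sets = 12, seed = 3)
  expect_s3_class(plot_cohort_shifts(rec), "ggplot")
  expect_s3_class(plot_cohort_ratios(rec), "ggplot")
})
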