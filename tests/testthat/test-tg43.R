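test_that("point geometry function is the inverse square law", {
  expect_equal(geometry_function(1, 90, model = "point"), 1)
  expect_equal(geometry_function(2, 90, model = "point"), 0.25)
  r <- c(0.5, 1, 1.7, 3, 4.2)
  ratio <- geometry_function(2 * r, 90, model = "point") /
    geometry_function(r, 90, model = "point")
  expect_equal(ratio, rep(0.25, length(r)), tolerance = 1e-12)
  expect_error(geometry_function(0, 90, model = "point"), "r <= 0")
})

test_that("line geometry function matches a numerical segment-integration oracle", {
  cases <- expand.grid(r = c(0.5, 1, 2, 3.6), theta = c(10, 45, 90, 135, 170))
  for (i in seq_len(nrow(cases))) {
    got <- geometry_function(cases$r[i], cases$theta[i], 3.5, "line")
    want <- g_line_numeric(cases$r[i], cases$theta[i], 3.5)
    expect_equal(got, want, tolerance = 1e-8)
  }
  # frozen oracle value at the reference geometry
  expect_equal(geometry_function(1, 90, 3.5, "line"), 0.9899752,
               tolerance = 1e-6)
  expect_error(geometry_function(1, 90, -3, "line"), "positive active length")
})

test_that("line geometry converges to the point model as L -> 0", {
  r <- c(1, 2, 5)
  for (L in c(0.01, 0.001)) {
    rel <- abs(geometry_function(r, 90, L, "line") * r^2 - 1)
    expect_true(all(rel < 1e-6))
  }
  # on-axis limit form is continuous with the off-axis branch
  near <- geometry_function(2, 0.001, 3.5, "line")
  on <- geometry_function(2, 0, 3.5, "line")
  expect_equal(near, on, tolerance = 1e-5)
})

test_that("radial interpolation is linear inside and clamps with warning outside", {
  tab <- data.frame(r_cm = c(1, 2), g = c(1.0, 0.9))
  expect_equal(interpolate_radial(tab, 1), 1.0)
  expect_equal(interpolate_radial(tab, 1.5), 0.95)
  expect_warning(out <- interpolate_radial(tab, 2.3), "clamping")
  expect_equal(out, 0.9)
  expect_error(interpolate_radial(tab, 3), "outside the supported range")
  expect_error(interpolate_radial(data.frame(r_cm = numeric(), g = numeric()), 1),
               "Empty")
})

test_that("toy dose rate reduces to inverse square at unit strength", {
  src <- toy_source()
  dwell <- data.frame(x_mm = 0, y_mm = 0, z_mm = 0)
  p1 <- data.frame(x_mm = 0, y_mm = 10, z_mm = 0)
  p2 <- data.frame(x_mm = 0, y_mm = 20, z_mm = 0)
  expect_equal(dose_rate_at(p1, dwell, src, 1), 0.01)
  expect_equal(dose_rate_at(p2, dwell, src, 1), 0.0025)
  expect_error(dose_rate_at(dwell, dwell, src, 1), "coincides")
})

test_that("line and point sources agree at the reference point when tables are flat", {
  flat <- data.frame(r_cm = c(0.1, 1, 10), g = c(1, 1, 1))
  pt <- source_dataset("p", "toy", 1, geometry_model = "point",
                       radial_dose = flat)
  ln <- source_dataset("l", "toy", 1, active_length_mm = 3.5,
                       geometry_model = "line", radial_dose = flat)
  p <- data.frame(x_mm = 0, y_mm = 10, z_mm = 0) # r = 1 cm, theta = 90
  dwell <- data.frame(x_mm = 0, y_mm = 0, z_mm = 0)
  expect_equal(dose_rate_at(p, dwell, pt, 5),
               dose_rate_at(p, dwell, ln, 5), tolerance = 1e-12)
})

test_that("dose accumulation is rate x time, additive, and matches a hand sum", {
  src <- toy_source()
  p <- data.frame(x_mm = 10, y_mm = 0, z_mm = 0)
  one <- data.frame(x_mm = 0, y_mm = 0, z_mm = 0, dwell_time_s = 3600)
  expect_equal(accumulate_dose(p, dplyr::mutate(one, dwell_time_s = 0),
                               src, 1)$dose_Gy, 0)
  expect_equal(accumulate_dose(p, one, src, 1)$dose_Gy, 0.01)
  # splitting the time across two co-located dwells changes nothing
  split2 <- dplyr::bind_rows(one, one) |>
    dplyr::mutate(dwell_time_s = 1800)
  expect_equal(accumulate_dose(p, split2, src, 1)$dose_Gy, 0.01)

  # independent hand-summed 3-dwell inverse-square oracle
  dwells <- data.frame(x_mm = c(0, 10, -20), y_mm = c(0, 10, 0),
                       z_mm = 0, dwell_time_s = c(3600, 1800, 7200))
  pt <- data.frame(x_mm = 0, y_mm = 20, z_mm = 0)
  r2_cm2 <- c(2^2, 1^2 + 1^2, 2^2 + 2^2)
  want <- sum(0.01 / r2_cm2 * c(1, 0.5, 2))
  expect_equal(accumulate_dose(pt, dwells, src, 1)$dose_Gy, want,
               tolerance = 1e-15)
  expect_error(
    accumulate_dose(pt, dplyr::mutate(dwells, dwell_time_s = c(1, Inf, 1)),
                    src, 1),
    "finite"
  )
})

test_that("reference-plan dose field is mirror symmetric in x and y", {
  plan <- build_reference_plan(brachy_source("ir192"), rakr = 40000)
  pts <- tidyr::expand_grid(x_mm = c(1.5, 7, 13), y_mm = c(0.5, 4),
                            z_mm = c(0, 2))
  mirror_x <- dplyr::mutate(pts, x_mm = -x_mm)
  mirror_y <- dplyr::mutate(pts, y_mm = -y_mm)
  d0 <- accumulate_dose(pts, plan$dwells, plan$source, plan$rakr)$dose_Gy
  dx <- accumulate_dose(mirror_x, plan$dwells, plan$source, plan$rakr)$dose_Gy
  dy <- accumulate_dose(mirror_y, plan$dwells, plan$source, plan$rakr)$dose_Gy
  expect_equal(dx, d0, tolerance = 1e-10)
  expect_equal(dy, d0, tolerance = 1e-10)
})
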