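# Independent oracles and fixture builders shared across tests.

# Line-source geometry function by brute-force numerical integration of
# 1/d^2 along the active length, independent of the closed form used in
# the package.
g_line_numeric <- function(r_cm, theta_deg, L_mm) {
  L <- L_mm / 10
  th <- theta_deg * pi / 180
  rho <- r_cm * sin(th)
  z <- r_cm * cos(th)
  stats::integrate(function(l) 1 / (rho^2 + (z - l)^2), -L / 2, L / 2,
                   rel.tol = 1e-12)$value / L
}

# Deterministic reading set with exact mean and SD.
set_with_moments <- function(mean, sd, n) {
  z <- seq_len(n)
  z <- (z - mean(z)) / stats::sd(z)
  mean + sd * z
}

interpolate_anisotropy_pub <- brachyaudit:::interpolate_anisotropy

# Unit-strength point source with flat dose functions, built in code so
# engine tests do not depend on the bundled fixtures.
toy_source <- function() {
  source_dataset(
    label = "test-toy", radionuclide = "toy",
    lambda_cGy_per_h_per_U = 1, geometry_model = "point",
    radial_dose = data.frame(r_cm = c(0.1, 1, 10), g = c(1, 1, 1))
  )
}
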