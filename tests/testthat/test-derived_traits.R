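test_that("g_min matches hand arithmetic on a constant-rate drying curve", {
  # oracle: 1.08 mg/h over 10 cm2 at 20 C, RH 50%, 101.3 kPa;
  # esat(20) by Tetens = 0.61078 * exp(17.27*20/257.3)
  esat20 <- 0.61078 * exp(17.27 * 20 / (20 + 237.3))
  vpd <- esat20 * 0.5
  expected <- (1.08e-3 / 3600 / 18.015) / 1e-3 / (vpd / 101.3)
  res <- compute_gmin(drying_series(rate_g_per_h = 1.08e-3))
  expect_equal(res$value, expected, tolerance = 1e-10)
  expect_equal(expected, 1.44e-3, tolerance = 0.01)   # magnitude sanity

  # invariant to resampling of the time grid on a constant-slope series
  res4 <- compute_gmin(drying_series(rate_g_per_h = 1.08e-3,
                                     hours = seq(0, 24, 4)))
  expect_equal(res4$value, res$value, tolerance = 1e-10)
})

test_that("g_min edge cases: zero loss, low Fv/Fm, mass gain", {
  s <- drying_series(rate_g_per_h = 0)
  expect_equal(compute_gmin(s)$value, 0)

  s_bad <- drying_series(fvfm = 0.5)
  res <- compute_gmin(s_bad)
  expect_true(is.na(res$value))
  expect_match(res$reason, "Fv/Fm")

  s_gain <- drying_series()
  s_gain$leaf_mass[5] <- s_gain$leaf_mass[4] + 0.01   # transient gain
  expect_warning(compute_gmin(s_gain), "mass gain")
})

test_that("k_leaf divides transpiration by the psi gradient and filters", {
  r <- compute_kleaf(2, -0.5, -1.5)
  expect_equal(r$kleaf, 2)
  expect_false(r$excluded)

  r2 <- compute_kleaf(1.5, -1.0, -1.2)       # gradient 0.2 < 0.3
  expect_true(r2$excluded)
  expect_match(r2$reason, "0.3")

  r3 <- compute_kleaf(1.5, -1.4, -1.2)       # negative gradient
  expect_true(r3$excluded)
  expect_match(r3$reason, "non-positive")

  expect_equal(compute_kleaf(0, -0.5, -1.5)$kleaf, 0)
  expect_error(compute_kleaf(-1, -0.5, -1.5), ">= 0")
})

test_that("K_stem is the flow-pressure slope, viscosity-corrected and area-scaled", {
  grads <- rep(c(1e-5, 3e-5, 5e-5), each = 3)
  s <- data.frame(flow = 0.01 * grads, pressure_gradient = grads,
                  temperature = 20, xylem_area = 1, leaf_area = 0.05)
  expect_equal(compute_kstem(s)$value, 0.01, tolerance = 1e-12)

  # same data logged at 25 C: correction is eta(25)/eta(20) ~ 0.890/1.002
  s25 <- s; s25$temperature <- 25
  expect_equal(compute_kstem(s25)$value, 0.01 * 0.8900 / 1.002,
               tolerance = 0.002)

  s_flat <- s; s_flat$flow <- 0.5
  expect_match(compute_kstem(s_flat)$flag, "non-positive")
  expect_error(compute_kstem(s[1:3, ]), "distinct pressures")

  s2 <- s; s2$xylem_area <- 4
  expect_equal(compute_kstem(s2)$value, 0.01 / 4, tolerance = 1e-12)
  expect_equal(compute_kstem(s2, area_basis = "leaf")$value, 0.01 / 0.05,
               tolerance = 1e-12)
})

test_that("hydraulic diameter is the power-4 mean with its inequalities", {
  expect_equal(hydraulic_diameter(c(15, 15, 15)), 15)
  expect_equal(hydraulic_diameter(c(10, 20)), ((10^4 + 20^4) / 2)^(1 / 4))
  expect_equal(hydraulic_diameter(30), 30)
  expect_error(hydraulic_diameter(numeric(0)), "empty")

  set.seed(5)
  for (i in 1:20) {
    d <- stats::rlnorm(30, 3, 0.4)
    dh <- hydraulic_diameter(d)
    expect_gte(dh, mean(d))           # power-mean inequality, exponent 4
    expect_lte(dh, max(d))
    expect_gte(dh, min(d))
  }
})

test_that("theoretical conductivity follows Poiseuille's quartic sum", {
  # constant-by-constant oracle: 4 vessels of 50 um in 1 mm2
  rho <- 998.2; eta <- 1.002e-3
  expected <- (pi * rho / (128 * eta)) * 4 * (50e-6)^4 / 1e-6 * 1e6
  expect_equal(theoretical_conductivity(rep(50, 4), 1), expected,
               tolerance = 1e-12)

  base <- theoretical_conductivity(c(20, 35, 50), 2)
  expect_equal(theoretical_conductivity(2 * c(20, 35, 50), 2), 16 * base,
               tolerance = 1e-12)
  expect_error(theoretical_conductivity(numeric(0), 1), "empty")
})

test_that("relative growth rate is the log-size slope in field units", {
  expect_equal(relative_growth_rate(c(0, 100), c(1, exp(1))), 10)
  expect_equal(relative_growth_rate(c(0, 50, 100), rep(2, 3)), 0)
  r <- 0.025
  days <- c(10, 40, 90)
  expect_equal(relative_growth_rate(days, 3 * exp(r * days), units = "none"),
               r, tolerance = 1e-12)
  expect_equal(relative_growth_rate(days, 3 * exp(r * days), units = "height"),
               10 * r, tolerance = 1e-12)
  expect_error(relative_growth_rate(c(0, 10), c(1, -2)), "> 0")
})

test_that("root-mass imputation recovers a planted allometry exactly", {
  raw <- simulate_raw_streams(seed = 3)
  res <- impute_root_mass(raw$roots)
  expect_equal(res$total_mass, raw$truth$root_total, tolerance = 1e-9)
  expect_equal(unname(res$allometry),
               unname(raw$truth$root_allometry), tolerance = 1e-9)
  # measured masses never altered
  n0 <- nrow(raw$roots)
  expect_equal(res$table$dry_mass[seq_len(n0)], raw$roots$dry_mass)

  # no breakage: every distal end continues into a match or tapers to a tip
  clean <- raw$roots
  clean$distal_diameter <- c(0.2, 0.3, 0.5, 0.8, 1.2, 2.4, 4.0)
  res0 <- impute_root_mass(clean)
  expect_equal(res0$imputed_fraction, 0)
  expect_equal(res0$total_mass, sum(clean$dry_mass))

  expect_error(impute_root_mass(raw$roots[1:2, ]), "complete segments")
})

test_that("standardized ratio recovers group intercepts under a common slope", {
  # T1 = c_g * T2^beta exactly: returned values equal ln(c_g) within group
  set.seed(7)
  g <- rep(c("a", "b", "c"), each = 8)
  t2 <- stats::rlnorm(24, 1, 0.5)
  cg <- c(a = 2, b = 5, c = 0.4)
  beta <- 0.75
  t1 <- cg[g] * t2^beta
  res <- standardized_ratio(t1, t2, g)
  expect_equal(res$beta, beta, tolerance = 1e-10)
  expect_equal(unname(res$ratio), unname(log(cg[g])), tolerance = 1e-10)

  # beta = 1 with T1 = T2 gives all zeros
  res1 <- standardized_ratio(t2, t2, g)
  expect_equal(res1$ratio, rep(0, 24), tolerance = 1e-12)

  # invariance: scaling T2 by a constant shifts all ratios by -beta*log(k)
  res_k <- standardized_ratio(t1, t2 * 3, g)
  expect_equal(res_k$ratio, res$ratio - res$beta * log(3), tolerance = 1e-10)

  # noisy recovery of a planted slope within 3 se
  t1n <- t1 * exp(stats::rnorm(24, 0, 0.1))
  resn <- standardized_ratio(t1n, t2, g)
  se_b <- summary(resn$fit)$coefficients["l2", "Std. Error"]
  expect_lt(abs(resn$beta - beta), 3 * se_b)
})
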