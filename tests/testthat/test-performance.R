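test_that("realized growth and its standard error match hand arithmetic", {
  # p=0.5, n'=100, m=10, s=2, n=25:
  # se2 = (0.25 + 0.0025) * 0.16 + 100 * 0.0025 = 0.2904
  cells <- performance_cells("a", "s1", 100, 50, 25, 10, 2)
  rg <- realized_growth(cells)
  expect_equal(rg$h_star, 5)
  expect_equal(rg$se^2, 0.2904, tolerance = 1e-12)
  expect_equal(rg$se, 0.5388877, tolerance = 1e-6)

  # certain survival: se reduces to the SE of the mean
  c1 <- performance_cells("a", "s1", 80, 80, 30, 12, 3)
  expect_equal(realized_growth(c1)$se, 3 / sqrt(30), tolerance = 1e-12)
  expect_equal(realized_growth(c1)$h_star, 12)

  # nothing survived: both zero
  c0 <- performance_cells("a", "s1", 80, 0, 0, NA, NA)
  rg0 <- realized_growth(c0)
  expect_equal(rg0$h_star, 0)
  expect_equal(rg0$se, 0)
  expect_true(rg0$se_defined)
})

test_that("the delta-method se matches a Monte-Carlo oracle", {
  # oracle: survival ~ binomial(n', p)/n', trait mean ~ normal(m, s/sqrt(n))
  set.seed(99)
  grid <- expand.grid(p = c(0.2, 0.5, 0.9), np = c(50, 200), sm = c(0.1, 0.4))
  for (i in seq_len(nrow(grid))) {
    p <- grid$p[i]; np <- grid$np[i]; m <- 10; s <- grid$sm[i] * m
    n <- min(25, round(p * np))
    cells <- performance_cells("a", "s1", np, round(p * np), n, m, s)
    rg <- realized_growth(cells)
    R <- 2e5
    draws <- (stats::rbinom(R, np, cells$p_hat) / np) *
      stats::rnorm(R, m, s / sqrt(n))
    expect_equal(rg$se, stats::sd(draws), tolerance = 0.02)
  }
})

test_that("pairwise realized-growth z-tests and letters behave as derived", {
  rg <- data.frame(species_id = c("a", "b"), site_id = "s1",
                   h_star = c(10, 5), se = c(1, 1), se_defined = TRUE)
  out <- compare_realized(rg)
  expect_equal(out$pairs$z, 5 / sqrt(2), tolerance = 1e-6)
  expect_equal(out$pairs$p, 2 * stats::pnorm(-5 / sqrt(2)), tolerance = 1e-10)
  expect_equal(out$pairs$p, 4.06e-4, tolerance = 0.01)

  # identical cells: p = 1
  rg_eq <- data.frame(species_id = c("a", "b"), site_id = "s1",
                      h_star = c(4, 4), se = c(0.5, 0.5), se_defined = TRUE)
  expect_equal(compare_realized(rg_eq)$pairs$p, 1, tolerance = 1e-12)

  # three species, one clearly distinct: letters {a, b, b}
  rg3 <- data.frame(species_id = c("big", "s1x", "s2x"), site_id = "s1",
                    h_star = c(50, 10, 10.5), se = c(1, 1, 1),
                    se_defined = TRUE)
  lt <- compare_realized(rg3)$letters
  expect_equal(unname(lt["big"]), "a")
  expect_equal(unname(lt["s1x"]), "b")
  expect_equal(unname(lt["s2x"]), "b")

  # invariance under common positive rescaling of H* and se
  rg_s <- rg3
  rg_s$h_star <- rg3$h_star * 7.3
  rg_s$se <- rg3$se * 7.3
  expect_equal(compare_realized(rg_s)$pairs$p, compare_realized(rg3)$pairs$p,
               tolerance = 1e-12)
})

test_that("survival comparisons use the Yates-corrected chi-square", {
  # textbook Yates formula on 90/100 vs 10/100:
  # chi2 = N(|ad-bc| - N/2)^2 / row/col products = 124.82
  cells <- performance_cells(c("a", "b"), "s1", c(100, 100), c(90, 10),
                             c(90, 10), c(1, 1), c(0.1, 0.1))
  out <- compare_survival(cells)
  n <- 200; ad_bc <- abs(90 * 90 - 10 * 10)
  chi_hand <- n * (ad_bc - n / 2)^2 / (100 * 100 * 100 * 100)
  expect_equal(out$chisq, chi_hand, tolerance = 1e-10)
  expect_equal(out$chisq, 124.82, tolerance = 1e-10)
  expect_lt(out$p, 1e-28)

  cells_eq <- performance_cells(c("a", "b"), "s1", c(100, 100), c(50, 50),
                                c(50, 50), c(1, 1), c(0.1, 0.1))
  expect_equal(compare_survival(cells_eq)$p, 1, tolerance = 1e-12)

  cells_zero <- performance_cells(c("a", "b"), "s1", c(2, 2), c(0, 0),
                                  c(0, 0), c(NA, NA), c(NA, NA))
  expect_warning(out0 <- compare_survival(cells_zero), "zero-margin")
  expect_equal(out0$p, 1)

  small <- performance_cells(c("a", "b"), "s1", c(2, 2), c(1, 2), c(1, 2),
                             c(1, 1), c(0, 0))
  outs <- compare_survival(small)
  expect_gte(outs$chisq, 0)
  expect_true(outs$p > 0 && outs$p <= 1)
})

test_that("Tukey HSD letters separate well-spread groups and drop singletons", {
  vals <- c(rep(0, 10), rep(0.2, 10), rep(10, 10))
  grp <- rep(c("lo", "lo2", "hi"), each = 10)
  set.seed(1)
  vals <- vals + stats::rnorm(30, 0, 0.5)
  out <- compare_means_hsd(vals, grp)
  expect_equal(out$letters[["hi"]], "a")
  expect_equal(out$letters[["lo"]], out$letters[["lo2"]])
  expect_false(out$letters[["hi"]] == out$letters[["lo"]])

  # studentized-range oracle for a balanced layout
  fit <- stats::aov(vals ~ factor(grp))
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  means <- tapply(vals, grp, mean)
  q_obs <- abs(means["lo"] - means["lo2"]) / sqrt(mse / 10)
  p_hand <- stats::ptukey(q_obs, nmeans = 3, df = 27, lower.tail = FALSE)
  i <- grep("lo2-lo|lo-lo2", rownames(out$hsd))
  expect_equal(unname(out$hsd[i, "p adj"]), unname(p_hand), tolerance = 1e-8)

  # singleton group excluded
  out2 <- compare_means_hsd(c(vals, 99), c(grp, "solo"))
  expect_equal(out2$excluded, "solo")
  expect_false("solo" %in% names(out2$letters))
})

test_that("identical constant groups share one letter", {
  vals <- rep(5, 12)
  grp <- rep(c("a", "b", "c"), each = 4)
  out <- compare_means_hsd(vals, grp)
  expect_equal(unname(out$letters), rep("a", 3))
})

test_that("sigmoidal survival fits recover planted parameters", {
  set.seed(12)
  pe <- seq(0.15, 1.1, length.out = 10)
  s_true <- 0.9 / (1 + exp(-10 * (0.5 - pe)))
  fit <- fit_survival_sigmoid(s_true, pe)
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-10)
  expect_equal(fit$s_max, 0.9, tolerance = 1e-4)
  expect_equal(fit$beta, -10, tolerance = 1e-3)
  expect_equal(fit$a, 0.5, tolerance = 1e-4)

  s_noisy <- pmin(1, pmax(0, s_true + stats::rnorm(10, 0, 0.02)))
  fitn <- fit_survival_sigmoid(s_noisy, pe)
  expect_lt(abs(fitn$beta - (-10)), 3 * fitn$se[["beta"]] + 1e-9)
  expect_equal(fitn$preferred, "sigmoid")

  s_const <- rep(0.6, 8) + stats::rnorm(8, 0, 0.01)
  fitc <- fit_survival_sigmoid(s_const, seq(0.2, 1, length.out = 8))
  expect_equal(fitc$preferred, "linear")
  expect_error(fit_survival_sigmoid(c(0.1, 0.5, 0.9), 1:3), "4 points")
})

test_that("counterfactual survival replacement follows the fitted line", {
  # regression over the other species: slope -0.5, intercept 0.9
  species <- species_info(sprintf("s%d", 1:5), c(0.2, 0.4, 0.6, 0.8, 1.0))
  p_line <- 0.9 - 0.5 * species$species_pe
  cells <- performance_cells(species$species_id, "g1", rep(100, 5),
                             round(c(p_line[1:2], 0.95, p_line[4:5]) * 100),
                             rep(20, 5), rep(10, 5), rep(2, 5))
  out <- counterfactual_survival(cells, "s3", species)
  expect_equal(out$p_replaced, 0.9 - 0.5 * 0.6, tolerance = 1e-10)
  expect_equal(out$realized$h_star[3], 0.6 * 10, tolerance = 1e-10)

  # an outlier above the line is strictly reduced
  expect_lt(out$realized$h_star[3], realized_growth(cells)$h_star[3])
  # non-target species keep their ordering
  others <- setdiff(seq_len(5), 3)
  expect_equal(order(out$realized$h_star[others]),
               order(realized_growth(cells)$h_star[others]))

  # a target already on the line is unchanged
  cells_on <- performance_cells(species$species_id, "g1", rep(100, 5),
                                round(p_line * 100), rep(20, 5), rep(10, 5),
                                rep(2, 5))
  out_on <- counterfactual_survival(cells_on, "s3", species)
  expect_equal(out_on$p_replaced, cells_on$p_hat[3], tolerance = 1e-2)
  expect_error(counterfactual_survival(cells[1:3, ], "s3", species),
               "3 other species")
})

test_that("cross-over detection distinguishes planted reversal from none", {
  cfg <- sim_config()
  st <- simulate_study(cfg, seed = 5)
  rg <- realized_growth(st$performance)
  xo <- detect_crossover(rg, cfg$sites, cfg$species)
  expect_true(xo$crossover)
  expect_lt(xo$cor_driest, 0)
  expect_gt(xo$cor_wettest, 0)

  # identical reaction norms for all species: no reversal
  cfg_flat <- sim_config()
  cfg_flat$survival$beta <- rep(4, 4)
  cfg_flat$survival$a <- rep(0.3, 4)
  cfg_flat$survival$s_max <- rep(0.9, 4)
  cfg_flat$height$b1 <- 0
  st_flat <- simulate_study(cfg_flat, seed = 5)
  xo_flat <- detect_crossover(realized_growth(st_flat$performance),
                              cfg_flat$sites, cfg_flat$species)
  expect_false(xo_flat$crossover)

  expect_error(detect_crossover(rg[rg$site_id == "site1", ], cfg$sites,
                                cfg$species), "2 sites")
})
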