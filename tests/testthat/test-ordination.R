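make_ord <- function(scores, species_id, site_id, loadings = NULL) {
  structure(list(scores = scores, species_id = species_id, site_id = site_id,
                 loadings = loadings), class = "ordination_result")
}

test_that("PCA basics: variance fractions, centering, reconstruction", {
  cfg <- sim_config()
  st <- simulate_study(cfg, seed = 8)
  ord <- run_pca(st$traits, sites = cfg$sites)
  expect_equal(sum(ord$variance_fraction), 1, tolerance = 1e-12)
  expect_equal(unname(colMeans(ord$scores)), rep(0, ncol(ord$scores)),
               tolerance = 1e-10)
  # loadings columns orthonormal
  expect_equal(unname(crossprod(ord$loadings)),
               diag(ncol(ord$loadings)), tolerance = 1e-10)
  # full reconstruction of the standardized matrix
  Z <- ord$scores %*% t(ord$loadings)
  X <- as.matrix(st$traits[, trait_ids(st$traits)])
  Xstd <- scale(X)
  expect_equal(unname(Z), unname(Xstd), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("two perfectly correlated traits collapse onto one axis", {
  tt <- data.frame(species_id = rep(sprintf("s%d", 1:5), 2),
                   site_id = rep(c("g1", "g2"), each = 5),
                   a = 1:10, b = 2 * (1:10) + 3, excluded = FALSE)
  class(tt) <- c("trait_table", "data.frame")
  ord <- run_pca(tt)
  expect_equal(ord$variance_fraction[1], 1, tolerance = 1e-12)
})

test_that("constant columns are rejected by name", {
  tt <- data.frame(species_id = sprintf("s%d", 1:8), site_id = "g1",
                   good = stats::rnorm(8), flat = 5, excluded = FALSE)
  class(tt) <- c("trait_table", "data.frame")
  expect_error(run_pca(tt), "flat")
})

test_that("gradient projection recovers exact score alignments", {
  sp <- sprintf("s%d", 1:10)
  species <- species_info(sp, exp(seq(log(0.2), log(1), length.out = 10)))
  sites <- site_info(c("g1", "g2"), c(0.2, 1.2))
  grid <- expand.grid(species_id = sp, site_id = sites$site_id,
                      stringsAsFactors = FALSE)
  lsp <- log(species$species_pe[match(grid$species_id, species$species_id)])
  noise <- sin(seq_len(nrow(grid)))          # fixed, uncorrelated with lsp
  scores <- cbind(PC1 = lsp, PC2 = noise - mean(noise))

  v <- project_gradients(make_ord(scores, grid$species_id, grid$site_id),
                         sites, species)
  expect_equal(abs(v$species[1]), 1, tolerance = 1e-6)
  expect_equal(v$species[2], 0, tolerance = 1e-6)

  # swapping the two score columns swaps the vector coordinates
  v2 <- project_gradients(make_ord(scores[, 2:1], grid$species_id,
                                   grid$site_id), sites, species)
  expect_equal(v2$species, rev(v$species), tolerance = 1e-8)

  sites_flat <- site_info(c("g1", "g2"), c(0.5, 0.5))
  expect_error(project_gradients(make_ord(scores, grid$species_id,
                                          grid$site_id), sites_flat, species),
               "degenerate")
})

test_that("sector classification respects gradient geometry", {
  u <- c(1, 0); v <- c(0, 1)    # orthogonal site / species directions
  vectors <- list(site = u, species = v)
  L <- rbind(along_species = c(0, 0.9),
             against_species = c(0, -0.8),
             along_site = c(0.7, 0),
             against_site = c(-0.6, 0.05),
             both = c(0.5, 0.5),
             zero = c(0, 0))
  colnames(L) <- c("PC1", "PC2")
  defs <- trait_definitions(rownames(L), predicted_direction = 1)
  ord <- make_ord(NULL, NULL, NULL, loadings = L)
  sec <- classify_sectors(ord, vectors, defs)
  expect_equal(sec$sector[sec$trait_id == "along_species"], "adaptive-species")
  expect_equal(sec$sector[sec$trait_id == "against_species"],
               "maladaptive-fixed")
  expect_equal(sec$sector[sec$trait_id == "along_site"], "adaptive-site")
  expect_equal(sec$sector[sec$trait_id == "against_site"],
               "maladaptive-plastic")
  expect_equal(sec$sector[sec$trait_id == "both"], "adaptive-both")
  expect_equal(sec$sector[sec$trait_id == "zero"], "unclassified")

  # a trait predicted to decrease that points against the species gradient
  # accords with theory
  defs_dn <- trait_definitions(rownames(L), predicted_direction = -1)
  sec_dn <- classify_sectors(ord, vectors, defs_dn)
  expect_equal(sec_dn$sector[sec_dn$trait_id == "against_species"],
               "adaptive-species")

  # rotating loadings and both gradient vectors together leaves labels fixed
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  ord_rot <- make_ord(NULL, NULL, NULL, loadings = L %*% t(R))
  vec_rot <- list(site = drop(R %*% u), species = drop(R %*% v))
  sec_rot <- classify_sectors(ord_rot, vec_rot, defs)
  expect_equal(sec_rot$sector, sec$sector)
})

test_that("reaction-norm slopes recover an exact linear score surface", {
  sp <- sprintf("s%d", 1:6)
  species <- species_info(sp, seq(0.2, 0.9, length.out = 6))
  sites <- site_info(c("g1", "g2", "g3"), c(0.2, 0.6, 1.2))
  grid <- expand.grid(species_id = sp, site_id = sites$site_id,
                      stringsAsFactors = FALSE)
  pe_si <- sites$site_pe[match(grid$site_id, sites$site_id)]
  pe_sp <- species$species_pe[match(grid$species_id, species$species_id)]
  scores <- cbind(PC1 = 6 * pe_si + 10 * pe_sp, PC2 = 0)
  ord <- make_ord(scores, grid$species_id, grid$site_id)
  rn <- suppressWarnings(pc_reaction_norms(ord, sites, species))  # exact fit
  expect_equal(rn$plastic$slope, rep(6, 6), tolerance = 1e-10)
  expect_equal(rn$fixed$slope, rep(10, 3), tolerance = 1e-10)
  expect_equal(rn$plastic_sd, 0, tolerance = 1e-10)
  expect_equal(rn$slope_ratio_pct, 60, tolerance = 1e-8)

  # permuting row order changes nothing
  o <- sample(nrow(grid))
  ord_p <- make_ord(scores[o, , drop = FALSE], grid$species_id[o],
                    grid$site_id[o])
  rn_p <- suppressWarnings(pc_reaction_norms(ord_p, sites, species))
  expect_equal(rn_p$fixed_mean, rn$fixed_mean, tolerance = 1e-10)
  expect_equal(rn_p$plastic_mean, rn$plastic_mean, tolerance = 1e-10)
})

test_that("species observed at a single site are skipped with a warning", {
  sp <- sprintf("s%d", 1:4)
  species <- species_info(sp, seq(0.3, 0.9, length.out = 4))
  sites <- site_info(c("g1", "g2"), c(0.3, 1.1))
  grid <- expand.grid(species_id = sp, site_id = sites$site_id,
                      stringsAsFactors = FALSE)
  grid <- grid[!(grid$species_id == "s4" & grid$site_id == "g2"), ]
  set.seed(2)
  scores <- cbind(PC1 = stats::rnorm(nrow(grid)), PC2 = 0)
  ord <- make_ord(scores, grid$species_id, grid$site_id)
  expect_warning(rn <- pc_reaction_norms(ord, sites, species), "s4")
  expect_equal(nrow(rn$plastic), 3)
})
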