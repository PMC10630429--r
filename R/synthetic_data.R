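#' Default configuration for a synthetic common-garden study
#'
#' The default design mirrors a ten-species, four-garden transplant study
#' along a climatic moisture gradient: site P/Ep of 0.16, 0.39, 1.03 and
#' 1.25; species P/Ep spanning 0.19-0.98 (log-evenly spaced); 81-254
#' individuals planted per species per garden. Traits respond log-linearly
#' to log site and species P/Ep with Brownian phylogenetic random effects
#' and Gaussian observation noise on the transformed scale; survival
#' follows a per-site logistic (sigmoid) function of species P/Ep that
#' declines with species P/Ep at dry sites and rises at wet sites; heights
#' of survivors are lognormal with a mean that increases with species P/Ep
#' more steeply at moister sites.
#'
#' @param n_species number of species (default 10).
#' @param n_sites number of gardens (default 4).
#' @param site_pe site P/Ep values, length `n_sites`.
#' @param species_pe species P/Ep values, length `n_species`; default is
#'   log-even between 0.19 and 0.98.
#' @param trait_params data.frame of generative coefficients per trait:
#'   `trait_id`, intercept `a`, `b_site` (slope on ln site P/Ep),
#'   `b_species` (slope on ln species P/Ep), interaction `c`, and variances
#'   `sigma2_phylo`, `sigma2_site`, `sigma2_e` (plus optional
#'   `sigma2_phylo_site` for the phylogenetic-attraction component).
#'   Defaults to [default_trait_params()].
#' @param defs [trait_definitions()] matching `trait_params`; defaults are
#'   derived from the sign of `b_site`/`b_species`.
#' @param survival data.frame with per-site sigmoid parameters `site_id`,
#'   `s_max`, `beta`, `a` for
#'   `s = s_max / (1 + exp(beta * (a - species_pe)))`.
#' @param height list of height-model parameters: log-mean
#'   `a + (b0 + b1 * site_pe) * species_pe`, lognormal `sdlog`.
#' @param n_planted_range inclusive range the per-cell planting count is
#'   drawn from.
#' @param tree_height stem age (height) of the simulated phylogeny, My.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 10L, n_sites = 4L,
                       site_pe = c(0.16, 0.39, 1.03, 1.25),
                       species_pe = NULL,
                       trait_params = default_trait_params(),
                       defs = NULL,
                       survival = NULL,
                       height = list(a = 3, b0 = 0.3, b1 = 1.2, sdlog = 0.35),
                       n_planted_range = c(81L, 254L),
                       tree_height = 52) {
  n_species <- as.integer(n_species)
  n_sites <- as.integer(n_sites)
  if (n_species < 2L) stop("need at least 2 species")
  site_pe <- rep_len(site_pe, n_sites)
  if (is.null(species_pe)) {
    species_pe <- exp(seq(log(0.19), log(0.98), length.out = n_species))
  }
  if (any(site_pe <= 0) || any(species_pe <= 0)) stop("P/Ep values must be > 0")
  vc <- c("sigma2_phylo", "sigma2_site", "sigma2_e")
  if (!all(c("trait_id", "a", "b_site", "b_species", "c", vc) %in%
           names(trait_params))) {
    stop("trait_params is missing required columns")
  }
  if (is.null(trait_params$sigma2_phylo_site)) trait_params$sigma2_phylo_site <- 0
  if (any(!is.finite(as.matrix(trait_params[, c("a", "b_site", "b_species", "c")])))) {
    stop("non-finite trait_params coefficients")
  }
  if (any(trait_params[, c(vc, "sigma2_phylo_site")] < 0)) {
    stop("variances must be >= 0")
  }
  sites <- site_info(paste0("site", seq_len(n_sites)), site_pe)
  species <- species_info(sprintf("sp%02d", seq_len(n_species)), species_pe)
  if (is.null(defs)) {
    dir <- ifelse(trait_params$b_species + trait_params$b_site >= 0, 1L, -1L)
    defs <- trait_definitions(trait_params$trait_id,
                              transform = if (!is.null(trait_params$transform))
                                trait_params$transform else "log",
                              predicted_direction = dir)
  }
  if (is.null(survival)) {
    survival <- data.frame(
      site_id = sites$site_id[order(sites$site_pe)],
      s_max = rep_len(c(0.95, 0.90, 0.90, 0.95), n_sites),
      beta  = rep_len(c(-12, -4, 2, 8), n_sites),
      a     = rep_len(c(0.55, 0.30, 0.00, 0.45), n_sites),
      stringsAsFactors = FALSE)
  }
  cfg <- list(n_species = n_species, n_sites = n_sites, sites = sites,
              species = species, trait_params = trait_params, defs = defs,
              survival = survival, height = height,
              n_planted_range = as.integer(n_planted_range),
              tree_height = tree_height)
  class(cfg) <- "sim_config"
  cfg
}

#' Default generative trait coefficients
#'
#' Ten traits on a log scale: half increasing with moisture supply (e.g.
#' SLA-like, photosynthesis-like), half decreasing (e.g. vein-density-like,
#' wood-density-like), with moderate phylogenetic, site and residual
#' variances relative to slope magnitudes near one.
#'
#' @return data.frame usable as `trait_params` in [sim_config()].
#' @export
default_trait_params <- function() {
  up <- c("t_sla", "t_amass", "t_gs", "t_kleaf", "t_rgr")
  dn <- c("t_vla", "t_wood_density", "t_narea", "t_thickness", "t_reflectance")
  data.frame(
    trait_id = c(up, dn),
    a = rep(1, 10),
    b_site = c(0.8, 1.0, 1.2, 0.9, 0.7, -0.8, -0.6, -1.0, -0.7, -0.9),
    b_species = c(1.1, 0.9, 1.0, 1.2, 0.8, -1.0, -0.9, -0.8, -1.1, -0.7),
    c = 0,
    sigma2_phylo = 0.08,
    sigma2_site = 0.03,
    sigma2_e = 0.04,
    sigma2_phylo_site = 0,
    transform = "log",
    stringsAsFactors = FALSE)
}

#' Trait coefficients with independent site and species effects
#'
#' Half the traits respond only to site P/Ep (pure plasticity) and half
#' only to species P/Ep (pure fixed differentiation). Because no trait
#' mixes the two gradients, the projected site and species P/Ep vectors in
#' the PCA plane are close to orthogonal — the configuration used to probe
#' gradient independence in the ordination.
#'
#' @return data.frame usable as `trait_params` in [sim_config()].
#' @export
independent_trait_params <- function() {
  p <- default_trait_params()
  site_only <- seq_len(5)
  p$b_species[site_only] <- 0
  p$b_site[-site_only] <- 0
  p
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' @param n_species number of tips (>= 2).
#' @param total_height stem-to-tip height of the returned tree (My).
#' @param seed integer RNG seed; the same seed yields the identical tree.
#' @return An [ape::phylo] object with tips `sp01`, `sp02`, ... scaled to
#'   `total_height`, validated by [validate_phylogeny()].
#' @export
simulate_tree <- function(n_species, total_height = 52, seed = 1L) {
  n_species <- as.integer(n_species)
  if (n_species < 2L) stop("need at least 2 species")
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n_species, birth = 0.2, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (total_height / depth)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  validate_phylogeny(tree)
}

#' Simulate a species-by-site trait table
#'
#' For each trait the transformed value is
#' `a + b_site * ln(site_pe) + b_species * ln(species_pe)
#'  + c * ln(site_pe) * ln(species_pe) + u_phylo(species) + u_site(site)
#'  + u_phylo_site(species, site) + e`,
#' where `u_phylo` is a multivariate normal draw with covariance
#' `sigma2_phylo` times the Brownian matrix of `tree` (scaled to unit
#' height), shared across sites; `u_phylo_site` is an independent Brownian
#' draw per site (the "phylogenetic attraction" component); `u_site` is iid
#' normal per site; and `e` is iid residual noise. Values are back-
#' transformed according to the trait's transform before being stored.
#'
#' @param cfg a [sim_config()].
#' @param tree phylogeny whose tips are `cfg$species$species_id`.
#' @param seed integer RNG seed.
#' @return A `trait_table` data.frame; attribute `truth` holds the
#'   generative parameters and the seed.
#' @export
simulate_traits <- function(cfg, tree, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!setequal(tree$tip.label, cfg$species$species_id)) {
    stop("tree tips do not match cfg species")
  }
  set.seed(as.integer(seed))
  sp <- cfg$species; si <- cfg$sites
  C <- brownian_covariance(tree, sp$species_id)
  C <- C / max(diag(C))          # unit-height scaling so variances are comparable
  L <- t(chol(C + diag(1e-10, nrow(C))))
  grid <- expand.grid(species_id = sp$species_id, site_id = si$site_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lsp <- log(sp$species_pe)[match(grid$species_id, sp$species_id)]
  lsi <- log(si$site_pe)[match(grid$site_id, si$site_id)]
  out <- grid
  for (k in seq_len(nrow(cfg$trait_params))) {
    p <- cfg$trait_params[k, ]
    mu <- p$a + p$b_site * lsi + p$b_species * lsp + p$c * lsi * lsp
    u_phy <- drop(L %*% stats::rnorm(nrow(C))) * sqrt(p$sigma2_phylo)
    y <- mu + u_phy[match(grid$species_id, sp$species_id)]
    u_site <- stats::rnorm(nrow(si), 0, sqrt(p$sigma2_site))
    y <- y + u_site[match(grid$site_id, si$site_id)]
    if (p$sigma2_phylo_site > 0) {
      for (s in si$site_id) {
        u_ps <- drop(L %*% stats::rnorm(nrow(C))) * sqrt(p$sigma2_phylo_site)
        idx <- grid$site_id == s
        y[idx] <- y[idx] + u_ps[match(grid$species_id[idx], sp$species_id)]
      }
    }
    y <- y + stats::rnorm(nrow(grid), 0, sqrt(p$sigma2_e))
    tf <- cfg$defs$transform[match(p$trait_id, cfg$defs$trait_id)]
    out[[p$trait_id]] <- switch(tf, none = y, log = exp(y), sqrt = y^2)
  }
  out$excluded <- FALSE
  class(out) <- c("trait_table", "data.frame")
  attr(out, "truth") <- list(trait_params = cfg$trait_params, seed = seed)
  out
}

sigmoid_survival <- function(pe, s_max, beta, a) {
  s <- s_max / (1 + exp(beta * (a - pe)))
  if (any(s < 0 | s > 1)) {
    warning("survival probability clipped to [0, 1]")
    s <- pmin(pmax(s, 0), 1)
  }
  s
}

#' Simulate survival and growth performance for every species-by-site cell
#'
#' Survivor counts are binomial with the per-site sigmoid survival
#' probability evaluated at each species' P/Ep; heights of survivors are
#' lognormal with log-mean `a + (b0 + b1 * site_pe) * species_pe`, so height
#' rises with species P/Ep and does so more steeply at moister sites.
#'
#' @param cfg a [sim_config()].
#' @param seed integer RNG seed.
#' @return A `performance_cells` data.frame; cells with zero survivors have
#'   `NA` trait mean/s.d. Attribute `truth` records the expected survival
#'   and expected height per cell and the seed.
#' @export
simulate_performance <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed))
  sp <- cfg$species; si <- cfg$sites; h <- cfg$height
  grid <- expand.grid(species_id = sp$species_id, site_id = si$site_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pe_sp <- sp$species_pe[match(grid$species_id, sp$species_id)]
  pe_si <- si$site_pe[match(grid$site_id, si$site_id)]
  sv <- cfg$survival[match(grid$site_id, cfg$survival$site_id), ]
  s_true <- sigmoid_survival(pe_sp, sv$s_max, sv$beta, sv$a)
  n_planted <- sample(seq(cfg$n_planted_range[1], cfg$n_planted_range[2]),
                      nrow(grid), replace = TRUE)
  n_surv <- stats::rbinom(nrow(grid), n_planted, s_true)
  mulog <- h$a + (h$b0 + h$b1 * pe_si) * pe_sp
  tm <- ts <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (n_surv[i] >= 1) {
      x <- stats::rlnorm(n_surv[i], mulog[i], h$sdlog)
      tm[i] <- mean(x)
      ts[i] <- if (n_surv[i] >= 2) stats::sd(x) else NA_real_
    }
  }
  out <- performance_cells(grid$species_id, grid$site_id, n_planted, n_surv,
                           n_surv, tm, ts)
  attr(out, "truth") <- list(
    expected_survival = s_true,
    expected_height = exp(mulog + h$sdlog^2 / 2),
    seed = seed)
  out
}

#' Simulate raw measurement streams with known ground truth
#'
#' Generates the raw inputs the derived-trait functions consume, each with
#' its true derived value recorded, so recovery can be checked exactly:
#' a leaf drying curve (fast decline then quasi-linear mass loss at a rate
#' implied by `gmin`), a stem flow-pressure series with a known slope, a
#' vessel-diameter sample, a root segment table with one broken tip whose
#' mass follows the planted allometry exactly, and an exponential growth
#' series.
#'
#' @param cfg a [sim_config()] (used only for reproducibility metadata).
#' @param seed integer RNG seed.
#' @param noise relative noise level applied to the drying and
#'   flow-pressure streams (0 gives exact recovery).
#' @return list with elements `drying`, `flow_pressure`, `vessels`, `roots`,
#'   `growth`, and `truth` (the planted derived values plus the seed).
#' @export
simulate_raw_streams <- function(cfg = sim_config(), seed = 1L, noise = 0) {
  set.seed(as.integer(seed))
  truth <- list(seed = seed)

  # drying curve: conductance gmin over a chamber at fixed T, RH, pressure
  gmin <- 1.5e-3                      # mol m-2 s-1
  leaf_area <- 1e-3                   # m2 (10 cm2)
  tc <- 20; rh <- 0.5; patm <- 101.3
  vpd <- tetens_esat(tc) * (1 - rh)
  rate <- gmin * (vpd / patm) * leaf_area * 18.015      # g s-1
  times <- seq(0, 48, by = 2)                           # h
  mult <- c(6, 3, 1.5, rep(1, length(times) - 4))       # per-interval factors
  mass <- 2 - c(0, cumsum(mult * rate * 7200))          # 2 h = 7200 s steps
  mass <- mass * (1 + stats::rnorm(length(mass), 0, noise))
  fvfm <- rep(NA_real_, length(times))
  fvfm[seq(1, length(times), by = 2)] <- 0.82
  drying <- data.frame(time = times, leaf_mass = mass, fvfm = fvfm,
                       rh = rh, temperature = tc, pressure = patm,
                       leaf_area = leaf_area)
  truth$gmin <- gmin

  # flow-pressure: slope k in g s-1 per MPa mm-1, measured at 20 C
  k <- 0.012; xa <- 2.4
  grads <- rep(c(0.4, 2.6, 4.9) * 1e-3 / 110, each = 3)  # kPa over 110 mm
  flow <- k * grads * (1 + stats::rnorm(length(grads), 0, noise))
  flow_pressure <- data.frame(flow = flow, pressure_gradient = grads,
                              temperature = 20, xylem_area = xa,
                              leaf_area = 0.05, site_id = "site1")
  truth$kstem <- k / xa

  # vessel diameters, um, in a counted area of 1 mm2
  d <- stats::rlnorm(60, log(28), 0.25)
  vessels <- list(diameters = d, counted_area = 1)
  truth$dh <- (mean(d^4))^(1 / 4)

  # root segments on an exact allometry ln(mass) = alpha + b * ln(diameter);
  # every distal end continues into a matching proximal diameter or tapers
  # to a fine-root tip, except the 3 mm end whose child segment is lost
  alpha <- -1.2; b <- 2.3
  prox <- c(0.5, 0.8, 1.2, 1.8, 2.4, 4.0, 5.5)
  dist <- c(0.2, 0.3, 0.5, 0.8, 1.2, 3.0, 4.0)
  mass_r <- exp(alpha + b * log(prox))
  roots <- data.frame(proximal_diameter = prox, distal_diameter = dist,
                      dry_mass = mass_r)
  truth$root_allometry <- c(alpha = alpha, slope = b)
  truth$root_total <- sum(mass_r) + exp(alpha + b * log(3.0))

  # geometric-mean biomass growing exponentially at r per day
  r <- 0.012
  days <- c(60, 120, 180, 240)
  growth <- data.frame(day = days, size = 0.8 * exp(r * days))
  truth$rgr_mass <- r * 1000

  list(drying = drying, flow_pressure = flow_pressure, vessels = vessels,
       roots = roots, growth = growth, truth = truth)
}

#' Simulate a complete study and optionally write it to disk
#'
#' Convenience wrapper running [simulate_tree()], [simulate_traits()] and
#' [simulate_performance()] under stage-specific seeds derived from one
#' master seed.
#'
#' @param cfg a [sim_config()].
#' @param seed master integer seed.
#' @param out_dir optional directory; when given, writes `traits.csv`,
#'   `performance.csv`, `sites.csv`, `species.csv`, `predictions.csv`,
#'   `tree.nwk` (synthetic) and `truth.json`.
#' @return list with `tree`, `traits`, `performance`, `cfg`, `seed`.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1L, out_dir = NULL) {
  seed <- as.integer(seed)
  seeds <- stage_seeds(seed)
  tree <- simulate_tree(cfg$n_species, cfg$tree_height, seeds["tree"])
  traits <- simulate_traits(cfg, tree, seeds["traits"])
  perf <- simulate_performance(cfg, seeds["performance"])
  res <- list(tree = tree, traits = traits, performance = perf,
              cfg = cfg, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trait_table(traits, file.path(out_dir, "traits.csv"))
    utils::write.csv(as.data.frame(perf), file.path(out_dir, "performance.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cfg$sites), file.path(out_dir, "sites.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cfg$species),
                     file.path(out_dir, "species.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(cfg$defs),
                     file.path(out_dir, "predictions.csv"), row.names = FALSE)
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    jsonlite::write_json(
      list(seed = seed, stage_seeds = as.list(seeds),
           trait_params = cfg$trait_params, survival = cfg$survival,
           height = cfg$height),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

# Deterministic per-stage seed derivation from one master seed, kept within
# 32-bit integer range.
stage_seeds <- function(seed) {
  stages <- c("tree", "traits", "performance", "raw", "analysis")
  s <- (as.double(seed) * 1009 + seq_along(stages) * 9973) %% 2147483647
  stats::setNames(as.integer(s), stages)
}
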