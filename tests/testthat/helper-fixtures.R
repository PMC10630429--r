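# Shared fixtures, built in code at test time.

star_tree <- function(n, labels = sprintf("sp%02d", seq_len(n)), bl = 1) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(bl, n)
  tr$tip.label <- labels
  tr
}

# Three-taxon tree with known path lengths: ((A:1,B:1):1,C:2);
abc_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

# Noiseless drying series at constant mass-loss rate (g per h), Fv/Fm read
# on every other weighing.
drying_series <- function(rate_g_per_h = 1.08e-3, hours = seq(0, 24, 2),
                          fvfm = 0.82, temp = 20, rh = 0.5, patm = 101.3,
                          area = 1e-3, mass0 = 2) {
  fv <- rep(NA_real_, length(hours))
  fv[seq(1, length(hours), 2)] <- fvfm
  data.frame(time = hours, leaf_mass = mass0 - rate_g_per_h * hours,
             fvfm = fv, rh = rh, temperature = temp, pressure = patm,
             leaf_area = area)
}

# A small deterministic trait table on an exact response plane.
plane_config <- function(b_site = 1, b_species = 1, a = 0, c = 0,
                         transform = "log") {
  p <- default_trait_params()[1, ]
  p$a <- a; p$b_site <- b_site; p$b_species <- b_species; p$c <- c
  p$sigma2_phylo <- 0; p$sigma2_site <- 0; p$sigma2_e <- 0
  p$transform <- transform
  sim_config(trait_params = p)
}

expect_no_warning <- function(expr) expect_warning(expr, regexp = NA)
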