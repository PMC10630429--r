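#' Standardized PCA of a species-by-site trait table
#'
#' Principal components analysis of the centered and standardized
#' (correlation-scale) trait matrix over species-by-site rows. Rows flagged
#' `excluded` are dropped; sporadic missing cells are mean-imputed with the
#' count recorded. When site information is supplied, axis signs are fixed
#' so the projected site-P/Ep gradient has positive coordinates in the
#' PC1-PC2 plane, making orientation deterministic.
#'
#' @param tt a `trait_table`.
#' @param traits trait columns to include (default all).
#' @param sites optional [site_info()] used for sign fixing.
#' @return list of class `ordination_result`: `loadings` (trait x axis,
#'   orthonormal columns), `scores` (rows x axis, with species/site ids),
#'   `variance_fraction`, `sdev`, `n_imputed`.
#' @export
run_pca <- function(tt, traits = trait_ids(tt), sites = NULL) {
  d <- tt[!tt$excluded, , drop = FALSE]
  X <- as.matrix(d[, traits, drop = FALSE])
  cons <- apply(X, 2, function(v) stats::var(v, na.rm = TRUE)) == 0
  if (any(cons, na.rm = TRUE)) {
    stop("constant trait column(s): ", paste(traits[which(cons)], collapse = ", "))
  }
  n_imputed <- sum(is.na(X))
  if (n_imputed) {
    for (j in seq_len(ncol(X))) {
      miss <- is.na(X[, j])
      X[miss, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  loadings <- pc$rotation
  scores <- pc$x
  if (!is.null(sites)) {
    lpe <- log(sites$site_pe[match(d$site_id, sites$site_id)])
    for (ax in 1:2) {
      b <- stats::coef(stats::lm(lpe ~ scores[, ax]))[2]
      if (is.finite(b) && b < 0) {
        scores[, ax] <- -scores[, ax]
        loadings[, ax] <- -loadings[, ax]
      }
    }
  }
  out <- list(loadings = loadings, scores = scores,
              species_id = d$species_id, site_id = d$site_id,
              variance_fraction = var_frac, sdev = pc$sdev,
              center = pc$center, scale = pc$scale, n_imputed = n_imputed)
  class(out) <- "ordination_result"
  out
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("PCA of %d traits over %d rows; PC1+PC2 = %.1f%% of variance\n",
              nrow(x$loadings), nrow(x$scores),
              100 * sum(x$variance_fraction[1:2])))
  invisible(x)
}

#' Project the site and species P/Ep gradients onto the PC1-PC2 plane
#'
#' Each gradient vector is the pair of coefficients from the regression of
#' the log gradient on the PC1 and PC2 scores (the supplementary-variable
#' projection), scaled to unit length. The angle between the two projected
#' gradients measures how independently site and species moisture supply
#' structure the trait space.
#'
#' @param ord an `ordination_result`.
#' @param sites,species [site_info()] / [species_info()] tables.
#' @return list with unit `site` and `species` vectors (PC1, PC2
#'   coordinates), `angle_deg` between them, and `cos_angle`.
#' @export
project_gradients <- function(ord, sites, species) {
  s1 <- ord$scores[, 1]; s2 <- ord$scores[, 2]
  proj <- function(g) {
    if (stats::var(g) == 0) stop("degenerate (zero-variance) gradient")
    b <- stats::coef(stats::lm(log(g) ~ s1 + s2))[2:3]
    unname(b / sqrt(sum(b^2)))
  }
  v_site <- proj(sites$site_pe[match(ord$site_id, sites$site_id)])
  v_sp <- proj(species$species_pe[match(ord$species_id, species$species_id)])
  cosang <- sum(v_site * v_sp)
  list(site = v_site, species = v_sp,
       angle_deg = acos(max(-1, min(1, cosang))) * 180 / pi,
       cos_angle = cosang)
}

#' Classify trait loading vectors into eight gradient-aligned sectors
#'
#' The PC1-PC2 plane is divided into eight sectors centred on the
#' projected site-P/Ep direction, the species-P/Ep direction, their
#' opposites, and the four bisecting directions; each trait's loading
#' vector (sign-adjusted by its predicted direction, so alignment means
#' accord with theory) is assigned to the nearest sector centre. Labels
#' describe what the alignment implies: accord with site P/Ep is adaptive
#' plasticity, accord with species P/Ep is adaptive fixed differentiation,
#' anti-alignment is nominally maladaptive.
#'
#' @param ord an `ordination_result`.
#' @param vectors output of [project_gradients()].
#' @param defs [trait_definitions()] supplying `predicted_direction`.
#' @return data.frame with `trait_id`, `sector`, `angle_deg` (angle of the
#'   sign-adjusted loading), `length`. Zero-length loadings are
#'   `"unclassified"`.
#' @export
classify_sectors <- function(ord, vectors, defs) {
  u <- vectors$site; v <- vectors$species
  unit <- function(w) w / sqrt(sum(w^2))
  centres <- rbind(
    "adaptive-site"                    = u,
    "adaptive-both"                    = unit(u + v),
    "adaptive-species"                 = v,
    "adaptive-species-maladaptive-site" = unit(v - u),
    "maladaptive-plastic"              = -u,
    "maladaptive-both"                 = -unit(u + v),
    "maladaptive-fixed"                = -v,
    "adaptive-site-maladaptive-species" = unit(u - v))
  traits <- rownames(ord$loadings)
  pred <- defs$predicted_direction[match(traits, defs$trait_id)]
  pred[is.na(pred)] <- 1L
  out <- data.frame(trait_id = traits, sector = NA_character_,
                    angle_deg = NA_real_, length = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(traits)) {
    w <- pred[i] * ord$loadings[i, 1:2]
    len <- sqrt(sum(w^2))
    out$length[i] <- len
    if (len < 1e-12) {
      out$sector[i] <- "unclassified"
      next
    }
    w <- w / len
    out$angle_deg[i] <- atan2(w[2], w[1]) * 180 / pi
    out$sector[i] <- rownames(centres)[which.max(centres %*% w)]
  }
  out
}

#' Reaction-norm slopes of PC1 scores along the two gradients
#'
#' Within each garden, PC1 is regressed on species P/Ep (fixed multivariate
#' differentiation); within each species grown at two or more sites, PC1 is
#' regressed on site P/Ep (multivariate plasticity). Reports each slope
#' set with mean and s.d., an ANCOVA F-test of slope homogeneity, and the
#' ratio of mean plastic to mean fixed slope.
#'
#' @param ord an `ordination_result`.
#' @param sites,species [site_info()] / [species_info()] tables.
#' @return list of class `reaction_norms`: `fixed` (per-site slopes of PC1
#'   vs species P/Ep), `plastic` (per-species slopes of PC1 vs site P/Ep),
#'   their `mean`/`sd`, `slope_ratio` (plastic mean over fixed mean),
#'   `slope_ratio_pct`, and common-slope test p-values.
#' @export
pc_reaction_norms <- function(ord, sites, species) {
  d <- data.frame(pc1 = ord$scores[, 1], species_id = ord$species_id,
                  site_id = ord$site_id, stringsAsFactors = FALSE)
  d$site_pe <- sites$site_pe[match(d$site_id, sites$site_id)]
  d$species_pe <- species$species_pe[match(d$species_id, species$species_id)]
  if (length(unique(d$site_id)) < 2L || length(unique(d$species_id)) < 2L) {
    stop("need at least 2 sites and 2 species")
  }
  slope_by <- function(by, x) {
    grp <- split(d, d[[by]])
    res <- lapply(grp, function(g) {
      if (nrow(g) < 2L || stats::var(g[[x]]) == 0) return(NULL)
      f <- stats::lm(stats::reformulate(x, "pc1"), data = g)
      data.frame(group = g[[by]][1], slope = unname(stats::coef(f)[2]),
                 p = summary(f)$coefficients[2, 4], n = nrow(g))
    })
    skipped <- names(res)[vapply(res, is.null, logical(1))]
    if (length(skipped)) {
      warning("skipped (fewer than 2 usable rows): ",
              paste(skipped, collapse = ", "))
    }
    do.call(rbind, res[!vapply(res, is.null, logical(1))])
  }
  fixed <- slope_by("site_id", "species_pe")
  plastic <- slope_by("species_id", "site_pe")
  ancova_p <- function(x, g) {
    full <- stats::lm(pc1 ~ d[[x]] * factor(d[[g]]), data = d)
    red <- stats::lm(pc1 ~ d[[x]] + factor(d[[g]]), data = d)
    stats::anova(red, full)[2, "Pr(>F)"]
  }
  out <- list(fixed = fixed, plastic = plastic,
              fixed_mean = mean(fixed$slope), fixed_sd = stats::sd(fixed$slope),
              plastic_mean = mean(plastic$slope),
              plastic_sd = stats::sd(plastic$slope),
              slope_ratio = mean(plastic$slope) / mean(fixed$slope),
              slope_ratio_pct = 100 * mean(plastic$slope) / mean(fixed$slope),
              common_slope_p = c(fixed = ancova_p("species_pe", "site_id"),
                                 plastic = ancova_p("site_pe", "species_id")))
  class(out) <- "reaction_norms"
  out
}

#' @export
print.reaction_norms <- function(x, ...) {
  cat(sprintf("PC1 vs species P/Ep (fixed): %.2f +/- %.2f over %d sites\n",
              x$fixed_mean, x$fixed_sd, nrow(x$fixed)))
  cat(sprintf("PC1 vs site P/Ep (plastic):  %.2f +/- %.2f over %d species\n",
              x$plastic_mean, x$plastic_sd, nrow(x$plastic)))
  cat(sprintf("plastic/fixed slope ratio: %.0f%%\n", x$slope_ratio_pct))
  invisible(x)
}
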