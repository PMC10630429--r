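#' Realized growth (survival x mean growth) with delta-method standard error
#'
#' Realized height growth `H* = p_hat * m` (and its mass analogue M*)
#' treats dead plants as having zero height, combining survival and growth
#' into one performance index. Because survival is estimated from all
#' planted individuals (n') while the trait mean m and s.d. s come from a
#' measured subset (n), the standard error combines both sources:
#' `se^2 = (p_hat^2 + p_hat (1 - p_hat) / n') * s^2 / n
#'         + m^2 * p_hat (1 - p_hat) / n'`.
#'
#' @param cells a [performance_cells()] data.frame.
#' @return data.frame of class `realized_growth`: the input keys plus
#'   `h_star` and `se` (`se` is `NA`, flagged via `se_defined`, when fewer
#'   than 2 plants were measured; both are 0 when nothing survived).
#' @export
realized_growth <- function(cells) {
  stopifnot(inherits(cells, "performance_cells") ||
              all(c("p_hat", "n_planted", "n_measured", "trait_mean",
                    "trait_sd") %in% names(cells)))
  p <- cells$p_hat
  m <- cells$trait_mean
  s <- cells$trait_sd
  n <- cells$n_measured
  np <- cells$n_planted
  h_star <- ifelse(p == 0, 0, p * m)
  se2 <- (p^2 + p * (1 - p) / np) * s^2 / n + m^2 * p * (1 - p) / np
  se <- sqrt(se2)
  se[p == 0] <- 0
  se_defined <- (p == 0) | (!is.na(n) & n >= 2 & !is.na(s))
  out <- data.frame(species_id = cells$species_id, site_id = cells$site_id,
                    p_hat = p, trait_mean = m, h_star = h_star, se = se,
                    se_defined = se_defined, n_planted = np, n_measured = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("realized_growth", "data.frame")
  out
}

# Compact letter display by insert-and-absorb on the pairwise
# "significantly different" matrix. Groups sharing a letter do not differ.
compact_letters <- function(diff_mat, order_by = NULL) {
  g <- nrow(diff_mat)
  sets <- list(seq_len(g))
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    if (!isTRUE(diff_mat[i, j])) next
    for (k in seq_along(sets)) {
      s <- sets[[k]]
      if (i %in% s && j %in% s) {
        sets[[k]] <- setdiff(s, i)
        sets[[length(sets) + 1L]] <- setdiff(s, j)
      }
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(sets))
    for (a in seq_along(sets)) for (b in seq_along(sets)) {
      if (a != b && keep[a] && all(sets[[a]] %in% sets[[b]]) &&
          length(sets[[a]]) < length(sets[[b]])) keep[a] <- FALSE
    }
    sets <- unique(sets[keep])
  }
  if (!is.null(order_by)) {
    sets <- sets[order(vapply(sets, function(s) -max(order_by[s]), numeric(1)))]
  }
  lab <- rep("", g)
  for (k in seq_along(sets)) {
    lab[sets[[k]]] <- paste0(lab[sets[[k]]], letters[k])
  }
  lab
}

#' Pairwise comparison of realized growth within a site
#'
#' For every species pair, `z = (H*_1 - H*_2) / sqrt(se_1^2 + se_2^2)` with
#' a two-sided normal p-value; p-values are Benjamini-Hochberg adjusted
#' within the site and summarised as a compact letter display (species
#' sharing a letter do not differ significantly).
#'
#' @param rg a `realized_growth` data.frame for a single site (species with
#'   undefined se are excluded from comparisons).
#' @param alpha significance level on adjusted p-values.
#' @return list with `pairs` (species pair, z, p, p_adj) and `letters`
#'   (per included species, ordered as in `rg`).
#' @export
compare_realized <- function(rg, alpha = 0.05) {
  if (length(unique(rg$site_id)) > 1L) stop("one site at a time")
  inc <- rg[rg$se_defined, , drop = FALSE]
  if (nrow(inc) < 2L) stop("need at least 2 species with defined se")
  cmb <- utils::combn(nrow(inc), 2)
  z <- p <- numeric(ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1, k]; j <- cmb[2, k]
    num <- inc$h_star[i] - inc$h_star[j]
    den <- sqrt(inc$se[i]^2 + inc$se[j]^2)
    if (den == 0) {
      z[k] <- ifelse(num == 0, 0, sign(num) * Inf)
      p[k] <- ifelse(num == 0, 1, 0)
      if (num != 0) warning("zero se with unequal H*: p set to 0")
    } else {
      z[k] <- num / den
      p[k] <- 2 * stats::pnorm(-abs(z[k]))
    }
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  pairs <- data.frame(species_1 = inc$species_id[cmb[1, ]],
                      species_2 = inc$species_id[cmb[2, ]],
                      z = z, p = p, p_adj = p_adj, stringsAsFactors = FALSE)
  dm <- matrix(FALSE, nrow(inc), nrow(inc))
  for (k in seq_len(ncol(cmb))) {
    dm[cmb[1, k], cmb[2, k]] <- dm[cmb[2, k], cmb[1, k]] <- p_adj[k] < alpha
  }
  letters_out <- compact_letters(dm, order_by = inc$h_star)
  list(pairs = pairs,
       letters = stats::setNames(letters_out, inc$species_id))
}

#' Pairwise survival comparisons with Yates continuity correction
#'
#' Each species pair within a site is compared by a 2x2 chi-square test of
#' survived/died counts with Yates' continuity correction, followed by
#' Benjamini-Hochberg adjustment within the site.
#'
#' @param cells [performance_cells()] for a single site.
#' @return data.frame: species pair, chi-square statistic, raw and adjusted
#'   p (a degenerate zero-margin table gives p = 1 with a warning).
#' @export
compare_survival <- function(cells) {
  if (length(unique(cells$site_id)) > 1L) stop("one site at a time")
  if (nrow(cells) < 2L) stop("need at least 2 species")
  cmb <- utils::combn(nrow(cells), 2)
  stat <- p <- numeric(ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1, k]; j <- cmb[2, k]
    tab <- rbind(c(cells$n_survived[i], cells$n_planted[i] - cells$n_survived[i]),
                 c(cells$n_survived[j], cells$n_planted[j] - cells$n_survived[j]))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning("zero-margin table for ", cells$species_id[i], " vs ",
              cells$species_id[j], "; p set to 1")
      stat[k] <- 0; p[k] <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
      stat[k] <- unname(ct$statistic); p[k] <- ct$p.value
    }
  }
  data.frame(species_1 = cells$species_id[cmb[1, ]],
             species_2 = cells$species_id[cmb[2, ]],
             chisq = stat, p = p, p_adj = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE)
}

#' Tukey HSD comparison of per-plant means within a site
#'
#' One-way layout of a measurement (height or mass) across species within
#' a site, compared with Tukey's Honest Significant Differences; singleton
#' groups are excluded (their plotting symbols carry no letters).
#'
#' @param values per-plant measurements.
#' @param group species label per plant.
#' @param alpha significance level.
#' @return list with `hsd` (the `TukeyHSD` table), `letters` per included
#'   group, and `excluded` singleton groups.
#' @export
compare_means_hsd <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  sizes <- table(group)
  excluded <- names(sizes)[sizes < 2]
  keep <- !(group %in% excluded)
  values <- values[keep]; group <- droplevels(group[keep])
  if (nlevels(group) < 2L) stop("need at least 2 groups with >= 2 observations")
  fit <- stats::aov(values ~ group)
  hsd <- stats::TukeyHSD(fit)$group
  lv <- levels(group)
  dm <- matrix(FALSE, length(lv), length(lv), dimnames = list(lv, lv))
  prs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  for (k in seq_along(prs)) {
    a <- prs[[k]][1]; b <- prs[[k]][2]
    dm[a, b] <- dm[b, a] <- hsd[k, "p adj"] < alpha
  }
  means <- tapply(values, group, mean)
  lets <- compact_letters(dm, order_by = means)
  list(hsd = hsd, letters = stats::setNames(lets, lv), excluded = excluded)
}

#' Fit a sigmoidal survival response to species P/Ep
#'
#' Least-squares fit of `s = s_max / (1 + exp(beta * (a - pe)))` where
#' `s_max` is the asymptotic survival, `beta` a slope parameter (either
#' sign: negative beta gives survival declining with P/Ep) and `a` the
#' P/Ep at half-maximal survival. The linear alternative is always fitted
#' and the lower-AIC model reported.
#'
#' @param survival observed survival fractions (>= 4 points).
#' @param pe species P/Ep values.
#' @return list of class `sigmoid_fit`: `s_max`, `beta`, `a`, `rss`,
#'   `converged`, `AIC_sigmoid`, `AIC_linear`, `preferred`
#'   (`"sigmoid"`/`"linear"`), and `linear` (the lm fit).
#' @export
fit_survival_sigmoid <- function(survival, pe) {
  if (length(survival) < 4L) stop("need at least 4 points")
  lin <- stats::lm(survival ~ pe)
  d <- data.frame(s = survival, pe = pe)
  slope0 <- unname(stats::coef(lin)[2])
  # logistic linearization for starting values:
  # log(s / (s_max - s)) = beta * pe - beta * a
  smax0 <- min(1, max(survival) * 1.02 + 1e-6)
  eps <- 1e-4
  z <- log(pmax(survival, eps) / pmax(smax0 - survival, eps))
  lf <- stats::lm(z ~ pe)
  beta0 <- unname(stats::coef(lf)[2])
  a0 <- if (abs(beta0) > 1e-8) -unname(stats::coef(lf)[1]) / beta0 else
    stats::median(pe)
  starts <- list(
    list(s_max = smax0, beta = beta0, a = min(5, max(-5, a0))),
    list(s_max = smax0, beta = if (slope0 >= 0) 5 else -5,
         a = stats::median(pe)))
  fit <- NULL
  for (start in starts) {
    cand <- tryCatch(
      minpack.lm::nlsLM(s ~ s_max / (1 + exp(beta * (a - pe))), data = d,
                        start = start,
                        lower = c(s_max = 1e-6, beta = -200, a = -5),
                        upper = c(s_max = 1, beta = 200, a = 5),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) || stats::deviance(cand) < stats::deviance(fit))) {
      fit <- cand
    }
  }
  if (is.null(fit)) {
    out <- list(s_max = NA_real_, beta = NA_real_, a = NA_real_,
                rss = NA_real_, converged = FALSE,
                AIC_sigmoid = NA_real_, AIC_linear = stats::AIC(lin),
                preferred = "linear", linear = lin,
                se = c(s_max = NA_real_, beta = NA_real_, a = NA_real_))
    class(out) <- "sigmoid_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  aic_s <- stats::AIC(fit); aic_l <- stats::AIC(lin)
  out <- list(s_max = unname(cf["s_max"]), beta = unname(cf["beta"]),
              a = unname(cf["a"]), rss = sum(stats::residuals(fit)^2),
              converged = TRUE, AIC_sigmoid = aic_s, AIC_linear = aic_l,
              preferred = if (aic_s < aic_l) "sigmoid" else "linear",
              linear = lin, se = se, fit = fit)
  class(out) <- "sigmoid_fit"
  out
}

#' Counterfactual survival replacement for one species at a site
#'
#' Refits the survival versus species-P/Ep relationship at a site excluding
#' the target species, replaces the target's survival fraction with the
#' fitted prediction (clipped to \[0, 1\]), and recomputes its realized
#' growth and standard error. Used to ask how a species would have
#' performed had its survival followed the site-wide trend.
#'
#' @param cells [performance_cells()] for one site.
#' @param target_species species whose survival is replaced.
#' @param species [species_info()] giving species P/Ep.
#' @param form `"linear"` (default) or `"sigmoid"` regression of survival
#'   on species P/Ep.
#' @return list with `cells` (the adjusted table), `realized` (recomputed
#'   [realized_growth()]), `p_replaced`, `p_observed`, and the `fit`.
#' @export
counterfactual_survival <- function(cells, target_species, species,
                                    form = c("linear", "sigmoid")) {
  form <- match.arg(form)
  if (length(unique(cells$site_id)) > 1L) stop("one site at a time")
  i <- match(target_species, cells$species_id)
  if (is.na(i)) stop("target species not present at site")
  others <- cells[-i, , drop = FALSE]
  if (nrow(others) < 3L) stop("need at least 3 other species at the site")
  pe <- species$species_pe[match(others$species_id, species$species_id)]
  pe_t <- species$species_pe[match(target_species, species$species_id)]
  if (form == "linear") {
    fit <- stats::lm(others$p_hat ~ pe)
    pred <- unname(stats::predict(fit, data.frame(pe = pe_t)))
    pred <- unname(stats::coef(fit)[1] + stats::coef(fit)[2] * pe_t)
  } else {
    fit <- fit_survival_sigmoid(others$p_hat, pe)
    pred <- fit$s_max / (1 + exp(fit$beta * (fit$a - pe_t)))
  }
  if (pred < 0) {
    warning("predicted survival < 0 clipped to 0")
    pred <- 0
  }
  if (pred > 1) pred <- 1
  out <- cells
  out$p_hat[i] <- pred
  out$n_survived[i] <- round(pred * out$n_planted[i])
  list(cells = out, realized = realized_growth(out),
       p_replaced = pred, p_observed = cells$p_hat[i], fit = fit)
}

#' Detect adaptive cross-over in realized growth along the gradient
#'
#' Adaptive cross-over means species performance ranks reverse along the
#' moisture gradient so each species outperforms others under conditions
#' like those it dominates in nature. Operationally: the rank correlation
#' of H* with species P/Ep changes sign between the driest and the wettest
#' site. Per site, the report also flags whether the top-ranked species'
#' P/Ep is closer to the site's P/Ep than the median competitor's is.
#'
#' @param rg a `realized_growth` table over multiple sites.
#' @param sites,species [site_info()] / [species_info()] tables.
#' @return list of class `crossover_report`: `crossover` (logical),
#'   `cor_driest`, `cor_wettest` (Spearman correlations of H* with species
#'   P/Ep at the extreme sites), and `per_site` (top species, whether it is
#'   locally matched, correlation).
#' @export
detect_crossover <- function(rg, sites, species) {
  site_ids <- unique(rg$site_id)
  if (length(site_ids) < 2L) stop("need at least 2 sites")
  pe_site <- sites$site_pe[match(site_ids, sites$site_id)]
  per_site <- list()
  cors <- stats::setNames(rep(NA_real_, length(site_ids)), site_ids)
  for (s in site_ids) {
    d <- rg[rg$site_id == s & !is.na(rg$h_star), , drop = FALSE]
    if (nrow(d) < 2L) next
    pe_sp <- species$species_pe[match(d$species_id, species$species_id)]
    cors[s] <- suppressWarnings(
      stats::cor(d$h_star, pe_sp, method = "spearman"))
    top <- which.max(d$h_star)
    spe <- sites$site_pe[match(s, sites$site_id)]
    dist_top <- abs(pe_sp[top] - spe)
    dist_med <- stats::median(abs(pe_sp[-top] - spe))
    per_site[[s]] <- data.frame(
      site_id = s, site_pe = spe, top_species = d$species_id[top],
      top_species_pe = pe_sp[top], locally_matched = dist_top < dist_med,
      spearman = cors[s], stringsAsFactors = FALSE)
  }
  measured <- !is.na(cors)
  ord <- order(pe_site)
  dri <- site_ids[ord][which(measured[site_ids[ord]])[1]]
  wet_candidates <- rev(site_ids[ord])
  wet <- wet_candidates[which(measured[wet_candidates])[1]]
  cd <- cors[dri]; cw <- cors[wet]
  crossover <- isTRUE(cd * cw < 0)
  out <- list(crossover = crossover, cor_driest = unname(cd),
              cor_wettest = unname(cw), driest_site = dri, wettest_site = wet,
              per_site = do.call(rbind, per_site))
  class(out) <- "crossover_report"
  out
}

#' @export
print.crossover_report <- function(x, ...) {
  cat(sprintf(
    "Adaptive cross-over: %s (rank cor %.2f at %s vs %.2f at %s)\n",
    if (x$crossover) "detected" else "not detected",
    x$cor_driest, x$driest_site, x$cor_wettest, x$wettest_site))
  invisible(x)
}
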