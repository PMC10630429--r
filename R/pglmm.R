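#' Random-effect covariance structures over a species-by-site grid
#'
#' Builds the N x N covariance contribution of each candidate random effect
#' for observations that are species-by-site trait means:
#' \describe{
#'   \item{site}{iid site intercepts: 1 where two observations share a site.}
#'   \item{species}{iid species intercepts: 1 where they share a species.}
#'   \item{species_phylo}{Brownian phylogenetic species effect, shared
#'     across sites: the phylogenetic covariance of the two species.}
#'   \item{phylo_in_site}{phylogenetic attraction: an independent Brownian
#'     draw per site, so the phylogenetic covariance applies only within a
#'     site.}
#' }
#' The Brownian matrix is scaled to unit height so all variance components
#' are on the scale of the transformed trait.
#'
#' @param species_id,site_id vectors of length N labelling each observation.
#' @param tree phylogeny containing all species.
#' @return named list of N x N matrices.
#' @export
pglmm_structures <- function(species_id, site_id, tree) {
  C <- brownian_covariance(tree, unique(species_id))
  C <- C / max(diag(C))
  same_site <- outer(site_id, site_id, "==") * 1
  same_sp <- outer(species_id, species_id, "==") * 1
  Cobs <- C[species_id, species_id]
  list(site = same_site,
       species = same_sp,
       species_phylo = Cobs,
       phylo_in_site = Cobs * same_site)
}

# Profiled negative log-likelihood of the Gaussian variance-component model
# y ~ N(X beta, sigma2_e (I + sum_k gamma_k V_k)), over theta = log(gamma).
# method "ML" or "REML" (restricted likelihood; used for interval
# estimation, since ML variance components are biased low with few
# site/species levels). Returns the objective, or with details = TRUE the
# GLS solution.
vc_profile <- function(theta, y, X, Vk, details = FALSE, method = "ML") {
  n <- length(y)
  p <- ncol(X)
  V <- diag(n)
  for (k in seq_along(Vk)) V <- V + exp(theta[k]) * Vk[[k]]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    V <- V + diag(1e-8 * mean(diag(V)), n)
    R <- chol(V)
  }
  Xs <- backsolve(R, X, transpose = TRUE)
  ys <- backsolve(R, y, transpose = TRUE)
  qrX <- qr(Xs)
  beta <- qr.coef(qrX, ys)
  r <- ys - Xs %*% beta
  # floor on the profiled variance keeps the objective finite when the
  # fixed effects explain the data exactly (degenerate zero-residual case)
  s2_floor <- 1e-13 * sum((y - mean(y))^2) / n + 1e-300
  logdetV <- 2 * sum(log(diag(R)))
  if (method == "REML") {
    s2 <- max(sum(r^2) / (n - p), s2_floor)
    XtX <- crossprod(Xs)
    nll <- 0.5 * ((n - p) * log(2 * pi * s2) + (n - p) + logdetV +
                    determinant(XtX, logarithm = TRUE)$modulus -
                    p * log(s2))
    nll <- as.numeric(nll)
  } else {
    s2 <- max(sum(r^2) / n, s2_floor)
    nll <- 0.5 * (n * log(2 * pi * s2) + n + logdetV)
  }
  if (!details) return(nll)
  XtX <- crossprod(Xs)
  vcov_beta <- tryCatch(s2 * solve(XtX), error = function(e) {
    s2 * solve(XtX + diag(1e-10, ncol(XtX)))
  })
  list(nll = nll, beta = drop(beta), vcov_beta = vcov_beta, sigma2_e = s2)
}

#' Fit one candidate phylogenetic mixed model for a trait
#'
#' Gaussian mixed model of the transformed species-by-site trait mean on
#' `ln(site_pe)` and `ln(species_pe)` (plus their interaction for the
#' interactive form), with any subset of the four random effects of
#' [pglmm_structures()]. Variance components are estimated by maximum
#' likelihood (profiled over fixed effects and residual variance,
#' multi-start bounded quasi-Newton on the log-variance-ratio scale), so
#' AIC values are comparable across fixed-effect forms.
#'
#' @param trait trait column name in `tt`.
#' @param tt a `trait_table`.
#' @param tree phylogeny covering the species in `tt`.
#' @param sites,species [site_info()] / [species_info()] tables.
#' @param fixed_form `"additive"` or `"interaction"`.
#' @param transform `"none"`, `"log"` or `"sqrt"` applied to the trait.
#' @param random_effects character subset of
#'   `c("site", "species", "species_phylo", "phylo_in_site")`; may be empty
#'   for an ordinary regression.
#' @param n_starts number of optimizer starts (spread over start values).
#' @param method `"ML"` (default; AIC values are then comparable across
#'   fixed-effect forms) or `"REML"` (restricted likelihood; preferred for
#'   interval estimation because ML variance components — and hence Wald
#'   standard errors — are biased low with few site or species levels).
#' @return An object of class `pglmm_fit`: coefficient table (estimate,
#'   se, z, and a Wald p-value against a t reference with between-cluster
#'   df), variance components, log-likelihood, AIC (and
#'   `AIC_raw_scale`, Jacobian-corrected to the untransformed trait scale,
#'   used when comparing transforms), convergence flag.
#' @export
fit_candidate <- function(trait, tt, tree, sites, species,
                          fixed_form = c("additive", "interaction"),
                          transform = c("none", "log", "sqrt"),
                          random_effects = c("site", "species",
                                             "species_phylo", "phylo_in_site"),
                          n_starts = 3L, method = c("ML", "REML")) {
  fixed_form <- match.arg(fixed_form)
  transform <- match.arg(transform)
  method <- match.arg(method)
  if (length(random_effects)) {
    random_effects <- match.arg(random_effects, several.ok = TRUE)
  }
  d <- tt[!tt$excluded & !is.na(tt[[trait]]), , drop = FALSE]
  if (nrow(d) < 8L) stop("fewer than 8 non-missing cells for trait ", trait)
  x <- d[[trait]]
  if (transform == "log" && any(x <= 0)) stop("log transform needs positive values")
  if (transform == "sqrt" && any(x < 0)) stop("sqrt transform needs non-negative values")
  y <- switch(transform, none = x, log = log(x), sqrt = sqrt(x))
  jac <- switch(transform, none = 0, log = -sum(log(x)),
                sqrt = -sum(log(2 * sqrt(x))))
  lsi <- log(sites$site_pe[match(d$site_id, sites$site_id)])
  lsp <- log(species$species_pe[match(d$species_id, species$species_id)])
  if (anyNA(lsi) || anyNA(lsp)) stop("trait table references unknown sites/species")
  X <- cbind(`(Intercept)` = 1, ln_site_pe = lsi, ln_species_pe = lsp)
  if (fixed_form == "interaction") {
    X <- cbind(X, `ln_site_pe:ln_species_pe` = lsi * lsp)
  }
  Vk <- if (length(random_effects)) {
    pglmm_structures(d$species_id, d$site_id, tree)[random_effects]
  } else list()
  n <- length(y)
  converged <- TRUE
  if (!length(Vk)) {
    sol <- vc_profile(numeric(0), y, X, Vk, details = TRUE, method = method)
    theta <- numeric(0)
  } else {
    starts <- list(rep(-2, length(Vk)), rep(0, length(Vk)), rep(-6, length(Vk)))
    starts <- starts[seq_len(min(n_starts, length(starts)))]
    obj <- function(th) vc_profile(th, y, X, Vk, method = method)
    best <- NULL
    for (th0 in starts) {
      o <- tryCatch(
        stats::optim(th0, obj, method = "L-BFGS-B", lower = -18, upper = 12,
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$value < best$value - 1e-10) best <- o
    }
    if (is.null(best)) stop("optimizer failed for trait ", trait)
    converged <- best$convergence == 0
    theta <- best$par
    sol <- vc_profile(theta, y, X, Vk, details = TRUE, method = method)
  }
  se <- sqrt(diag(sol$vcov_beta))
  z <- sol$beta / se
  # Wald tests against a t reference with between-cluster df: the site
  # slope is identified by the number of gardens and the species slope by
  # the number of species, so a normal reference is far too optimistic
  n_site_lv <- length(unique(d$site_id))
  n_sp_lv <- length(unique(d$species_id))
  df <- vapply(colnames(X), function(tm) {
    if (tm == "ln_site_pe") max(1L, n_site_lv - 2L)
    else if (tm == "ln_species_pe") max(1L, n_sp_lv - 2L)
    else max(1L, min(n_site_lv, n_sp_lv) - 2L)
  }, numeric(1))
  coefs <- data.frame(term = colnames(X), estimate = sol$beta, se = se, z = z,
                      df = df, p = 2 * stats::pt(-abs(z), df),
                      row.names = NULL, stringsAsFactors = FALSE)
  varcomp <- c(stats::setNames(exp(theta) * sol$sigma2_e, names(Vk)),
               sigma2_e = sol$sigma2_e)
  ll <- -vc_profile(theta, y, X, Vk, method = method)
  k <- ncol(X) + length(Vk) + 1L
  out <- list(trait_id = trait, fixed_form = fixed_form, transform = transform,
              random_effects = names(Vk), coefficients = coefs,
              varcomp = varcomp, loglik = ll, AIC = -2 * ll + 2 * k,
              AIC_raw_scale = -2 * (ll + jac) + 2 * k, n = n, n_par = k,
              method = method, converged = converged, data = d,
              n_sites = length(unique(d$site_id)),
              n_species = length(unique(d$species_id)))
  class(out) <- "pglmm_fit"
  out
}

#' Confidence intervals for fixed effects of a phylogenetic mixed model
#'
#' Intervals use Student-t quantiles with between-cluster degrees of
#' freedom: the site slope is identified by the number of distinct sites
#' and the species slope by the number of distinct species, so each gets
#' `n_levels - 2` degrees of freedom (intercept and interaction use the
#' smaller of the two). With only a handful of gardens, normal-quantile
#' (Wald z) intervals undercover badly; between-cluster df is the standard
#' small-sample remedy for cluster-level predictors.
#'
#' @param object a `pglmm_fit`.
#' @param parm coefficient names (default all).
#' @param level confidence level.
#' @param ... unused.
#' @return matrix with lower/upper bounds and the df used.
#' @export
confint.pglmm_fit <- function(object, parm = NULL, level = 0.95, ...) {
  co <- object$coefficients
  if (is.null(parm)) parm <- co$term
  df_site <- object$n_sites - 2L
  df_sp <- object$n_species - 2L
  df <- vapply(co$term, function(tm) {
    if (tm == "ln_site_pe") df_site
    else if (tm == "ln_species_pe") df_sp
    else min(df_site, df_sp)
  }, numeric(1))
  q <- stats::qt(1 - (1 - level) / 2, df)
  out <- cbind(lower = co$estimate - q * co$se,
               upper = co$estimate + q * co$se, df = df)
  rownames(out) <- co$term
  out[parm, , drop = FALSE]
}

#' @export
print.pglmm_fit <- function(x, ...) {
  cat("Phylogenetic mixed model for", x$trait_id,
      sprintf("(%s, transform=%s, n=%d)\n", x$fixed_form, x$transform, x$n))
  print(x$coefficients, digits = 4)
  cat("Variance components:\n")
  print(round(x$varcomp, 6))
  cat(sprintf("logLik %.4f  AIC %.2f\n", x$loglik, x$AIC))
  invisible(x)
}

#' Select the model for one trait and summarise it
#'
#' Reproduces the per-trait modelling sequence: (1) choose the fixed-effect
#' form (additive vs interaction) and trait transform by lowest AIC on
#' preliminary ordinary regressions, with AIC made comparable across
#' transforms by the transform Jacobian and ties within `delta_aic` broken
#' toward fewer parameters; (2) fit the phylogenetic mixed model with all
#' four random effects and backward-eliminate random effects whose
#' likelihood-ratio p-value is at or above `p_drop` (a deliberately
#' generous 0.5), never removing the iid species effect while a
#' phylogenetic term remains (species absorbs non-phylogenetic species
#' differences while phylogeny is tested); (3) report Wald p-values for
#' the fixed effects (t reference, between-cluster df), the likelihood-ratio total R-squared
#' `1 - exp(-(2/N) (logLik_model - logLik_null))` against the
#' intercept-only ordinary model, and partial R-squared per predictor as
#' the drop in total R-squared when that predictor's terms are removed.
#'
#' @inheritParams fit_candidate
#' @param transforms candidate transforms (infeasible ones are skipped).
#' @param forms candidate fixed forms.
#' @param p_drop backward-elimination cutoff on the LRT p-value.
#' @param delta_aic AIC window treated as a tie (parsimony rule).
#' @param phylo set `FALSE` for the phylogenetically unstructured analysis
#'   (only site and species random effects are offered).
#' @return list of class `regression_result` with the chosen form and
#'   transform, coefficient table, retained variance components, AIC,
#'   total and partial R-squared, and per-predictor slopes/p-values.
#' @export
select_model <- function(trait, tt, tree, sites, species,
                         transforms = c("none", "log", "sqrt"),
                         forms = c("additive", "interaction"),
                         p_drop = 0.5, delta_aic = 2, phylo = TRUE,
                         n_starts = 3L) {
  d <- tt[!tt$excluded & !is.na(tt[[trait]]), , drop = FALSE]
  x <- d[[trait]]
  feasible <- transforms
  if (any(x <= 0)) feasible <- setdiff(feasible, "log")
  if (any(x < 0)) feasible <- setdiff(feasible, "sqrt")
  if (!length(feasible)) stop("no feasible transform for trait ", trait)

  # stage 1: fixed form + transform on ordinary regressions
  cand <- expand.grid(form = forms, transform = feasible,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    fits[[i]] <- tryCatch(
      fit_candidate(trait, tt, tree, sites, species,
                    fixed_form = cand$form[i], transform = cand$transform[i],
                    random_effects = character(0)),
      error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all candidate fits failed for trait ", trait)
  cand <- cand[ok, , drop = FALSE]; fits <- fits[ok]
  aics <- vapply(fits, `[[`, numeric(1), "AIC_raw_scale")
  npar <- vapply(fits, `[[`, numeric(1), "n_par")
  tied <- which(aics <= min(aics) + delta_aic)
  pick <- tied[order(npar[tied], aics[tied])][1]
  form <- cand$form[pick]; transform <- cand$transform[pick]

  # stage 2: backward elimination of random effects
  res_all <- if (phylo) c("site", "species", "species_phylo", "phylo_in_site")
  else c("site", "species")
  fit_re <- function(re) fit_candidate(trait, tt, tree, sites, species,
                                       fixed_form = form, transform = transform,
                                       random_effects = re, n_starts = n_starts)
  current <- tryCatch(fit_re(res_all), error = function(e) NULL)
  if (is.null(current)) stop("full model did not converge for trait ", trait)
  repeat {
    re <- current$random_effects
    removable <- re
    if ("species" %in% removable &&
        any(c("species_phylo", "phylo_in_site") %in% re)) {
      removable <- setdiff(removable, "species")
    }
    if (!length(removable)) break
    ps <- fits_red <- stats::setNames(vector("list", length(removable)), removable)
    pvals <- rep(NA_real_, length(removable))
    for (j in seq_along(removable)) {
      red <- tryCatch(fit_re(setdiff(re, removable[j])),
                      error = function(e) NULL)
      if (is.null(red)) next
      lr <- max(0, 2 * (current$loglik - red$loglik))
      pvals[j] <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
      fits_red[[j]] <- red
    }
    if (all(is.na(pvals)) || max(pvals, na.rm = TRUE) < p_drop) break
    j <- which.max(pvals)
    current <- fits_red[[j]]
  }

  # stage 3: R-squared partition
  null_fit <- fit_candidate(trait, tt, tree, sites, species,
                            fixed_form = "additive", transform = transform,
                            random_effects = character(0))
  # intercept-only log-likelihood on the transformed scale
  y <- switch(transform, none = x, log = log(x), sqrt = sqrt(x))
  n <- length(y)
  s2_null <- mean((y - mean(y))^2)
  ll_null <- -0.5 * n * (log(2 * pi * s2_null) + 1)
  r2_lik <- function(ll) min(1, max(0, 1 - exp(-(2 / n) * (ll - ll_null))))
  r2_total <- r2_lik(current$loglik)
  partial <- c(site_pe = NA_real_, species_pe = NA_real_)
  drop_terms <- list(site_pe = "ln_site_pe", species_pe = "ln_species_pe")
  for (p in names(drop_terms)) {
    red <- tryCatch(
      fit_reduced_fixed(trait, tt, tree, sites, species, form, transform,
                        current$random_effects, drop_terms[[p]],
                        n_starts = n_starts),
      error = function(e) NULL)
    if (!is.null(red)) partial[p] <- max(0, r2_total - r2_lik(red$loglik))
  }
  coefs <- current$coefficients
  slope <- function(term) {
    i <- match(term, coefs$term)
    c(estimate = coefs$estimate[i], se = coefs$se[i], p = coefs$p[i])
  }
  out <- list(trait_id = trait, fixed_form = form, transform = transform,
              coefficients = coefs, random_effects = current$random_effects,
              varcomp = current$varcomp, AIC = current$AIC,
              loglik = current$loglik, n = current$n,
              R2_total = r2_total, R2_partial = partial,
              site = slope("ln_site_pe"), species = slope("ln_species_pe"),
              converged = current$converged)
  class(out) <- "regression_result"
  out
}

# Refit the current model with some fixed-effect columns removed (used for
# partial R2). Interaction terms containing a dropped predictor go with it.
fit_reduced_fixed <- function(trait, tt, tree, sites, species, form,
                              transform, random_effects, drop, n_starts = 3L) {
  fit <- fit_candidate(trait, tt, tree, sites, species, fixed_form = form,
                       transform = transform, random_effects = random_effects,
                       n_starts = n_starts)
  d <- fit$data
  x <- d[[trait]]
  y <- switch(transform, none = x, log = log(x), sqrt = sqrt(x))
  lsi <- log(sites$site_pe[match(d$site_id, sites$site_id)])
  lsp <- log(species$species_pe[match(d$species_id, species$species_id)])
  X <- cbind(`(Intercept)` = 1, ln_site_pe = lsi, ln_species_pe = lsp)
  if (form == "interaction") X <- cbind(X, `ln_site_pe:ln_species_pe` = lsi * lsp)
  keep <- !grepl(drop, colnames(X), fixed = TRUE)
  X <- X[, keep, drop = FALSE]
  Vk <- if (length(random_effects)) {
    pglmm_structures(d$species_id, d$site_id, tree)[random_effects]
  } else list()
  if (!length(Vk)) {
    sol <- vc_profile(numeric(0), y, X, Vk, details = TRUE)
    return(list(loglik = -sol$nll))
  }
  best <- NULL
  for (th0 in list(rep(-2, length(Vk)), rep(0, length(Vk)))) {
    o <- tryCatch(stats::optim(th0, vc_profile, y = y, X = X, Vk = Vk,
                               method = "L-BFGS-B", lower = -18, upper = 12,
                               control = list(maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("reduced fit failed")
  list(loglik = -best$value)
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s: %s/%s model, n=%d, AIC=%.2f, R2=%.3f\n", x$trait_id,
              x$fixed_form, x$transform, x$n, x$AIC, x$R2_total))
  print(x$coefficients, digits = 4)
  cat("Random effects kept:",
      if (length(x$random_effects)) paste(x$random_effects, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
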