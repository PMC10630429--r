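# Physical constants used across hydraulic computations.
# Molar mass of water g mol-1; density kg m-3 and dynamic viscosity Pa s at 20 C.
.water <- list(M = 18.015, rho20 = 998.2, eta20 = 1.002e-3)

#' Saturation vapor pressure of water (Tetens equation)
#'
#' Valid over liquid water for typical lab chamber temperatures (0-40 C).
#'
#' @param temp_c air temperature, degrees C.
#' @return saturation vapor pressure, kPa.
#' @export
tetens_esat <- function(temp_c) {
  0.61078 * exp(17.27 * temp_c / (temp_c + 237.3))
}

#' Dynamic viscosity of liquid water
#'
#' Empirical correlation (accurate to ~0.1% between 0 and 100 C), anchored
#' at 1.002 mPa s at 20 C.
#'
#' @param temp_c water temperature, degrees C.
#' @return dynamic viscosity, mPa s.
#' @export
water_viscosity <- function(temp_c) {
  1.002 * 10^((20 - temp_c) * (1.3272 - 0.001053 * (temp_c - 20)) /
                (temp_c + 105))
}

#' Minimum epidermal conductance from a leaf drying curve
#'
#' Converts interval mass losses of a drying leaf to conductances
#' (mol m-2 s-1) using the chamber vapor-pressure deficit, restricts to
#' intervals whose bracketing Fv/Fm readings exceed `fvfm_min` (damaged
#' leaves are excluded), identifies the quasi-linear phase as the longest
#' suffix of valid intervals whose conductance stays within `phase_tol` of
#' its median, and reports the mean of the sequential pair with the lowest
#' conductance inside that phase (ties broken toward the earliest pair).
#'
#' @param series data.frame with columns `time` (h, strictly increasing),
#'   `leaf_mass` (g), `fvfm` (dimensionless, `NA` on weighings where it was
#'   not read), `rh` (fraction), `temperature` (C), `pressure` (kPa), and
#'   `leaf_area` (m2). Scalars are recycled.
#' @param fvfm_min intervals whose bracketing Fv/Fm is at or below this are
#'   excluded (default 0.7).
#' @param phase_tol relative half-width of the quasi-linear band around the
#'   phase median conductance (default 0.2).
#' @return list with `value` (g_min, mol m-2 s-1, or `NA` when flagged),
#'   `conductance` per interval, `valid` logical per interval, `phase`
#'   (indices of quasi-linear intervals), and `reason` when flagged.
#' @export
compute_gmin <- function(series, fvfm_min = 0.7, phase_tol = 0.2) {
  n <- nrow(series)
  if (n < 4L) stop("need at least 4 weighings")
  if (any(diff(series$time) <= 0)) stop("time must be strictly increasing")
  if (any(series$leaf_mass <= 0)) stop("leaf masses must be > 0")
  dm <- -diff(series$leaf_mass)                       # g lost per interval
  dt <- diff(series$time) * 3600                      # s
  mid <- function(x) (x[-n] + x[-1]) / 2
  temp <- rep_len(series$temperature, n); rh <- rep_len(series$rh, n)
  patm <- rep_len(series$pressure, n); area <- rep_len(series$leaf_area, n)
  vpd <- tetens_esat(mid(temp)) * (1 - mid(rh))
  g <- (dm / dt / .water$M) / mid(area) / (vpd / mid(patm))
  gain <- dm < 0
  if (any(gain)) warning(sum(gain), " interval(s) with mass gain excluded")
  # carry Fv/Fm readings forward/backward so each interval is bracketed by
  # its nearest observed values
  fv <- rep_len(series$fvfm, n)
  obs <- which(!is.na(fv))
  if (!length(obs)) stop("no Fv/Fm readings in series")
  locf <- function(i) { j <- obs[obs <= i]; fv[if (length(j)) max(j) else min(obs)] }
  nocb <- function(i) { j <- obs[obs >= i]; fv[if (length(j)) min(j) else max(obs)] }
  fv_before <- vapply(seq_len(n - 1L), locf, numeric(1))
  fv_after <- vapply(seq_len(n - 1L) + 1L, nocb, numeric(1))
  ok_fv <- fv_before > fvfm_min & fv_after > fvfm_min
  valid <- ok_fv & !gain
  if (sum(valid) < 2L) {
    return(list(value = NA_real_, conductance = g, valid = valid,
                phase = integer(0),
                reason = "fewer than 2 intervals pass the Fv/Fm criterion"))
  }
  # quasi-linear phase: longest all-valid suffix whose conductances stay
  # within phase_tol of their median
  phase <- integer(0)
  for (start in seq_len(n - 1L)) {
    idx <- start:(n - 1L)
    if (!all(valid[idx])) next
    med <- stats::median(g[idx])
    if (all(abs(g[idx] - med) <= phase_tol * abs(med)) || all(g[idx] == 0)) {
      phase <- idx
      break
    }
  }
  if (!length(phase)) {
    # fall back to the longest valid suffix, then trim until within band
    idx <- seq_len(n - 1L)
    idx <- idx[valid[idx]]
    phase <- utils::tail(idx, 2L)
  }
  if (length(phase) == 1L) {
    return(list(value = g[phase], conductance = g, valid = valid,
                phase = phase, reason = NULL))
  }
  pair_means <- (g[phase[-length(phase)]] + g[phase[-1]]) / 2
  best <- which.min(pair_means)                       # earliest on ties
  list(value = pair_means[best], conductance = g, valid = valid,
       phase = phase, reason = NULL)
}

#' Leaf hydraulic conductance from paired water potentials
#'
#' `k_leaf = T / (psi_stem - psi_leaf)` where the driving gradient is the
#' xylem pressure difference between adjacent bagged (stem proxy) and
#' unbagged leaves. Measurements with a small gradient (< `min_gradient`,
#' default 0.3 MPa) are excluded because they likely reflect continued
#' transpiration of the bagged leaf; non-positive gradients are excluded
#' outright.
#'
#' @param transpiration mmol m-2 s-1 (>= 0).
#' @param psi_stem,psi_leaf water potentials, MPa (<= 0).
#' @param min_gradient exclusion threshold on `psi_stem - psi_leaf`, MPa.
#' @return data.frame with `kleaf` (mmol m-2 s-1 MPa-1, `NA` when
#'   excluded), `excluded` and `reason`.
#' @export
compute_kleaf <- function(transpiration, psi_stem, psi_leaf,
                          min_gradient = 0.3) {
  if (any(transpiration < 0)) stop("transpiration must be >= 0")
  if (any(psi_stem > 0) || any(psi_leaf > 0)) stop("psi values must be <= 0")
  dpsi <- psi_stem - psi_leaf
  reason <- rep(NA_character_, length(dpsi))
  reason[dpsi <= 0] <- "non-positive gradient"
  reason[dpsi > 0 & dpsi < min_gradient] <-
    sprintf("gradient < %.2g MPa", min_gradient)
  excluded <- !is.na(reason)
  k <- ifelse(excluded, NA_real_, transpiration / dpsi)
  data.frame(kleaf = k, dpsi = dpsi, excluded = excluded, reason = reason,
             stringsAsFactors = FALSE)
}

#' Stem hydraulic conductivity from a flow-pressure series
#'
#' The raw conductivity is the OLS slope of flow rate (g s-1) against
#' pressure gradient (MPa mm-1), standardized to 20 C by the dynamic-
#' viscosity ratio of water and divided by cross-sectional xylem area (or
#' by leaf area).
#'
#' @param series data.frame with `flow`, `pressure_gradient`,
#'   `temperature` (C), `xylem_area` (mm2) and `leaf_area` (m2); the last
#'   three may be scalars.
#' @param area_basis `"xylem"` (default) or `"leaf"`.
#' @return list with `value` (area-scaled conductivity, `NA` when flagged),
#'   `slope` (raw, g s-1 per MPa mm-1), `slope_20C`, and `flag`.
#' @export
compute_kstem <- function(series, area_basis = c("xylem", "leaf")) {
  area_basis <- match.arg(area_basis)
  if (nrow(series) < 3L) stop("need at least 3 steady-state points")
  if (length(unique(series$pressure_gradient)) < 2L) {
    stop("need at least 2 distinct pressures")
  }
  fit <- stats::lm(flow ~ pressure_gradient, data = series)
  slope <- unname(stats::coef(fit)["pressure_gradient"])
  tc <- series$temperature[1]
  slope20 <- slope * water_viscosity(tc) / water_viscosity(20)
  area <- if (area_basis == "xylem") series$xylem_area[1] else
    series$leaf_area[1]
  scale_ref <- max(abs(series$flow)) / diff(range(series$pressure_gradient))
  if (slope20 <= 1e-10 * max(scale_ref, 1e-300)) {
    return(list(value = NA_real_, slope = slope, slope_20C = slope20,
                flag = "non-positive fitted slope"))
  }
  list(value = slope20 / area, slope = slope, slope_20C = slope20, flag = NULL)
}

#' Rescale stem conductivities to a reference xylem area
#'
#' Xylem area does not fully standardize conductivity, so per-species
#' conductivities are rescaled to a reference (median) xylem area using the
#' regression `ln(K/XA) ~ ln(XA) + site` fitted within each species; the
#' fitted ln(XA) slope is used to move every measurement to the reference
#' area while keeping its site intercept.
#'
#' @param df data.frame with columns `species_id`, `site_id`, `kstem`
#'   (already per unit xylem area) and `xylem_area` (mm2).
#' @param reference `"species-median"` (default) or `"global-median"`.
#' @return `df` with an added `kstem_rescaled` column.
#' @export
rescale_kstem <- function(df, reference = c("species-median", "global-median")) {
  reference <- match.arg(reference)
  stopifnot(all(c("species_id", "site_id", "kstem", "xylem_area") %in% names(df)))
  if (any(df$kstem <= 0 | df$xylem_area <= 0, na.rm = TRUE)) {
    stop("kstem and xylem_area must be > 0")
  }
  gmed <- stats::median(df$xylem_area, na.rm = TRUE)
  out <- df
  out$kstem_rescaled <- NA_real_
  for (sp in unique(df$species_id)) {
    idx <- which(df$species_id == sp & !is.na(df$kstem))
    if (length(idx) < 3L) {
      out$kstem_rescaled[idx] <- df$kstem[idx]
      next
    }
    d <- df[idx, ]
    d$lnxa <- log(d$xylem_area)
    form <- if (length(unique(d$site_id)) > 1L) log(kstem) ~ lnxa + site_id else
      log(kstem) ~ lnxa
    fit <- stats::lm(form, data = d)
    b <- unname(stats::coef(fit)["lnxa"])
    ref <- if (reference == "species-median")
      stats::median(d$xylem_area) else gmed
    out$kstem_rescaled[idx] <- exp(log(d$kstem) + b * (log(ref) - d$lnxa))
  }
  out
}

#' Hydraulically weighted vessel diameter
#'
#' `D_h = ((1/n) * sum(D_i^4))^(1/4)`: the power-4 mean, which weights each
#' conduit by its contribution to Poiseuille flow.
#'
#' @param diameters vessel diameters, um (> 0, non-empty).
#' @return D_h, um.
#' @export
hydraulic_diameter <- function(diameters) {
  if (!length(diameters)) stop("empty diameter sample")
  if (any(diameters <= 0)) stop("diameters must be > 0")
  (mean(diameters^4))^(1 / 4)
}

#' Theoretical stem conductivity from vessel anatomy (Poiseuille)
#'
#' Assuming no embolisms, summed Poiseuille conductances of the observed
#' conduits per counted sapwood area:
#' `K_theo = (pi * rho_w / (128 * eta_20)) * sum(D_i^4) / A`,
#' with water density and viscosity at 20 C.
#'
#' @param diameters vessel diameters, um.
#' @param counted_area sapwood area over which they were counted, mm2.
#' @return theoretical conductivity, kg m-1 MPa-1 s-1.
#' @export
theoretical_conductivity <- function(diameters, counted_area) {
  if (!length(diameters)) stop("empty diameter sample")
  if (any(diameters <= 0)) stop("diameters must be > 0")
  if (counted_area <= 0) stop("counted_area must be > 0")
  d_m <- diameters * 1e-6
  a_m2 <- counted_area * 1e-6
  (pi * .water$rho20 / (128 * .water$eta20)) * sum(d_m^4) / a_m2 * 1e6
}

#' Relative growth rate from a log-size regression
#'
#' The slope of `ln(size)` against day, rescaled to the field's customary
#' units: mg g-1 day-1 for mass (x1000) or mm cm-1 day-1 for height (x10).
#'
#' @param day days since planting (>= 2 points).
#' @param size geometric-mean biomass (g) or height (cm), > 0.
#' @param units `"mass"`, `"height"`, or `"none"` (raw per-day log slope).
#' @return relative growth rate.
#' @export
relative_growth_rate <- function(day, size, units = c("mass", "height", "none")) {
  units <- match.arg(units)
  if (length(day) < 2L) stop("need at least 2 time points")
  if (any(size <= 0)) stop("sizes must be > 0")
  slope <- unname(stats::coef(stats::lm(log(size) ~ day))[2])
  slope * switch(units, mass = 1000, height = 10, none = 1)
}

#' Impute masses of broken root segments from allometry
#'
#' Fits `ln(mass) ~ ln(proximal_diameter)` on segments with measured mass
#' and completes the excavated root system. Each cut (distal) end should
#' continue into another segment whose proximal diameter matches it, or
#' taper into fine roots; working from the largest distal end down, ends
#' are matched to unattached segments with a proximal diameter within
#' `match_tol` relative tolerance. An unmatched distal end at least as
#' large as the smallest proximal diameter in the table indicates
#' breakage: the lost child segment's mass is predicted from the allometry
#' at that diameter, proceeding from the smallest broken end to the
#' largest so newly completed segments enter the totals. Segments with an
#' unmeasured mass are likewise filled from the allometry. Measured masses
#' are never altered.
#'
#' @param segments data.frame with `proximal_diameter` (mm),
#'   `distal_diameter` (mm) and `dry_mass` (g, `NA` where unmeasured).
#' @param match_tol relative tolerance for matching a distal end to the
#'   proximal diameter of a continuing segment (default 0.1).
#' @return list with `table` (input rows plus imputed rows, flagged by the
#'   `imputed` column), `total_mass`, `imputed_fraction`, and `allometry`
#'   (intercept and slope on the log scale).
#' @export
impute_root_mass <- function(segments, match_tol = 0.1) {
  stopifnot(all(c("proximal_diameter", "distal_diameter", "dry_mass") %in%
                  names(segments)))
  if (any(segments$proximal_diameter <= 0 | segments$distal_diameter <= 0)) {
    stop("diameters must be > 0")
  }
  complete <- !is.na(segments$dry_mass)
  if (sum(complete) < 3L) stop("need >= 3 complete segments to fit allometry")
  fit <- stats::lm(log(dry_mass) ~ log(proximal_diameter),
                   data = segments[complete, ])
  ab <- unname(stats::coef(fit))
  predict_mass <- function(d) exp(ab[1] + ab[2] * log(d))

  tab <- segments
  tab$imputed <- FALSE
  # missing masses of existing segments, smallest first
  ord <- order(segments$proximal_diameter)
  for (i in ord[!complete[ord]]) {
    tab$dry_mass[i] <- predict_mass(tab$proximal_diameter[i])
    tab$imputed[i] <- TRUE
  }
  # match distal ends (largest first) to unattached continuing segments
  prox <- tab$proximal_diameter
  attached <- rep(FALSE, nrow(tab))
  tip_cut <- min(prox) * (1 - match_tol)
  broken_d <- numeric(0)
  for (i in order(tab$distal_diameter, decreasing = TRUE)) {
    d <- tab$distal_diameter[i]
    cand <- which(!attached & abs(prox / d - 1) <= match_tol)
    cand <- setdiff(cand, i)
    if (length(cand)) {
      attached[cand[which.min(abs(prox[cand] - d))]] <- TRUE
    } else if (d >= tip_cut) {
      broken_d <- c(broken_d, d)   # no continuation and too thick for a tip
    }
  }
  for (d in sort(broken_d)) {
    add <- data.frame(proximal_diameter = d, distal_diameter = NA_real_,
                      dry_mass = predict_mass(d), imputed = TRUE)
    extra <- setdiff(names(tab), names(add))
    for (e in extra) add[[e]] <- NA
    tab <- rbind(tab, add[names(tab)])
  }
  total <- sum(tab$dry_mass)
  list(table = tab, total_mass = total,
       imputed_fraction = sum(tab$dry_mass[tab$imputed]) / total,
       allometry = c(intercept = ab[1], slope = ab[2]))
}

#' Common-slope standardized ratio of two traits
#'
#' Simple trait ratios confound size differences when the traits are
#' allometrically related. The standardized ratio removes this by fitting
#' `ln(T1) = a_group + beta * ln(T2)` with one intercept per
#' (species, site) group and a single common slope, and returning
#' `ln(T1) - beta * ln(T2)` per observation — the intercept each point
#' implies under the common slope.
#'
#' @param t1,t2 positive paired trait vectors.
#' @param group group labels (e.g. interaction of species and site).
#' @return list with `beta` (common slope), `ratio` (per observation), and
#'   `fit` (the underlying `lm`).
#' @export
standardized_ratio <- function(t1, t2, group) {
  if (any(t1 <= 0 | t2 <= 0, na.rm = TRUE)) stop("traits must be > 0")
  group <- factor(group)
  if (length(t1) < nlevels(group) + 2L) {
    stop("too few observations to identify a common slope")
  }
  d <- data.frame(l1 = log(t1), l2 = log(t2), group = group)
  fit <- stats::lm(l1 ~ 0 + group + l2, data = d)
  beta <- unname(stats::coef(fit)["l2"])
  list(beta = beta, ratio = d$l1 - beta * d$l2, fit = fit)
}
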