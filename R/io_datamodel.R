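#' Construct a site information table
#'
#' Sites are common gardens positioned along a climatic moisture gradient,
#' indexed by their moisture supply `site_pe`, the ratio of mean annual
#' precipitation to pan evaporation (P/Ep, mm/mm).
#'
#' @param site_id character vector of unique site identifiers.
#' @param site_pe numeric vector of site P/Ep values (> 0).
#' @param mat optional mean annual temperature (degrees C).
#' @param map optional mean annual precipitation (mm).
#' @return A `data.frame` of class `site_info` with one row per site.
#' @export
site_info <- function(site_id, site_pe, mat = NA_real_, map = NA_real_) {
  site_id <- as.character(site_id)
  if (anyDuplicated(site_id)) stop("site_id values must be unique")
  if (any(!is.finite(site_pe)) || any(site_pe <= 0)) {
    stop("site_pe must be finite and > 0")
  }
  out <- data.frame(site_id = site_id, site_pe = as.numeric(site_pe),
                    mat = mat, map = map, stringsAsFactors = FALSE)
  class(out) <- c("site_info", "data.frame")
  out
}

#' Construct a species information table
#'
#' Species are characterised by their mean moisture supply over their native
#' range (`species_pe`), its spread, and subgenus membership.
#'
#' @param species_id character vector of unique species identifiers; these
#'   must match phylogeny tip labels.
#' @param species_pe numeric vector of species mean P/Ep values (> 0).
#' @param species_pe_sd optional s.d. of P/Ep over each species' range.
#' @param subgenus optional subgenus labels.
#' @return A `data.frame` of class `species_info`, one row per species.
#' @export
species_info <- function(species_id, species_pe, species_pe_sd = NA_real_,
                         subgenus = NA_character_) {
  species_id <- as.character(species_id)
  if (anyDuplicated(species_id)) stop("species_id values must be unique")
  if (any(!is.finite(species_pe)) || any(species_pe <= 0)) {
    stop("species_pe must be finite and > 0")
  }
  out <- data.frame(species_id = species_id,
                    species_pe = as.numeric(species_pe),
                    species_pe_sd = species_pe_sd, subgenus = subgenus,
                    stringsAsFactors = FALSE)
  class(out) <- c("species_info", "data.frame")
  out
}

#' Construct trait definitions
#'
#' Each trait carries its measurement units, the transform applied before
#' regression, and the direction in which theory predicts it to respond to
#' increasing moisture supply.
#'
#' @param trait_id character vector of trait identifiers.
#' @param units character vector of unit strings (metadata only).
#' @param transform one of `"none"`, `"log"`, `"sqrt"` per trait.
#' @param predicted_direction +1 or -1 per trait: sign of the predicted
#'   response to P/Ep.
#' @param discount_rule optional per-trait exception rule, one of
#'   `NA`, `"species-exception"`, `"garden-exception"`.
#' @return A `data.frame` of class `trait_definitions`.
#' @export
trait_definitions <- function(trait_id, units = "", transform = "none",
                              predicted_direction = 1L,
                              discount_rule = NA_character_) {
  trait_id <- as.character(trait_id)
  if (anyDuplicated(trait_id)) stop("trait_id values must be unique")
  n <- length(trait_id)
  transform <- rep_len(as.character(transform), n)
  bad <- setdiff(unique(transform), c("none", "log", "sqrt"))
  if (length(bad)) stop("unknown transform: ", paste(bad, collapse = ", "))
  predicted_direction <- rep_len(as.integer(predicted_direction), n)
  if (!all(predicted_direction %in% c(-1L, 1L))) {
    stop("predicted_direction must be -1 or +1")
  }
  dr <- rep_len(as.character(discount_rule), n)
  bad <- setdiff(unique(dr[!is.na(dr)]), c("species-exception", "garden-exception"))
  if (length(bad)) stop("unknown discount_rule: ", paste(bad, collapse = ", "))
  out <- data.frame(trait_id = trait_id, units = rep_len(units, n),
                    transform = transform,
                    predicted_direction = predicted_direction,
                    discount_rule = dr, stringsAsFactors = FALSE)
  class(out) <- c("trait_definitions", "data.frame")
  out
}

#' Read a species-by-site trait table from CSV
#'
#' The table holds one row per (species, site) combination and one column
#' per trait. Combinations excluded from analysis (e.g. total mortality at
#' a site) are flagged through the optional logical `excluded` column rather
#' than silently dropped. Cells that cannot be coerced to numbers are set to
#' `NA` and reported.
#'
#' @param path CSV file with key columns `species_id` and `site_id`, an
#'   optional logical `excluded` column, and one numeric column per trait.
#'   Empty cells and `"NA"` are missing values.
#' @param defs optional [trait_definitions()]; trait columns not listed
#'   there are reported via a message.
#' @return A `data.frame` of class `trait_table` with attributes
#'   `coercion_failures` (data.frame of cell-level failures) and
#'   `unknown_traits` (character).
#' @export
read_trait_table <- function(path, defs = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", ""), colClasses = "character")
  key_cols <- c("species_id", "site_id")
  if (!all(key_cols %in% names(raw))) {
    stop("missing key column(s): ",
         paste(setdiff(key_cols, names(raw)), collapse = ", "))
  }
  key <- paste(raw$species_id, raw$site_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicated (species_id, site_id) key: ",
         gsub("\r", " / ", d, fixed = TRUE))
  }
  trait_cols <- setdiff(names(raw), c(key_cols, "excluded"))
  fails <- list()
  for (tc in trait_cols) {
    v <- raw[[tc]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      fails[[tc]] <- data.frame(trait_id = tc, row = bad, value = v[bad],
                                stringsAsFactors = FALSE)
    }
    raw[[tc]] <- num
  }
  raw$excluded <- if ("excluded" %in% names(raw)) {
    tolower(raw$excluded) %in% c("true", "t", "1", "yes")
  } else FALSE
  unknown <- character(0)
  if (!is.null(defs)) {
    unknown <- setdiff(trait_cols, defs$trait_id)
    if (length(unknown)) {
      message("trait columns not in definitions: ",
              paste(unknown, collapse = ", "))
    }
  }
  out <- raw[, c(key_cols, trait_cols, "excluded")]
  attr(out, "coercion_failures") <-
    if (length(fails)) do.call(rbind, fails) else
      data.frame(trait_id = character(), row = integer(), value = character())
  attr(out, "unknown_traits") <- unknown
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Write a trait table to CSV
#'
#' Values round-trip at full double precision (up to 17 significant digits).
#'
#' @param tt a `trait_table` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(tt, path) {
  df <- as.data.frame(tt)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    df[[j]] <- vapply(df[[j]], function(x)
      if (is.na(x)) NA_character_ else format(x, digits = 17, trim = TRUE,
                                              scientific = TRUE), character(1))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Extract trait column names of a trait table
#' @param tt a `trait_table`.
#' @return character vector of trait column names.
#' @export
trait_ids <- function(tt) {
  setdiff(names(tt), c("species_id", "site_id", "excluded"))
}

#' Read and validate a Newick phylogeny
#'
#' Wraps [ape::read.tree()] with the validation this analysis requires:
#' branch lengths present and non-negative, unique tip labels, and a report
#' of tree height. Ultrametricity is checked within a relative tolerance of
#' `1e-6` times tree height and recorded (not enforced) as an attribute.
#'
#' @param path Newick file containing a single tree with branch lengths.
#' @return An [ape::phylo] object with attributes `height` and `ultrametric`.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in '", path,
                                            "': ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in '", path, "'")
  if (inherits(tree, "multiPhylo")) stop("expected a single tree, found ",
                                         length(tree))
  validate_phylogeny(tree)
}

#' Validate a phylogeny object
#' @param tree an [ape::phylo] object.
#' @return The tree, with `height` and `ultrametric` attributes set.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("tip labels are not unique")
  depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  h <- max(depth)
  attr(tree, "height") <- h
  attr(tree, "ultrametric") <- (h - min(depth)) <= 1e-6 * h
  tree
}

#' Brownian-motion covariance matrix of a phylogeny
#'
#' Under Brownian trait evolution the covariance between two tips equals
#' their shared root-to-tip path length; the variance of each tip is its
#' root-to-tip distance. For an ultrametric tree the diagonal is constant
#' and equal to tree height.
#'
#' @param tree an [ape::phylo] object.
#' @param tips_order optional character vector giving the row/column order;
#'   defaults to `tree$tip.label`. All entries must be tips of the tree.
#' @return Symmetric positive semi-definite matrix with dimnames
#'   `tips_order`.
#' @export
brownian_covariance <- function(tree, tips_order = tree$tip.label) {
  tips_order <- as.character(tips_order)
  unknown <- setdiff(tips_order, tree$tip.label)
  if (length(unknown)) stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  V <- ape::vcv.phylo(tree)
  V[tips_order, tips_order, drop = FALSE]
}

#' Validate a trait table against site and species registries
#'
#' @param tt a `trait_table`.
#' @param species a [species_info()] table.
#' @param sites a [site_info()] table.
#' @return `tt` invisibly; errors describe the first violation found.
#' @export
validate_trait_table <- function(tt, species, sites) {
  bad_sp <- setdiff(unique(tt$species_id), species$species_id)
  if (length(bad_sp)) stop("unknown species in trait table: ",
                           paste(bad_sp, collapse = ", "))
  bad_site <- setdiff(unique(tt$site_id), sites$site_id)
  if (length(bad_site)) stop("unknown sites in trait table: ",
                             paste(bad_site, collapse = ", "))
  key <- paste(tt$species_id, tt$site_id)
  if (anyDuplicated(key)) stop("duplicated (species, site) rows")
  invisible(tt)
}

#' Per-cell performance records for realized-growth statistics
#'
#' One row per (species, site): the number planted, the number surviving,
#' and the mean and s.d. of the growth trait (final height or shoot mass)
#' over the `n_measured` plants it was measured on.
#'
#' @param species_id,site_id identifiers.
#' @param n_planted number of individuals planted (n').
#' @param n_survived number surviving the census.
#' @param n_measured number of plants on which the trait mean is based
#'   (at most `n_survived`).
#' @param trait_mean,trait_sd trait mean m and s.d. s over measured plants.
#' @return A `data.frame` of class `performance_cells` with the derived
#'   survival fraction `p_hat`.
#' @export
performance_cells <- function(species_id, site_id, n_planted, n_survived,
                              n_measured, trait_mean, trait_sd) {
  n <- length(species_id)
  out <- data.frame(species_id = as.character(species_id),
                    site_id = rep_len(as.character(site_id), n),
                    n_planted = as.integer(n_planted),
                    n_survived = as.integer(n_survived),
                    n_measured = as.integer(n_measured),
                    trait_mean = as.numeric(trait_mean),
                    trait_sd = as.numeric(trait_sd),
                    stringsAsFactors = FALSE)
  with(out, {
    if (any(n_planted < 1)) stop("n_planted must be >= 1")
    if (any(n_survived < 0 | n_survived > n_planted)) {
      stop("need 0 <= n_survived <= n_planted")
    }
    if (any(n_measured > n_survived)) stop("n_measured must be <= n_survived")
    if (any(trait_sd < 0, na.rm = TRUE)) stop("trait_sd must be >= 0")
  })
  out$p_hat <- out$n_survived / out$n_planted
  class(out) <- c("performance_cells", "data.frame")
  out
}
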