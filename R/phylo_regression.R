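#' Benjamini-Yekutieli (YBH) false-discovery-rate adjustment
#'
#' Step-up FDR control valid under arbitrary dependence: raw p-values are
#' multiplied by `m_total * c(m_total) / rank`, where
#' `c(m) = sum_{i=1..m} 1/i` is the harmonic correction, then made monotone
#' from the largest rank down and clipped to \[0, 1\]. `m_total` may exceed
#' the number of p-values supplied, in which case the family is treated
#' conservatively as containing that many tests (the unsupplied ones at
#' p = 1).
#'
#' @param pvals numeric vector of raw p-values in \[0, 1\].
#' @param m_total size of the test family; defaults to `length(pvals)`.
#' @return adjusted p-values in the original order.
#' @export
ybh_adjust <- function(pvals, m_total = length(pvals)) {
  k <- length(pvals)
  if (!k) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  if (m_total < k) stop("m_total must be >= length(pvals)")
  cm <- sum(1 / seq_len(m_total))
  o <- order(pvals, decreasing = TRUE, na.last = TRUE)
  ro <- order(o)
  ranks <- k:1L
  adj <- pmin(1, cummin(cm * m_total / ranks * pvals[o]))[ro]
  adj
}

# Significance tier symbols used in results figures: o/*/**/*** at
# alpha = 0.1, 0.05, 0.01, 0.001.
significance_tier <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
      labels = c("***", "**", "*", "o", "ns"), right = FALSE)
}

#' Fit and summarise the trait regressions for a whole trait table
#'
#' Runs [select_model()] for every trait, collects the slopes on
#' `ln(site_pe)` and `ln(species_pe)` with their Wald p-values, and applies
#' the Benjamini-Yekutieli adjustment jointly over the
#' `2 x n_traits` family (both predictors of every trait), conservatively
#' sized by `m_total`.
#'
#' @inheritParams select_model
#' @param traits trait columns to analyse; defaults to all in `tt`.
#' @param m_total FDR family size; defaults to twice the number of traits.
#' @param ... passed on to [select_model()].
#' @return list with `results` (named list of `regression_result`) and
#'   `table` (one row per trait x predictor: slope, se, raw and adjusted p,
#'   significance tier).
#' @export
regress_traits <- function(tt, tree, sites, species, traits = trait_ids(tt),
                           m_total = 2L * length(traits), ...) {
  results <- list()
  rows <- list()
  for (tr in traits) {
    res <- tryCatch(select_model(tr, tt, tree, sites, species, ...),
                    error = function(e) {
                      warning("trait ", tr, " skipped: ", conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) next
    results[[tr]] <- res
    rows[[tr]] <- data.frame(
      trait_id = tr,
      predictor = c("site_pe", "species_pe"),
      estimate = c(res$site["estimate"], res$species["estimate"]),
      se = c(res$site["se"], res$species["se"]),
      p = c(res$site["p"], res$species["p"]),
      R2_partial = unname(res$R2_partial[c("site_pe", "species_pe")]),
      R2_total = res$R2_total,
      fixed_form = res$fixed_form, transform = res$transform,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_adj <- ybh_adjust(tab$p, m_total = max(m_total, nrow(tab)))
  tab$tier <- as.character(significance_tier(tab$p_adj))
  list(results = results, table = tab)
}

#' Tally agreement of fitted trait responses with predicted directions
#'
#' Each trait x predictor relationship is scored against its predicted
#' direction: full agreement scores 1; relationships that agree for all
#' but the one or two driest species score 0.9 or 0.8; for all but the one
#' or two driest gardens, 0.75 or 0.5; disagreement scores 0. Exceptions
#' are supplied by the caller (they encode inspection of per-species /
#' per-garden refits). The aggregate percentage for a predictor is 100
#' times the summed weights over the number of traits; the significant
#' percentage additionally requires the adjusted p-value below `alpha`.
#'
#' @param table the `table` element of [regress_traits()].
#' @param defs [trait_definitions()] giving `predicted_direction` per trait.
#' @param exceptions optional data.frame with columns `trait_id`,
#'   `predictor` (`"site_pe"`/`"species_pe"`), `type` (`"species"` or
#'   `"garden"`), `n_exceptions` (1 or 2).
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @return list of class `tally_report`: `detail` (verdict and weight per
#'   trait x predictor) and `summary` (per predictor: weighted percent
#'   agreeing, percent significant-and-agreeing, counts of significant
#'   disagreements).
#' @export
tally_agreement <- function(table, defs, exceptions = NULL, alpha = 0.05) {
  missing_pred <- setdiff(unique(table$trait_id), defs$trait_id)
  if (length(missing_pred)) {
    warning("no predicted direction for: ", paste(missing_pred, collapse = ", "),
            "; excluded from tallies")
    table <- table[!table$trait_id %in% missing_pred, , drop = FALSE]
  }
  pred <- defs$predicted_direction[match(table$trait_id, defs$trait_id)]
  obs <- sign(table$estimate)
  verdict <- ifelse(obs == pred, "agree", "disagree")
  weight <- ifelse(verdict == "agree", 1, 0)
  if (!is.null(exceptions) && nrow(exceptions)) {
    stopifnot(all(c("trait_id", "predictor", "type", "n_exceptions") %in%
                    names(exceptions)))
    if (!all(exceptions$n_exceptions %in% 1:2)) {
      stop("n_exceptions must be 1 or 2")
    }
    wmap <- list(species = c(0.9, 0.8), garden = c(0.75, 0.5))
    for (i in seq_len(nrow(exceptions))) {
      e <- exceptions[i, ]
      j <- which(table$trait_id == e$trait_id & table$predictor == e$predictor)
      if (!length(j)) next
      verdict[j] <- "agree-with-exception"
      weight[j] <- wmap[[e$type]][e$n_exceptions]
    }
  }
  detail <- cbind(table[, c("trait_id", "predictor", "estimate", "p", "p_adj",
                            "tier")],
                  predicted = pred, verdict = verdict, weight = weight)
  n_traits <- length(unique(detail$trait_id))
  summ <- do.call(rbind, lapply(split(detail, detail$predictor), function(d) {
    sig <- d$p_adj < alpha
    data.frame(predictor = d$predictor[1],
               n_traits = n_traits,
               pct_agree = 100 * sum(d$weight) / n_traits,
               pct_significant_agree =
                 100 * sum(d$weight[sig & d$verdict != "disagree"]) / n_traits,
               n_significant_disagree = sum(sig & d$verdict == "disagree"),
               row.names = NULL)
  }))
  out <- list(detail = detail, summary = summ, alpha = alpha)
  class(out) <- "tally_report"
  out
}

#' @export
print.tally_report <- function(x, ...) {
  cat("Agreement with predicted trait directions\n")
  print(x$summary, digits = 3)
  invisible(x)
}
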