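Package: traitclines
Title: Trait-Environment Analysis Along Climatic Moisture Gradients in
    Common Gardens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how plant functional traits respond to
    climatic moisture supply (the precipitation to pan-evaporation ratio,
    P/Ep) when multiple species are grown together in common gardens along
    a climate gradient. Implements derivation of physiological and
    hydraulic traits from raw measurements (minimum epidermal conductance
    from leaf drying curves, leaf and stem hydraulic conductance,
    hydraulically weighted vessel diameter and Poiseuille theoretical
    conductivity, relative growth rates, allometric root-mass imputation,
    common-slope standardized ratios); phylogenetic generalized linear
    mixed models of trait means on log site and species P/Ep with four
    candidate random effects and AIC plus parsimony model choice;
    Benjamini-Yekutieli false-discovery-rate control and weighted
    agreement tallies against predicted trait directions; standardized
    principal components ordination with gradient projection, sector
    classification and reaction-norm slopes; and realized-growth
    (survival times growth) statistics with delta-method standard errors,
    within-site multiple comparisons, sigmoidal survival fits and
    adaptive cross-over detection. A synthetic-data generator reproduces
    the statistical structure of a ten-species, four-garden study so the
    full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
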