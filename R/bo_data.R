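# Packaged survey tables for the Bo City case study. These are the
# published per-section tables (survey populations, areas, measured and
# estimated densities) shipped as plain CSV; the satellite scene itself is
# not distributed, so the pixel-level stages are exercised on synthetic
# scenes instead.

bo_csv <- function(file) {
  utils::read.csv(system.file("extdata", file, package = "popdensat",
                              mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Bo City section survey table
#'
#' The 20 surveyed sections of Bo City (Sierra Leone, 2011) with surveyed
#' population, area in km^2, and measured population density
#' d = persons/km^2.
#'
#' @return Data frame `section, persons, area_km2, density`.
#' @export
bo_sections <- function() bo_csv("bo_sections.csv")

#' Published per-section density estimates for Bo City
#'
#' The published best-model estimates: measured density, estimated density
#' `density_hat`, estimated population `pop_hat`, and signed relative error
#' `re_pct`, for the standard g-prior analysis (`which = "bma"`) or the
#' empirical-Bayes-local variant (`which = "ebl"`).
#'
#' @param which `"bma"` or `"ebl"`.
#' @return Data frame with one row per section.
#' @export
bo_estimates <- function(which = c("bma", "ebl")) {
  which <- match.arg(which)
  bo_csv(paste0("bo_estimates_", which, ".csv"))
}

#' Published leave-one-out cross-validation records for Bo City
#'
#' The published LOOCV table (14 of the 20 folds were printed): per omitted
#' section, the observed density and its square root, the fold prediction
#' on the sqrt scale, the back-transformed density estimate, and signed
#' errors / percent relative errors on both scales.
#'
#' @return Data frame with one row per printed fold.
#' @export
bo_loocv_published <- function() bo_csv("bo_loocv.csv")
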