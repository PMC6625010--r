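# Error metrics, leave-one-out cross-validation, and the optional NDVI
# vegetation mask.

#' Relative (proportional) error in percent
#'
#' `RE = (estimate - truth) / truth x 100%`, signed; summaries are taken
#' over absolute values.
#'
#' @param estimate Estimated value(s).
#' @param truth Measured value(s), strictly positive.
#' @return Signed percentage(s).
#' @export
relative_error <- function(estimate, truth) {
  if (any(truth <= 0)) stop("truth must be strictly positive")
  (estimate - truth) / truth * 100
}

#' Per-section evaluation report
#'
#' Computes the signed relative error of each density estimate, absolute-RE
#' summaries (the median of an even count is the midpoint of the two
#' central values), and the total-population error when areas are given.
#'
#' @param density_hat Estimated densities.
#' @param density Measured densities.
#' @param area Optional section areas (km^2) for population totals.
#' @param section Optional section names.
#' @return List with `table` (per-section data frame), `median_abs_re`,
#'   `mean_abs_re`, and (given areas) `total_estimated`, `total_measured`,
#'   `total_error_pct`.
#' @export
evaluate_estimates <- function(density_hat, density, area = NULL,
                               section = NULL) {
  re <- relative_error(density_hat, density)
  tab <- data.frame(
    section = if (is.null(section)) seq_along(density) else section,
    density = density, density_hat = density_hat, re_pct = re,
    stringsAsFactors = FALSE)
  out <- list(table = tab,
              median_abs_re = stats::median(abs(re)),
              mean_abs_re = mean(abs(re)))
  if (!is.null(area)) {
    pops <- estimate_populations(density_hat, area)
    measured <- sum(density * area)
    out$total_estimated <- pops$total
    out$total_measured <- measured
    out$total_error_pct <- relative_error(pops$total, measured)
  }
  out
}

#' Leave-one-out cross-validation with a frozen covariate set
#'
#' For each fold, the model is refit by OLS on the remaining n - 1 sections
#' using the SAME covariate set (coefficients only are re-estimated), the
#' omitted section's transformed density is predicted and back-transformed,
#' and the signed error and relative error are recorded on both scales.
#' Setting `research = TRUE` instead re-runs the full MC3 search within
#' each fold and uses each fold's own top model (a stricter generalization
#' test than the frozen-set protocol).
#'
#' @param density Measured densities (strictly positive).
#' @param X Covariate table restricted to the selected model's covariates
#'   (or, with `research = TRUE`, the full candidate table).
#' @param section Optional section names.
#' @param transform Response transform (default `"sqrt"`).
#' @param research Re-run the model search in every fold?
#' @param ... With `research = TRUE`, arguments passed to [mc3_sample()].
#' @return List with `folds` (per-fold data frame: section, d, sqrt-scale
#'   observation/prediction, back-transformed estimate, signed errors and
#'   percent relative errors on both scales) and `summary` (median/mean of
#'   the absolute errors). Folds whose refit fails are flagged in
#'   `failed` and excluded from the summaries with a warning.
#' @export
loocv <- function(density, X, section = NULL,
                  transform = c("sqrt", "ln", "identity"),
                  research = FALSE, ...) {
  transform <- match.arg(transform)
  X <- as.data.frame(X)
  n <- length(density)
  if (!research && n < ncol(X) + 3L) stop("need n >= k + 3 observations")
  y <- transform_density(density, transform)
  sec <- if (is.null(section)) as.character(seq_len(n)) else section
  rows <- vector("list", n)
  failed <- character(0)
  for (j in seq_len(n)) {
    res <- tryCatch({
      Xj <- X[-j, , drop = FALSE]
      if (research) {
        led <- mc3_sample(y[-j], Xj, ...)
        Xj <- Xj[, led$models[[1L]], drop = FALSE]
      }
      fit <- ols_fit(y[-j], Xj)
      pred_t <- predict_density(fit, newdata = X[j, colnames(Xj),
                                                 drop = FALSE],
                                transform = transform)
      d_hat <- pred_t$density[1L]
      data.frame(
        section = sec[j], d = density[j],
        obs_t = y[j], pred_t = pred_t$fit_t[1L], d_hat = d_hat,
        er_t = pred_t$fit_t[1L] - y[j],
        pct_er_t = (pred_t$fit_t[1L] - y[j]) / y[j] * 100,
        er_d = d_hat - density[j],
        pct_re_d = relative_error(d_hat, density[j]),
        stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sec[j])
      rows[[j]] <- NULL
    } else {
      rows[[j]] <- res
    }
  }
  if (length(failed)) {
    warning("fold(s) failed and were excluded: ",
            paste(failed, collapse = ", "))
  }
  folds <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  summary <- data.frame(
    statistic = c("median_abs", "mean_abs"),
    er_t = c(stats::median(abs(folds$er_t)), mean(abs(folds$er_t))),
    pct_er_t = c(stats::median(abs(folds$pct_er_t)),
                 mean(abs(folds$pct_er_t))),
    er_d = c(stats::median(abs(folds$er_d)), mean(abs(folds$er_d))),
    pct_re_d = c(stats::median(abs(folds$pct_re_d)),
                 mean(abs(folds$pct_re_d))),
    stringsAsFactors = FALSE)
  list(folds = folds, summary = summary, failed = failed)
}

#' Mask out vegetated pixels by NDVI threshold
#'
#' Computes the per-pixel normalized difference vegetation index
#' `NDVI = (band4 - band3) / (band4 + band3)` and removes pixels with
#' `NDVI > threshold` from the section mask before covariate computation.
#' Zero-denominator pixels are retained (their NDVI is undefined, not
#' high).
#'
#' @param raster A [section_raster()] with bands 3 and 4.
#' @param threshold NDVI cutoff in \[-1, 1\]; vegetation has high positive
#'   NDVI.
#' @param recompute_area Recompute the pixel-count area from the surviving
#'   mask (attribute `area_km2`)?
#' @return The raster with the reduced mask (removed pixels set to `NA`),
#'   with attributes `n_excluded` and optionally `area_km2`.
#' @export
ndvi_mask <- function(raster, threshold, recompute_area = FALSE) {
  stopifnot(inherits(raster, "section_raster"))
  if (threshold < -1 || threshold > 1) stop("threshold must be in [-1, 1]")
  if (!all(c("3", "4") %in% names(raster$bands))) {
    stop("NDVI needs bands 3 and 4")
  }
  b3 <- raster$bands[["3"]]
  b4 <- raster$bands[["4"]]
  den <- b4 + b3
  ndvi <- ifelse(den == 0, NA_real_, (b4 - b3) / den)
  drop_px <- raster$mask & !is.na(ndvi) & ndvi > threshold
  new_mask <- raster$mask & !drop_px
  if (!any(new_mask)) stop("NDVI mask removed every pixel of ", raster$name)
  bands <- lapply(raster$bands, function(m) {
    m[!new_mask] <- NA_real_
    m
  })
  out <- section_raster(raster$name, bands, new_mask,
                        pixel_size_m = raster$pixel_size_m)
  attr(out, "n_excluded") <- sum(drop_px)
  if (recompute_area) {
    attr(out, "area_km2") <- area_from_pixel_count(sum(new_mask),
                                                   raster$pixel_size_m^2)
  }
  out
}
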