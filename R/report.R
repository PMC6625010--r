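# Figures and plot-data sidecars for a pipeline bundle: response-transform
# comparison, estimates vs measurements with intervals, and relative-error
# bar charts for the fit and the cross-validation.

#' Render report figures for a pipeline bundle
#'
#' Writes up to four PNG figures plus matching plot-data CSV sidecars to
#' `dir`:
#' * `transform_comparison`: back-transformed top-model estimates vs the
#'   measured density under the identity, log and square-root response
#'   transforms (the top model is refit by OLS under each transform);
#' * `estimates`: estimated vs measured density with back-transformed 95
#'   percent intervals, and estimated population vs measured population;
#' * `re_fit`: absolute relative error per section for the full fit;
#' * `re_loocv`: absolute relative error per LOOCV fold (skipped with a
#'   warning when the bundle has no LOOCV stage).
#'
#' @param bundle A bundle from [run_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
render_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  est <- bundle$estimates
  files <- character(0)
  save_plot <- function(p, stem) {
    f <- file.path(dir, paste0(stem, ".png"))
    grDevices::png(f, width = 1400, height = 900, res = 150)
    print(p)
    grDevices::dev.off()
    files <<- c(files, f)
  }
  save_csv <- function(df, stem) {
    f <- file.path(dir, paste0(stem, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }

  # transform comparison: refit the selected covariates under each transform
  top <- bundle$fit$covariates
  red_all <- bundle$covariates[, top, drop = FALSE]
  cmp <- do.call(rbind, lapply(c("identity", "ln", "sqrt"), function(tr) {
    yt <- transform_density(est$density, tr)
    ft <- ols_fit(yt, red_all)
    pr <- predict_density(ft, transform = tr)
    data.frame(transform = tr, section = est$section,
               density = est$density, density_hat = pr$density,
               stringsAsFactors = FALSE)
  }))
  save_csv(cmp, "transform_comparison")
  p1 <- ggplot2::ggplot(cmp, ggplot2::aes(x = density, y = density_hat)) +
    ggplot2::geom_abline(color = "darkgreen") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~transform) +
    ggplot2::labs(x = "measured density (persons/km^2)",
                  y = "back-transformed estimate",
                  title = "Response transform comparison")
  save_plot(p1, "transform_comparison")

  # estimates with intervals; populations
  save_csv(est, "estimates")
  p2 <- ggplot2::ggplot(est, ggplot2::aes(x = density, y = density_hat)) +
    ggplot2::geom_abline(color = "darkgreen") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = density_lwr,
                                        ymax = density_upr), width = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "measured density", y = "estimated density",
                  title = "Estimated vs measured density (95% intervals)")
  save_plot(p2, "estimates")

  re_fit <- data.frame(section = est$section, abs_re = abs(est$re_pct))
  save_csv(re_fit, "re_fit")
  p3 <- ggplot2::ggplot(re_fit,
                        ggplot2::aes(x = stats::reorder(section, abs_re),
                                     y = abs_re)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "|RE| (%)",
                  title = "Absolute relative error of the fit")
  save_plot(p3, "re_fit")

  if (is.null(bundle$loocv)) {
    warning("bundle has no LOOCV stage; cross-validation panel skipped")
  } else {
    lf <- bundle$loocv$folds
    re_cv <- data.frame(section = lf$section, abs_re = abs(lf$pct_re_d))
    save_csv(re_cv, "re_loocv")
    p4 <- ggplot2::ggplot(re_cv,
                          ggplot2::aes(x = stats::reorder(section, abs_re),
                                       y = abs_re)) +
      ggplot2::geom_col() +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "|RE| (%)",
                    title = "Absolute relative error, LOOCV")
    save_plot(p4, "re_loocv")
  }
  invisible(files)
}
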