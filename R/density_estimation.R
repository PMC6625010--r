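# OLS refit of the selected model on the transformed scale, back-transform
# to densities, and conversion to section population counts.

transform_density <- function(d, transform = c("sqrt", "ln", "identity")) {
  transform <- match.arg(transform)
  switch(transform, sqrt = sqrt(d), ln = log(d), identity = d)
}

#' Ordinary least squares fit of the selected model
#'
#' Classical OLS of the transformed density on the selected covariates,
#' with per-covariate variance inflation factors
#' `VIF_j = 1 / (1 - R^2_j)` (equivalently, the diagonal of the inverse
#' covariate correlation matrix).
#'
#' @param y Transformed response.
#' @param X Data frame or matrix of the selected covariates (named columns).
#' @return A `density_fit`: list with the underlying `lm` object, the
#'   coefficient table (estimate, SE, t, p), `vif`, `r_squared`,
#'   `adj_r_squared`, `df_residual` and `covariates`.
#' @export
ols_fit <- function(y, X) {
  X <- as.data.frame(X)
  n <- length(y)
  k <- ncol(X)
  if (n <= k + 1L) stop("need n > k + 1 observations")
  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < k + 1L) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, k + 1L)] - 1L]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  dat <- cbind(.y = y, X)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  vif <- if (k >= 2L) diag(solve(stats::cor(as.matrix(X))))
         else stats::setNames(1, colnames(X))
  structure(list(
    lm = fit,
    coefficients = sm$coefficients,
    vif = stats::setNames(as.numeric(vif), colnames(X)),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    df_residual = fit$df.residual,
    covariates = colnames(X)),
    class = "density_fit")
}

#' @export
print.density_fit <- function(x, ...) {
  cat("<density_fit> ", length(x$covariates), " covariates, R^2 = ",
      round(x$r_squared, 4), " (adj. ", round(x$adj_r_squared, 4),
      "), df = ", x$df_residual, "\n", sep = "")
  ct <- cbind(round(x$coefficients, 4),
              VIF = c(NA, round(x$vif, 2)))
  print(ct)
  invisible(x)
}

#' Back-transform predictions to the density scale
#'
#' Inverts the response transform endpoint-wise, with no smearing or bias
#' correction: squares for `sqrt` (negative predictions are clipped to 0
#' first, with a warning), exponentiates for `ln`, identity otherwise.
#'
#' @param x Numeric vector (or matrix of point estimate and interval
#'   endpoints) on the transformed scale.
#' @param transform `"sqrt"`, `"ln"` or `"identity"`.
#' @return `x` mapped to the density scale, same shape.
#' @export
back_transform <- function(x, transform = c("sqrt", "ln", "identity")) {
  transform <- match.arg(transform)
  switch(transform,
         sqrt = {
           if (any(x < 0, na.rm = TRUE)) {
             warning(sum(x < 0, na.rm = TRUE),
                     " negative transformed value(s) clipped to 0")
           }
           pmax(x, 0)^2
         },
         ln = exp(x),
         identity = x)
}

#' Predict densities (with intervals) from a fitted model
#'
#' Predicts on the transformed scale with 95 percent intervals
#' (confidence intervals for the mean response by default; prediction
#' intervals behind the `interval` flag) and back-transforms the estimate
#' and both endpoints.
#'
#' @param fit A [ols_fit()] result.
#' @param newdata Optional data frame of covariates; defaults to the
#'   training rows.
#' @param transform Response transform used for the fit.
#' @param interval `"confidence"` or `"prediction"`.
#' @param level Interval level (default 0.95).
#' @return Data frame with transformed-scale `fit_t, lwr_t, upr_t` and
#'   back-transformed `density, density_lwr, density_upr`.
#' @export
predict_density <- function(fit, newdata = NULL,
                            transform = c("sqrt", "ln", "identity"),
                            interval = c("confidence", "prediction"),
                            level = 0.95) {
  transform <- match.arg(transform)
  interval <- match.arg(interval)
  stopifnot(inherits(fit, "density_fit"))
  pr <- if (is.null(newdata)) {
    stats::predict(fit$lm, interval = interval, level = level)
  } else {
    stats::predict(fit$lm, newdata = as.data.frame(newdata),
                   interval = interval, level = level)
  }
  out <- data.frame(fit_t = pr[, "fit"], lwr_t = pr[, "lwr"],
                    upr_t = pr[, "upr"])
  out$density <- back_transform(out$fit_t, transform)
  out$density_lwr <- back_transform(out$lwr_t, transform)
  out$density_upr <- back_transform(out$upr_t, transform)
  out
}

#' Section populations from estimated densities
#'
#' `p_hat_i = area_i x d_hat_i`, with the scalar-product total.
#'
#' @param density Estimated densities (persons per km^2).
#' @param area Section areas in km^2 (all positive).
#' @return List with `population` (per-section, unrounded), `rounded`, and
#'   `total` (sum of the unrounded estimates).
#' @export
estimate_populations <- function(density, area) {
  if (length(density) != length(area)) stop("length mismatch")
  if (any(area <= 0)) stop("areas must be positive")
  p_hat <- area * density
  list(population = p_hat, rounded = round(p_hat), total = sum(p_hat))
}
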