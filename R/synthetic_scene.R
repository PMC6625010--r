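# Synthetic scene generator. Emulates ~20 irregular neighborhood masks over
# six correlated reflectance bands with spatially clustered "vegetation",
# "built" and "bare" cover classes, and population densities produced by a
# known sparse linear model on the sqrt(density) scale. The spatial
# clustering matters: the covariates that carry the density signal are
# texture (spatial-variation) statistics, which i.i.d. class labels would
# render uninformative.

#' Default spectral mixture for the three cover classes
#'
#' Vegetation is dark in the visible bands and bright in the near infrared
#' (band 4); built surfaces are brighter in the visible and shortwave
#' infrared (bands 5, 7); bare soil sits between them with a strong SWIR
#' response. Reflectance units, in (0, 1).
#'
#' @param band_cor Common between-band correlation of the within-class
#'   reflectance (default 0.6).
#' @return Named list of classes, each with `mean` and `sd` vectors over the
#'   six bands and the shared `cor`.
#' @export
default_band_mixture <- function(band_cor = 0.6) {
  bn <- as.character(tm_bands())
  mk <- function(mean, sd) {
    list(mean = stats::setNames(mean, bn), sd = stats::setNames(sd, bn),
         cor = band_cor)
  }
  list(
    vegetation = mk(c(0.045, 0.070, 0.050, 0.380, 0.200, 0.090),
                    rep(0.012, 6L)),
    built      = mk(c(0.115, 0.135, 0.155, 0.235, 0.270, 0.235),
                    rep(0.030, 6L)),
    bare       = mk(c(0.100, 0.130, 0.160, 0.260, 0.320, 0.280),
                    rep(0.020, 6L))
  )
}

#' Specification of a synthetic scene
#'
#' Collects every knob of the generator behind a single seeded
#' specification, so a scene is fully reproducible from its spec.
#'
#' @param n_sections Number of sections (>= 2).
#' @param band_ids Band labels; the engine expects `c(1,2,3,4,5,7)`.
#' @param pixel_size_m Pixel edge length in meters (default 30).
#' @param section_size_range `c(min, max)` in-mask pixel counts per section.
#' @param built_fraction_range `c(min, max)` fraction of built pixels.
#' @param band_mixture Per-class spectral mixture; see
#'   [default_band_mixture()].
#' @param noise_sd Additional i.i.d. reflectance noise SD.
#' @param spectral_jitter_sd SD of the per-section, per-class, per-band
#'   shift of the class mean reflectances. Real neighborhoods differ in
#'   roofing materials, soil moisture and vegetation condition band by
#'   band; without this heterogeneity every covariate would be driven by
#'   the single built-fraction factor and no sparse truth model would be
#'   identifiable among the candidates.
#' @param texture_jitter SD (log scale) of the per-section, per-band
#'   lognormal multiplier on the within-class reflectance spread; gives
#'   each section its own band-specific texture level.
#' @param truth_model List with `intercept`, named `coefficients` (valid
#'   covariate names), and `residual_sd` on the sqrt(density) scale.
#' @param seed RNG seed.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(n_sections = 20L,
                       band_ids = c(1, 2, 3, 4, 5, 7),
                       pixel_size_m = 30,
                       section_size_range = c(300L, 2600L),
                       built_fraction_range = c(0.15, 0.90),
                       band_mixture = default_band_mixture(),
                       noise_sd = 0.005,
                       spectral_jitter_sd = 0.03,
                       texture_jitter = 0.4,
                       truth_model = list(
                         intercept = -35,
                         coefficients = c(nb7 = 210, nb4s = 80),
                         residual_sd = 2),
                       seed = 1L) {
  if (n_sections < 2L) stop("n_sections must be >= 2")
  if (length(section_size_range) != 2L || any(section_size_range < 4L) ||
      section_size_range[1L] > section_size_range[2L]) {
    stop("section_size_range must be c(min, max) with min >= 4")
  }
  if (any(built_fraction_range < 0) || any(built_fraction_range > 1) ||
      built_fraction_range[1L] > built_fraction_range[2L]) {
    stop("built_fraction_range must be an ordered pair in [0, 1]")
  }
  for (cl in band_mixture) {
    if (any(cl$mean <= 0) || any(cl$mean >= 1)) {
      stop("class mean reflectances must lie in (0, 1)")
    }
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (spectral_jitter_sd < 0 || texture_jitter < 0) {
    stop("spectral_jitter_sd and texture_jitter must be >= 0")
  }
  if (is.null(truth_model$residual_sd) || truth_model$residual_sd < 0) {
    stop("truth_model$residual_sd must be >= 0")
  }
  if (pixel_size_m <= 0) stop("pixel_size_m must be positive")
  structure(
    list(n_sections = as.integer(n_sections),
         band_ids = band_ids,
         pixel_size_m = pixel_size_m,
         section_size_range = as.integer(round(section_size_range)),
         built_fraction_range = built_fraction_range,
         band_mixture = band_mixture,
         noise_sd = noise_sd,
         spectral_jitter_sd = spectral_jitter_sd,
         texture_jitter = texture_jitter,
         truth_model = truth_model,
         seed = as.integer(seed)),
    class = "scene_spec")
}

# Separable Gaussian smoothing of a matrix; used to build spatially
# correlated random fields (banded weight-matrix multiplication, edges
# renormalized by construction).
smooth_matrix <- function(m, sigma) {
  band_weights <- function(n) {
    r <- max(1L, ceiling(3 * sigma))
    w <- stats::dnorm(seq(-r, r), sd = sigma)
    W <- matrix(0, n, n)
    for (d in seq(-r, r)) {
      idx <- seq_len(n - abs(d))
      if (d >= 0) W[cbind(idx, idx + d)] <- w[d + r + 1L]
      else W[cbind(idx - d, idx)] <- w[-d + r + 1L]
    }
    sweep(W, 1L, rowSums(W), "/")
  }
  Wr <- band_weights(nrow(m))
  Wc <- band_weights(ncol(m))
  Wr %*% m %*% t(Wc)
}

# Smoothed standard-normal-ish random field on an n x n grid.
random_field <- function(n, sigma) {
  f <- smooth_matrix(matrix(stats::rnorm(n * n), n, n), sigma)
  (f - mean(f)) / stats::sd(f)
}

# Draw rows from N(mean, Sigma) where Sigma has common correlation rho
# between bands; via Cholesky of the correlation matrix.
draw_class_spectra <- function(n, mix_class) {
  p <- length(mix_class$mean)
  R <- matrix(mix_class$cor, p, p)
  diag(R) <- 1
  L <- chol(R)
  z <- matrix(stats::rnorm(n * p), n, p) %*% L
  sweep(sweep(z, 2L, mix_class$sd, "*"), 2L, mix_class$mean, "+")
}

# One irregular section mask of exactly np pixels: top-np pixels of a
# smoothed field plus a radial bias toward the grid center, which yields a
# compact blob with a ragged boundary.
section_mask <- function(np) {
  n <- max(8L, ceiling(sqrt(np * 2)))
  f <- random_field(n, sigma = n / 10)
  ctr <- (n + 1) / 2
  dist <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  score <- f - 1.5 * dist / max(dist)
  thr <- sort(score, decreasing = TRUE)[np]
  score >= thr
}

#' Generate a synthetic scene of section rasters
#'
#' Each section gets an irregular mask with a pixel count drawn from
#' `section_size_range`, a spatially clustered partition into vegetation /
#' built / bare cover (built fraction drawn from `built_fraction_range`;
#' 15 percent of the built area is bare ground), and per-class correlated
#' reflectance spectra plus i.i.d. sensor noise, clamped to (0, 1).
#' Populations are left at 0; [generate_truth()] fills them in.
#'
#' @param spec A [scene_spec()].
#' @return List with `rasters` (list of [section_raster()]) and `sections`
#'   (data frame `section, persons, area_km2, density`; `persons` all 0 and
#'   `density` `NA` until [generate_truth()]).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  bn <- as.character(spec$band_ids)
  rasters <- vector("list", spec$n_sections)
  for (s in seq_len(spec$n_sections)) {
    np <- sample(seq(spec$section_size_range[1L], spec$section_size_range[2L]),
                 1L)
    mask <- section_mask(np)
    n <- nrow(mask)
    # spatially clustered class labels from a second smoothed field
    f_built <- spec$built_fraction_range[1L] +
      stats::runif(1) * diff(spec$built_fraction_range)
    g <- random_field(n, sigma = n / 8)
    gv <- g[mask]
    cls <- rep("vegetation", np)
    if (f_built > 0) {
      q_built <- stats::quantile(gv, 1 - f_built, type = 7)
      built_all <- gv >= q_built
      cls[built_all] <- "built"
      if (any(built_all)) {
        h <- random_field(n, sigma = n / 8)[mask]
        hb <- h[built_all]
        cls[built_all][hb >= stats::quantile(hb, 0.85, type = 7)] <- "bare"
      }
    }
    # per-section spectral heterogeneity: each section shifts its class
    # mean spectra and scales its within-class spread, band by band
    px <- matrix(NA_real_, np, length(bn))
    tex <- exp(stats::rnorm(length(bn), sd = spec$texture_jitter))
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      mix <- spec$band_mixture[[cl]]
      mix$mean <- pmin(pmax(
        mix$mean + stats::rnorm(length(bn), sd = spec$spectral_jitter_sd),
        0.01), 0.99)
      mix$sd <- mix$sd * tex
      px[idx, ] <- draw_class_spectra(length(idx), mix)
    }
    px <- px + matrix(stats::rnorm(np * length(bn), sd = spec$noise_sd),
                      np, length(bn))
    px <- pmin(pmax(px, 1e-4), 1 - 1e-4)
    bands <- stats::setNames(lapply(seq_along(bn), function(q) {
      m <- matrix(NA_real_, n, n)
      m[mask] <- px[, q]
      m
    }), bn)
    rasters[[s]] <- section_raster(sprintf("section_%02d", s), bands, mask,
                                   pixel_size_m = spec$pixel_size_m)
  }
  sections <- data.frame(
    section = vapply(rasters, function(r) r$name, character(1)),
    persons = 0,
    area_km2 = vapply(rasters, function(r) {
      area_from_pixel_count(pixel_count(r), spec$pixel_size_m^2)
    }, numeric(1)),
    density = NA_real_,
    stringsAsFactors = FALSE)
  list(rasters = rasters, sections = sections)
}

#' Attach ground-truth populations generated by a sparse linear model
#'
#' Computes the named truth covariates on each raster and draws
#' `sqrt(d) = intercept + sum(coef * covariate) + N(0, residual_sd)`.
#' Non-positive draws of `sqrt(d)` are redrawn (densities are strictly
#' positive); the redraw count is reported in a warning. The section table
#' gets `density = d` (the exact generated density, kept unrounded so the
#' generating model is identifiable downstream) and
#' `persons = round(d * area)`.
#'
#' @param rasters List of [section_raster()].
#' @param truth_model List with `intercept` and named `coefficients`.
#' @param residual_sd Residual SD on the sqrt(density) scale.
#' @param seed RNG seed.
#' @return Section table data frame with `section, persons, area_km2,
#'   density`, plus attribute `truth` recording the model and the noiseless
#'   linear predictor.
#' @export
generate_truth <- function(rasters, truth_model, residual_sd, seed = 1L) {
  valid <- covariate_names("all")$name
  cn <- names(truth_model$coefficients)
  bad <- setdiff(cn, valid)
  if (length(bad)) {
    stop("unknown covariate name(s) in truth model: ",
         paste(bad, collapse = ", "),
         ". Valid names are those of covariate_names().")
  }
  tab <- build_covariate_table(rasters, subset = "all")
  X <- as.matrix(tab[, cn, drop = FALSE])
  eta <- truth_model$intercept + drop(X %*% truth_model$coefficients)
  set.seed(seed)
  sqrt_d <- eta + stats::rnorm(length(eta), sd = residual_sd)
  n_redraw <- 0L
  for (i in seq_along(sqrt_d)) {
    tries <- 0L
    while (sqrt_d[i] <= 0) {
      sqrt_d[i] <- eta[i] + stats::rnorm(1L, sd = residual_sd)
      n_redraw <- n_redraw + 1L
      tries <- tries + 1L
      if (tries > 1000L) stop("cannot draw a positive sqrt(density) for ",
                              rasters[[i]]$name)
    }
  }
  if (n_redraw > 0L) {
    warning(n_redraw, " non-positive sqrt(density) draw(s) redrawn")
  }
  d <- sqrt_d^2
  area <- vapply(rasters, function(r) {
    area_from_pixel_count(pixel_count(r), r$pixel_size_m^2)
  }, numeric(1))
  out <- data.frame(
    section = vapply(rasters, function(r) r$name, character(1)),
    persons = round(d * area),
    area_km2 = area,
    density = d,
    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(model = truth_model, linear_predictor = eta,
                             sqrt_density = sqrt_d)
  out
}
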