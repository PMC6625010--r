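# Covariate engine: the 379 candidate covariates per section.
#
# Two blocks, following the standard taxonomy for thematic-mapper density
# covariates:
#   * non-spectral transforms (75): per-band pixel moments of the raw
#     reflectance (b, bs, bv, bc), plus squares, cross products, ratios and
#     difference-to-sum ratios of the six band MEANS;
#   * spectral (pixel-level) transforms (304): moments of the min-max
#     normalized bands (nb...), and the four moments of per-pixel band
#     ratios (r_sp..), difference-to-sum ratios (ds..), and cylindrical /
#     rectangular hue transforms over band triples (ch.., rh..).
# Band 6 (thermal) is never used; bands are 1,2,3,4,5,7.

tm_bands <- function() c(1L, 2L, 3L, 4L, 5L, 7L)

tm_band_pairs <- function() {
  b <- tm_bands()
  cmb <- utils::combn(b, 2L)
  data.frame(i = cmb[1L, ], j = cmb[2L, ])
}

tm_band_triples <- function() {
  b <- tm_bands()
  cmb <- utils::combn(b, 3L)
  data.frame(i = cmb[1L, ], j = cmb[2L, ], k = cmb[3L, ])
}

# Sample (n-1) denominators for sd/variance throughout the covariate engine.
# A single constant governs the convention.
COV_SD_SAMPLE <- TRUE

#' Catalogue of candidate covariate names
#'
#' Returns the stable column order and metadata for the candidate covariate
#' table: 379 columns in total, of which 304 are spectral (pixel-level)
#' transforms and 75 are non-spectral transforms of the band means.
#'
#' @param subset One of `"all"`, `"spectral"`, `"nonspectral"`.
#' @return Data frame with columns `name`, `family`, `bands` (label such as
#'   `"3"`, `"37"`, `"245"`), and `spectral` (logical).
#' @export
covariate_names <- function(subset = c("all", "spectral", "nonspectral")) {
  subset <- match.arg(subset)
  b <- tm_bands()
  pr <- tm_band_pairs()
  tr <- tm_band_triples()
  pair_lab <- paste0(pr$i, pr$j)
  trip_lab <- paste0(tr$i, tr$j, tr$k)
  sfx <- c("", "s", "v", "c")
  fam_sfx <- function(fam) paste0(fam, c("", "s", "v", "c"))

  rows <- list()
  add <- function(names, family, bands, spectral) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = names, family = family, bands = bands, spectral = spectral,
      stringsAsFactors = FALSE)
  }
  # Non-spectral block (75)
  for (m in seq_along(sfx)) {
    add(paste0("b", b, sfx[m]), fam_sfx("B")[m], as.character(b), FALSE)
  }
  add(paste0("s", b), "S", as.character(b), FALSE)
  add(paste0("p", pair_lab), "P", pair_lab, FALSE)
  add(paste0("r.re", pair_lab), "R.re", pair_lab, FALSE)
  add(paste0("d", pair_lab), "D", pair_lab, FALSE)
  # Spectral block (304)
  for (m in seq_along(sfx)) {
    add(paste0("nb", b, sfx[m]), fam_sfx("NB")[m], as.character(b), TRUE)
  }
  for (m in seq_along(sfx)) {
    add(paste0("r_sp", pair_lab, sfx[m]), fam_sfx("R")[m], pair_lab, TRUE)
  }
  for (m in seq_along(sfx)) {
    add(paste0("ds", pair_lab, sfx[m]), fam_sfx("DS")[m], pair_lab, TRUE)
  }
  for (m in seq_along(sfx)) {
    add(paste0("ch", trip_lab, sfx[m]), fam_sfx("CH")[m], trip_lab, TRUE)
  }
  for (m in seq_along(sfx)) {
    add(paste0("rh", trip_lab, sfx[m]), fam_sfx("RH")[m], trip_lab, TRUE)
  }
  out <- do.call(rbind, rows)
  switch(subset,
         all = out,
         spectral = out[out$spectral, , drop = FALSE],
         nonspectral = out[!out$spectral, , drop = FALSE])
}

#' Section area from its pixel count
#'
#' Area_i = NP_i x PA x 1e-6 km^2, where NP_i is the number of in-section
#' pixels and PA the pixel area in square meters (900 for 30 m pixels).
#'
#' @param np Non-negative pixel count.
#' @param pixel_area_m2 Pixel area in m^2 (default 900).
#' @return Area in km^2.
#' @export
area_from_pixel_count <- function(np, pixel_area_m2 = 900) {
  if (any(np < 0)) stop("pixel count must be non-negative")
  if (pixel_area_m2 <= 0) stop("pixel area must be positive")
  np * pixel_area_m2 * 1e-6
}

#' Min-max normalization of a pixel vector
#'
#' Rescales values to \[0, 1\] as (x - min)/(max - min). The range defaults to
#' the vector's own (per-section scope); supplying `range` normalizes against
#' a global (scene-wide) range instead. A constant input maps to all zeros
#' with a warning.
#'
#' @param x Numeric vector with at least one finite value.
#' @param range Optional length-2 numeric `c(min, max)` defining the scope.
#' @return Normalized vector.
#' @export
minmax_normalize <- function(x, range = NULL) {
  if (length(x) == 0L || !any(is.finite(x))) {
    stop("minmax_normalize() needs at least one finite value")
  }
  if (is.null(range)) range <- base::range(x, finite = TRUE)
  lo <- range[1L]
  hi <- range[2L]
  if (hi == lo) {
    warning("constant input in min-max normalization; returning zeros")
    return(rep(0, length(x)))
  }
  (x - lo) / (hi - lo)
}

# Four moments of a pixel-level quantity: mean, sd, variance, cv = sd/mean.
# A zero mean makes the cv undefined; it is flagged as NA (never Inf).
stat4 <- function(x, prefix = "") {
  m <- mean(x)
  if (length(x) >= 2L) {
    v <- stats::var(x)
    if (!COV_SD_SAMPLE) v <- v * (length(x) - 1) / length(x)
    s <- sqrt(v)
  } else {
    v <- 0
    s <- 0
  }
  cv <- if (m == 0) {
    warning("zero mean: coefficient of variation flagged as missing")
    NA_real_
  } else {
    s / m
  }
  stats::setNames(c(m, s, v, cv), paste0(prefix, c("", "s", "v", "c")))
}

#' Per-band moment statistics of a section raster
#'
#' Mean, standard deviation, variance and coefficient of variation of the
#' in-mask pixel values of one band, optionally after min-max normalization.
#' Sample (n-1) denominators are used for the sd and variance.
#'
#' @param raster A [section_raster()].
#' @param band Band label (one of 1,2,3,4,5,7).
#' @param normalized Normalize first with [minmax_normalize()]?
#' @param range Optional global normalization range (see [minmax_normalize()]).
#' @return Named numeric vector `(mean, sd, var, cv)` named with the
#'   band-statistic convention (`b3`, `b3s`, `b3v`, `b3c` or `nb3`, ...).
#' @export
band_statistics <- function(raster, band, normalized = FALSE, range = NULL) {
  x <- band_pixels(raster, band)
  if (normalized) x <- minmax_normalize(x, range = range)
  stat4(x, prefix = paste0(if (normalized) "nb" else "b", band))
}

#' Non-spectral covariates from the six band means
#'
#' Given the per-band raw moments, returns the 75 non-spectral covariates:
#' the 24 band moments themselves, the 6 squares `s_i = b_i^2`, and over the
#' 15 band pairs (i < j) the cross products `p_ij = b_i b_j`, ratios
#' `r.re_ij = b_i / b_j`, and difference-to-sum ratios
#' `d_ij = (b_i - b_j)/(b_i + b_j)`.
#'
#' @param band_stats Named numeric vector containing `b{i}`, `b{i}s`,
#'   `b{i}v`, `b{i}c` for every band, e.g. the concatenation of
#'   [band_statistics()] over the six bands.
#' @return Named numeric vector of 75 covariates in stable column order.
#' @export
nonspectral_covariates <- function(band_stats) {
  b <- tm_bands()
  need <- as.vector(outer(paste0("b", b), c("", "s", "v", "c"), paste0))
  miss <- setdiff(need, names(band_stats))
  if (length(miss)) stop("missing band statistics: ", paste(miss, collapse = ", "))
  means <- band_stats[paste0("b", b)]
  pr <- tm_band_pairs()
  lab <- paste0(pr$i, pr$j)
  bi <- means[paste0("b", pr$i)]
  bj <- means[paste0("b", pr$j)]
  ratio <- ifelse(bj == 0, NA_real_, bi / bj)
  dsum <- ifelse(bi + bj == 0, NA_real_, (bi - bj) / (bi + bj))
  if (any(bj == 0) || any(bi + bj == 0)) {
    warning("zero denominator in non-spectral ratio; flagged as missing")
  }
  out <- c(
    band_stats[need],
    stats::setNames(means^2, paste0("s", b)),
    stats::setNames(as.numeric(bi * bj), paste0("p", lab)),
    stats::setNames(as.numeric(ratio), paste0("r.re", lab)),
    stats::setNames(as.numeric(dsum), paste0("d", lab))
  )
  out
}

#' Moments of per-pixel two-band transforms (ratio / difference-to-sum)
#'
#' Computes per in-mask pixel either the band ratio `b_i(n)/b_j(n)` or the
#' difference-to-sum ratio `(b_i(n)-b_j(n))/(b_i(n)+b_j(n))`, then its four
#' moments. The difference-to-sum of bands 4 and 3 is the per-pixel NDVI.
#' Pixels with a zero denominator are excluded from the statistics; the
#' exclusion count is attached as attribute `n_excluded`.
#'
#' @param raster A [section_raster()].
#' @param i,j Distinct band labels.
#' @param kind `"ratio"` or `"diffsum"`.
#' @return Named `(mean, sd, var, cv)` vector (`r_sp{ij}`/`ds{ij}` naming)
#'   with attribute `n_excluded`.
#' @export
pixel_pair_transform <- function(raster, i, j, kind = c("ratio", "diffsum")) {
  kind <- match.arg(kind)
  if (as.character(i) == as.character(j)) stop("bands i and j must differ")
  xi <- band_pixels(raster, i)
  xj <- band_pixels(raster, j)
  den <- if (kind == "ratio") xj else xi + xj
  ok <- den != 0
  t_n <- if (kind == "ratio") xi[ok] / xj[ok] else (xi[ok] - xj[ok]) / den[ok]
  n_excl <- sum(!ok)
  prefix <- paste0(if (kind == "ratio") "r_sp" else "ds", i, j)
  if (length(t_n) == 0L) {
    warning("all pixels excluded (zero denominators) for ", prefix)
    out <- stats::setNames(rep(NA_real_, 4L),
                           paste0(prefix, c("", "s", "v", "c")))
  } else {
    out <- stat4(t_n, prefix = prefix)
  }
  attr(out, "n_excluded") <- n_excl
  out
}

# Default per-pixel hue formulas over an (R, G, B) assignment of the band
# triple (i, j, k) -> (R, G, B). Both are pluggable in build_covariate_table().
hue_cylindrical <- function(R, G, B) {
  h <- atan2(sqrt(3) * (G - B), 2 * R - G - B)
  h %% (2 * pi)
}

hue_rectangular <- function(R, G, B) {
  (2 * R - G - B) / (2 * (R + G + B))
}

#' Moments of per-pixel hue transforms over a band triple
#'
#' Maps the ordered band triple (i, j, k) onto (R, G, B) and computes a
#' per-pixel hue scalar: cylindrical hue `atan2(sqrt(3)(G-B), 2R-G-B)`
#' wrapped to \[0, 2*pi), or rectangular hue `(2R-G-B)/(2(R+G+B))`.
#' Achromatic pixels (R = G = B) have undefined hue and are excluded (the
#' count is attached as `n_excluded`), as are zero-intensity pixels for the
#' rectangular kind. Moments are linear (not circular).
#'
#' @param raster A [section_raster()].
#' @param i,j,k Distinct band labels, ordered i < j < k.
#' @param kind `"cylindrical"` or `"rectangular"`.
#' @param hue_fun Optional replacement per-pixel formula `function(R, G, B)`.
#' @return Named `(mean, sd, var, cv)` vector (`ch{ijk}`/`rh{ijk}` naming)
#'   with attribute `n_excluded`.
#' @export
hue_transform <- function(raster, i, j, k,
                          kind = c("cylindrical", "rectangular"),
                          hue_fun = NULL) {
  kind <- match.arg(kind)
  if (anyDuplicated(c(i, j, k))) stop("bands i, j, k must be distinct")
  R <- band_pixels(raster, i)
  G <- band_pixels(raster, j)
  B <- band_pixels(raster, k)
  ok <- !(R == G & G == B)
  if (kind == "rectangular") ok <- ok & (R + G + B != 0)
  f <- if (!is.null(hue_fun)) hue_fun
       else if (kind == "cylindrical") hue_cylindrical else hue_rectangular
  h <- f(R[ok], G[ok], B[ok])
  prefix <- paste0(if (kind == "cylindrical") "ch" else "rh", i, j, k)
  if (length(h) == 0L) {
    warning("all pixels achromatic/degenerate for ", prefix,
            "; flagged as missing")
    out <- stats::setNames(rep(NA_real_, 4L),
                           paste0(prefix, c("", "s", "v", "c")))
  } else {
    out <- stat4(h, prefix = prefix)
  }
  attr(out, "n_excluded") <- sum(!ok)
  out
}

# All covariates for one section (internal).
section_covariates <- function(raster, norm_ranges = NULL, spectral_only = FALSE,
                               hue_funs = NULL) {
  b <- tm_bands()
  miss <- setdiff(as.character(b), names(raster$bands))
  if (length(miss)) {
    stop("raster ", raster$name, " is missing band(s): ",
         paste(miss, collapse = ", "))
  }
  pr <- tm_band_pairs()
  tr <- tm_band_triples()
  vals <- list()
  if (!spectral_only) {
    raw <- unlist(lapply(b, function(bi) band_statistics(raster, bi)))
    vals$nonspectral <- nonspectral_covariates(raw)
  }
  vals$normband <- unlist(lapply(b, function(bi) {
    band_statistics(raster, bi, normalized = TRUE,
                    range = norm_ranges[[as.character(bi)]])
  }))
  vals$r <- unlist(lapply(seq_len(nrow(pr)), function(q) {
    pixel_pair_transform(raster, pr$i[q], pr$j[q], "ratio")
  }))
  vals$ds <- unlist(lapply(seq_len(nrow(pr)), function(q) {
    pixel_pair_transform(raster, pr$i[q], pr$j[q], "diffsum")
  }))
  vals$ch <- unlist(lapply(seq_len(nrow(tr)), function(q) {
    hue_transform(raster, tr$i[q], tr$j[q], tr$k[q], "cylindrical",
                  hue_fun = hue_funs$cylindrical)
  }))
  vals$rh <- unlist(lapply(seq_len(nrow(tr)), function(q) {
    hue_transform(raster, tr$i[q], tr$j[q], tr$k[q], "rectangular",
                  hue_fun = hue_funs$rectangular)
  }))
  # c() over the groups keeps the inner names untouched (some contain dots).
  do.call(c, unname(vals))
}

#' Build the section-by-covariate candidate table
#'
#' One row per section, one column per candidate covariate in the stable
#' order of [covariate_names()]: 379 columns for `subset = "all"`, 304 for
#' `"spectral"`, 75 for `"nonspectral"`.
#'
#' @param rasters List of [section_raster()] objects sharing the six bands.
#' @param subset Covariate subset flag.
#' @param norm_scope `"section"` (min-max range per section, the default) or
#'   `"global"` (range over the union of all sections' pixels, per band).
#' @param hue_funs Optional list with elements `cylindrical` and/or
#'   `rectangular`: replacement per-pixel hue formulas `function(R, G, B)`.
#' @return Data frame (sections x covariates) with section names as row
#'   names and a `metadata` attribute (the matching [covariate_names()]
#'   rows).
#' @export
build_covariate_table <- function(rasters,
                                  subset = c("all", "spectral", "nonspectral"),
                                  norm_scope = c("section", "global"),
                                  hue_funs = NULL) {
  subset <- match.arg(subset)
  norm_scope <- match.arg(norm_scope)
  if (length(rasters) < 1L) stop("need at least one section raster")
  norm_ranges <- NULL
  if (norm_scope == "global") {
    norm_ranges <- lapply(stats::setNames(nm = as.character(tm_bands())),
                          function(b) {
      range(unlist(lapply(rasters, band_pixels, band = b)), finite = TRUE)
    })
  }
  meta <- covariate_names(subset)
  rows <- lapply(rasters, function(r) {
    v <- section_covariates(r, norm_ranges = norm_ranges,
                            spectral_only = (subset == "spectral"),
                            hue_funs = hue_funs)
    v[meta$name]
  })
  tab <- as.data.frame(do.call(rbind, rows))
  colnames(tab) <- meta$name
  rownames(tab) <- vapply(rasters, function(r) r$name, character(1))
  attr(tab, "metadata") <- meta
  tab
}
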