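# Covariate engine: catalogue identities, arithmetic anchors, and agreement
# with independent brute-force pixel loops.

test_that("covariate catalogue has the family-count identities", {
  all_ <- covariate_names("all")
  sp <- covariate_names("spectral")
  ns <- covariate_names("nonspectral")
  expect_equal(nrow(all_), 379)
  expect_equal(nrow(sp), 304)
  expect_equal(nrow(ns), 75)
  # 75 = 6*5 + 15*3 ; 304 = 6*4 + 15*8 + 20*8
  expect_equal(sum(ns$family %in% c("B", "Bs", "Bv", "Bc", "S")), 6 * 5)
  expect_equal(sum(ns$family %in% c("P", "R.re", "D")), 15 * 3)
  fam_counts <- table(all_$family)
  for (f in c("P", "R.re", "D", "R", "Rs", "Rv", "Rc",
              "DS", "DSs", "DSv", "DSc")) {
    expect_equal(unname(fam_counts[f]), 15)  # C(6,2) pairs
  }
  for (f in c("CH", "CHs", "CHv", "CHc", "RH", "RHs", "RHv", "RHc")) {
    expect_equal(unname(fam_counts[f]), 20)  # C(6,3) triples
  }
  expect_false(anyDuplicated(all_$name) > 0)
  # names used by the published selected models exist
  expect_true(all(c("nb7v", "r_sp37", "nb1v", "r_sp15s", "ch245c", "r_sp14c",
                    "nb3s", "nb7c", "ds15s", "ds35c", "ch127", "ch357") %in%
                    all_$name))
})

test_that("pixel-count area follows the 900 m^2 pixel formula", {
  expect_equal(round(area_from_pixel_count(670), 2), 0.60)
  expect_equal(area_from_pixel_count(670), 0.603)
  expect_equal(area_from_pixel_count(559), 0.5031)
  expect_equal(area_from_pixel_count(0), 0)
  expect_equal(area_from_pixel_count(100, pixel_area_m2 = 100), 0.01)
  expect_error(area_from_pixel_count(-1), "non-negative")
})

test_that("min-max normalization is the affine map with degenerate guard", {
  expect_equal(minmax_normalize(c(0.2, 0.4, 0.6)), c(0, 0.5, 1))
  expect_warning(z <- minmax_normalize(rep(0.3, 5)), "constant")
  expect_equal(z, rep(0, 5))
  expect_error(minmax_normalize(numeric(0)), "finite")
  # global scope: external range
  expect_equal(minmax_normalize(c(0.2, 0.4), range = c(0, 0.8)),
               c(0.25, 0.5))
})

test_that("band statistics match hand arithmetic and the pixel-loop oracle", {
  # two-pixel hand case: mean .5, sample variance .5
  r2 <- section_raster("two", list(`1` = matrix(c(0, 1, NA, NA), 2),
                                   `2` = matrix(c(3, 3, NA, NA), 2),
                                   `3` = matrix(c(1, 2, NA, NA), 2),
                                   `4` = matrix(c(1, 3, NA, NA), 2),
                                   `5` = matrix(c(2, 2, NA, NA), 2),
                                   `7` = matrix(c(0, 4, NA, NA), 2)),
                       matrix(c(TRUE, TRUE, FALSE, FALSE), 2))
  s <- band_statistics(r2, 1)
  expect_equal(unname(s), c(0.5, sqrt(0.5), 0.5, sqrt(0.5) / 0.5))
  # constant band: (v, 0, 0, 0)
  s2 <- band_statistics(r2, 2)
  expect_equal(unname(s2), c(3, 0, 0, 0))
  # oracle agreement on the deterministic fixture, raw and normalized
  r <- make_test_raster()
  for (b in c(1, 3, 7)) {
    px <- oracle_band_pixels(r, b)
    expect_equal(unname(band_statistics(r, b)), unname(oracle_stat4(px)),
                 tolerance = 1e-12)
    expect_equal(unname(band_statistics(r, b, normalized = TRUE)),
                 unname(oracle_stat4(oracle_minmax(px))),
                 tolerance = 1e-12)
  }
})

test_that("non-spectral covariates follow their defining arithmetic", {
  r <- make_test_raster()
  raw <- unlist(lapply(c(1, 2, 3, 4, 5, 7),
                       function(b) band_statistics(r, b)))
  ns <- nonspectral_covariates(raw)
  expect_length(ns, 75)
  b1 <- raw[["b1"]]; b2 <- raw[["b2"]]
  expect_equal(ns[["s1"]], b1^2)
  expect_equal(ns[["p12"]], b1 * b2)
  expect_equal(ns[["r.re12"]], b1 / b2)
  expect_equal(ns[["d12"]], (b1 - b2) / (b1 + b2))
  # hand case via equal means: every d = 0 and every ratio = 1
  eq <- stats::setNames(rep(c(0.3, 0.1, 0.01, 0.2), each = 6),
                        as.vector(outer(paste0("b", c(1, 2, 3, 4, 5, 7)),
                                        c("", "s", "v", "c"), paste0)))
  nse <- nonspectral_covariates(eq)
  expect_equal(unname(nse[paste0("d", c(12, 34, 57))]), rep(0, 3))
  expect_equal(unname(nse[paste0("r.re", c(12, 34, 57))]), rep(1, 3))
  # hand numbers: b = (0.1, 0.3) for bands 1, 2
  h <- eq
  h[["b1"]] <- 0.1; h[["b2"]] <- 0.3
  nh <- nonspectral_covariates(h)
  expect_equal(nh[["p12"]], 0.03)
  expect_equal(nh[["d12"]], -0.5)
})

test_that("pixel pair transforms match the oracle; diffsum(4,3) is NDVI", {
  r <- make_test_raster()
  b3 <- oracle_band_pixels(r, 3)
  b4 <- oracle_band_pixels(r, 4)
  ds <- pixel_pair_transform(r, 3, 4, "diffsum")
  expect_equal(unname(ds), unname(oracle_stat4((b3 - b4) / (b3 + b4))),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(ds, "n_excluded"), 0L)
  rt <- pixel_pair_transform(r, 3, 4, "ratio")
  expect_equal(unname(rt), unname(oracle_stat4(b3 / b4)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # NDVI = diffsum of (band4, band3)
  ndvi <- (b4 - b3) / (b4 + b3)
  expect_equal(unname(pixel_pair_transform(r, 4, 3, "diffsum")["ds43"]),
               mean(ndvi), tolerance = 1e-12)
  # identical bands: diffsum (0, 0), ratio (1, 0)
  same <- section_raster("same",
                         stats::setNames(rep(list(matrix(0.4, 3, 3)), 6),
                                         c("1", "2", "3", "4", "5", "7")),
                         matrix(TRUE, 3, 3))
  d0 <- pixel_pair_transform(same, 1, 2, "diffsum")
  expect_equal(unname(d0[1:3]), c(0, 0, 0))
  r1 <- pixel_pair_transform(same, 1, 2, "ratio")
  expect_equal(unname(r1[1:2]), c(1, 0))
})

test_that("hue transforms: convention anchor, exclusions, oracle agreement", {
  # single red pixel (R,G,B) = (1, 0, 0) -> cylindrical hue 0; need >= 1 px
  red1 <- section_raster("red",
                         list(`1` = matrix(1, 1), `2` = matrix(1e-8, 1),
                              `3` = matrix(1e-8, 1), `4` = matrix(0.5, 1),
                              `5` = matrix(0.5, 1), `7` = matrix(0.5, 1)),
                         matrix(TRUE, 1, 1))
  h <- hue_transform(red1, 1, 2, 3, "cylindrical")
  expect_equal(unname(h[["ch123"]]), 0, tolerance = 1e-7)
  # achromatic raster: flagged missing with warning
  same <- section_raster("same",
                         stats::setNames(rep(list(matrix(0.4, 2, 2)), 6),
                                         c("1", "2", "3", "4", "5", "7")),
                         matrix(TRUE, 2, 2))
  expect_warning(ha <- hue_transform(same, 1, 2, 3, "cylindrical"),
                 "achromatic")
  expect_true(all(is.na(ha)))
  expect_equal(attr(ha, "n_excluded"), 4L)
  # oracle agreement on the fixture
  r <- make_test_raster()
  R <- oracle_band_pixels(r, 2); G <- oracle_band_pixels(r, 4)
  B <- oracle_band_pixels(r, 5)
  hcyl <- (atan2(sqrt(3) * (G - B), 2 * R - G - B)) %% (2 * pi)
  expect_equal(unname(hue_transform(r, 2, 4, 5, "cylindrical")),
               unname(oracle_stat4(hcyl)), tolerance = 1e-12,
               ignore_attr = TRUE)
  hrect <- (2 * R - G - B) / (2 * (R + G + B))
  expect_equal(unname(hue_transform(r, 2, 4, 5, "rectangular")),
               unname(oracle_stat4(hrect)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # pluggable formula
  alt <- hue_transform(r, 2, 4, 5, "cylindrical",
                       hue_fun = function(R, G, B) R - G)
  expect_equal(unname(alt[1]), mean(R - G), tolerance = 1e-12)
})

test_that("covariate table has the advertised shape and stable order", {
  sc <- small_scene()$scene
  tab <- build_covariate_table(sc$rasters, subset = "all")
  expect_equal(dim(tab), c(8, 379))
  expect_equal(colnames(tab), covariate_names("all")$name)
  expect_false(anyNA(tab))
  sp <- build_covariate_table(sc$rasters[1:2], subset = "spectral")
  expect_equal(ncol(sp), 304)
  ns <- build_covariate_table(sc$rasters[1:2], subset = "nonspectral")
  expect_equal(ncol(ns), 75)
  expect_equal(ncol(sp) + ncol(ns), 379)
  # spectral columns agree between subset and full table
  expect_equal(tab[1:2, colnames(sp)], sp, ignore_attr = TRUE)
  # missing band errors with the band named
  broken <- sc$rasters[[1]]
  broken$bands[["4"]] <- NULL
  expect_error(build_covariate_table(list(broken)), "4")
})

test_that("scale invariance: rescaling all bands moves only level families", {
  r <- make_test_raster()
  cc <- 3.7
  scaled <- r
  for (b in names(scaled$bands)) {
    scaled$bands[[b]] <- scaled$bands[[b]] * cc
  }
  t1 <- build_covariate_table(list(r))
  t2 <- build_covariate_table(list(scaled))
  meta <- covariate_names("all")
  inv_fams <- c("Bc", "R.re", "D", "NB", "NBs", "NBv", "NBc",
                "R", "Rs", "Rv", "Rc", "DS", "DSs", "DSv", "DSc",
                "RH", "RHs", "RHv", "RHc", "CHc")
  inv <- meta$name[meta$family %in% inv_fams]
  expect_equal(unlist(t2[inv]), unlist(t1[inv]), tolerance = 1e-10)
  # level families scale as c, c^2, c^2
  expect_equal(unlist(t2[meta$name[meta$family == "B"]]),
               cc * unlist(t1[meta$name[meta$family == "B"]]),
               tolerance = 1e-12)
  expect_equal(unlist(t2[meta$name[meta$family == "S"]]),
               cc^2 * unlist(t1[meta$name[meta$family == "S"]]),
               tolerance = 1e-12)
  expect_equal(unlist(t2[meta$name[meta$family == "P"]]),
               cc^2 * unlist(t1[meta$name[meta$family == "P"]]),
               tolerance = 1e-12)
})

test_that("global normalization scope uses the union range", {
  sc <- small_scene()$scene
  r12 <- sc$rasters[1:2]
  tg <- build_covariate_table(r12, subset = "spectral",
                              norm_scope = "global")
  # oracle: normalize each section against the two-section range
  for (b in c(1, 4)) {
    all_px <- c(oracle_band_pixels(r12[[1]], b),
                oracle_band_pixels(r12[[2]], b))
    rng <- range(all_px)
    px1 <- (oracle_band_pixels(r12[[1]], b) - rng[1]) / diff(rng)
    expect_equal(tg[1, paste0("nb", b)], mean(px1), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # per-section scope differs from global on heterogeneous sections
  ts <- build_covariate_table(r12, subset = "spectral")
  expect_false(isTRUE(all.equal(ts$nb4, tg$nb4)))
})
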