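#' Section raster: masked multi-band reflectance grid for one section
#'
#' A `section_raster` holds the per-band pixel grids of one neighborhood
#' ("section") together with the boolean membership mask. All bands share one
#' grid shape; pixels outside the mask are `NA`. Reflectance is expected on
#' the surface-reflectance scale, nominally in \[0, 1\].
#'
#' @param name Section name (scalar character).
#' @param bands Named list of numeric matrices, one per band. Names are band
#'   labels such as `"1"`, `"2"`, ..., `"7"` (thermal band 6 is never used).
#' @param mask Logical matrix of the same shape; `TRUE` marks in-section
#'   pixels.
#' @param pixel_size_m Pixel edge length in meters (default 30).
#'
#' @return An object of class `section_raster`.
#' @export
section_raster <- function(name, bands, mask, pixel_size_m = 30) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.list(bands) || is.null(names(bands)) || any(names(bands) == "")) {
    stop("`bands` must be a named list of matrices")
  }
  dims <- lapply(bands, dim)
  if (length(unique(dims)) != 1L) stop("all bands must share one grid shape")
  if (!is.logical(mask) || !identical(dim(mask), dims[[1L]])) {
    stop("`mask` must be a logical matrix matching the band shape")
  }
  np <- sum(mask)
  if (np < 1L) stop("mask must select at least one pixel")
  for (b in names(bands)) {
    v <- bands[[b]][mask]
    if (any(!is.finite(v))) stop("non-finite reflectance inside mask, band ", b)
  }
  if (!is.numeric(pixel_size_m) || pixel_size_m <= 0) {
    stop("`pixel_size_m` must be positive")
  }
  structure(
    list(name = name, bands = bands, mask = mask,
         pixel_size_m = as.numeric(pixel_size_m)),
    class = "section_raster"
  )
}

#' @export
print.section_raster <- function(x, ...) {
  cat("<section_raster> ", x$name, "\n", sep = "")
  cat("  grid: ", nrow(x$mask), " x ", ncol(x$mask),
      ", in-mask pixels: ", sum(x$mask), "\n", sep = "")
  cat("  bands: ", paste(names(x$bands), collapse = ", "),
      "  pixel size: ", x$pixel_size_m, " m\n", sep = "")
  invisible(x)
}

#' Number of in-mask pixels of a section raster
#' @param raster A `section_raster`.
#' @return Integer pixel count.
#' @export
pixel_count <- function(raster) {
  stopifnot(inherits(raster, "section_raster"))
  sum(raster$mask)
}

# In-mask pixel vector for one band (internal).
band_pixels <- function(raster, band) {
  b <- as.character(band)
  if (!b %in% names(raster$bands)) {
    stop("band ", b, " not present in raster ", raster$name)
  }
  raster$bands[[b]][raster$mask]
}

#' Write a scene to disk as multi-page TIFF rasters plus a CSV section table
#'
#' Each section is stored as one float TIFF with one page per band in the
#' band order of the raster (out-of-mask pixels as 0) plus a trailing 0/1
#' mask page. The section table is written as `sections.csv` with columns
#' `section, persons, area_km2, density`.
#'
#' @param scene A list with elements `rasters` (list of `section_raster`)
#'   and `sections` (data frame), as returned by [generate_scene()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (r in scene$rasters) {
    pages <- lapply(r$bands, function(m) {
      m[!r$mask] <- 0
      m
    })
    pages$mask <- r$mask + 0
    f <- file.path(dir, paste0(r$name, ".tif"))
    tiff::writeTIFF(unname(pages), f, bits.per.sample = 32L)
    files <- c(files, f)
  }
  tf <- file.path(dir, "sections.csv")
  utils::write.csv(scene$sections, tf, row.names = FALSE)
  invisible(c(files, tf))
}

#' Read a section raster written by [write_scene()]
#'
#' @param path Path to a multi-page float TIFF (band pages + mask page).
#' @param band_ids Band labels, in page order (default `c(1,2,3,4,5,7)`).
#' @param name Section name; defaults to the file name without extension.
#' @param pixel_size_m Pixel edge length in meters.
#' @return A `section_raster`. The mask comes from the trailing 0/1 page.
#' @export
read_section_raster <- function(path, band_ids = c(1, 2, 3, 4, 5, 7),
                                name = NULL, pixel_size_m = 30) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(band_ids) + 1L) {
    stop("file has ", length(pages), " pages but ", length(band_ids),
         " band ids (+ mask page) were given")
  }
  mask <- pages[[length(pages)]] > 0.5
  bands <- stats::setNames(lapply(pages[seq_along(band_ids)], function(m) {
    m[!mask] <- NA_real_
    m
  }), as.character(band_ids))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  section_raster(name, bands, mask, pixel_size_m = pixel_size_m)
}
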