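# Core data model: centroided spectra, pixel-indexed datasets, ion images
# and tissue ROIs. Plain S3 over base structures; pixel coordinates are
# 0-based with x = column, y = row, row-major over a rectangular grid.

#' Construct a centroided spectrum
#'
#' @param mz strictly ascending m/z values (Da).
#' @param intensity non-negative intensities (a.u.), same length as `mz`.
#' @param coord length-2 integer pixel coordinate `c(x, y)`, 0-based.
#' @return object of class `spectrum`.
#' @export
new_spectrum <- function(mz, intensity, coord = c(0L, 0L)) {
  stopifnot(length(mz) == length(intensity), length(coord) == 2)
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    stopf("spectrum m/z values must be strictly ascending")
  }
  if (any(intensity < 0)) stopf("spectrum intensities must be non-negative")
  structure(
    list(mz = as.numeric(mz), intensity = as.numeric(intensity),
         coord = as.integer(coord)),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> pixel (%d, %d), %d peaks", x$coord[1], x$coord[2],
              length(x$mz)))
  if (length(x$mz)) {
    cat(sprintf(", m/z %.4f-%.4f", min(x$mz), max(x$mz)))
  }
  cat("\n")
  invisible(x)
}

#' Construct an imaging-MS dataset
#'
#' A pixel-indexed collection of centroided spectra on a rectangular grid.
#'
#' @param spectra list of [new_spectrum()] objects.
#' @param dims grid dimensions `c(width, height)` in pixels.
#' @param raster pixel pitch in micrometres (metadata only).
#' @param mz_range declared m/z range `c(lo, hi)` in Da.
#' @return object of class `ims_dataset`.
#' @export
new_ims_dataset <- function(spectra, dims, raster = 50,
                            mz_range = c(700, 900)) {
  stopifnot(is.list(spectra), length(dims) == 2, length(mz_range) == 2)
  dims <- as.integer(dims)
  coords <- t(vapply(spectra, function(s) s$coord, integer(2)))
  if (length(spectra)) {
    if (any(coords[, 1] < 0 | coords[, 1] >= dims[1] |
            coords[, 2] < 0 | coords[, 2] >= dims[2])) {
      stopf("pixel coordinate outside the %dx%d grid", dims[1], dims[2])
    }
    key <- coords[, 1] + coords[, 2] * dims[1]
    if (anyDuplicated(key)) stopf("duplicate pixel coordinates")
    for (s in spectra) {
      if (length(s$mz) &&
          (min(s$mz) < mz_range[1] || max(s$mz) > mz_range[2])) {
        stopf("spectrum at pixel (%d, %d) has m/z outside the declared range",
              s$coord[1], s$coord[2])
      }
    }
  }
  structure(
    list(spectra = spectra, dims = dims, raster = raster,
         mz_range = as.numeric(mz_range)),
    class = "ims_dataset"
  )
}

#' @export
print.ims_dataset <- function(x, ...) {
  cat(sprintf("<ims_dataset> %d spectra on a %dx%d grid, raster %g um, m/z %g-%g\n",
              length(x$spectra), x$dims[1], x$dims[2], x$raster,
              x$mz_range[1], x$mz_range[2]))
  invisible(x)
}

#' Number of pixels with a spectrum
#' @param dataset an `ims_dataset`.
#' @return integer count.
#' @export
n_pixels <- function(dataset) length(dataset$spectra)

#' Construct an ion image
#'
#' @param values intensity matrix, `dims[2]` rows (y) by `dims[1]` columns (x).
#' @param center interval centre m/z (Da).
#' @param halfwidth interval half-width (Da), > 0.
#' @param label provenance label; default is the centre m/z to 3 decimals.
#' @return object of class `ion_image`.
#' @export
new_ion_image <- function(values, center, halfwidth,
                          label = sprintf("%.3f", center)) {
  stopifnot(is.matrix(values), halfwidth > 0)
  structure(
    list(values = values, center = center, halfwidth = halfwidth,
         label = label),
    class = "ion_image"
  )
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("<ion_image> %s (m/z %.4f +/- %.4f), %dx%d, max %.3g\n",
              x$label, x$center, x$halfwidth, ncol(x$values), nrow(x$values),
              max(x$values)))
  invisible(x)
}

#' Construct a region of interest (tissue mask)
#'
#' @param mask logical matrix, TRUE = on tissue; must contain at least one
#'   TRUE pixel.
#' @return object of class `roi`.
#' @export
new_roi <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stopf("ROI mask is empty")
  structure(list(mask = mask), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %dx%d, %d on-tissue pixels\n", ncol(x$mask),
              nrow(x$mask), sum(x$mask)))
  invisible(x)
}

# Index of pixel (x, y) in a dense row-major vector over the grid, 1-based.
pixel_index <- function(coord, dims) coord[1] + coord[2] * dims[1] + 1L

# Stack ion images into a pixels x images matrix (dense grid, row-major).
# Optionally restricted to ROI pixels.
stack_images <- function(images, roi = NULL) {
  stopifnot(length(images) >= 1)
  d <- dim(images[[1]]$values)
  for (img in images) {
    if (!identical(dim(img$values), d)) stopf("ion images differ in dimensions")
  }
  m <- vapply(images, function(img) as.vector(t(img$values)), numeric(prod(d)))
  colnames(m) <- vapply(images, function(img) img$label, character(1))
  if (!is.null(roi)) {
    keep <- as.vector(t(roi$mask))
    m <- m[keep, , drop = FALSE]
  }
  m
}
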