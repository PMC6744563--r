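# Average spectrum, peak picking and ion-image extraction.

#' Average spectrum of a dataset
#'
#' Bins all peaks of all spectra on a fixed grid and divides each bin's
#' summed intensity by the number of pixels, i.e. the mean over pixels of
#' the intensity falling into that bin. Only bins with non-zero mass are
#' returned, as a centroided `spectrum` at the bin centres.
#'
#' @param dataset an `ims_dataset` with at least one spectrum.
#' @param bin_width bin width in Da (> 0, default 0.001).
#' @return a `spectrum` (pixel coordinate `(0, 0)` by convention).
#' @export
average_spectrum <- function(dataset, bin_width = 0.001) {
  stopifnot(inherits(dataset, "ims_dataset"))
  if (length(dataset$spectra) == 0) stopf("dataset is empty")
  stopifnot(bin_width > 0)
  all_mz <- unlist(lapply(dataset$spectra, `[[`, "mz"))
  all_int <- unlist(lapply(dataset$spectra, `[[`, "intensity"))
  if (length(all_mz) == 0) {
    return(new_spectrum(numeric(0), numeric(0), c(0L, 0L)))
  }
  origin <- dataset$mz_range[1]
  if (!is.finite(origin)) origin <- floor(min(all_mz))
  bin <- floor((all_mz - origin) / bin_width)
  sums <- tapply(all_int, bin, sum)
  bins <- as.numeric(names(sums))
  ord <- order(bins)
  centers <- origin + (bins[ord] + 0.5) * bin_width
  new_spectrum(centers, as.numeric(sums[ord]) / length(dataset$spectra),
               c(0L, 0L))
}

# Robust noise estimate: 1.4826 * MAD of the intensities after excluding
# the top 5%. Returns 0 for degenerate (constant) input.
estimate_noise <- function(intensity, trim = 0.05) {
  if (!length(intensity)) return(0)
  cut <- stats::quantile(intensity, probs = 1 - trim, type = 1)
  kept <- intensity[intensity <= cut]
  if (!length(kept)) kept <- intensity
  stats::mad(kept)  # 1.4826 * median absolute deviation
}

#' Pick peaks from a centroided spectrum
#'
#' Local maxima with signal-to-noise at or above `snr_threshold`; maxima
#' closer than `width` are merged, keeping the most intense member (ties
#' resolved toward lower m/z). The noise level is a trimmed
#' median-absolute-deviation estimate (see Details), making the output
#' invariant to uniform intensity scaling.
#'
#' @details The noise estimate is `1.4826 * mad(intensities)` after
#'   excluding the top 5% of intensities, a robust floor estimate for
#'   sparse centroided spectra. If the estimate is zero (e.g. a spectrum of
#'   a single isolated peak), every positive local maximum is kept.
#'
#' @param spectrum a `spectrum`, typically from [average_spectrum()].
#' @param snr_threshold minimum signal-to-noise ratio (default 10).
#' @param width merge radius in Da (default 0.2, > 0).
#' @return object of class `peakset`: list with ascending `mz`, `intensity`
#'   and `snr` vectors plus the parameters used.
#' @export
pick_peaks <- function(spectrum, snr_threshold = 10, width = 0.2) {
  stopifnot(inherits(spectrum, "spectrum"))
  if (width <= 0) stopf("width must be positive")
  if (length(spectrum$mz) == 0) stopf("spectrum is empty")
  mz <- spectrum$mz
  int <- spectrum$intensity
  n <- length(mz)

  # strict local maxima (endpoints qualify against their single neighbour)
  if (n == 1) {
    is_max <- int > 0
  } else {
    left <- c(-Inf, int[-n])
    right <- c(int[-1], -Inf)
    is_max <- int > left & int > right & int > 0
  }
  noise <- estimate_noise(int)
  snr <- if (noise > 0) int / noise else ifelse(int > 0, Inf, 0)
  cand <- which(is_max & snr >= snr_threshold)

  # greedy merge: accept by decreasing intensity (ties -> lower m/z),
  # rejecting candidates within `width` of an accepted peak
  ord <- cand[order(-int[cand], mz[cand])]
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(mz[i] - mz[accepted]) >= width)) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- sort(accepted)
  structure(
    list(mz = mz[accepted], intensity = int[accepted], snr = snr[accepted],
         snr_threshold = snr_threshold, width = width, noise = noise),
    class = "peakset"
  )
}

#' @export
print.peakset <- function(x, ...) {
  cat(sprintf("<peakset> %d peaks (S/N >= %g, merge width %g Da, noise %.4g)\n",
              length(x$mz), x$snr_threshold, x$width, x$noise))
  invisible(x)
}

#' Extract an ion image
#'
#' Per-pixel intensity of the m/z interval `[center - halfwidth, center +
#' halfwidth]`. In `"maximum"` mode (the default and only mode) a pixel's
#' value is the most intense peak inside the interval, 0 if none. Pixels
#' without a spectrum stay 0.
#'
#' @param dataset an `ims_dataset`.
#' @param center interval centre (Da).
#' @param halfwidth interval half-width (Da, > 0, default 0.004).
#' @param mode interval processing mode; `"maximum"`.
#' @return an `ion_image`. If `center` lies outside the dataset's declared
#'   m/z range a warning is issued and the image is all-zero.
#' @export
ion_image <- function(dataset, center, halfwidth = 0.004,
                      mode = c("maximum")) {
  mode <- match.arg(mode)
  ion_images_at(dataset, center, halfwidth)[[1]]
}

# Flatten a dataset to parallel (pixel, mz, intensity) vectors sorted by
# m/z, for fast repeated interval queries.
flatten_dataset <- function(dataset) {
  mz <- unlist(lapply(dataset$spectra, `[[`, "mz"))
  int <- unlist(lapply(dataset$spectra, `[[`, "intensity"))
  pix <- rep(
    vapply(dataset$spectra, function(s) pixel_index(s$coord, dataset$dims),
           integer(1)),
    vapply(dataset$spectra, function(s) length(s$mz), integer(1)))
  ord <- order(mz)
  list(mz = mz[ord], intensity = int[ord], pixel = pix[ord])
}

# Shared worker: one ion image per centre m/z.
ion_images_at <- function(dataset, centers, halfwidth = 0.004,
                          flat = NULL) {
  stopifnot(inherits(dataset, "ims_dataset"))
  if (halfwidth <= 0) stopf("halfwidth must be positive")
  if (is.null(flat)) flat <- flatten_dataset(dataset)
  w <- dataset$dims[1]; h <- dataset$dims[2]
  lapply(centers, function(center) {
    values <- matrix(0, nrow = h, ncol = w)
    if (center < dataset$mz_range[1] || center > dataset$mz_range[2]) {
      warning(sprintf(
        "center %.4f outside dataset m/z range [%g, %g]; empty image",
        center, dataset$mz_range[1], dataset$mz_range[2]))
      return(new_ion_image(values, center, halfwidth))
    }
    i1 <- findInterval(center - halfwidth, flat$mz, left.open = TRUE) + 1L
    i2 <- findInterval(center + halfwidth, flat$mz)
    if (i2 >= i1) {
      sel <- i1:i2
      mx <- tapply(flat$intensity[sel], flat$pixel[sel], max)
      p <- as.integer(names(mx)) - 1L
      values[cbind(p %/% w + 1L, p %% w + 1L)] <- as.numeric(mx)
    }
    new_ion_image(values, center, halfwidth)
  })
}

#' Ion images for every peak of a peak set
#'
#' @param dataset an `ims_dataset`.
#' @param peaks a `peakset` (or a numeric vector of centre m/z values).
#' @param halfwidth interval half-width (Da, default 0.004).
#' @return list of `ion_image` objects, one per peak.
#' @export
ion_images <- function(dataset, peaks, halfwidth = 0.004) {
  centers <- if (inherits(peaks, "peakset")) peaks$mz else as.numeric(peaks)
  ion_images_at(dataset, centers, halfwidth)
}
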