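# On-tissue screening of ion images: keep tissue-enriched distributions,
# discard homogeneous-everywhere and off-tissue-enriched artefacts.

SCREEN_LABELS <- c("biomolecule", "artefact_homogeneous", "artefact_off_tissue")

#' Classify one ion image against a tissue ROI
#'
#' Mean intensities are computed over all pixels (zeros included) inside
#' and outside the ROI. The image is `artefact_off_tissue` if the outside
#' mean exceeds the inside mean, `artefact_homogeneous` if the enrichment
#' ratio `mean(inside) / mean(outside)` is below `enrichment_threshold`,
#' and `biomolecule` otherwise. Labels are invariant to uniform scaling of
#' the image.
#'
#' @param image an `ion_image`.
#' @param roi an `roi` with matching dimensions.
#' @param enrichment_threshold minimum on/off-tissue mean ratio for a
#'   biomolecule call (default 2).
#' @return one-row data.frame: `label`, `mean_inside`, `mean_outside`,
#'   `enrichment`.
#' @export
classify_distribution <- function(image, roi, enrichment_threshold = 2) {
  stopifnot(inherits(image, "ion_image"), inherits(roi, "roi"))
  if (!identical(dim(image$values), dim(roi$mask))) {
    stopf("ROI dimensions do not match image dimensions")
  }
  inside <- mean(image$values[roi$mask])
  if (all(roi$mask)) stopf("ROI covers the whole grid; no off-tissue pixels")
  outside <- mean(image$values[!roi$mask])
  enrichment <- if (outside > 0) inside / outside else Inf
  label <- if (outside > inside) {
    "artefact_off_tissue"
  } else if (enrichment < enrichment_threshold) {
    "artefact_homogeneous"
  } else {
    "biomolecule"
  }
  data.frame(label = label, mean_inside = inside, mean_outside = outside,
             enrichment = enrichment, stringsAsFactors = FALSE)
}

#' Screen a set of ion images
#'
#' Applies [classify_distribution()] to every image; biomolecule-labelled
#' images are kept in their input order.
#'
#' @param images list of `ion_image` objects.
#' @param roi tissue `roi`.
#' @param enrichment_threshold see [classify_distribution()].
#' @return list with `kept` (the biomolecule images) and `report` (an
#'   object of class `screen_report`: per-image label, means, enrichment
#'   and the threshold used).
#' @export
screen_dataset <- function(images, roi, enrichment_threshold = 2) {
  stopifnot(length(images) >= 1)
  rows <- lapply(images, classify_distribution, roi = roi,
                 enrichment_threshold = enrichment_threshold)
  report <- do.call(rbind, rows)
  report <- cbind(
    data.frame(label_mz = vapply(images, function(i) i$label, character(1)),
               stringsAsFactors = FALSE),
    report)
  attr(report, "enrichment_threshold") <- enrichment_threshold
  class(report) <- c("screen_report", "data.frame")
  list(kept = images[report$label == "biomolecule"], report = report)
}

#' @export
print.screen_report <- function(x, ...) {
  counts <- table(factor(x$label, levels = SCREEN_LABELS))
  cat(sprintf(
    "<screen_report> %d images (enrichment threshold %g): %d biomolecule, %d homogeneous, %d off-tissue\n",
    nrow(x), attr(x, "enrichment_threshold"), counts[["biomolecule"]],
    counts[["artefact_homogeneous"]], counts[["artefact_off_tissue"]]))
  invisible(x)
}
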