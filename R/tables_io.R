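# Plain-text table I/O: ion-image matrices, ROI masks and phantom
# ground-truth manifests.

#' Export an ion-image stack as a TSV matrix
#'
#' Rows are pixels (columns `x`, `y` first, 0-based), one column per ion
#' image labelled by its centre m/z to 3 decimals.
#'
#' @param images list of `ion_image` objects sharing dimensions.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_ion_image_table <- function(images, path) {
  m <- stack_images(images)
  d <- dim(images[[1]]$values)  # rows = height, cols = width
  grid <- expand.grid(x = 0:(d[2] - 1), y = 0:(d[1] - 1))
  tab <- cbind(grid, as.data.frame(m, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ion-image table written by [export_ion_image_table()]
#'
#' @param path file path.
#' @return list of `ion_image` objects; halfwidth metadata is not stored in
#'   the table and is restored as the package default (0.004 Da).
#' @export
read_ion_image_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(c("x", "y") %in% names(tab)))
  width <- max(tab$x) + 1L
  height <- max(tab$y) + 1L
  cols <- setdiff(names(tab), c("x", "y"))
  lapply(cols, function(cn) {
    v <- matrix(0, nrow = height, ncol = width)
    v[cbind(tab$y + 1L, tab$x + 1L)] <- tab[[cn]]
    new_ion_image(v, center = as.numeric(cn), halfwidth = 0.004, label = cn)
  })
}

#' Write an ROI mask as a 0/1 text grid
#'
#' One line per grid row, space-separated 0/1 values.
#'
#' @param roi an `roi`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roi_mask <- function(roi, path) {
  stopifnot(inherits(roi, "roi"))
  lines <- apply(roi$mask, 1, function(r) paste(as.integer(r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ROI mask written by [write_roi_mask()]
#'
#' @param path file path.
#' @return an `roi`.
#' @export
read_roi_mask <- function(path) {
  rows <- lapply(strsplit(readLines(path), " +"), as.integer)
  new_roi(do.call(rbind, rows) == 1)
}

#' Write a phantom ground-truth manifest as TSV
#'
#' @param truth a `ground_truth` (see [make_ground_truth()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  tab <- truth$molecules
  tab$adducts <- vapply(tab$adducts, paste, character(1), collapse = ",")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth manifest written by [write_ground_truth()]
#'
#' @param path file path.
#' @param seed seed recorded in the returned object (manifests do not store
#'   it; defaults to NA).
#' @param raster raster metadata (um).
#' @return a `ground_truth`.
#' @export
read_ground_truth <- function(path, seed = NA_integer_, raster = 50) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$adducts <- strsplit(tab$adducts, ",", fixed = TRUE)
  structure(list(molecules = tab, seed = seed, raster = raster),
            class = "ground_truth")
}
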