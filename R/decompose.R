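# Spatial principal-component decomposition of an ion-image stack.

#' PCA of an ion-image stack
#'
#' Columns (one per ion image) are centred and scaled to unit variance, and
#' the top `n_components` principal components are computed from the
#' resulting correlation structure via a deterministic singular value
#' decomposition. Scores are the pixel-space component maps (the spatial
#' images), loadings the per-image weights. Signs are fixed by making the
#' largest-magnitude entry of each loading vector positive, so results are
#' reproducible bit for bit.
#'
#' @param stack numeric matrix, pixels x images (>= 2 of each); or a list of
#'   `ion_image` objects, which is stacked over all grid pixels.
#' @param n_components number of components to retain (default 5).
#' @param scaling `"unit_variance"` (the only supported scaling).
#' @param dims optional grid dims `c(width, height)` used to reshape score
#'   vectors into score images (inferred when `stack` is an image list).
#' @return object of class `pca_result`: `loadings` (images x k), `scores`
#'   (pixels x k), `contributions` (% of total variance, length k),
#'   `eigenvalues`, `score_images` (list of matrices if `dims` known),
#'   `parameters`.
#' @export
run_pca <- function(stack, n_components = 5, scaling = "unit_variance",
                    dims = NULL) {
  if (is.list(stack) && !is.matrix(stack)) {
    if (is.null(dims)) {
      d <- dim(stack[[1]]$values)
      dims <- c(d[2], d[1])
    }
    stack <- stack_images(stack)
  }
  stopifnot(is.matrix(stack))
  if (!identical(scaling, "unit_variance")) {
    stopf("only unit_variance scaling is supported")
  }
  n <- nrow(stack); p <- ncol(stack)
  if (n < 2 || p < 2) stopf("need at least 2 pixels and 2 images")
  n_components <- min(n_components, p, n - 1)

  mu <- colMeans(stack)
  sdv <- apply(stack, 2, stats::sd)
  zero <- which(sdv == 0)
  if (length(zero)) {
    lab <- colnames(stack)[zero[1]] %||% as.character(zero[1])
    stopf("image '%s' is constant (zero variance); cannot scale", lab)
  }
  xs <- sweep(sweep(stack, 2, mu, "-"), 2, sdv, "/")

  sv <- svd(xs, nu = n_components, nv = n_components)
  eig <- sv$d^2 / (n - 1)          # all p correlation eigenvalues
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)

  # sign convention: largest-|loading| entry positive
  for (k in seq_len(n_components)) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(loadings) <- colnames(stack)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(n_components))

  score_images <- NULL
  if (!is.null(dims)) {
    score_images <- lapply(seq_len(n_components), function(k) {
      matrix(scores[, k], nrow = dims[2], ncol = dims[1], byrow = TRUE)
    })
    names(score_images) <- colnames(scores)
  }

  structure(
    list(loadings = loadings, scores = scores,
         eigenvalues = eig,
         contributions = eig[seq_len(n_components)] / sum(eig) * 100,
         score_images = score_images,
         parameters = list(n_components = n_components, scaling = scaling,
                           normalisation = "none", denoising = "none"),
         n_pixels = n, n_images = p),
    class = "pca_result"
  )
}

#' Variance contribution of one component
#'
#' @param result a `pca_result`.
#' @param k component index (1-based, <= n_components).
#' @return contribution in percent of total variance:
#'   `eigenvalue_k / sum(all eigenvalues) * 100`.
#' @export
pca_contribution <- function(result, k) {
  stopifnot(inherits(result, "pca_result"))
  if (k < 1 || k > result$parameters$n_components) {
    stopf("component index %d out of range 1..%d", k,
          result$parameters$n_components)
  }
  result$eigenvalues[k] / sum(result$eigenvalues) * 100
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components over %d images x %d pixels\n",
              x$parameters$n_components, x$n_images, x$n_pixels))
  cat("contributions (%):",
      paste(sprintf("%.1f", x$contributions), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pca_result <- function(object, ...) {
  k <- object$parameters$n_components
  tab <- data.frame(
    component = paste0("PC", seq_len(k)),
    eigenvalue = object$eigenvalues[seq_len(k)],
    contribution_pct = object$contributions,
    cumulative_pct = cumsum(object$contributions)
  )
  print(tab, row.names = FALSE)
  invisible(tab)
}
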