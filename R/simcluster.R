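# Cosine-similarity matrix of ion images, hierarchical ordering, threshold
# group extraction and the occupancy table.

#' Pairwise cosine similarity of ion images
#'
#' `value(i, j) = sum(x_i x_j) / (||x_i|| ||x_j||)` over the selected
#' pixels. For non-negative images values lie in [0, 1]; the diagonal is 1.
#'
#' @param stack pixels x images matrix, or a list of `ion_image` objects.
#' @param roi optional `roi`; when given, only on-tissue pixels enter the
#'   similarity (the usual choice, matching an ROI drawn around the
#'   section).
#' @return object of class `similarity_matrix`: symmetric numeric matrix
#'   with image labels as dimnames.
#' @export
cosine_similarity_matrix <- function(stack, roi = NULL) {
  if (is.list(stack) && !is.matrix(stack)) stack <- stack_images(stack, roi)
  else if (!is.null(roi)) stack <- stack[as.vector(t(roi$mask)), , drop = FALSE]
  stopifnot(is.matrix(stack))
  if (ncol(stack) < 2) stopf("need at least 2 images")
  norms <- sqrt(colSums(stack^2))
  zero <- which(norms == 0)
  if (length(zero)) {
    lab <- colnames(stack)[zero[1]] %||% as.character(zero[1])
    stopf("image '%s' has zero norm over the selected pixels", lab)
  }
  s <- crossprod(stack) / tcrossprod(norms)
  s[s > 1] <- 1  # guard numerical overshoot
  diag(s) <- 1
  structure(s, class = c("similarity_matrix", "matrix"))
}

#' Order a similarity matrix by hierarchical clustering
#'
#' Agglomerative clustering on the distance `1 - similarity`; the dendrogram
#' leaf order groups similar images contiguously, which is what makes
#' threshold blocks visible on the reordered heat map.
#'
#' @param sim a `similarity_matrix`.
#' @param linkage `"average"` (UPGMA, default), `"single"` or `"complete"`.
#' @return list with `order` (integer leaf permutation), `labels` (leaf
#'   labels in that order) and `hclust` (the [stats::hclust()] tree).
#' @export
order_by_clustering <- function(sim, linkage = c("average", "single",
                                                 "complete")) {
  stopifnot(inherits(sim, "similarity_matrix") ||
              (is.matrix(sim) && isSymmetric(unclass(sim))))
  linkage <- match.arg(linkage)
  if (nrow(sim) == 1) {
    return(list(order = 1L, labels = rownames(sim), hclust = NULL))
  }
  d <- stats::as.dist(1 - unclass(sim))
  hc <- stats::hclust(d, method = linkage)
  list(order = hc$order, labels = rownames(sim)[hc$order], hclust = hc)
}

# Mean pairwise similarity within a contiguous index run (excluding the
# diagonal).
run_mean_sim <- function(sim, idx) {
  if (length(idx) < 2) return(1)
  block <- sim[idx, idx]
  (sum(block) - length(idx)) / (length(idx)^2 - length(idx))
}

#' Extract molecule groups from a clustered similarity matrix
#'
#' Diagonal groups are the dendrogram clusters obtained by cutting the tree
#' at distance `1 - threshold` (so every cluster's internal merges stay
#' above the similarity threshold), verified against the block `criterion`
#' and reported when they hold at least `min_size` members. Because cluster
#' members are contiguous in leaf order these appear as blocks on the
#' reordered heat map's diagonal. Off-diagonal groups capture high
#' similarity between blocks the dendrogram keeps apart: pairs of tight
#' sub-blocks (dendrogram nodes merged below the cut) belonging to
#' different clusters whose mean cross-block similarity exceeds the
#' threshold; each is reported as the union of the two blocks, maximal
#' pairs only.
#'
#' @param sim a `similarity_matrix`.
#' @param ordering result of [order_by_clustering()] on `sim`.
#' @param threshold similarity threshold in (0, 1) (default 0.5).
#' @param min_size minimum reported group size (default 7; a block of
#'   exactly `min_size` is reported).
#' @param criterion `"mean"` (default): a cluster qualifies when its mean
#'   pairwise similarity exceeds the threshold; `"all"`: every pair must.
#' @return list of `molecule_group` objects: each a list with `members`
#'   (labels), `indices` (matrix columns), `kind` (`"diagonal"` or
#'   `"off_diagonal"`) and `size`.
#' @export
extract_groups <- function(sim, ordering, threshold = 0.5, min_size = 7,
                           criterion = c("mean", "all")) {
  criterion <- match.arg(criterion)
  if (threshold <= 0 || threshold >= 1) {
    stopf("threshold must be inside (0, 1)")
  }
  labels <- rownames(sim)
  s <- unclass(sim)
  n <- nrow(s)
  hc <- ordering$hclust

  qualifies <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    block <- s[idx, idx]
    if (criterion == "mean") {
      run_mean_sim(sim, idx) > threshold
    } else {
      all(block[upper.tri(block)] > threshold)
    }
  }

  groups <- list()
  if (is.null(hc)) return(groups)  # single image
  cut_h <- 1 - threshold

  # walk the merge list: collect tight nodes (merged at or below the cut)
  # and derive the cut clusters by union, which tolerates the tied /
  # epsilon-unsorted heights average linkage can produce
  node_leaves <- vector("list", nrow(hc$merge))
  tight <- list()
  cl <- seq_len(n)
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    leaves <- c(
      if (kids[1] < 0) -kids[1] else node_leaves[[kids[1]]],
      if (kids[2] < 0) -kids[2] else node_leaves[[kids[2]]])
    node_leaves[[i]] <- leaves
    if (hc$height[i] <= cut_h) {
      tight[[length(tight) + 1]] <- leaves
      cl[leaves] <- min(cl[leaves])
    }
  }

  for (k in sort(unique(cl))) {
    idx <- which(cl == k)
    if (length(idx) >= min_size && qualifies(idx)) {
      groups[[length(groups) + 1]] <- structure(
        list(members = labels[idx], indices = idx, kind = "diagonal",
             size = length(idx)),
        class = "molecule_group")
    }
  }

  # candidate off-diagonal pairs: tight blocks in different clusters
  cands <- list()
  for (a in seq_along(tight)) {
    for (b in seq_along(tight)) {
      if (b <= a) next
      ia <- tight[[a]]; ib <- tight[[b]]
      if (cl[ia[1]] == cl[ib[1]]) next  # same diagonal cluster
      if (length(ia) + length(ib) < min_size) next
      if (mean(s[ia, ib]) > threshold) {
        cands[[length(cands) + 1]] <- sort(c(ia, ib))
      }
    }
  }
  if (length(cands)) {
    # keep maximal unions only
    cands <- cands[order(-lengths(cands))]
    kept <- list()
    for (u in cands) {
      if (!any(vapply(kept, function(v) all(u %in% v), logical(1)))) {
        kept[[length(kept) + 1]] <- u
        groups[[length(groups) + 1]] <- structure(
          list(members = labels[u], indices = u, kind = "off_diagonal",
               size = length(u)),
          class = "molecule_group")
      }
    }
  }
  groups
}

#' @export
print.molecule_group <- function(x, ...) {
  cat(sprintf("<molecule_group> %s, %d members: %s%s\n", x$kind, x$size,
              paste(utils::head(x$members, 6), collapse = ", "),
              if (x$size > 6) ", ..." else ""))
  invisible(x)
}

#' Occupancy table of molecule groups
#'
#' Per group: member count and its percentage of the total number of
#' molecules, rounded half away from zero to 1 decimal; a final
#' `grouped_total` row counts the distinct members across all groups.
#'
#' @param groups list of `molecule_group` objects (or a numeric vector of
#'   group sizes, in which case members are assumed disjoint).
#' @param total total number of molecules (> 0, >= the grouped total).
#' @return data.frame with columns `group`, `n`, `ratio_pct`.
#' @export
occupancy_table <- function(groups, total) {
  if (total <= 0) stopf("total must be positive")
  if (is.numeric(groups)) {
    sizes <- as.integer(groups)
    grouped_total <- sum(sizes)
    names <- if (!is.null(names(groups))) names(groups)
             else as.character(utils::as.roman(seq_along(sizes)))
  } else {
    sizes <- vapply(groups, function(g) g$size, numeric(1))
    grouped_total <- length(unique(unlist(lapply(groups, `[[`, "members"))))
    names <- as.character(utils::as.roman(seq_along(groups)))
  }
  if (grouped_total > total) stopf("grouped total exceeds total")
  data.frame(
    group = c(names, "grouped_total"),
    n = c(sizes, grouped_total),
    ratio_pct = round_half_up(100 * c(sizes, grouped_total) / total, 1),
    stringsAsFactors = FALSE
  )
}
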