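# Cosine similarity, dendrogram ordering, group extraction, occupancy.

block_similarity <- function(sizes, within = 1, between = 0) {
  n <- sum(sizes)
  s <- matrix(between, n, n)
  start <- 1
  for (sz in sizes) {
    idx <- start:(start + sz - 1)
    s[idx, idx] <- within
    start <- start + sz
  }
  diag(s) <- 1
  rownames(s) <- colnames(s) <- sprintf("m%03d", seq_len(n))
  structure(s, class = c("similarity_matrix", "matrix"))
}

test_that("cosine similarity matches its definition and basic identities", {
  set.seed(5)
  x <- matrix(runif(40), 8, 5)
  colnames(x) <- paste0("img", 1:5)
  s <- cosine_similarity_matrix(x)
  expect_equal(diag(unclass(s)), rep(1, 5), ignore_attr = TRUE)
  # brute-force double loop
  for (i in 1:5) {
    for (j in 1:5) {
      manual <- sum(x[, i] * x[, j]) /
        sqrt(sum(x[, i]^2) * sum(x[, j]^2))
      expect_equal(unclass(s)[i, j], manual, tolerance = 1e-12)
    }
  }
  # disjoint supports give zero similarity
  y <- cbind(a = c(1, 2, 0, 0), b = c(0, 0, 3, 4))
  expect_equal(unclass(cosine_similarity_matrix(y))[1, 2], 0)
  # invariance to positive per-image scaling
  xs <- sweep(x, 2, c(10, 0.1, 3, 7, 100), "*")
  expect_equal(unclass(cosine_similarity_matrix(xs)), unclass(s),
               tolerance = 1e-12)
  expect_error(cosine_similarity_matrix(cbind(a = c(1, 1), b = c(0, 0))),
               "'b'")
})

test_that("UPGMA ordering matches a naive agglomeration oracle", {
  set.seed(9)
  # random symmetric similarity with distinct off-diagonal values
  n <- 6
  s <- matrix(0, n, n)
  s[upper.tri(s)] <- runif(n * (n - 1) / 2)
  s <- s + t(s)
  diag(s) <- 1
  rownames(s) <- colnames(s) <- letters[1:n]
  sm <- structure(s, class = c("similarity_matrix", "matrix"))

  ord <- order_by_clustering(sm)
  coph_hc <- as.matrix(stats::cophenetic(ord$hclust))
  coph_naive <- naive_upgma_cophenetic(s)
  dimnames(coph_naive) <- dimnames(coph_hc)
  expect_equal(coph_hc, coph_naive, tolerance = 1e-12)
})

test_that("leaf order keeps perfect blocks contiguous; singletons are identity", {
  s <- block_similarity(c(4, 3))
  ord <- order_by_clustering(s)$order
  expect_true(identical(sort(ord[1:4]), 1:4) ||
                identical(sort(ord[1:3]), 5:7))

  single <- structure(matrix(1, 1, 1, dimnames = list("a", "a")),
                      class = c("similarity_matrix", "matrix"))
  expect_equal(order_by_clustering(single)$order, 1L)
})

test_that("diagonal groups are threshold blocks of sufficient size", {
  s <- block_similarity(c(8, 9))
  ord <- order_by_clustering(s)
  groups <- extract_groups(s, ord, threshold = 0.5, min_size = 7)
  expect_length(groups, 2)
  expect_setequal(vapply(groups, `[[`, 0, "size"), c(8, 9))
  expect_true(all(vapply(groups, `[[`, "", "kind") == "diagonal"))

  # everything below threshold: no groups
  low <- block_similarity(c(8, 9), within = 0.4, between = 0.4)
  expect_length(extract_groups(low, order_by_clustering(low)), 0)

  # a block of exactly min_size members is reported
  s7 <- block_similarity(c(7, 3))
  g7 <- extract_groups(s7, order_by_clustering(s7), min_size = 7)
  expect_length(g7, 1)
  expect_equal(g7[[1]]$size, 7)

  expect_error(extract_groups(s, ord, threshold = 1.5), "threshold")
})

test_that("off-diagonal groups join blocks the dendrogram keeps apart", {
  # A (5) is pulled into a cluster with B (8) (cross 0.7), leaving C (6)
  # isolated; yet A x C similarity (0.55) exceeds the threshold, so A and
  # C light up off the diagonal, as isotope/adduct duplicates do
  s <- block_similarity(c(5, 8, 6), within = 0.95, between = 0)
  s[1:5, 6:13] <- 0.7; s[6:13, 1:5] <- 0.7
  s[1:5, 14:19] <- 0.55; s[14:19, 1:5] <- 0.55
  diag(s) <- 1
  ord <- order_by_clustering(s)
  groups <- extract_groups(s, ord, threshold = 0.5, min_size = 7)
  kinds <- vapply(groups, `[[`, "", "kind")
  expect_equal(sum(kinds == "diagonal"), 1)
  expect_equal(groups[[which(kinds == "diagonal")]]$size, 13)
  expect_true("off_diagonal" %in% kinds)
  off <- groups[[which(kinds == "off_diagonal")[1]]]
  expect_setequal(off$members, rownames(s)[c(1:5, 14:19)])
})

test_that("group extraction is stable under image relabelling", {
  s <- block_similarity(c(8, 9), within = 0.9, between = 0.1)
  perm <- c(9:17, 1:8)
  sp <- unclass(s)[perm, perm]
  sp <- structure(sp, class = c("similarity_matrix", "matrix"))
  g1 <- extract_groups(s, order_by_clustering(s))
  g2 <- extract_groups(sp, order_by_clustering(sp))
  sets1 <- lapply(g1, function(g) sort(g$members))
  sets2 <- lapply(g2, function(g) sort(g$members))
  expect_setequal(sets1, sets2)
})

test_that("occupancy ratios are percentages rounded half away from zero", {
  tab <- occupancy_table(c(59), total = 488)
  expect_equal(tab$ratio_pct[1], 12.1)

  empty <- occupancy_table(numeric(0), total = 100)
  expect_equal(empty$n, 0)
  expect_equal(empty$ratio_pct, 0)

  expect_error(occupancy_table(c(5), total = 0), "positive")
  expect_error(occupancy_table(c(50, 60), total = 100), "exceeds")
})
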