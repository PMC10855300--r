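test_that("PCA decomposition conserves variance and matches eigen oracle", {
  set.seed(13)
  x <- make_expr(matrix(rnorm(13 * 18), 13, 18))
  pca <- pca_decompose(x)
  expect_equal(sum(pca$explained_variance_pct), 100, tolerance = 1e-6)
  expect_true(all(diff(pca$explained_variance_pct) <= 1e-12))
  expect_equal(unname(colSums(pca$contributions_pct)),
               rep(100, ncol(pca$contributions_pct)), tolerance = 1e-6)

  # independent oracle: eigenvalues of the gene-gene correlation matrix
  ev <- eigen(cor(t(unclass(x))), symmetric = TRUE, only.values = TRUE)$values
  got <- pca$explained_variance_pct / 100 * sum(ev)
  expect_equal(got[seq_along(ev)], ev[seq_along(ev)], tolerance = 1e-8,
               ignore_attr = TRUE)

  # permutation invariance of the spectrum
  perm <- sample(ncol(x))
  x2 <- expression_matrix(unclass(x)[, perm], "log2fc")
  expect_equal(pca_decompose(x2)$explained_variance_pct,
               pca$explained_variance_pct, tolerance = 1e-9)

  # rank-1: duplicated gene after scaling puts 100% on PC1
  g1 <- rnorm(10)
  r1 <- pca_decompose(make_expr(rbind(g1, 3 * g1 + 2)))
  expect_equal(r1$explained_variance_pct[1], 100, tolerance = 1e-9)

  expect_error(pca_decompose(make_expr(rbind(g1, rep(1, 10)))),
               class = "lutd_zero_variance")
})

test_that("average-linkage merge heights match a naive O(n^3) oracle", {
  set.seed(4)
  x <- make_expr(matrix(rnorm(3 * 5), 3, 5))
  hc <- hierarchical_cluster(x, distance = "euclidean")

  # naive average-linkage agglomeration on the same distances
  m <- t(unclass(x))
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(5))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < bh) { bh <- h; best <- c(i, j) }
    }
    heights <- c(heights, bh)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  expect_equal(hc$merge_heights, heights, tolerance = 1e-12)
})

test_that("hierarchical clustering contracts hold", {
  set.seed(6)
  base <- matrix(rnorm(4 * 6), 4, 6)
  base[, 2] <- base[, 1] # two identical samples
  x <- make_expr(base)
  hc <- hierarchical_cluster(x, distance = "euclidean")
  expect_equal(hc$merge_heights[1], 0)
  expect_equal(unname(cut_tree(hc, 2)[1]), unname(cut_tree(hc, 2)[2]))
  for (k in 1:6) expect_equal(length(unique(cut_tree(hc, k))), k)
  # average linkage heights are monotone here
  expect_true(all(diff(hc$merge_heights) >= -1e-12))

  cx <- make_expr(cbind(matrix(rnorm(3 * 2), 3, 2), rep(2, 3)))
  expect_error(hierarchical_cluster(cx, distance = "one_minus_pearson"), "S3",
               class = "lutd_zero_variance")
})

test_that("k-means partitioning: degenerate k and blob recovery", {
  blobs <- make_blobs(n_per = 8, seed = 9)
  m <- t(unclass(blobs$x))

  k1 <- kmeans_partition(blobs$x, 1, seed = 2)
  tss <- sum(sweep(m, 2, colMeans(m))^2)
  expect_equal(unname(k1$wss), tss, tolerance = 1e-9)

  kn <- kmeans_partition(blobs$x, ncol(blobs$x), seed = 2)
  expect_equal(unname(kn$wss), 0)
  expect_error(kmeans_partition(blobs$x, 99, seed = 2), class = "lutd_invalid_k")

  k3 <- kmeans_partition(blobs$x, 3, seed = 2)
  expect_equal(adjusted_rand_index(k3$assignments[["3"]], blobs$truth), 1)

  # pam shares the contract
  p3 <- pam_partition(blobs$x, 3)
  expect_equal(adjusted_rand_index(p3$assignments[["3"]], blobs$truth), 1)

  # determinism
  expect_identical(kmeans_partition(blobs$x, 3, seed = 7)$assignments,
                   kmeans_partition(blobs$x, 3, seed = 7)$assignments)
})

test_that("elbow profile suggests k = 3 on three blobs and flags flat curves", {
  blobs <- make_blobs(n_per = 8, seed = 31)
  eb <- elbow_profile(blobs$x, seed = 5)
  expect_equal(eb$suggested_k, 3L)
  expect_false(eb$low_confidence)
  expect_true(all(diff(eb$wss) <= 1e-9)) # non-increasing in k

  set.seed(77)
  single <- make_expr(matrix(rnorm(5 * 24), 5, 24))
  eb1 <- elbow_profile(single, seed = 5)
  expect_true(eb1$low_confidence)
  expect_error(elbow_profile(single, k_range = 4), class = "lutd_invalid_k")
})

test_that("clustree transitions conserve mass and expose nested splits", {
  a1 <- rep(1L, 10)
  a2 <- rep(c(1L, 2L), c(6, 4))
  a3 <- c(rep(1L, 3), rep(3L, 3), rep(2L, 4)) # cluster 1 splits into 1 and 3
  tr <- clustree_transitions(list(`1` = a1, `2` = a2, `3` = a3))
  expect_equal(sum(tr$count[tr$k_from == 1]), 10)
  expect_equal(sum(tr$count[tr$k_from == 2]), 10)
  step2 <- tr[tr$k_from == 2, ]
  expect_equal(nrow(step2), 3L) # one split, one passthrough
  expect_setequal(step2$count, c(3L, 3L, 4L))

  # identical assignments produce an identity-like table
  tr2 <- clustree_transitions(list(`2` = a2, `3` = a2))
  expect_equal(nrow(tr2), 2L)
  expect_equal(tr2$cluster_from, tr2$cluster_to)

  expect_error(clustree_transitions(list(`1` = a1, `3` = a3)),
               class = "lutd_missing_k")
})

test_that("Mahalanobis distances honour the covariance geometry", {
  set.seed(12)
  x <- make_expr(matrix(rnorm(3 * 30), 3, 30), genes = c("A", "B", "C"))
  rep <- mahalanobis_from_centroid(x, c("A", "B", "C"))
  expect_true(all(rep$distances >= 0))

  # a sample placed exactly at the centroid has distance 0
  v <- unclass(x)
  v <- cbind(v, centroid = rep$centroid)
  rep2 <- mahalanobis_from_centroid(expression_matrix(v, "log2fc"), c("A", "B", "C"))
  expect_equal(unname(rep2$distances["centroid"]), 0, tolerance = 1e-9)

  # identity covariance: Mahalanobis equals Euclidean (standardised fixture)
  set.seed(3)
  z <- matrix(rnorm(2 * 500), 2, 500)
  z <- t(scale(t(z))) # unit sample variance
  z[2, ] <- z[2, ] - drop(cor(z[1, ], z[2, ])) * z[1, ] # decorrelate
  z[2, ] <- z[2, ] / sd(z[2, ])
  xz <- make_expr(z, genes = c("A", "B"))
  rz <- mahalanobis_from_centroid(xz, c("A", "B"))
  eu <- sqrt(colSums((z - rowMeans(z))^2))
  expect_equal(unname(rz$distances), unname(eu), tolerance = 1e-6)

  # diagonal covariance {4, 1}: a unit step on the first axis counts half
  n <- 2000
  set.seed(5)
  d2 <- rbind(rnorm(n, sd = 2), rnorm(n, sd = 1))
  d2 <- d2 - rowMeans(d2)
  xd <- make_expr(d2, genes = c("A", "B"))
  rd <- mahalanobis_from_centroid(xd, c("A", "B"))
  S <- cov(t(d2))
  probe <- c(1, 0) # one unit along the first axis
  expect_equal(sqrt(drop(t(probe) %*% solve(S) %*% probe)), 0.5, tolerance = 0.05)

  expect_error(mahalanobis_from_centroid(x, c("A", "Z")),
               class = "lutd_missing_gene")
  sing <- make_expr(rbind(z[1, 1:10], z[1, 1:10] * 2), genes = c("A", "B"))
  expect_error(mahalanobis_from_centroid(sing, c("A", "B")),
               class = "lutd_singular_covariance")
})

test_that("k-means dimension contributions rank informative genes first", {
  g <- generate_qpcr_like(synthetic_config(preset = "planted3",
                                           effect_size = 2.0, seed = 42))
  kc <- kmeans_dimension_contributions(g$matrix, k = 2, seed = 42)
  expect_equal(sum(kc), 100, tolerance = 1e-9)
  expect_setequal(names(sort(-kc))[1:3], c("TPPP3", "FAT1", "NCALD"))
})
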