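#' PCA with explained variance and variable contributions
#'
#' Singular-value decomposition of the centred (and by default scaled)
#' samples-by-genes matrix: samples are observations, genes are variables
#' (set `observations = "genes"` for the transposed analysis). Contributions
#' are `100 * loading^2 / sum(loading^2)` per component, as in the standard
#' variable-contribution decomposition.
#'
#' @param x a `lutd_expr` matrix (genes x samples).
#' @param scale scale genes to unit variance (requires nonzero sd).
#' @param observations `"samples"` (default) or `"genes"`.
#' @return list of class `lutd_pca`: `scores` (observations x PCs),
#'   `loadings` (variables x PCs), `explained_variance_pct`,
#'   `contributions_pct` (variables x PCs, columns sum to 100).
#' @export
pca_decompose <- function(x, scale = TRUE, observations = c("samples", "genes")) {
  observations <- match.arg(observations)
  v <- unclass(x)
  m <- if (observations == "samples") t(v) else v
  if (nrow(m) < 2 || ncol(m) < 2)
    stop_lutd("lutd_too_few_samples", "need >= 2 observations and >= 2 variables")
  if (scale) {
    sds <- apply(m, 2, sd)
    if (any(sds == 0))
      stop_lutd("lutd_zero_variance", "zero-variance variable(s): %s",
                paste(colnames(m)[sds == 0], collapse = ", "))
  }
  pc <- prcomp(m, center = TRUE, scale. = scale)
  ev <- pc$sdev^2
  ev_pct <- 100 * ev / sum(ev)
  contrib <- 100 * sweep(pc$rotation^2, 2, colSums(pc$rotation^2), "/")
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained_variance_pct = ev_pct,
                 contributions_pct = contrib),
            class = "lutd_pca")
}

# distance helper shared by hierarchical clustering
expr_distance <- function(m, distance) {
  if (distance == "one_minus_pearson") {
    sds <- apply(m, 1, sd)
    if (any(sds == 0))
      stop_lutd("lutd_zero_variance", "constant vector(s) under Pearson distance: %s",
                paste(rownames(m)[sds == 0], collapse = ", "))
    as.dist(1 - cor(t(m)))
  } else {
    dist(m, method = "euclidean")
  }
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering with average linkage (UPGMA by default) on either
#' a one-minus-Pearson-correlation or Euclidean distance between samples.
#' The full merge history is retained and the tree can be cut at any k.
#'
#' @param x a `lutd_expr` matrix (samples are clustered).
#' @param distance `"one_minus_pearson"` or `"euclidean"`.
#' @param linkage linkage method passed to the agglomeration.
#' @param k_range cluster counts for which assignments are precomputed.
#' @return `lutd_clustering` list: `method`, `assignments` (named list by k),
#'   `merge_heights`, `hclust` (the tree), `wss` per k.
#' @export
hierarchical_cluster <- function(x, distance = c("one_minus_pearson", "euclidean"),
                                 linkage = "average", k_range = NULL) {
  distance <- match.arg(distance)
  m <- t(unclass(x)) # samples in rows
  if (nrow(m) < 2) stop_lutd("lutd_too_few_samples", "need >= 2 samples")
  d <- expr_distance(m, distance)
  hc <- hclust(d, method = linkage)
  n <- nrow(m)
  ks <- k_range %||% seq_len(n)
  assignments <- lapply(ks, function(k) cutree(hc, k = k))
  names(assignments) <- as.character(ks)
  wss <- vapply(assignments, function(a) total_wss(m, a), numeric(1))
  structure(list(method = "hierarchical", assignments = assignments,
                 merge_heights = hc$height, hclust = hc, wss = wss,
                 distance = distance, linkage = linkage),
            class = "lutd_clustering")
}

#' @rdname hierarchical_cluster
#' @param k number of clusters.
#' @param result a `lutd_clustering` from [hierarchical_cluster()].
#' @export
cut_tree <- function(result, k) {
  if (is.null(result$hclust)) stop_lutd("lutd_invalid_input", "not a hierarchical result")
  cutree(result$hclust, k = k)
}

total_wss <- function(m, assignment) {
  sum(vapply(unique(assignment), function(cl) {
    sub <- m[assignment == cl, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1)))
}

#' k-means partitioning of samples
#'
#' Best of `n_init` seeded restarts by total within-cluster sum of squares;
#' deterministic given the seed. Squared Euclidean distance on the values as
#' given (scale upstream if desired).
#'
#' @param x a `lutd_expr` matrix (samples are partitioned).
#' @param k number of clusters, 1 <= k <= n.
#' @param n_init random restarts.
#' @param seed integer seed.
#' @return `lutd_clustering` list with `assignments[[as.character(k)]]`,
#'   `wss`, `centers`.
#' @export
kmeans_partition <- function(x, k, n_init = 25L, seed = 1L) {
  m <- t(unclass(x))
  n <- nrow(m)
  if (k < 1 || k > n) stop_lutd("lutd_invalid_k", "k must lie in [1, %d], got %d", n, k)
  if (k == n) { # every sample its own cluster; stats::kmeans rejects k = n
    a <- setNames(seq_len(n), rownames(m))
    return(structure(list(method = "kmeans",
                          assignments = setNames(list(a), as.character(k)),
                          wss = setNames(0, as.character(k)), centers = m),
                     class = "lutd_clustering"))
  }
  km <- with_seed(seed, kmeans(m, centers = k, nstart = n_init, iter.max = 50))
  a <- setNames(km$cluster, rownames(m))
  structure(list(method = "kmeans",
                 assignments = setNames(list(a), as.character(k)),
                 wss = setNames(km$tot.withinss, as.character(k)),
                 centers = km$centers),
            class = "lutd_clustering")
}

#' Partitioning around medoids (PAM)
#'
#' Alternative partitioner sharing the clustering contract; deterministic.
#'
#' @inheritParams kmeans_partition
#' @return `lutd_clustering` list.
#' @export
pam_partition <- function(x, k) {
  m <- t(unclass(x))
  n <- nrow(m)
  if (k < 1 || k > n) stop_lutd("lutd_invalid_k", "k must lie in [1, %d], got %d", n, k)
  pm <- cluster::pam(m, k = k)
  a <- setNames(pm$clustering, rownames(m))
  structure(list(method = "pam",
                 assignments = setNames(list(a), as.character(k)),
                 wss = setNames(total_wss(m, a), as.character(k)),
                 medoids = pm$medoids),
            class = "lutd_clustering")
}

#' Elbow profile: WSS over a k range with a suggested k
#'
#' Runs [kmeans_partition()] over `k_range` (default 2..7) and reports the
#' within-cluster sum of squares per k. The suggested k sits at the maximal
#' curvature (largest second difference of the WSS curve, computed over the
#' curve extended with k = 1, the total sum of squares). The elbow is chosen
#' visually in practice, so the suggestion is advisory: when the curvature
#' profile is nearly flat (max second difference < 20% of the initial WSS
#' drop) the suggestion is flagged low-confidence.
#'
#' @param x a `lutd_expr` matrix.
#' @param k_range integer vector of cluster counts (default `2:7`).
#' @param n_init,seed passed to [kmeans_partition()].
#' @return list: `wss` (named by k, including k = 1), `suggested_k`,
#'   `low_confidence`, `assignments` per k, class `lutd_elbow`.
#' @export
elbow_profile <- function(x, k_range = 2:7, n_init = 25L, seed = 1L) {
  k_range <- sort(unique(as.integer(k_range)))
  n <- ncol(x)
  if (length(k_range) < 2 || any(k_range < 1) || any(k_range > n))
    stop_lutd("lutd_invalid_k", "degenerate k range")
  m <- t(unclass(x))
  ks <- union(1L, k_range)
  fits <- lapply(ks, function(k) kmeans_partition(x, k, n_init = n_init,
                                                  seed = derive_seed(seed, k)))
  wss <- vapply(fits, function(f) unname(f$wss), numeric(1))
  names(wss) <- ks
  # enforce monotone non-increasing WSS: restart jitter can leave a worse
  # solution at larger k; reuse the better smaller-k partition in that case
  for (i in seq_along(ks)[-1]) if (wss[i] > wss[i - 1]) {
    fits[[i]] <- fits[[i - 1]]
    wss[i] <- wss[i - 1]
  }
  second_diff <- if (length(ks) >= 3)
    wss[seq_len(length(ks) - 2)] - 2 * wss[seq_along(ks)[-c(1, length(ks))]] +
      wss[seq_along(ks)[-(1:2)]]
  else setNames(numeric(0), character(0))
  if (length(second_diff) == 0) {
    suggested <- ks[length(ks)]
    low_conf <- TRUE
  } else {
    suggested <- ks[which.max(second_diff) + 1L]
    # confidence heuristic: a real elbow's curvature dominates the background
    # curvature of the WSS curve by an order of magnitude; smooth single-blob
    # curves stay within a small factor of their median curvature
    low_conf <- max(second_diff) < 10 * median(abs(second_diff))
  }
  assignments <- lapply(fits, function(f) f$assignments[[1]])
  names(assignments) <- ks
  structure(list(wss = wss, suggested_k = as.integer(suggested),
                 low_confidence = low_conf, assignments = assignments),
            class = "lutd_elbow")
}

#' Cluster-transition (clustree-style) table between consecutive k
#'
#' For each pair of consecutive cluster counts, counts how many samples move
#' from each cluster at k to each cluster at k + 1. Row sums at each k equal
#' the sample count, so mass is conserved along the tree.
#'
#' @param assignments named list of assignment vectors, names = k.
#' @return data.frame: `k_from`, `cluster_from`, `k_to`, `cluster_to`, `count`.
#' @export
clustree_transitions <- function(assignments) {
  ks <- sort(as.integer(names(assignments)))
  if (length(ks) < 2) stop_lutd("lutd_invalid_input", "need assignments for >= 2 consecutive k")
  if (any(diff(ks) != 1))
    stop_lutd("lutd_missing_k", "missing k level(s) in %s", paste(ks, collapse = ","))
  out <- list()
  for (i in seq_len(length(ks) - 1)) {
    a <- assignments[[as.character(ks[i])]]
    b <- assignments[[as.character(ks[i + 1])]]
    tb <- table(a, b)
    idx <- which(tb > 0, arr.ind = TRUE)
    out[[i]] <- data.frame(
      k_from = ks[i], cluster_from = as.integer(rownames(tb))[idx[, 1]],
      k_to = ks[i + 1], cluster_to = as.integer(colnames(tb))[idx[, 2]],
      count = as.integer(tb[idx]), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Mahalanobis distance of each sample from a marker-subspace centroid
#'
#' Distances are computed in the subspace spanned by the requested genes
#' (three markers for the confidence-ellipsoid view), using the sample mean
#' and covariance of that subspace: `d(s) = sqrt((v - mu)' Sigma^-1 (v - mu))`.
#'
#' @param x a `lutd_expr` matrix.
#' @param genes gene subset (typically 3).
#' @return list: `distances` (named per sample), `centroid`, `covariance`;
#'   class `lutd_mahalanobis`.
#' @export
mahalanobis_from_centroid <- function(x, genes) {
  v <- unclass(x)
  miss <- setdiff(genes, rownames(v))
  if (length(miss) > 0)
    stop_lutd("lutd_missing_gene", "gene(s) not in matrix: %s", paste(miss, collapse = ", "))
  m <- t(v[genes, , drop = FALSE])
  if (nrow(m) < length(genes) + 1)
    stop_lutd("lutd_too_few_samples", "need >= %d samples", length(genes) + 1)
  mu <- colMeans(m)
  S <- cov(m)
  if (rcond_safe(S) < 1e-12)
    stop_lutd("lutd_singular_covariance",
              "singular covariance in subspace {%s}; consider a regularized estimate (off by default)",
              paste(genes, collapse = ", "))
  d2 <- mahalanobis(m, mu, S)
  structure(list(distances = setNames(sqrt(pmax(d2, 0)), rownames(m)),
                 centroid = mu, covariance = S),
            class = "lutd_mahalanobis")
}

rcond_safe <- function(S) tryCatch(1 / kappa(S, exact = TRUE), error = function(e) 0)

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between clusterings, used to score cluster
#' recovery against planted truth (1 = identical partitions up to labels).
#'
#' @param a,b integer/character assignment vectors of equal length.
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_lutd("lutd_invalid_input", "length mismatch")
  tb <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tb))
  sum_a <- sum(comb2(rowSums(tb)))
  sum_b <- sum(comb2(colSums(tb)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Per-gene contribution to a k-means partition
#'
#' Share of between-cluster variance carried by each gene (percent, summing
#' to 100) for a k-means partition of the samples on standardised values.
#' This ranking is driven directly by cluster-mean separation and
#' complements the PCA loadings-based contributions as unsupervised evidence
#' for marker candidacy.
#'
#' @param x a `lutd_expr` matrix.
#' @param k number of clusters.
#' @param n_init,seed passed to [kmeans_partition()].
#' @return named numeric vector (percent per gene).
#' @export
kmeans_dimension_contributions <- function(x, k = 3, n_init = 25L, seed = 1L) {
  v <- t(unclass(x))
  v <- scale(v)
  xs <- expression_matrix(t(v), expr_unit(x))
  km <- kmeans_partition(xs, k, n_init = n_init, seed = seed)
  a <- km$assignments[[1]]
  bss <- vapply(colnames(v), function(g) {
    gm <- mean(v[, g])
    sum(vapply(unique(a), function(cl)
      sum(a == cl) * (mean(v[a == cl, g]) - gm)^2, numeric(1)))
  }, numeric(1))
  100 * bss / sum(bss)
}
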