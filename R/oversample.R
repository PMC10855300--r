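#' Oversampler roster
#'
#' The three minority-class oversamplers of the evaluation grid:
#' Borderline-SMOTE, SVM-SMOTE and the Random Over Sampler. All three
#' equalise class counts by appending synthetic (or duplicated) rows to the
#' minority class, leaving every original row untouched. SMOTE-family rows
#' are convex combinations of two minority samples, so each synthetic
#' coordinate lies componentwise between its parents.
#'
#' @return character vector of oversampler ids.
#' @export
oversampler_ids <- function() c("BorderlineSMOTE", "SVMSMOTE", "RandomOverSampler")

#' Oversample a training fold to balance classes
#'
#' Must only ever be applied to the training portion of a CV fold: fitting an
#' oversampler before splitting leaks synthetic copies of test samples into
#' training, the classic small-cohort failure mode.
#'
#' Methods:
#' \describe{
#'   \item{RandomOverSampler}{duplicates randomly chosen minority rows.}
#'   \item{BorderlineSMOTE}{(borderline-1) seeds synthesis from minority
#'     samples whose m-neighbourhood (m = `m_danger`, over all samples) is
#'     majority-dominated but not pure; interpolates toward random minority
#'     neighbours. Falls back to all minority samples (with a warning) when
#'     the danger set is empty.}
#'   \item{SVMSMOTE}{seeds synthesis from minority samples inside the margin
#'     of a linear SVM fitted to the fold (margin < 1); interpolation only,
#'     so the convexity contract of the SMOTE family holds. Falls back to all
#'     minority samples when no minority point is inside the margin.}
#' }
#' If the minority class is smaller than `k_neighbors + 1`, the neighbour
#' count is reduced with a warning; fewer than 2 minority samples is an error.
#'
#' @param features numeric matrix, samples x features.
#' @param labels logical or two-level vector; the rarer level is oversampled.
#' @param method oversampler id.
#' @param seed integer seed.
#' @param k_neighbors minority neighbours used for interpolation (default 5).
#' @param m_danger neighbourhood size for the borderline danger test.
#' @return list with `features`, `labels` (originals first, in input order),
#'   and `synthetic` (logical marker for appended rows).
#' @export
oversample_training_fold <- function(features, labels,
                                     method = oversampler_ids(), seed = 1L,
                                     k_neighbors = 5L, m_danger = 5L) {
  method <- match.arg(method)
  features <- as.matrix(features)
  lv <- unique(labels)
  if (length(lv) != 2) stop_lutd("lutd_invalid_input", "need exactly two classes")
  cnt <- table(factor(labels, levels = lv))
  minority <- lv[which.min(cnt)]
  n_new <- max(cnt) - min(cnt)
  if (n_new == 0)
    return(list(features = features, labels = labels,
                synthetic = rep(FALSE, nrow(features))))
  min_idx <- which(labels == minority)
  n_min <- length(min_idx)
  if (n_min < 2)
    stop_lutd("lutd_minority_too_small", "minority class has %d sample(s); need >= 2", n_min)

  if (method == "RandomOverSampler") {
    pick <- with_seed(seed, sample(min_idx, n_new, replace = TRUE))
    new_rows <- features[pick, , drop = FALSE]
  } else {
    if (n_min - 1 < k_neighbors) {
      k_neighbors <- n_min - 1L
      warn_lutd("minority class too small for requested neighbours; reduced to %d", k_neighbors)
    }
    seeds_idx <- smote_seed_points(features, labels, minority, method, m_danger)
    if (length(seeds_idx) == 0) {
      warn_lutd("no %s seed points found; falling back to all minority samples",
                if (method == "BorderlineSMOTE") "danger-zone" else "in-margin")
      seeds_idx <- min_idx
    }
    new_rows <- with_seed(seed, {
      out <- matrix(NA_real_, n_new, ncol(features))
      picks <- sample(seeds_idx, n_new, replace = TRUE)
      for (j in seq_len(n_new)) {
        s <- picks[j]
        # nearest minority neighbours of the seed (excluding itself),
        # ties broken lowest-index-first for reproducibility
        d <- colSums((t(features[min_idx, , drop = FALSE]) - features[s, ])^2)
        ord <- min_idx[order(d, seq_along(d))]
        nn <- setdiff(ord, s)[seq_len(k_neighbors)]
        nb <- nn[sample.int(length(nn), 1)]
        u <- runif(1)
        out[j, ] <- features[s, ] + u * (features[nb, ] - features[s, ])
      }
      out
    })
  }
  colnames(new_rows) <- colnames(features)
  lab_new <- if (is.factor(labels)) factor(rep(minority, n_new), levels = levels(labels))
             else rep(minority, n_new)
  list(features = rbind(features, new_rows),
       labels = c(labels, lab_new),
       synthetic = c(rep(FALSE, nrow(features)), rep(TRUE, n_new)))
}

smote_seed_points <- function(features, labels, minority, method, m_danger) {
  min_idx <- which(labels == minority)
  if (method == "BorderlineSMOTE") {
    m <- min(m_danger, nrow(features) - 1L)
    keep <- logical(length(min_idx))
    for (i in seq_along(min_idx)) {
      s <- min_idx[i]
      d <- colSums((t(features) - features[s, ])^2)
      d[s] <- Inf
      nn <- order(d, seq_along(d))[seq_len(m)]
      n_maj <- sum(labels[nn] != minority)
      keep[i] <- n_maj >= m / 2 && n_maj < m # danger, not noise
    }
    min_idx[keep]
  } else {
    y <- labels == minority
    # standardise for the margin fit only; seeds are original rows
    mu <- colMeans(features); sdv <- apply(features, 2, sd); sdv[sdv == 0] <- 1
    Z <- sweep(sweep(features, 2, mu), 2, sdv, "/")
    svm <- fit_svm(Z, y, C = 1, kernel = "linear")
    margin <- ifelse(y, 1, -1) * (drop(Z %*% svm$w) + svm$b)
    min_idx[margin[min_idx] < 1]
  }
}
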