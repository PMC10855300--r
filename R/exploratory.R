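#' Per-gene z-score deviation profile with High/Low calls
#'
#' For each gene, samples are standardised across the cohort using the sample
#' (n-1) standard deviation: `z = (x - mean) / sd`. Samples with z > 0 are
#' called `High`, otherwise `Low` (z = 0 classified Low for determinism — a
#' measure-zero event on continuous data). A constant gene has no defined
#' z-score and is an error.
#'
#' @param x a `lutd_expr` matrix.
#' @return list with `z` (genes x samples matrix) and `call` (character
#'   matrix `"High"`/`"Low"` of the same shape), class `lutd_zscore`.
#' @export
zscore_profile <- function(x) {
  v <- unclass(x)
  sds <- apply(v, 1, sd)
  if (any(sds == 0))
    stop_lutd("lutd_zero_variance", "zero-variance gene(s): %s",
              paste(rownames(v)[sds == 0], collapse = ", "))
  z <- (v - rowMeans(v)) / sds
  calls <- ifelse(z > 0, "High", "Low")
  dimnames(calls) <- dimnames(z)
  structure(list(z = z, call = calls), class = "lutd_zscore")
}

#' Evaluate the empirical cumulative distribution function
#'
#' Fraction of observations less than or equal to `threshold` — the standard
#' weak-inequality ECDF convention `P(X <= x)`.
#'
#' @param values non-empty numeric vector.
#' @param threshold evaluation point(s).
#' @return fraction(s) in \[0, 1\].
#' @export
ecdf_eval <- function(values, threshold) {
  if (length(values) == 0)
    stop_lutd("lutd_empty_input", "ecdf_eval needs a non-empty vector")
  vapply(threshold, function(t) mean(values <= t), numeric(1))
}

#' ECDF curve as a table
#'
#' @param values non-empty numeric vector.
#' @return data.frame with sorted unique `value` and cumulative `fraction`.
#' @export
ecdf_curve <- function(values) {
  if (length(values) == 0)
    stop_lutd("lutd_empty_input", "ecdf_curve needs a non-empty vector")
  u <- sort(unique(values))
  data.frame(value = u, fraction = ecdf_eval(values, u))
}

#' Gene-by-gene Pearson correlogram with significance
#'
#' Pairwise Pearson correlations across samples plus two-sided p-values from
#' the t-distribution, `t = r * sqrt((n-2) / (1-r^2))` on n-2 degrees of
#' freedom. The export adds significance stars at 0.05/0.01/0.001.
#'
#' @param x a `lutd_expr` matrix with >= 3 samples.
#' @return list with matrices `r` and `p` (unit diagonal, symmetric) and a
#'   long-format `stars` data.frame; class `lutd_correlogram`.
#' @export
correlation_report <- function(x) {
  v <- unclass(x)
  n <- ncol(v)
  if (n < 3) stop_lutd("lutd_too_few_samples", "need >= 3 samples, got %d", n)
  sds <- apply(v, 1, sd)
  if (any(sds == 0))
    stop_lutd("lutd_zero_variance", "zero-variance gene(s): %s",
              paste(rownames(v)[sds == 0], collapse = ", "))
  r <- cor(t(v))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  stars <- data.frame(
    gene_a = rownames(r)[pairs[, 1]], gene_b = colnames(r)[pairs[, 2]],
    r = r[pairs], p = p[pairs],
    stars = cut(p[pairs], c(-Inf, 0.001, 0.01, 0.05, Inf),
                labels = c("***", "**", "*", "")),
    stringsAsFactors = FALSE)
  structure(list(r = r, p = p, stars = stars), class = "lutd_correlogram")
}

#' Shapiro-Wilk normality assessment
#'
#' Delegates to the standard Shapiro-Wilk routine; the verdict is `"normal"`
#' when p >= 0.05.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list with `statistic`, `p_value`, `verdict`.
#' @export
normality_assess <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000)
    stop_lutd("lutd_invalid_n", "Shapiro-Wilk needs 3 <= n <= 5000, got %d", n)
  sw <- shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       verdict = if (sw$p.value >= 0.05) "normal" else "non-normal")
}

#' Per-gene group-difference tests
#'
#' Two modes. `kruskal_wallis_pairwise`: Kruskal-Wallis omnibus per gene,
#' followed by pairwise Wilcoxon rank-sum tests with Benjamini-Hochberg
#' adjustment. `anova_tukey`: one-way ANOVA with Tukey HSD pairwise
#' comparisons. Significance is declared at p < 0.05.
#'
#' @param x a `lutd_expr` matrix.
#' @param annotation a sample annotation; every group needs >= 2 samples.
#' @param mode `"kruskal_wallis_pairwise"` or `"anova_tukey"`.
#' @return list with `omnibus` (gene, statistic, p_value, significant) and
#'   `pairwise` (gene, comparison, p_value, significant) data.frames.
#' @export
group_difference_tests <- function(x, annotation,
                                   mode = c("kruskal_wallis_pairwise", "anova_tukey")) {
  mode <- match.arg(mode)
  grp <- align_annotation(x, annotation, min_per_group = 2L)
  if (nlevels(grp) < 2)
    stop_lutd("lutd_too_few_groups", "need >= 2 groups")
  v <- unclass(x)
  omni <- vector("list", nrow(v)); pw <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    g <- rownames(v)[i]; y <- v[i, ]
    if (mode == "kruskal_wallis_pairwise") {
      kt <- suppressWarnings(kruskal.test(y, grp))
      stat <- unname(kt$statistic)
      pval <- kt$p.value
      # all-tied boundary: the tie correction divides by zero; report 0 / 1
      if (is.na(stat)) stat <- 0
      if (is.na(pval)) pval <- 1
      pwt <- suppressWarnings(
        pairwise.wilcox.test(y, grp, p.adjust.method = "BH", exact = FALSE))
      m <- pwt$p.value
      # structural cells are the lower triangle (incl. diagonal) of the
      # (k-1) x (k-1) layout; an all-tied comparison computes NA -> p = 1
      cmp <- which(row(m) >= col(m), arr.ind = TRUE)
      pvals <- m[cmp]
      pvals[is.na(pvals)] <- 1
      pw[[i]] <- data.frame(
        gene = rep(g, nrow(cmp)),
        comparison = paste(rownames(m)[cmp[, 1]], colnames(m)[cmp[, 2]], sep = "_vs_"),
        p_value = pvals, stringsAsFactors = FALSE)
    } else {
      fit <- aov(y ~ grp)
      sm <- summary(fit)[[1]]
      stat <- sm$`F value`[1]
      pval <- sm$`Pr(>F)`[1]
      if (is.na(pval)) { stat <- 0; pval <- 1 }
      tk <- TukeyHSD(fit)$grp
      pw[[i]] <- data.frame(
        gene = g,
        comparison = gsub("-", "_vs_", rownames(tk)),
        p_value = tk[, "p adj"], stringsAsFactors = FALSE, row.names = NULL)
    }
    omni[[i]] <- data.frame(gene = g, statistic = stat, p_value = pval,
                            stringsAsFactors = FALSE)
  }
  omnibus <- do.call(rbind, omni)
  pairwise <- do.call(rbind, pw)
  omnibus$significant <- omnibus$p_value < 0.05
  pairwise$significant <- pairwise$p_value < 0.05
  list(omnibus = omnibus, pairwise = pairwise, mode = mode)
}
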