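test_that("z-score profile standardises and calls High/Low", {
  x <- make_expr(matrix(c(1, 2, 3), 1, 3))
  z <- zscore_profile(x)
  expect_equal(unname(z$z[1, ]), c(-1, 0, 1)) # sample (n-1) sd
  expect_equal(unname(z$call[1, ]), c("Low", "Low", "High")) # z = 0 is Low

  expect_error(zscore_profile(make_expr(matrix(2, 1, 3))),
               class = "lutd_zero_variance")

  set.seed(5)
  big <- make_expr(matrix(rnorm(13 * 20), 13, 20))
  zz <- zscore_profile(big)$z
  expect_true(all(abs(rowMeans(zz)) < 1e-9))
  expect_true(all(abs(apply(zz, 1, sd) - 1) < 1e-9))
})

test_that("strong BPS up-shift yields mostly High calls in BPS", {
  hits <- 0
  for (s in 1:20) {
    g <- generate_qpcr_like(synthetic_config(effect_size = 2.0, seed = 400 + s))
    z <- zscore_profile(g$matrix)
    bps <- g$annotation$sample_id[g$annotation$group == "BPS"]
    if (mean(z$call["TPPP3", bps] == "High") > 0.8) hits <- hits + 1
  }
  expect_gte(hits, 18) # >80% High in >=90% of seeds
})

test_that("ECDF evaluation and curve", {
  v <- c(1, 2, 2, 4)
  expect_equal(ecdf_eval(v, 2), 0.75)
  expect_equal(ecdf_eval(v, max(v)), 1)
  expect_equal(ecdf_eval(v, min(v) - 1), 0)
  expect_error(ecdf_eval(numeric(0), 1), class = "lutd_empty_input")

  cur <- ecdf_curve(v)
  expect_equal(cur$value, c(1, 2, 4))
  expect_true(all(diff(cur$fraction) > 0))
  expect_equal(cur$fraction[length(cur$fraction)], 1)

  # mean ECDF over the sample points equals (n+1)/(2n) for distinct values
  set.seed(8)
  u <- rnorm(25)
  expect_equal(mean(ecdf_eval(u, u)), (25 + 1) / (2 * 25))
})

test_that("correlation report matches a brute-force oracle", {
  set.seed(2)
  x <- make_expr(matrix(rnorm(4 * 5), 4, 5))
  rep <- correlation_report(x)
  expect_equal(diag(rep$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(rep$r, t(rep$r))

  # brute-force covariance / (sd * sd) on one pair
  a <- unclass(x)[1, ]; b <- unclass(x)[2, ]
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) / (4 * sd(a) * sd(b))
  expect_equal(rep$r[1, 2], r_oracle, tolerance = 1e-12)
  # p-value against cor.test
  ct <- cor.test(a, b)
  expect_equal(rep$p[1, 2], ct$p.value, tolerance = 1e-9)

  # exact anticorrelation
  y <- make_expr(rbind(a, -a, b))
  expect_equal(correlation_report(y)$r[1, 2], -1)

  # positive semidefinite up to tolerance
  ev <- eigen(rep$r, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-10)

  expect_error(correlation_report(make_expr(matrix(1:4, 2, 2))),
               class = "lutd_too_few_samples")
  expect_error(correlation_report(make_expr(rbind(a, rep(1, 5)))),
               class = "lutd_zero_variance")
})

test_that("normality assessment discriminates normal from exponential", {
  normal_ok <- 0; exp_ok <- 0
  for (s in 1:100) {
    set.seed(s)
    if (normality_assess(rnorm(200))$verdict == "normal") normal_ok <- normal_ok + 1
    if (normality_assess(rexp(200))$verdict == "non-normal") exp_ok <- exp_ok + 1
  }
  expect_gte(normal_ok, 95)
  expect_gte(exp_ok, 95)
  expect_error(normality_assess(c(1, 2)), class = "lutd_invalid_n")
  expect_error(normality_assess(rnorm(5001)), class = "lutd_invalid_n")
})

test_that("group difference tests: boundaries, power, synthetic truth", {
  ann <- sample_annotation(paste0("S", 1:9),
                           rep(c("Control", "BPS", "DO"), each = 3))
  flat <- make_expr(matrix(5, 1, 9))
  kw <- group_difference_tests(flat, ann, "kruskal_wallis_pairwise")
  expect_equal(kw$omnibus$statistic, 0)
  expect_equal(kw$omnibus$p_value, 1)

  # three groups of 6 separated by 5 sd: omnibus significant in both modes
  set.seed(21)
  x <- make_expr(matrix(rnorm(18) + rep(c(0, 5, 10), each = 6), 1, 18))
  ann18 <- sample_annotation(paste0("S", 1:18), rep(c("Control", "BPS", "DO"), each = 6))
  for (mode in c("kruskal_wallis_pairwise", "anova_tukey")) {
    res <- group_difference_tests(x, ann18, mode)
    expect_lt(res$omnibus$p_value, 0.05)
    expect_equal(nrow(res$pairwise), 3L)
    expect_true(all(res$pairwise$significant))
  }

  expect_error(group_difference_tests(x, sample_annotation(
    paste0("S", 1:18), rep(c("Control", "BPS"), c(17, 1)))),
    class = "lutd_small_group")

  # generator truth: informative genes significant BPS vs Control, MFAP5 not
  agree <- 0
  for (s in 1:20) {
    g <- generate_qpcr_like(synthetic_config(seed = 600 + s))
    keep <- g$annotation$group %in% c("BPS", "Control")
    x2 <- expression_matrix(unclass(g$matrix)[c("TPPP3", "NCALD", "MFAP5"), keep],
                            "log2fc")
    ann2 <- sample_annotation(g$annotation$sample_id[keep],
                              as.character(g$annotation$group[keep]))
    res <- group_difference_tests(x2, ann2, "kruskal_wallis_pairwise")$omnibus
    ok <- res$significant[res$gene %in% c("TPPP3", "NCALD")]
    if (all(ok) && !res$significant[res$gene == "MFAP5"]) agree <- agree + 1
  }
  expect_gte(agree, 18) # >= 90% of 20 seeds
})
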