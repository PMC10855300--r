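test_that("expression matrix validation is total", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("TPPP3", "FAT1"), c("s1", "s2", "s3")))
  x <- expression_matrix(m, "read_count")
  expect_s3_class(x, "lutd_expr")
  expect_identical(expr_unit(x), "read_count")

  bad <- m; rownames(bad) <- c("TPPP3", "TPPP3")
  expect_error(expression_matrix(bad, "read_count"), "TPPP3",
               class = "lutd_duplicate_id")
  bad <- m; bad[1, 2] <- NA
  expect_error(expression_matrix(bad, "read_count"), class = "lutd_missing_value")
  bad <- m; bad[2, 1] <- -4
  expect_error(expression_matrix(bad, "read_count"), class = "lutd_invalid_value")
  expect_error(expression_matrix(unname(m), "ct"), class = "lutd_invalid_matrix")
})

test_that("read_expression_matrix parses TSV/CSV and reports bad cells", {
  p <- write_tmp(c("gene\ts1\ts2", "TPPP3\t1.5\t2.5", "FAT1\t-0.3\t0.25"))
  x <- read_expression_matrix(p, "log2fc")
  expect_equal(dim(x), c(2L, 2L))
  expect_equal(unclass(x)["FAT1", "s2"], 0.25)

  pc <- write_tmp(c("gene,s1,s2", "TPPP3,1,2", "FAT1,3,4"), ".csv")
  expect_equal(unclass(read_expression_matrix(pc, "read_count"))["FAT1", "s1"], 3)

  dup <- write_tmp(c("gene\ts1", "TPPP3\t1", "TPPP3\t2"))
  expect_error(read_expression_matrix(dup, "read_count"), "TPPP3")

  bad <- write_tmp(c("gene\ts1\ts2", "TPPP3\t1\tx", "FAT1\t3\t4"))
  err <- tryCatch(read_expression_matrix(bad, "read_count"), error = identity)
  expect_match(conditionMessage(err), "TPPP3")
  expect_match(conditionMessage(err), "s2")

  amb <- write_tmp(c("gene\ts1,s2", "TPPP3\t1,2"))
  expect_error(read_expression_matrix(amb, "read_count"),
               class = "lutd_ambiguous_delim")
})

test_that("round-trip through write_table preserves values", {
  set.seed(7)
  x <- make_expr(matrix(rnorm(13 * 8), 13, 8))
  p <- tempfile(fileext = ".tsv")
  write_table(unclass(x), p)
  y <- read_expression_matrix(p, "log2fc")
  expect_equal(unclass(y), signif(unclass(x), 6), tolerance = 1e-6)
  expect_identical(dimnames(y), dimnames(x))

  df <- data.frame(a = c("x", "y"), b = c(1.234567891, 2))
  p2 <- tempfile(fileext = ".tsv")
  write_table(df, p2)
  back <- read.delim(p2)
  expect_equal(back$b, signif(df$b, 6))

  empty <- data.frame(task = character(0), F1 = numeric(0))
  p3 <- tempfile(fileext = ".tsv")
  write_table(empty, p3)
  expect_equal(readLines(p3), "task\tF1")

  expect_error(write_table(df, file.path(tempdir(), "no", "such", "dir", "f.tsv")),
               class = "lutd_unwritable")
})

test_that("sample annotation enforces single-valued complete mapping", {
  p <- write_tmp(c("sample_id\tgroup",
                   paste(sprintf("C%02d", 1:14), "Control", sep = "\t"),
                   paste(sprintf("B%02d", 1:28), "BPS", sep = "\t"),
                   paste(sprintf("D%02d", 1:22), "DO", sep = "\t")))
  ann <- read_sample_annotation(p)
  expect_equal(as.vector(table(ann$group)), c(14L, 28L, 22L))

  expect_error(read_sample_annotation(write_tmp("sample_id\tgroup")),
               class = "lutd_empty_annotation")
  expect_error(
    sample_annotation(c("s1", "s1"), c("BPS", "DO")),
    class = "lutd_conflicting_annotation")
  # consistent duplicates collapse silently
  ann2 <- sample_annotation(c("s1", "s1", "s2"), c("BPS", "BPS", "DO"))
  expect_equal(nrow(ann2), 2L)
  expect_error(sample_annotation("s1", "Lesion"), class = "lutd_unknown_group")
  ext <- sample_annotation("s1", "Lesion", extensible = TRUE)
  expect_equal(as.character(ext$group), "Lesion")

  # matrix sample missing from annotation
  x <- make_expr(matrix(1:4, 2, 2), samples = c("s1", "sX"))
  ann3 <- sample_annotation(c("s1", "s2"), c("BPS", "DO"))
  expect_error(zscore_profile(x) -> ignored, NA) # zscore needs no annotation
  expect_error(group_difference_tests(x, ann3), class = "lutd_unannotated_sample")
})

test_that("DEG tables validate p-values and uniqueness", {
  d <- deg_table(c("A", "B"), c(1.2, -0.6), c(0.01, 0.2))
  expect_equal(nrow(d), 2L)
  expect_error(deg_table(c("A", "A"), c(1, 2), c(0.1, 0.2)),
               class = "lutd_duplicate_id")
  expect_error(deg_table("A", 1, 1.5), class = "lutd_invalid_value")
  p <- write_tmp(c("gene\tlog2fc\tpvalue", "A\t0.7\t0.01"))
  expect_equal(read_deg_table(p)$log2fc, 0.7)
})

test_that("run configuration validates and parses from file", {
  cfg <- run_config()
  expect_equal(cfg$cv_folds, 3L)
  expect_equal(cfg$cv_repeats, 10L)
  expect_equal(cfg$min_features, 3L)
  expect_equal(cfg$lfc_threshold, 0.5)
  expect_equal(cfg$p_threshold, 0.05)
  expect_equal(cfg$primary_metric, "F1")
  expect_length(cfg$classifiers, 12)
  expect_length(cfg$oversamplers, 3)

  expect_error(run_config(cv_folds = 1), class = "lutd_invalid_config")
  expect_error(run_config(min_features = 0), class = "lutd_invalid_config")
  expect_error(run_config(lfc_threshold = 0), class = "lutd_invalid_config")
  expect_error(run_config(classifiers = "XGB"), class = "lutd_invalid_config")

  p <- write_tmp(c("# comment", "cv_folds = 5", "cv_repeats: 2",
                   "classifiers = LR, LDA", "lfc_threshold = 1.0"))
  cfg2 <- read_run_config(p)
  expect_equal(cfg2$cv_folds, 5L)
  expect_equal(cfg2$classifiers, c("LR", "LDA"))
  expect_equal(cfg2$lfc_threshold, 1.0)
  expect_error(read_run_config(write_tmp("bogus_key = 1")),
               class = "lutd_invalid_config")
})
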