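#' Expression matrices, sample annotations, DEG tables and run configuration
#'
#' @description
#' The data model shared by every stage of the package. An expression matrix
#' is a genes-by-samples numeric matrix tagged with its measurement unit
#' (`"read_count"`, `"ct"` or `"log2fc"`); a sample annotation maps each
#' sample to a phenotype group (by default `Control`, `BPS`, `DO`); a DEG
#' table carries per-gene log2 fold changes and p-values from an upstream
#' differential-expression comparison.
#'
#' Validation is strict and total: duplicated identifiers, non-numeric cells,
#' missing values, negative read counts, or samples without annotation all
#' raise typed errors (condition class `lutd_error`). Nothing is imputed or
#' silently coerced, because every downstream statistic would change.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param unit one of `"read_count"`, `"ct"`, `"log2fc"`.
#' @return `expression_matrix()` returns a validated matrix of class
#'   `lutd_expr` with a `unit` attribute.
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("TPPP3", "FAT1"), c("s1", "s2", "s3"))), "read_count")
#' expr_unit(m)
#' @export
expression_matrix <- function(values, unit = c("log2fc", "read_count", "ct")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop_lutd("lutd_invalid_matrix", "values must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop_lutd("lutd_invalid_matrix", "matrix must have gene rownames and sample colnames")
  if (anyDuplicated(gid))
    stop_lutd("lutd_duplicate_id", "duplicated gene id(s): %s",
              paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop_lutd("lutd_duplicate_id", "duplicated sample id(s): %s",
              paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyNA(values)) {
    w <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop_lutd("lutd_missing_value", "missing value at gene '%s', sample '%s' (no imputation)",
              gid[w[1]], sid[w[2]])
  }
  if (unit == "read_count" && any(values < 0))
    stop_lutd("lutd_invalid_value", "read counts must be >= 0")
  structure(values, unit = unit, class = c("lutd_expr", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x a `lutd_expr` matrix.
#' @export
expr_unit <- function(x) attr(x, "unit")

# Detect tab vs comma; reject files where both occur in the header.
detect_delim <- function(path) {
  hdr <- readLines(path, n = 1L)
  has_tab <- grepl("\t", hdr, fixed = TRUE)
  has_comma <- grepl(",", hdr, fixed = TRUE)
  if (has_tab && has_comma)
    stop_lutd("lutd_ambiguous_delim", "both tab and comma in header of '%s'; ambiguous delimiter", path)
  if (has_tab) "\t" else if (has_comma) "," else "\t"
}

#' Read an expression matrix from delimited text
#'
#' First column gene ids, header row sample ids; tab or comma delimited
#' (auto-detected, ambiguous files rejected). Every cell must parse as a
#' number; missing or non-numeric cells are hard errors reported with their
#' gene/sample coordinates.
#'
#' @param path path to a TSV/CSV file.
#' @inheritParams expression_matrix
#' @return a `lutd_expr` matrix.
#' @export
read_expression_matrix <- function(path, unit = c("log2fc", "read_count", "ct")) {
  unit <- match.arg(unit)
  delim <- detect_delim(path)
  df <- read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop_lutd("lutd_invalid_matrix", "'%s' has no sample columns", path)
  gid <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which((is.na(num) & !is.na(vals) & vals != "NA") | vals == "", arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_lutd("lutd_invalid_value", "non-numeric cell at gene '%s', sample '%s' in '%s'",
              gid[bad[1, 1]], colnames(vals)[bad[1, 2]], path)
  dimnames(num) <- list(gid, colnames(vals))
  expression_matrix(num, unit)
}

#' Read a sample-to-group annotation table
#'
#' Two-column delimited text (`sample_id`, `group`). Each sample must have
#' exactly one group; conflicting duplicates are errors. With
#' `extensible = FALSE` only the labels in `groups` are accepted.
#'
#' @param path path to the annotation file.
#' @param groups permitted group labels when `extensible = FALSE`.
#' @param extensible allow arbitrary group labels.
#' @return a data.frame with columns `sample_id`, `group` (factor).
#' @export
read_sample_annotation <- function(path, groups = c("Control", "BPS", "DO"),
                                   extensible = FALSE) {
  delim <- detect_delim(path)
  df <- read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop_lutd("lutd_empty_annotation", "no annotations in '%s'", path)
  if (ncol(df) < 2) stop_lutd("lutd_invalid_annotation", "'%s' needs sample_id and group columns", path)
  sample_annotation(df[[1]], df[[2]], groups = groups, extensible = extensible)
}

#' @rdname read_sample_annotation
#' @param sample_id,group character vectors of equal length.
#' @export
sample_annotation <- function(sample_id, group, groups = c("Control", "BPS", "DO"),
                              extensible = FALSE) {
  if (length(sample_id) != length(group))
    stop_lutd("lutd_invalid_annotation", "sample_id and group lengths differ")
  dup <- duplicated(sample_id)
  if (any(dup)) {
    for (s in unique(sample_id[dup])) {
      if (length(unique(group[sample_id == s])) > 1)
        stop_lutd("lutd_conflicting_annotation", "sample '%s' annotated with conflicting groups", s)
    }
    keep <- !dup
    sample_id <- sample_id[keep]; group <- group[keep]
  }
  if (!extensible) {
    unknown <- setdiff(unique(group), groups)
    if (length(unknown) > 0)
      stop_lutd("lutd_unknown_group", "unknown group label(s): %s",
                paste(unknown, collapse = ", "))
    group <- factor(group, levels = groups)
    group <- droplevels(group)
  } else {
    group <- factor(group)
  }
  structure(data.frame(sample_id = sample_id, group = group,
                       stringsAsFactors = FALSE),
            class = c("lutd_annotation", "data.frame"))
}

# Align annotation to a matrix's samples; error if any sample is unannotated.
align_annotation <- function(x, annotation, min_per_group = 0L) {
  sid <- colnames(x)
  miss <- setdiff(sid, annotation$sample_id)
  if (length(miss) > 0)
    stop_lutd("lutd_unannotated_sample", "sample(s) without annotation: %s",
              paste(miss, collapse = ", "))
  grp <- annotation$group[match(sid, annotation$sample_id)]
  grp <- droplevels(grp)
  if (min_per_group > 0) {
    cnt <- table(grp)
    small <- names(cnt)[cnt < min_per_group]
    if (length(small) > 0)
      stop_lutd("lutd_small_group", "group(s) with < %d samples: %s",
                min_per_group, paste(small, collapse = ", "))
  }
  grp
}

#' Read a differential-expression (DEG) table
#'
#' Three-column delimited text: gene id, log2 fold change, p-value. One row
#' per gene; p-values must lie in \[0, 1\].
#'
#' @param path path to the DEG table.
#' @return data.frame with columns `gene_id`, `log2fc`, `p_value`.
#' @export
read_deg_table <- function(path) {
  delim <- detect_delim(path)
  df <- read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  deg_table(df[[1]], as.numeric(df[[2]]), as.numeric(df[[3]]))
}

#' @rdname read_deg_table
#' @param gene_id character; `log2fc`, `p_value` numeric.
#' @param log2fc,p_value per-gene effect size and significance.
#' @export
deg_table <- function(gene_id, log2fc, p_value) {
  if (anyDuplicated(gene_id))
    stop_lutd("lutd_duplicate_id", "duplicated gene id(s) in DEG table: %s",
              paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (anyNA(log2fc) || anyNA(p_value))
    stop_lutd("lutd_missing_value", "missing values in DEG table")
  if (any(p_value < 0 | p_value > 1))
    stop_lutd("lutd_invalid_value", "p-values must lie in [0, 1]")
  data.frame(gene_id = as.character(gene_id), log2fc = log2fc,
             p_value = p_value, stringsAsFactors = FALSE)
}

#' Write a tabular result as TSV
#'
#' Deterministic column order (as given), floats rendered with 6 significant
#' digits, no row names. Matrices gain a leading id column so that the file
#' round-trips through [read_expression_matrix()].
#'
#' @param result a data.frame or matrix.
#' @param path output file path.
#' @param id_column name for the leading id column when writing a matrix.
#' @return invisibly, the path.
#' @export
write_table <- function(result, path, id_column = "gene_id") {
  if (is.matrix(result)) {
    df <- data.frame(rownames(result), as.data.frame(unclass(result), check.names = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[1] <- id_column
    result <- df
  }
  num <- vapply(result, is.numeric, logical(1))
  result[num] <- lapply(result[num], function(v) signif(v, 6))
  ok <- tryCatch({
    write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_lutd("lutd_unwritable", "cannot write '%s'", path)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the tunable pipeline constants: `cv_folds` (k, default 3),
#' `cv_repeats` (n, default 10), `min_features` (RFE floor, default 3), the
#' panel thresholds (|log2FC| > 0.5, p < 0.05), the oversampler and
#' classifier rosters, the primary ranking metric (F1) and the random seed.
#'
#' @param cv_folds stratified CV folds k (>= 2).
#' @param cv_repeats CV repeats n (>= 1).
#' @param min_features RFE selection floor (>= 1).
#' @param lfc_threshold absolute log2FC threshold (> 0).
#' @param p_threshold p-value threshold (> 0).
#' @param oversamplers oversampler ids.
#' @param classifiers classifier ids (see [classifier_ids()]).
#' @param primary_metric metric used to sort models.
#' @param random_seed integer seed.
#' @return a `lutd_config` list.
#' @export
run_config <- function(cv_folds = 3L, cv_repeats = 10L, min_features = 3L,
                       lfc_threshold = 0.5, p_threshold = 0.05,
                       oversamplers = oversampler_ids(),
                       classifiers = classifier_ids(),
                       primary_metric = "F1", random_seed = 1L) {
  cv_folds <- as.integer(cv_folds); cv_repeats <- as.integer(cv_repeats)
  min_features <- as.integer(min_features)
  if (cv_folds < 2) stop_lutd("lutd_invalid_config", "cv_folds must be >= 2")
  if (cv_repeats < 1) stop_lutd("lutd_invalid_config", "cv_repeats must be >= 1")
  if (min_features < 1) stop_lutd("lutd_invalid_config", "min_features must be >= 1")
  if (lfc_threshold <= 0 || p_threshold <= 0)
    stop_lutd("lutd_invalid_config", "thresholds must be > 0")
  bad <- setdiff(classifiers, classifier_ids())
  if (length(bad) > 0)
    stop_lutd("lutd_invalid_config", "unknown classifier id(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(oversamplers, oversampler_ids())
  if (length(bad) > 0)
    stop_lutd("lutd_invalid_config", "unknown oversampler id(s): %s", paste(bad, collapse = ", "))
  if (!primary_metric %in% metric_names())
    stop_lutd("lutd_invalid_config", "unknown primary metric '%s'", primary_metric)
  structure(list(cv_folds = cv_folds, cv_repeats = cv_repeats,
                 min_features = min_features, lfc_threshold = lfc_threshold,
                 p_threshold = p_threshold, oversamplers = oversamplers,
                 classifiers = classifiers, primary_metric = primary_metric,
                 random_seed = as.integer(random_seed)),
            class = "lutd_config")
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments ignored.
#' List-valued fields (`oversamplers`, `classifiers`) are comma-separated.
#' Unknown keys are errors. Missing keys keep [run_config()] defaults.
#'
#' @param path config file path.
#' @return a `lutd_config` list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*[:=]\\s*(.+)$", ln))[[1]]
    if (length(m) != 3)
      stop_lutd("lutd_invalid_config", "cannot parse config line: '%s'", ln)
    kv[[m[2]]] <- trimws(m[3])
  }
  allowed <- c("cv_folds", "cv_repeats", "min_features", "lfc_threshold",
               "p_threshold", "oversamplers", "classifiers", "primary_metric",
               "random_seed")
  bad <- setdiff(names(kv), allowed)
  if (length(bad) > 0)
    stop_lutd("lutd_invalid_config", "unknown config key(s): %s", paste(bad, collapse = ", "))
  args <- list()
  for (k in names(kv)) {
    v <- kv[[k]]
    args[[k]] <- switch(k,
      cv_folds = , cv_repeats = , min_features = , random_seed = as.integer(v),
      lfc_threshold = , p_threshold = as.numeric(v),
      oversamplers = , classifiers = trimws(strsplit(v, ",")[[1]]),
      primary_metric = v)
  }
  do.call(run_config, args)
}
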