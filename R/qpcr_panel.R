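#' Compute QPCR log2 fold changes from Ct values (delta-delta-Ct)
#'
#' Each gene's Ct is normalised to the reference gene within the same sample
#' (`dCt(g, s) = Ct(g, s) - Ct(ref, s)`), then expressed relative to the mean
#' of the control group. Because a lower Ct means higher expression, the sign
#' is flipped so that positive log2FC means higher expression than the
#' control mean:
#' `log2FC(g, s) = mean_controls(dCt(g, .)) - dCt(g, s)`.
#' The reference gene (18S rRNA in the original assay) is dropped from the
#' output. Technical replicates are expected to be aggregated upstream: the
#' function takes exactly one Ct per gene per sample.
#'
#' @param ct a `lutd_expr` matrix with unit `"ct"`.
#' @param annotation a sample annotation (see [sample_annotation()]).
#' @param reference_gene row id of the reference gene.
#' @param control_group label of the control group.
#' @return a `lutd_expr` matrix with unit `"log2fc"`, reference gene removed.
#' @examples
#' ct <- expression_matrix(matrix(c(24, 10, 26, 10, 27, 11), 2, 3,
#'   dimnames = list(c("TPPP3", "RNA18S"), c("c1", "c2", "p1"))), "ct")
#' ann <- sample_annotation(c("c1", "c2", "p1"), c("Control", "Control", "BPS"))
#' compute_log2fc(ct, ann, "RNA18S", "Control")
#' @export
compute_log2fc <- function(ct, annotation, reference_gene, control_group = "Control") {
  if (expr_unit(ct) != "ct")
    stop_lutd("lutd_invalid_unit", "expected a Ct matrix, got unit '%s'", expr_unit(ct))
  if (!reference_gene %in% rownames(ct))
    stop_lutd("lutd_missing_reference", "reference gene '%s' not in matrix", reference_gene)
  grp <- align_annotation(ct, annotation)
  ctrl <- which(grp == control_group)
  if (length(ctrl) == 0)
    stop_lutd("lutd_empty_group", "control group '%s' is empty", control_group)
  dct <- sweep(unclass(ct), 2, unclass(ct)[reference_gene, ], "-")
  dct <- dct[setdiff(rownames(ct), reference_gene), , drop = FALSE]
  ctrl_mean <- rowMeans(dct[, ctrl, drop = FALSE])
  log2fc <- sweep(-dct, 1, -ctrl_mean, "-")
  expression_matrix(log2fc, "log2fc")
}

#' Select a marker panel by exclusive regulation
#'
#' Applies the exclusivity rule to two DEG tables: a gene is selected when it
#' is significant in the primary comparison (|log2FC| > `lfc_threshold` and
#' p < `p_threshold`) and **not** significant in the other comparison under
#' the same thresholds (absence from the other table counts as not
#' significant). Selected genes are ordered by decreasing |log2FC|; manual
#' additions follow, tagged `manual_addition`. Tightening either threshold
#' can only shrink the exclusive set (monotonicity).
#'
#' @param deg_primary,deg_other DEG tables (see [deg_table()]).
#' @param config a [run_config()] providing the thresholds.
#' @param manual_additions genes appended regardless of the filter.
#' @return data.frame of class `lutd_panel` with columns `gene_id`,
#'   `rationale`, `log2fc`, `p_value`; thresholds kept as attributes.
#' @export
select_marker_panel <- function(deg_primary, deg_other, config = run_config(),
                                manual_additions = character(0)) {
  lfc <- config$lfc_threshold; pth <- config$p_threshold
  sig <- function(d) d$gene_id[abs(d$log2fc) > lfc & d$p_value < pth]
  prim <- sig(deg_primary)
  excl <- setdiff(prim, sig(deg_other))
  ord <- order(-abs(deg_primary$log2fc[match(excl, deg_primary$gene_id)]), excl)
  excl <- excl[ord]

  manual_additions <- as.character(manual_additions)
  dup <- intersect(manual_additions, excl)
  if (length(dup) > 0) {
    warn_lutd("manual addition(s) already selected, deduplicated: %s",
              paste(dup, collapse = ", "))
    manual_additions <- setdiff(manual_additions, excl)
  }
  manual_additions <- unique(manual_additions)
  if (length(excl) == 0 && length(manual_additions) == 0)
    warn_lutd("empty panel: no gene passes the exclusivity filter")

  genes <- c(excl, manual_additions)
  idx <- match(genes, deg_primary$gene_id)
  out <- data.frame(
    gene_id = genes,
    rationale = rep(c("exclusive_pass", "manual_addition"),
                    c(length(excl), length(manual_additions))),
    log2fc = deg_primary$log2fc[idx],
    p_value = deg_primary$p_value[idx],
    stringsAsFactors = FALSE)
  structure(out, lfc_threshold = lfc, p_threshold = pth,
            class = c("lutd_panel", "data.frame"))
}
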