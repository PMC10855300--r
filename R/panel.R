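#' The 13-gene LUTD marker panel
#'
#' Gene symbols of the QPCR validation panel: 12 genes exclusively regulated
#' in BPS under the |log2FC| > 0.5, p < 0.05 rule, plus NRXN3 (exclusively
#' regulated in DO) added manually. Symbols are treated as case-sensitive
#' opaque strings; no alias resolution is attempted.
#'
#' @return character vector of 13 gene symbols.
#' @export
lutd_panel_genes <- function() {
  c("TPPP3", "FAT1", "SMTN", "ANGPTL7", "CLEC3B", "AIM1", "PALM",
    "NCALD", "P2RX2", "NRXN2", "FAM83A", "MFAP5", "NRXN3")
}

#' Default per-gene regulation directions for the synthetic generator
#'
#' Encodes the QPCR-cohort findings as a gene x group direction matrix with
#' entries `"up"`, `"down"` or `"null"` relative to controls: eight genes up
#' in BPS only; FAT1 up in BPS and down in DO; AIM1 down in both; FAM83A down
#' in BPS; NRXN3 up in DO; MFAP5 unregulated.
#'
#' @return character matrix, rows = panel genes, columns = `BPS`, `DO`.
#' @export
lutd_panel_directions <- function() {
  genes <- lutd_panel_genes()
  d <- matrix("null", length(genes), 2, dimnames = list(genes, c("BPS", "DO")))
  up_bps <- c("TPPP3", "SMTN", "ANGPTL7", "CLEC3B", "PALM", "NCALD", "P2RX2", "NRXN2")
  d[up_bps, "BPS"] <- "up"
  d["FAT1", ] <- c("up", "down")
  d["AIM1", ] <- c("down", "down")
  d["FAM83A", "BPS"] <- "down"
  d["NRXN3", "DO"] <- "up"
  d
}
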