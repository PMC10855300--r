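#' Cumulative performance score (radar-polygon area)
#'
#' Places the seven metric means at equal angles on a radar chart in the
#' canonical order ([metric_names()]) and scores a model by the shaded
#' polygon area relative to the unit polygon:
#' `score = sum(m_i * m_{i+1}) / M` with `m_{M+1} = m_1` (the `sin(2*pi/M)`
#' factors cancel). All-ones scores 1, all-zeros scores 0, a constant vector
#' `c` scores `c^2`. The score is invariant under cyclic rotation of the
#' axis order but not under arbitrary permutation, hence the frozen order.
#'
#' @param metrics named numeric vector over [metric_names()] (extra names
#'   ignored), all values in \[0, 1\].
#' @param order axis order (canonical by default).
#' @return numeric score in \[0, 1\].
#' @export
mlcps_score <- function(metrics, order = metric_names()) {
  m <- metrics[order]
  if (anyNA(m)) stop_lutd("lutd_invalid_input", "missing metric(s): %s",
                          paste(order[is.na(m)], collapse = ", "))
  if (any(m < 0 | m > 1))
    stop_lutd("lutd_invalid_value", "metrics must lie in [0, 1]")
  M <- length(m)
  sum(m * m[c(2:M, 1)]) / M
}

rank_order <- function(df, primary = "F1") {
  # descending primary, then descending mlcps, then model id lexicographic
  id <- paste(df$classifier, df$oversampler, sep = "+")
  ord <- order(-df[[primary]], -df$mlcps, id)
  r <- integer(nrow(df)); r[ord] <- seq_len(nrow(df))
  r
}

#' Rank an evaluation table by its primary metric
#'
#' Descending primary-metric mean; ties broken by cumulative performance
#' score, then lexicographically by `classifier+oversampler` id. Ranks form a
#' permutation of 1..N and are invariant to input row order.
#'
#' @param scores a `lutd_evaluation` data.frame (or any data.frame with the
#'   metric columns, `classifier`, `oversampler`, `mlcps`).
#' @param primary metric id used to sort (default `"F1"`).
#' @return the table sorted by rank, `rank` column rewritten.
#' @export
rank_models <- function(scores, primary = "F1") {
  if (nrow(scores) == 0) stop_lutd("lutd_invalid_input", "empty score table")
  scores$rank <- rank_order(scores, primary)
  scores[order(scores$rank), , drop = FALSE]
}

#' Spider-table export of the best and worst models
#'
#' Long-format metric-per-axis table for the requested number of top and
#' bottom models (by rank), suitable for radar plotting. Values pass through
#' unchanged from the score table.
#'
#' @param scores a ranked evaluation table.
#' @param top,bottom number of best / worst models to include.
#' @return data.frame: `model`, `rank`, `group` (`"top"`/`"bottom"`),
#'   `metric`, `value`; axis order follows [metric_names()].
#' @export
spider_table <- function(scores, top = 3L, bottom = 3L) {
  if (top < 0 || bottom < 0)
    stop_lutd("lutd_invalid_input", "top/bottom must be >= 0")
  if (top + bottom > nrow(scores))
    stop_lutd("lutd_invalid_input", "top + bottom exceeds the number of models")
  scores <- rank_models(scores)
  pick <- rbind(
    if (top > 0) cbind(head(scores, top), group = "top"),
    if (bottom > 0) cbind(scores[seq(nrow(scores) - bottom + 1, nrow(scores)), ],
                          group = "bottom"))
  out <- do.call(rbind, lapply(seq_len(nrow(pick)), function(i) {
    data.frame(model = paste(pick$classifier[i], pick$oversampler[i], sep = "+"),
               rank = pick$rank[i], group = pick$group[i],
               metric = metric_names(),
               value = as.numeric(pick[i, metric_names()]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
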