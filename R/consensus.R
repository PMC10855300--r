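#' Intersect per-model feature selections
#'
#' Exact set intersection of the gene sets selected by different models (or
#' RFE core estimators) for one task. An empty intersection is allowed but
#' warned about. Order-invariant and idempotent; the result is returned in
#' the gene order of the first set.
#'
#' @param per_model_sets non-empty list of character vectors.
#' @return character vector.
#' @export
intersect_selected_features <- function(per_model_sets) {
  if (length(per_model_sets) == 0)
    stop_lutd("lutd_invalid_input", "need >= 1 gene set")
  out <- Reduce(intersect, per_model_sets)
  if (length(out) == 0) warn_lutd("empty feature intersection")
  out
}

#' Top variance contributors of the first two dimensions
#'
#' Union of the `top_n` highest-contributing genes of dimensions `dims`
#' (default the first two) of a PCA contribution table — the unsupervised
#' route to candidate markers. Ties are broken lexicographically by gene id
#' for determinism.
#'
#' @param contributions a `lutd_pca` result or a genes x PCs contribution
#'   matrix (percent, columns summing to 100).
#' @param top_n contributors taken per dimension (default 2, the published
#'   usage; the pipeline default is `min_features`).
#' @param dims dimensions considered.
#' @param kmeans_dims optional extra contribution table or vector (e.g. from
#'   [kmeans_dimension_contributions()]); its per-column top `top_n` genes
#'   join the union.
#' @return character vector of gene ids.
#' @export
unsupervised_contributors <- function(contributions, top_n = 2L, dims = 1:2,
                                      kmeans_dims = NULL) {
  if (inherits(contributions, "lutd_pca"))
    contributions <- contributions$contributions_pct
  if (top_n > nrow(contributions))
    stop_lutd("lutd_invalid_input", "top_n = %d exceeds panel size %d",
              top_n, nrow(contributions))
  top_of <- function(vals, genes) {
    ord <- order(-vals, genes) # ties: lexicographic by gene id
    genes[ord[seq_len(top_n)]]
  }
  dims <- dims[dims <= ncol(contributions)]
  out <- character(0)
  for (d in dims)
    out <- union(out, top_of(contributions[, d], rownames(contributions)))
  if (!is.null(kmeans_dims)) {
    if (is.null(dim(kmeans_dims)))
      kmeans_dims <- matrix(kmeans_dims, ncol = 1,
                            dimnames = list(names(kmeans_dims), NULL))
    for (d in seq_len(ncol(kmeans_dims)))
      out <- union(out, top_of(kmeans_dims[, d], rownames(kmeans_dims)))
  }
  out
}

#' Consensus marker signature from supervised and unsupervised evidence
#'
#' Intersects the disease-discriminating supervised selections with the
#' unsupervised top-contributor set; optionally keeps only genes elevated in
#' the disease group (mean expression above the rest of the cohort), since
#' the biological reading of the markers rests on their elevated expression
#' in the disease cluster.
#'
#' @param supervised_sets list of supervised gene sets (e.g. per-task RFE
#'   intersections for the disease-of-interest tasks).
#' @param unsupervised character vector from [unsupervised_contributors()].
#' @param x optional `lutd_expr` matrix used for the elevation filter.
#' @param annotation sample annotation (required with `x`).
#' @param disease group whose elevation is required (default `"BPS"`).
#' @param filter_elevated apply the elevation filter (default TRUE when `x`
#'   is given).
#' @return character vector; attributes `supervised` and `unsupervised`
#'   carry the inputs when the consensus is empty.
#' @export
consensus_signature <- function(supervised_sets, unsupervised, x = NULL,
                                annotation = NULL, disease = "BPS",
                                filter_elevated = !is.null(x)) {
  if (length(supervised_sets) == 0 || length(unsupervised) == 0)
    stop_lutd("lutd_invalid_input", "both evidence sources must be non-empty")
  sup <- intersect_selected_features(supervised_sets)
  out <- intersect(sup, unsupervised)
  if (filter_elevated) {
    if (is.null(x) || is.null(annotation))
      stop_lutd("lutd_invalid_input", "elevation filter needs x and annotation")
    grp <- align_annotation(x, annotation)
    v <- unclass(x)
    elevated <- rownames(v)[rowMeans(v[, grp == disease, drop = FALSE]) >
                              rowMeans(v[, grp != disease, drop = FALSE])]
    out <- intersect(out, elevated)
  }
  if (length(out) == 0) {
    warn_lutd("empty consensus; supervised = {%s}, unsupervised = {%s}",
              paste(sup, collapse = ","), paste(unsupervised, collapse = ","))
    attr(out, "supervised") <- sup
    attr(out, "unsupervised") <- unsupervised
  }
  out
}

#' Run the end-to-end discovery pipeline
#'
#' Orchestrates every stage on a validated log2FC matrix: exploratory
#' statistics, unsupervised learning (PCA, elbow/k-means, hierarchical
#' clustering, cluster transitions), one-vs-one task construction, per-task
#' RFE-CV (all three core estimators), the classifier-by-oversampler
#' evaluation grid under the requested CV schemes, model ranking, and the
#' supervised/unsupervised consensus signature. Deterministic given
#' `config$random_seed`; when `out_dir` is given, all tables are written as
#' TSV plus a JSON run summary (seed, package version, config echo — no
#' timestamps, so identical runs produce identical bundles).
#'
#' @param x a `lutd_expr` log2FC matrix.
#' @param annotation a sample annotation.
#' @param config a [run_config()].
#' @param schemes evaluation schemes to run.
#' @param disease positive phenotype for the consensus (default `"BPS"`).
#' @param top_n contributors per PCA dimension for the unsupervised route
#'   (default `min_features`).
#' @param intersect_mode `"above-baseline"` restricts the per-task feature
#'   intersection display to models beating the Dummy baseline; `"all"` uses
#'   every model. Affects reporting only — RFE selections are per core
#'   estimator.
#' @param out_dir optional output directory.
#' @return list of class `lutd_run`: `explore`, `cluster`, `tasks`, `rfe`,
#'   `evaluations` (per scheme, per task), `signature`, `summary`.
#' @export
run_discovery_pipeline <- function(x, annotation, config = run_config(),
                                   schemes = c("repeated_kfold", "nested_cv"),
                                   disease = "BPS",
                                   top_n = config$min_features,
                                   intersect_mode = c("above-baseline", "all"),
                                   out_dir = NULL) {
  intersect_mode <- match.arg(intersect_mode)
  schemes <- match.arg(schemes, several.ok = TRUE)
  seed <- config$random_seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_lutd("lutd_stage_error", "[stage %s] %s", name, conditionMessage(e))
    })
  }

  explore <- stage("explore", list(
    zscore = zscore_profile(x),
    correlation = correlation_report(x),
    tests = group_difference_tests(x, annotation, mode = "kruskal_wallis_pairwise"),
    normality = lapply(setNames(nm = rownames(x)),
                       function(g) normality_assess(unclass(x)[g, ]))
  ))

  clust <- stage("cluster", {
    pca <- pca_decompose(x, scale = TRUE)
    elbow <- elbow_profile(x, k_range = 2:7, seed = derive_seed(seed, 21))
    hier <- hierarchical_cluster(x, distance = "euclidean", k_range = 1:7)
    list(pca = pca, elbow = elbow, hierarchical = hier,
         transitions = clustree_transitions(elbow$assignments))
  })

  tasks <- stage("tasks", build_pairwise_tasks(x, annotation, cv_folds = config$cv_folds))
  names(tasks) <- vapply(tasks, `[[`, character(1), "name")

  rfe <- stage("rfe", lapply(tasks, function(tk)
    rfecv_select(tk, config, seed = derive_seed(seed, 31, which(names(tasks) == tk$name)))))

  evaluations <- list()
  for (sc in schemes) {
    evaluations[[sc]] <- stage(sc, lapply(tasks, function(tk) {
      feats <- rfe[[tk$name]]$selected
      if (sc == "repeated_kfold")
        evaluate_model_grid(tk, model_grid(config$classifiers, config$oversamplers),
                            config, seed = derive_seed(seed, 41), features = feats)
      else
        nested_cv_evaluate(tk, model_grid(config$classifiers, config$oversamplers),
                           config, seed = derive_seed(seed, 42), features = feats)
    }))
  }

  signature <- stage("signature", {
    # generous per-model (peak-rule) selections, pruned by intersection —
    # mirrors the published pattern of large per-model RFECV selections
    # whose per-task intersection forms the candidate list
    task_sets <- lapply(rfe, function(r) intersect_selected_features(r$per_core_peak))
    disease_sets <- task_sets[vapply(tasks, `[[`, character(1), "positive") == disease]
    # k for the k-means evidence comes from the elbow diagnostic, mirroring
    # the elbow -> k-means sequence of the unsupervised analysis
    kdims <- kmeans_dimension_contributions(x, k = clust$elbow$suggested_k,
                                            seed = derive_seed(seed, 51))
    unsup <- unsupervised_contributors(clust$pca, top_n = top_n,
                                       kmeans_dims = kdims)
    consensus <- consensus_signature(disease_sets, unsup, x = x,
                                     annotation = annotation, disease = disease)
    list(per_task = task_sets, unsupervised = unsup, consensus = consensus)
  })

  summary <- list(seed = seed, package_version = as.character(utils::packageVersion("lutdsig")),
                  config = unclass(config), schemes = schemes,
                  n_tasks = length(tasks),
                  n_models = length(config$classifiers) * length(config$oversamplers),
                  consensus = signature$consensus)

  out <- structure(list(explore = explore, cluster = clust, tasks = tasks,
                        rfe = rfe, evaluations = evaluations,
                        signature = signature, summary = summary),
                   class = "lutd_run")
  if (!is.null(out_dir)) write_run_bundle(out, out_dir)
  out
}

# Serialise the pipeline bundle as TSV tables plus a JSON summary.
write_run_bundle <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_table(run$explore$zscore$z, p("zscore.tsv"))
  write_table(run$explore$correlation$stars, p("correlation.tsv"))
  write_table(run$explore$tests$omnibus, p("tests_omnibus.tsv"))
  write_table(run$explore$tests$pairwise, p("tests_pairwise.tsv"))
  write_table(run$cluster$pca$contributions_pct, p("pca_contributions.tsv"))
  write_table(run$cluster$pca$scores, p("pca_scores.tsv"), id_column = "sample_id")
  write_table(data.frame(k = names(run$cluster$elbow$wss),
                         wss = unname(run$cluster$elbow$wss)), p("wss.tsv"))
  write_table(run$cluster$transitions, p("transitions.tsv"))
  for (sc in names(run$evaluations)) {
    for (tn in names(run$evaluations[[sc]])) {
      write_table(as.data.frame(run$evaluations[[sc]][[tn]]),
                  p(sprintf("metrics_%s_%s.tsv", sc, tn)))
    }
  }
  feats <- do.call(rbind, lapply(names(run$rfe), function(tn)
    data.frame(task = tn, core = run$rfe[[tn]]$core,
               gene_id = run$rfe[[tn]]$selected, stringsAsFactors = FALSE)))
  write_table(feats, p("selected_features.tsv"))
  sig <- data.frame(gene_id = run$signature$consensus, stringsAsFactors = FALSE)
  write_table(sig, p("consensus_signature.tsv"))
  jsonlite::write_json(run$summary, p("run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
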