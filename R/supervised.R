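#' Build one-vs-one binary tasks from an annotated expression matrix
#'
#' One task per unordered pair of groups. The positive class is the
#' disease-of-interest: for a disease/control pair the disease; for a
#' disease/disease pair the group listed first in the annotation's level
#' order. Task names are `positive_vs_other` (e.g. `BPS_vs_Control`).
#'
#' @param x a `lutd_expr` matrix (genes x samples).
#' @param annotation a sample annotation covering every sample.
#' @param control_label label of the control group (never positive).
#' @param cv_folds if given, error when any group has fewer than `2 * cv_folds`
#'   samples (too small to stratify).
#' @return list of `lutd_task` objects: `name`, `positive`, `X` (samples x
#'   genes), `y` (logical, TRUE = positive), `sample_ids`.
#' @export
build_pairwise_tasks <- function(x, annotation, control_label = "Control",
                                 cv_folds = NULL) {
  grp <- align_annotation(x, annotation, min_per_group = 2L)
  lv <- levels(grp)
  if (length(lv) < 2) stop_lutd("lutd_too_few_groups", "need >= 2 groups")
  if (!is.null(cv_folds)) {
    cnt <- table(grp)
    small <- names(cnt)[cnt < 2 * cv_folds]
    if (length(small) > 0)
      stop_lutd("lutd_small_group", "group(s) too small to stratify %d folds: %s",
                cv_folds, paste(small, collapse = ", "))
  }
  pairs <- combn(lv, 2, simplify = FALSE)
  # control-pairs first, preserving level order, to match the conventional
  # disease-vs-control, then disease-vs-disease task ordering
  is_ctrl <- vapply(pairs, function(p) control_label %in% p, logical(1))
  pairs <- c(pairs[is_ctrl], pairs[!is_ctrl])
  v <- t(unclass(x))
  lapply(pairs, function(p) {
    pos <- if (control_label %in% p) setdiff(p, control_label) else p[1]
    neg <- setdiff(p, pos)
    keep <- grp %in% p
    structure(list(name = paste0(pos, "_vs_", neg), positive = pos,
                   X = v[keep, , drop = FALSE],
                   y = grp[keep] == pos,
                   sample_ids = rownames(v)[keep]),
              class = "lutd_task")
  })
}

#' Stratified k-fold partition
#'
#' Splits samples into k folds of near-equal size with per-fold class counts
#' differing by at most one. Within each class, samples are shuffled
#' (seeded) and dealt into chunks; remainder chunks of alternating classes
#' are assigned from opposite ends of the fold list so total fold sizes
#' balance. Deterministic given the seed.
#'
#' @param y logical or factor class vector.
#' @param k number of folds (every class must have >= k members).
#' @param seed integer seed.
#' @return list of k integer vectors (test indices per fold).
#' @export
stratified_partition <- function(y, k, seed = 1L) {
  k <- as.integer(k)
  classes <- unique(y)
  folds <- vector("list", k)
  for (ci in seq_along(classes)) {
    idx <- which(y == classes[ci])
    n_c <- length(idx)
    if (n_c < k)
      stop_lutd("lutd_small_class", "class '%s' has %d < k = %d samples",
                as.character(classes[ci]), n_c, k)
    idx <- with_seed(derive_seed(seed, ci), sample(idx))
    base <- n_c %/% k; extra <- n_c %% k
    sizes <- rep(base, k)
    if (extra > 0) {
      slots <- if (ci %% 2 == 1) seq_len(extra) else k - seq_len(extra) + 1L
      sizes[slots] <- sizes[slots] + 1L
    }
    at <- cumsum(c(0, sizes))
    for (f in seq_len(k))
      folds[[f]] <- c(folds[[f]], idx[(at[f] + 1):at[f + 1]])
  }
  lapply(folds, sort)
}

# standardiser fit on training rows only
fit_scaler <- function(X) {
  mu <- colMeans(X); sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
apply_scaler <- function(scaler, X) sweep(sweep(X, 2, scaler$mu), 2, scaler$sd, "/")

# Oversample a training fold, then derive raw and standardised views.
# Scaling is fit on the augmented training set; the untouched test fold is
# transformed with the same statistics.
prepare_fold <- function(X, y, train, test, oversampler, seed) {
  aug <- oversample_training_fold(X[train, , drop = FALSE], y[train],
                                  method = oversampler, seed = seed)
  scaler <- fit_scaler(aug$features)
  list(Xtr_raw = aug$features, ytr = aug$labels,
       Xtr_std = apply_scaler(scaler, aug$features),
       Xte_raw = X[test, , drop = FALSE],
       Xte_std = apply_scaler(scaler, X[test, , drop = FALSE]))
}

score_fold <- function(classifier, params, fold, yte, seed) {
  std <- classifier_needs_scaling(classifier)
  model <- fit_classifier(classifier,
                          if (std) fold$Xtr_std else fold$Xtr_raw,
                          fold$ytr, params = params, seed = seed)
  pred <- predict(model, if (std) fold$Xte_std else fold$Xte_raw)
  binary_metrics(yte, pred$label, pred$score)
}

#' Model-configuration grid
#'
#' Cross of classifier and oversampler rosters: the default 12 x 3 = 36
#' configurations (11 named algorithms plus the Dummy baseline, each paired
#' with the three oversamplers).
#'
#' @param classifiers,oversamplers id vectors.
#' @return data.frame with columns `classifier`, `oversampler`.
#' @export
model_grid <- function(classifiers = classifier_ids(),
                       oversamplers = oversampler_ids()) {
  expand.grid(classifier = classifiers, oversampler = oversamplers,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Recursive feature elimination with cross-validation (RFE-CV)
#'
#' For each core estimator (LR, LDA, linear SVM), features are eliminated one
#' at a time: the core is fitted on the full (standardised) task data, the
#' feature with the smallest absolute weight is dropped, and every candidate
#' feature count is scored by stratified k-fold CV F1. The core with the
#' highest peak CV score wins (ties broken in roster order). The selected
#' count follows a one-standard-error rule — the smallest count whose mean CV
#' F1 is within one standard error of the peak — so features with no impact
#' on performance are removed, and pure-noise panels collapse to the
#' `min_features` floor. The selection is flagged `low_score` when even the
#' peak score does not beat the trivial always-positive classifier
#' (F1 = 2p/(1+p) at positive prevalence p).
#'
#' Two count-selection rules are available. `"1se"` (default, described
#' above) favours parsimony and collapses to the floor on uninformative
#' panels. `"peak"` takes the count with the maximal mean CV F1 outright
#' (ties to the smaller count), the behaviour of the reference RFECV
#' implementations; it keeps redundant-but-informative features and is what
#' the consensus stage uses, where generous per-model selections are pruned
#' by intersection.
#'
#' @param task a `lutd_task`.
#' @param config a [run_config()] (`cv_folds`, `min_features`).
#' @param seed integer seed.
#' @param cores core estimator ids evaluated inside the RFE.
#' @param rule count-selection rule, `"1se"` or `"peak"`.
#' @return list of class `lutd_rfecv`: `selected` (gene ids), `core`
#'   (winning estimator), `per_core_selected`, `scores` (per core, per
#'   count: mean and sd CV F1), `low_score`.
#' @export
rfecv_select <- function(task, config = run_config(), seed = 1L,
                         cores = c("LR", "LDA", "SVM"),
                         rule = c("1se", "peak")) {
  rule <- match.arg(rule)
  X <- task$X; y <- task$y
  sds <- apply(X, 2, sd)
  if (all(sds == 0)) stop_lutd("lutd_zero_variance", "all features constant")
  keep0 <- colnames(X)[sds > 0]
  min_f <- min(config$min_features, length(keep0))

  # Both the per-count CV score and the elimination ranking average over the
  # configured repeated k-fold scheme (cv_repeats x cv_folds): a single
  # 3-fold pass is far too noisy in this small-n regime and destabilises
  # both the elimination order and the count choice.
  rfe_folds <- lapply(seq_len(config$cv_repeats), function(r)
    stratified_partition(y, config$cv_folds, derive_seed(seed, 11, r)))

  # Inside the RFE the linear cores are fitted with a stronger penalty
  # (C = 0.1) than the prediction-stage default: weight-based elimination
  # under a weak penalty is dominated by noise directions at these sample
  # sizes, degrading the ranking long before it degrades CV accuracy. The
  # LDA core self-tunes through its Ledoit-Wolf covariance shrinkage.
  fit_on <- function(core, feats, train, fold_seed) {
    scaler <- fit_scaler(X[train, feats, drop = FALSE])
    params <- switch(core, SVM = list(kernel = "linear", C = 0.1),
                     LR = list(C = 0.1), list())
    list(model = fit_classifier(core, apply_scaler(scaler, X[train, feats, drop = FALSE]),
                                y[train], params = params, seed = fold_seed),
         scaler = scaler)
  }

  cv_f1 <- function(feats, core) {
    f1s <- unlist(lapply(seq_along(rfe_folds), function(r) {
      vapply(seq_along(rfe_folds[[r]]), function(i) {
        test <- rfe_folds[[r]][[i]]; train <- setdiff(seq_along(y), test)
        ft <- fit_on(core, feats, train, derive_seed(seed, 12, r, i))
        pred <- predict(ft$model, apply_scaler(ft$scaler, X[test, feats, drop = FALSE]))
        unname(binary_metrics(y[test], pred$label, pred$score)["F1"])
      }, numeric(1))
    }))
    c(mean = mean(f1s), sd = sd(f1s))
  }

  rank_weights <- function(feats, core) {
    w <- 0
    for (r in seq_along(rfe_folds)) for (i in seq_along(rfe_folds[[r]])) {
      train <- setdiff(seq_along(y), rfe_folds[[r]][[i]])
      ft <- fit_on(core, feats, train, derive_seed(seed, 13, r, i))
      wi <- feature_weights(ft$model)
      w <- w + wi / max(sqrt(sum(wi^2)), 1e-12)
    }
    w
  }

  per_core <- lapply(cores, function(core) {
    feats <- keep0
    path <- list(); scores <- list()
    repeat {
      scores[[length(scores) + 1]] <- c(n = length(feats), cv_f1(feats, core))
      path[[length(path) + 1]] <- feats
      if (length(feats) <= min_f) break
      w <- rank_weights(feats, core)
      feats <- feats[feats != feats[which.min(w)]]
    }
    tab <- as.data.frame(do.call(rbind, scores))
    list(core = core, path = path, scores = tab)
  })

  pick <- function(pc) {
    tab <- pc$scores
    peak <- max(tab$mean)
    # repeated-CV fold scores share training samples and are correlated, so
    # the effective replication for the standard error is the fold count
    slack <- if (rule == "1se") tab$sd[which.max(tab$mean)] / sqrt(config$cv_folds)
             else 1e-12
    ok <- which(tab$mean >= peak - slack)
    pc$path[[ok[which.min(tab$n[ok])]]] # smallest admissible feature count
  }
  per_core_selected <- lapply(per_core, pick)
  names(per_core_selected) <- cores
  # peak-rule picks are always recorded for the consensus stage
  peak_pick <- function(pc) {
    ok <- which(pc$scores$mean >= max(pc$scores$mean) - 1e-12)
    pc$path[[ok[which.min(pc$scores$n[ok])]]]
  }
  per_core_peak <- lapply(per_core, peak_pick)
  names(per_core_peak) <- cores
  peaks <- vapply(per_core, function(pc) max(pc$scores$mean), numeric(1))
  best_i <- which.max(peaks) # ties: roster order
  # no-skill reference: the always-positive classifier scores F1 = 2p/(1+p);
  # a panel carries signal only if the peak clears it by more than one SE
  p_pos <- mean(y)
  best_tab <- per_core[[best_i]]$scores
  peak_se <- best_tab$sd[which.max(best_tab$mean)] / sqrt(config$cv_folds)
  structure(list(selected = per_core_selected[[best_i]], core = cores[best_i],
                 per_core_selected = per_core_selected,
                 per_core_peak = per_core_peak,
                 scores = setNames(lapply(per_core, `[[`, "scores"), cores),
                 peak_score = peaks[best_i],
                 low_score = peaks[best_i] < 2 * p_pos / (1 + p_pos) + peak_se),
            class = "lutd_rfecv")
}

#' Repeated stratified k-fold evaluation of a model grid
#'
#' For every configuration (classifier x oversampler), runs `cv_repeats`
#' repetitions of stratified `cv_folds`-fold CV. Inside each fold the
#' oversampler and the feature scaler are fitted on the training portion
#' only; the untouched test fold supplies all seven metrics. Results are
#' aggregated as mean and sd over the `n * k` fold scores, scored with the
#' cumulative performance score and ranked by the primary metric.
#'
#' @param task a `lutd_task`.
#' @param configs a [model_grid()] data.frame.
#' @param config a [run_config()].
#' @param seed integer seed (defaults to `config$random_seed`).
#' @param features optional gene subset (e.g. an RFE-CV selection).
#' @return data.frame of class `lutd_evaluation`: one row per configuration
#'   with per-metric means, sds, `mlcps` and `rank`; fold bookkeeping in
#'   `attr(, "audit")`.
#' @export
evaluate_model_grid <- function(task, configs = model_grid(),
                                config = run_config(), seed = NULL,
                                features = NULL) {
  if (nrow(configs) == 0) stop_lutd("lutd_invalid_input", "empty configuration grid")
  seed <- seed %||% config$random_seed
  X <- task$X
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  y <- task$y
  k <- config$cv_folds; nrep <- config$cv_repeats
  oss <- unique(configs$oversampler)

  fold_rows <- vector("list", nrow(configs))
  for (ci in seq_len(nrow(configs))) fold_rows[[ci]] <- list()
  audit <- list()

  for (rep_i in seq_len(nrep)) {
    folds <- stratified_partition(y, k, derive_seed(seed, rep_i))
    for (fi in seq_len(k)) {
      test <- folds[[fi]]; train <- setdiff(seq_along(y), test)
      audit[[length(audit) + 1]] <- list(rep = rep_i, fold = fi,
                                         train = train, test = test)
      prepared <- lapply(seq_along(oss), function(oi)
        prepare_fold(X, y, train, test, oss[oi],
                     seed = derive_seed(seed, rep_i, fi, oi)))
      names(prepared) <- oss
      for (ci in seq_len(nrow(configs))) {
        m <- score_fold(configs$classifier[ci], list(),
                        prepared[[configs$oversampler[ci]]], y[test],
                        seed = derive_seed(seed, rep_i, fi, ci))
        fold_rows[[ci]][[length(fold_rows[[ci]]) + 1]] <- m
      }
    }
  }
  finalize_evaluation(task, configs, fold_rows, scheme = "repeated_kfold",
                      config = config, audit = audit)
}

#' Nested cross-validated evaluation of a model grid
#'
#' Two-layer CV: the outer layer (`cv_folds` folds, `cv_repeats` repeats)
#' estimates generalisation; the inner layer (same k) tunes each classifier's
#' hyperparameters by grid search on mean inner F1, using only the outer
#' training portion. Oversampling and scaling are refitted inside every inner
#' and outer training split; outer test folds are never touched by tuning.
#'
#' @inheritParams evaluate_model_grid
#' @param grids per-classifier hyperparameter grids (see [default_grids()]).
#' @return a `lutd_evaluation` data.frame (scheme `"nested_cv"`); the audit
#'   attribute records outer test indices and all inner split indices.
#' @export
nested_cv_evaluate <- function(task, configs = model_grid(),
                               config = run_config(), seed = NULL,
                               grids = default_grids(), features = NULL) {
  if (nrow(configs) == 0) stop_lutd("lutd_invalid_input", "empty configuration grid")
  seed <- seed %||% config$random_seed
  X <- task$X
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  y <- task$y
  k <- config$cv_folds; nrep <- config$cv_repeats
  oss <- unique(configs$oversampler)

  fold_rows <- vector("list", nrow(configs))
  for (ci in seq_len(nrow(configs))) fold_rows[[ci]] <- list()
  best_params <- vector("list", nrow(configs))
  audit <- list()

  for (rep_i in seq_len(nrep)) {
    outer <- stratified_partition(y, k, derive_seed(seed, rep_i))
    for (fi in seq_len(k)) {
      test <- outer[[fi]]; train <- setdiff(seq_along(y), test)
      inner <- stratified_partition(y[train], k, derive_seed(seed, rep_i, fi))
      inner_abs <- lapply(inner, function(ix) train[ix])
      audit[[length(audit) + 1]] <- list(rep = rep_i, fold = fi, train = train,
                                         test = test, inner = inner_abs)
      # cache oversampled inner and outer folds per oversampler
      inner_prep <- lapply(seq_along(oss), function(oi)
        lapply(seq_along(inner), function(ii) {
          ite <- inner[[ii]]; itr <- setdiff(seq_along(train), ite)
          prepare_fold(X[train, , drop = FALSE], y[train], itr, ite, oss[oi],
                       seed = derive_seed(seed, rep_i, fi, ii, oi))
        }))
      names(inner_prep) <- oss
      outer_prep <- lapply(seq_along(oss), function(oi)
        prepare_fold(X, y, train, test, oss[oi],
                     seed = derive_seed(seed, rep_i, fi, 99, oi)))
      names(outer_prep) <- oss

      for (ci in seq_len(nrow(configs))) {
        cls <- configs$classifier[ci]; os <- configs$oversampler[ci]
        grid <- grids[[cls]] %||% list(list())
        if (length(grid) > 1) {
          gscore <- vapply(seq_along(grid), function(gi) {
            mean(vapply(seq_along(inner), function(ii) {
              prep <- inner_prep[[os]][[ii]]
              yte <- y[train][inner[[ii]]]
              unname(score_fold(cls, grid[[gi]], prep, yte,
                                seed = derive_seed(seed, rep_i, fi, ii, ci, gi))["F1"])
            }, numeric(1)))
          }, numeric(1))
          best <- grid[[which.max(gscore)]] # ties: first grid point
        } else best <- grid[[1]]
        best_params[[ci]] <- c(best_params[[ci]], list(best))
        m <- score_fold(cls, best, outer_prep[[os]], y[test],
                        seed = derive_seed(seed, rep_i, fi, ci, 7))
        fold_rows[[ci]][[length(fold_rows[[ci]]) + 1]] <- m
      }
    }
  }
  out <- finalize_evaluation(task, configs, fold_rows, scheme = "nested_cv",
                             config = config, audit = audit)
  attr(out, "best_params") <- best_params
  out
}

finalize_evaluation <- function(task, configs, fold_rows, scheme, config, audit) {
  rows <- lapply(seq_len(nrow(configs)), function(ci) {
    fm <- do.call(rbind, fold_rows[[ci]])
    ag <- aggregate_metrics(fm)
    means <- as.list(ag$mean)
    sds <- as.list(setNames(ag$sd, paste0(names(ag$sd), "_sd")))
    c(list(task = task$name, classifier = configs$classifier[ci],
           oversampler = configs$oversampler[ci], scheme = scheme),
      means, sds,
      list(mlcps = mlcps_score(ag$mean)))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  out$rank <- rank_order(out, config$primary_metric)
  class(out) <- c("lutd_evaluation", "data.frame")
  attr(out, "audit") <- audit
  out
}
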