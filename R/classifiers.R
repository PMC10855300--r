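#' Classifier roster
#'
#' The twelve classifier ids of the evaluation grid: Logistic Regression
#' (LR), Linear Discriminant Analysis (LDA), Gaussian Naive Bayes (GNB),
#' Support Vector Machine (SVM), k-nearest neighbours (KNN), Decision Tree
#' (DTC), Gaussian Process (GP), Random Forest (RF), Bagging (BC), Extra
#' Trees (ETC), Gradient Boosting (GBC), plus the stratified-random Dummy
#' baseline. Distance/margin-based learners (LR, SVM, KNN, GP) receive
#' standardised features; tree ensembles and the rest receive raw values.
#'
#' @return character vector of classifier ids.
#' @export
classifier_ids <- function() {
  c("LR", "LDA", "GNB", "SVM", "KNN", "DTC", "GP", "RF", "BC", "ETC",
    "GBC", "Dummy")
}

#' @rdname classifier_ids
#' @param id a classifier id.
#' @export
classifier_needs_scaling <- function(id) id %in% c("LR", "SVM", "KNN", "GP")

#' Default hyperparameter grids for nested cross-validation
#'
#' Small published-default grids: regularisation strength over log-spaced
#' values (LR, SVM), SVM kernel linear/RBF, KNN neighbour counts 3/5/7, tree
#' depth 3/5/unlimited, ensemble size fixed at 100, GP length-scale
#' multipliers around the median heuristic. Parameter-free learners (LDA,
#' GNB, Dummy) have a single empty grid point.
#'
#' @return named list: per classifier id, a list of parameter lists.
#' @export
default_grids <- function() {
  list(
    LR = lapply(c(0.01, 0.1, 1, 10), function(C) list(C = C)),
    LDA = list(list()),
    GNB = list(list()),
    SVM = unlist(lapply(c("linear", "rbf"), function(k)
      lapply(c(0.1, 1, 10, 100), function(C) list(kernel = k, C = C))),
      recursive = FALSE),
    KNN = lapply(c(3, 5, 7), function(k) list(k = k)),
    DTC = lapply(c(3, 5, 0), function(d) list(max_depth = d)),
    GP = lapply(c(0.5, 1, 2), function(s) list(lengthscale_mult = s)),
    RF = list(list(ntree = 100)),
    BC = list(list(ntree = 100)),
    ETC = list(list(ntree = 100)),
    GBC = list(list(ntree = 100)),
    Dummy = list(list())
  )
}

#' Fit a classifier by id
#'
#' Uniform fitting interface over the roster. `y` is a logical vector
#' (TRUE = positive class). All stochastic learners take an explicit seed
#' and are bitwise-reproducible.
#'
#' @param id classifier id from [classifier_ids()].
#' @param X numeric matrix, samples x features.
#' @param y logical vector of length `nrow(X)`.
#' @param params named list of hyperparameters (see [default_grids()]).
#' @param seed integer seed for stochastic learners.
#' @return model object of class `lutd_model`.
#' @export
fit_classifier <- function(id, X, y, params = list(), seed = 1L) {
  X <- as.matrix(X); y <- as.logical(y)
  if (length(unique(y)) < 2 && id != "Dummy")
    stop_lutd("lutd_single_class", "training data contains a single class")
  fit <- switch(id,
    LR = fit_lr(X, y, C = params$C %||% 1),
    LDA = fit_lda(X, y),
    GNB = fit_gnb(X, y),
    SVM = fit_svm(X, y, C = params$C %||% 1, kernel = params$kernel %||% "rbf"),
    KNN = list(X = X, y = y, k = params$k %||% 5L),
    DTC = fit_forest(X, y, ntree = 1L, mtry = ncol(X),
                     max_depth = params$max_depth %||% 0L,
                     bootstrap = FALSE, random_split = FALSE, seed = seed),
    GP = fit_gp(X, y, lengthscale_mult = params$lengthscale_mult %||% 1,
                noise = params$noise %||% 0.1),
    RF = fit_forest(X, y, ntree = params$ntree %||% 100L,
                    mtry = max(1L, floor(sqrt(ncol(X)))),
                    max_depth = 0L, bootstrap = TRUE, random_split = FALSE,
                    seed = seed),
    BC = fit_forest(X, y, ntree = params$ntree %||% 100L, mtry = ncol(X),
                    max_depth = 0L, bootstrap = TRUE, random_split = FALSE,
                    seed = seed),
    ETC = fit_forest(X, y, ntree = params$ntree %||% 100L,
                     mtry = max(1L, floor(sqrt(ncol(X)))),
                     max_depth = 0L, bootstrap = FALSE, random_split = TRUE,
                     seed = seed),
    GBC = list(model = .cpp_gbm_fit(X, as.numeric(y),
                                    params$ntree %||% 100L,
                                    params$max_depth %||% 3L,
                                    params$shrinkage %||% 0.1, 2L,
                                    as.integer(seed))),
    Dummy = list(p_pos = mean(y), seed = as.integer(seed)),
    stop_lutd("lutd_unknown_classifier", "unknown classifier id '%s'", id)
  )
  structure(list(id = id, fit = fit, params = params), class = "lutd_model")
}

#' Predict from a fitted classifier
#'
#' @param object a `lutd_model`.
#' @param newdata numeric matrix, samples x features.
#' @param ... unused.
#' @return list with `prob` (positive-class probability, may be `NULL` for
#'   margin-only learners), `score` (continuous decision value, larger =
#'   more positive) and `label` (logical hard prediction).
#' @export
predict.lutd_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  f <- object$fit
  out <- switch(object$id,
    LR = {
      eta <- drop(cbind(1, X) %*% f$coef)
      list(prob = plogis(eta), score = eta)
    },
    LDA = {
      sc <- drop(X %*% f$w) + f$b
      list(prob = plogis(sc), score = sc)
    },
    GNB = predict_gnb(f, X),
    SVM = {
      sc <- predict_svm(f, X)
      list(prob = NULL, score = sc)
    },
    KNN = predict_knn(f, X),
    DTC = ,
    RF = ,
    BC = ,
    ETC = {
      pr <- .cpp_forest_predict(f$trees, X)
      list(prob = pr, score = pr - 0.5)
    },
    GBC = {
      sc <- .cpp_gbm_predict(f$model, X)
      list(prob = plogis(sc), score = sc)
    },
    GP = predict_gp(f, X),
    Dummy = predict_dummy(f, X)
  )
  if (object$id == "Dummy") {
    # stratified-random hard predictions at the training prevalence
    out$label <- out$label_draw
    out$label_draw <- NULL
  } else {
    out$label <- if (!is.null(out$prob)) out$prob > 0.5 else out$score > 0
  }
  out
}

#' Linear coefficients for RFE feature ranking
#'
#' Absolute linear weights used by recursive feature elimination to rank
#' features; defined for the linear core estimators (LR, LDA, linear SVM).
#'
#' @param object a `lutd_model` for LR, LDA or linear SVM.
#' @return named numeric vector of absolute feature weights.
#' @export
feature_weights <- function(object) {
  f <- object$fit
  w <- switch(object$id,
    LR = abs(f$coef[-1]),
    LDA = abs(f$w),
    SVM = {
      if (f$kernel != "linear")
        stop_lutd("lutd_invalid_input", "feature weights require a linear SVM")
      abs(f$w)
    },
    stop_lutd("lutd_invalid_input", "no linear weights for classifier '%s'", object$id)
  )
  setNames(as.numeric(w), colnames(f$X) %||% names(w))
}

## ---- individual learners -------------------------------------------------

# Ridge-regularised logistic regression via damped IRLS (intercept
# unpenalised). lambda = 1/C mirrors the usual C parameterisation.
fit_lr <- function(X, y, C = 1, max_iter = 50L, tol = 1e-8) {
  Z <- cbind(1, X)
  p <- ncol(Z)
  lambda <- 1 / C
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  yn <- as.numeric(y)
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Z, yn - mu)) - pen %*% beta
    H <- crossprod(Z * w, Z) + pen
    step <- tryCatch(solve(H, grad), error = function(e) grad / max(diag(H)))
    beta_new <- beta + step
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  list(coef = drop(beta), X = X)
}

# Linear discriminant analysis with a Ledoit-Wolf-shrunk pooled covariance
# (shrinkage target: scaled identity). The shrinkage keeps the discriminant
# well-conditioned in the small-n / moderate-p regime these cohorts live in;
# with ample data the estimated shrinkage intensity goes to zero and the
# classical LDA direction is recovered.
fit_lda <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  mu1 <- colMeans(X[y, , drop = FALSE]); mu0 <- colMeans(X[!y, , drop = FALSE])
  Xc <- X
  Xc[y, ] <- sweep(X[y, , drop = FALSE], 2, mu1)
  Xc[!y, ] <- sweep(X[!y, , drop = FALSE], 2, mu0)
  S <- crossprod(Xc) / n
  mtr <- sum(diag(S)) / p
  d2 <- sum((S - diag(mtr, p))^2) / p
  if (d2 < 1e-12) {
    rho <- 1
  } else {
    b2 <- 0
    for (i in seq_len(n)) b2 <- b2 + sum((tcrossprod(Xc[i, ]) - S)^2)
    b2 <- min(b2 / (n^2 * p), d2)
    rho <- b2 / d2
  }
  Sh <- rho * diag(mtr, p) + (1 - rho) * S
  w <- tryCatch(solve(Sh, mu1 - mu0),
                error = function(e) solve(Sh + diag(1e-8 * max(mtr, 1), p), mu1 - mu0))
  b <- -sum(w * (mu1 + mu0)) / 2 + log(mean(y) / (1 - mean(y)))
  list(w = setNames(drop(w), colnames(X)), b = b, shrinkage = rho, X = X)
}

fit_gnb <- function(X, y) {
  eps <- 1e-9 * max(apply(X, 2, var), 1e-12)
  stats_for <- function(cls) {
    sub <- X[y == cls, , drop = FALSE]
    list(mu = colMeans(sub), var = apply(sub, 2, var) + eps)
  }
  list(pos = stats_for(TRUE), neg = stats_for(FALSE),
       prior_pos = mean(y), X = X)
}

predict_gnb <- function(f, X) {
  ll <- function(st) {
    rowSums(-0.5 * log(2 * pi * matrix(st$var, nrow(X), ncol(X), byrow = TRUE)) -
              0.5 * sweep(X, 2, st$mu)^2 / matrix(st$var, nrow(X), ncol(X), byrow = TRUE))
  }
  lp <- ll(f$pos) + log(max(f$prior_pos, 1e-12))
  ln <- ll(f$neg) + log(max(1 - f$prior_pos, 1e-12))
  score <- lp - ln
  list(prob = plogis(score), score = score)
}

# Primal squared-hinge SVM. Linear: parameters (w, b); RBF: representer
# coefficients alpha over the training kernel. Optimised by L-BFGS with
# analytic gradients; deterministic.
fit_svm <- function(X, y, C = 1, kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  ypm <- ifelse(y, 1, -1)
  n <- nrow(X); p <- ncol(X)
  if (kernel == "linear") {
    obj <- function(theta) {
      w <- theta[1:p]; b <- theta[p + 1]
      fx <- drop(X %*% w) + b
      xi <- pmax(0, 1 - ypm * fx)
      0.5 * sum(w^2) + C * sum(xi^2)
    }
    grd <- function(theta) {
      w <- theta[1:p]; b <- theta[p + 1]
      fx <- drop(X %*% w) + b
      xi <- pmax(0, 1 - ypm * fx)
      dfx <- -2 * C * ypm * xi
      c(w + drop(crossprod(X, dfx)), sum(dfx))
    }
    fit <- optim(numeric(p + 1), obj, grd, method = "L-BFGS-B",
                 control = list(maxit = 200))
    list(kernel = "linear", w = setNames(fit$par[1:p], colnames(X)),
         b = fit$par[p + 1], X = X)
  } else {
    gamma <- 1 / (p * max(mean(apply(X, 2, var)), 1e-12)) # sklearn "scale"
    K <- rbf_kernel(X, X, gamma)
    obj <- function(theta) {
      a <- theta[1:n]; b <- theta[n + 1]
      fx <- drop(K %*% a) + b
      xi <- pmax(0, 1 - ypm * fx)
      0.5 * sum(a * drop(K %*% a)) + C * sum(xi^2)
    }
    grd <- function(theta) {
      a <- theta[1:n]; b <- theta[n + 1]
      Ka <- drop(K %*% a)
      fx <- Ka + b
      xi <- pmax(0, 1 - ypm * fx)
      dfx <- -2 * C * ypm * xi
      c(Ka + drop(K %*% dfx), sum(dfx))
    }
    fit <- optim(numeric(n + 1), obj, grd, method = "L-BFGS-B",
                 control = list(maxit = 200))
    list(kernel = "rbf", alpha = fit$par[1:n], b = fit$par[n + 1],
         gamma = gamma, Xtrain = X, X = X)
  }
}

predict_svm <- function(f, X) {
  if (f$kernel == "linear") drop(X %*% f$w) + f$b
  else drop(rbf_kernel(X, f$Xtrain, f$gamma) %*% f$alpha) + f$b
}

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

predict_knn <- function(f, X) {
  k <- min(f$k, nrow(f$X))
  d2 <- outer(rowSums(X^2), rowSums(f$X^2), "+") - 2 * tcrossprod(X, f$X)
  prob <- apply(d2, 1, function(dr) {
    nn <- order(dr, seq_along(dr))[seq_len(k)] # ties: lowest index first
    mean(f$y[nn])
  })
  list(prob = prob, score = prob - 0.5)
}

# GP classifier as RBF-kernel label regression on +-1 targets with a fixed
# noise term; latent mean thresholded at 0, mapped to [0,1] for probabilities.
fit_gp <- function(X, y, lengthscale_mult = 1, noise = 0.1) {
  dmat <- as.matrix(dist(X))
  med <- median(dmat[upper.tri(dmat)])
  if (!is.finite(med) || med <= 0) med <- 1
  ell <- lengthscale_mult * med
  K <- exp(-dmat^2 / (2 * ell^2))
  alpha <- solve(K + noise * diag(nrow(X)), ifelse(y, 1, -1))
  list(alpha = alpha, ell = ell, Xtrain = X, X = X)
}

predict_gp <- function(f, X) {
  d2 <- outer(rowSums(X^2), rowSums(f$Xtrain^2), "+") - 2 * tcrossprod(X, f$Xtrain)
  Kstar <- exp(-pmax(d2, 0) / (2 * f$ell^2))
  fx <- drop(Kstar %*% f$alpha)
  list(prob = pmin(pmax((fx + 1) / 2, 0), 1), score = fx)
}

fit_forest <- function(X, y, ntree, mtry, max_depth, bootstrap, random_split, seed) {
  list(trees = .cpp_forest_fit(X, as.numeric(y), as.integer(ntree),
                               as.integer(mtry), as.integer(max_depth), 2L,
                               bootstrap, random_split, as.integer(seed)),
       X = X)
}

predict_dummy <- function(f, X) {
  n <- nrow(X)
  draws <- with_seed(derive_seed(f$seed, n), runif(n))
  prob <- with_seed(derive_seed(f$seed, n, 2), runif(n)) # uninformative scores
  list(prob = prob, score = prob - 0.5, label_draw = draws < f$p_pos)
}
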