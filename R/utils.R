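#' @useDynLib lutdsig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov as.dist cor cor.test cutree dist hclust kmeans kruskal.test
#'   mahalanobis p.adjust pairwise.wilcox.test prcomp pt rbinom rnbinom rnorm
#'   runif sd shapiro.test TukeyHSD var predict setNames optim cov quantile
#'   median plogis qlogis
#' @importFrom utils read.delim write.table combn head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic sub-seed derivation; keeps results below .Machine$integer.max.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) %% 1e6) %% 2147483629
  as.integer(s) + 1L
}

stop_lutd <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "lutd_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

warn_lutd <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
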