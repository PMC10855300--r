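# shared fixture builders; everything is generated in code at test time

make_expr <- function(values, genes = NULL, samples = NULL, unit = "log2fc") {
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, unit)
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# three well-separated Gaussian blobs in `p` dimensions (separation in sd units)
make_blobs <- function(n_per = 10, p = 5, sep = 10, seed = 1) {
  set.seed(seed)
  centers <- matrix(0, 3, p)
  centers[2, 1] <- sep
  centers[3, 2] <- sep
  vals <- do.call(cbind, lapply(1:3, function(b)
    replicate(n_per, rnorm(p, centers[b, ], 1))))
  truth <- rep(1:3, each = n_per)
  list(x = make_expr(vals), truth = truth)
}

# a binary task with perfectly separable classes along the first feature
make_separable_task <- function(n_pos = 15, n_neg = 12, p = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n_pos + n_neg) * p, sd = 0.3), ncol = p)
  X[seq_len(n_pos), 1] <- X[seq_len(n_pos), 1] + 6
  colnames(X) <- paste0("G", seq_len(p))
  rownames(X) <- paste0("S", seq_len(n_pos + n_neg))
  structure(list(name = "A_vs_B", positive = "A", X = X,
                 y = rep(c(TRUE, FALSE), c(n_pos, n_neg)),
                 sample_ids = rownames(X)),
            class = "lutd_task")
}

task_from <- function(g, pair = c("BPS", "Control")) {
  tasks <- build_pairwise_tasks(g$matrix, g$annotation)
  names(tasks) <- vapply(tasks, `[[`, character(1), "name")
  tasks[[paste0(pair[1], "_vs_", pair[2])]]
}
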