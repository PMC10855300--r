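#' Synthetic-data configuration
#'
#' Describes the world the generator emulates: a 13-gene QPCR-like log2FC
#' matrix over 64 samples (Control 14, BPS 28, DO 22) whose per-gene
#' regulation directions encode the QPCR-cohort findings (see
#' [lutd_panel_directions()]). `"up"`/`"down"` entries shift the group mean
#' by plus/minus `effect_size` log2 units around the control mean of 0;
#' values are Normal with sd `noise_sd`, matching the observed normality of
#' the cohort's log2FC values. Defaults: effect 1.5, sd 1.0 — calibration
#' constants chosen so the best models clearly beat the random baseline, not
#' values reported for the patient cohort.
#'
#' Presets: `"paper-qpcr"` (full direction matrix), `"planted3"` (only
#' TPPP3, FAT1 and NCALD up in BPS — the planted three-marker signature used
#' by the recovery tests), `"null"` (no regulated gene; pure noise).
#'
#' @param n_control,n_bps,n_do group sizes (each >= 2).
#' @param genes gene roster.
#' @param directions character matrix genes x groups (`"up"/"down"/"null"`);
#'   column names are the non-control group labels.
#' @param effect_size log2-unit group shift (>= 0).
#' @param noise_sd log2-unit noise sd (> 0).
#' @param equicorrelation optional shared-factor correlation between genes
#'   within a sample, in \[0, 1) (default 0: independent genes).
#' @param seed integer seed.
#' @param preset optional preset name overriding `directions`.
#' @return a `lutd_synth_config` list.
#' @export
synthetic_config <- function(n_control = 14L, n_bps = 28L, n_do = 22L,
                             genes = lutd_panel_genes(),
                             directions = lutd_panel_directions(),
                             effect_size = 1.5, noise_sd = 1.0,
                             equicorrelation = 0, seed = 1L,
                             preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("paper-qpcr", "planted3", "null"))
    directions <- lutd_panel_directions()
    if (preset == "planted3") {
      directions[] <- "null"
      directions[c("TPPP3", "FAT1", "NCALD"), "BPS"] <- "up"
    } else if (preset == "null") {
      directions[] <- "null"
    }
  }
  if (any(c(n_control, n_bps, n_do) < 2))
    stop_lutd("lutd_invalid_config", "group sizes must be >= 2")
  if (effect_size < 0) stop_lutd("lutd_invalid_config", "effect_size must be >= 0")
  if (noise_sd <= 0) stop_lutd("lutd_invalid_config", "noise_sd must be > 0")
  if (equicorrelation < 0 || equicorrelation >= 1)
    stop_lutd("lutd_invalid_config", "equicorrelation must lie in [0, 1)")
  if (!all(rownames(directions) == genes))
    directions <- directions[genes, , drop = FALSE]
  if (!all(directions %in% c("up", "down", "null")))
    stop_lutd("lutd_invalid_config", "directions must be up/down/null")
  structure(list(n_control = as.integer(n_control), n_bps = as.integer(n_bps),
                 n_do = as.integer(n_do), genes = genes,
                 directions = directions, effect_size = effect_size,
                 noise_sd = noise_sd, equicorrelation = equicorrelation,
                 seed = as.integer(seed)),
            class = "lutd_synth_config")
}

synth_truth_means <- function(config) {
  dirmult <- matrix(0, length(config$genes), 3,
                    dimnames = list(config$genes, c("Control", colnames(config$directions))))
  for (g in colnames(config$directions)) {
    dirmult[, g] <- c(up = 1, down = -1, null = 0)[config$directions[, g]]
  }
  dirmult * config$effect_size
}

#' Generate a QPCR-like log2FC matrix with planted truth
#'
#' `value(g, s) ~ Normal(mean(g, group(s)), noise_sd)`, with control means 0
#' and regulated means at plus/minus `effect_size`. With `equicorrelation`
#' rho > 0, a shared per-sample factor induces correlation rho between genes.
#' Bitwise-reproducible given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return list: `matrix` (`lutd_expr`, unit log2fc), `annotation`,
#'   `truth` (list: `means` gene x group, `informative` gene set, `seed`).
#' @export
generate_qpcr_like <- function(config = synthetic_config()) {
  sizes <- c(Control = config$n_control, BPS = config$n_bps, DO = config$n_do)
  grp <- rep(names(sizes), sizes)
  sid <- unlist(lapply(names(sizes), function(g)
    sprintf("%s%02d", g, seq_len(sizes[[g]]))))
  means <- synth_truth_means(config)
  G <- length(config$genes); S <- length(sid)
  rho <- config$equicorrelation
  vals <- with_seed(config$seed, {
    noise <- matrix(rnorm(G * S), G, S)
    if (rho > 0) {
      shared <- matrix(rnorm(S), G, S, byrow = TRUE)
      noise <- sqrt(rho) * shared + sqrt(1 - rho) * noise
    }
    means[, grp, drop = FALSE] + config$noise_sd * noise
  })
  dimnames(vals) <- list(config$genes, sid)
  informative <- config$genes[apply(config$directions != "null", 1, any)]
  list(matrix = expression_matrix(vals, "log2fc"),
       annotation = sample_annotation(sid, grp),
       truth = list(means = means, informative = informative,
                    seed = config$seed))
}

#' Generate an NGS-like negative-binomial count matrix
#'
#' Counts with group mean `baseline_mean * 2^(direction * effect_size)` and
#' a gamma-Poisson (negative binomial) noise model, emulating the skewed,
#' non-normal read-count distributions of small-cohort RNA-seq.
#'
#' @param config a [synthetic_config()].
#' @param dispersion NB dispersion (> 0); variance = mu + dispersion * mu^2.
#' @param baseline_mean control-group mean count (> 0).
#' @return list as in [generate_qpcr_like()] with a `read_count` matrix;
#'   `truth$means` holds the per-group mean counts.
#' @export
generate_count_like <- function(config = synthetic_config(), dispersion = 0.5,
                                baseline_mean = 500) {
  if (dispersion <= 0) stop_lutd("lutd_invalid_config", "dispersion must be > 0")
  if (baseline_mean <= 0) stop_lutd("lutd_invalid_config", "baseline_mean must be > 0")
  sizes <- c(Control = config$n_control, BPS = config$n_bps, DO = config$n_do)
  grp <- rep(names(sizes), sizes)
  sid <- unlist(lapply(names(sizes), function(g)
    sprintf("%s%02d", g, seq_len(sizes[[g]]))))
  mu <- baseline_mean * 2^synth_truth_means(config)
  G <- length(config$genes); S <- length(sid)
  vals <- with_seed(derive_seed(config$seed, 101), {
    matrix(rnbinom(G * S, size = 1 / dispersion,
                   mu = as.vector(mu[, grp, drop = FALSE])), G, S)
  })
  dimnames(vals) <- list(config$genes, sid)
  informative <- config$genes[apply(config$directions != "null", 1, any)]
  list(matrix = expression_matrix(vals, "read_count"),
       annotation = sample_annotation(sid, grp),
       truth = list(means = mu, informative = informative, seed = config$seed))
}
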