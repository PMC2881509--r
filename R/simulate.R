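#' Configuration for the two-group expression simulator
#'
#' Describes a synthetic two-group study on the scale of the micro-dissected
#' stromal microarray cohorts this package emulates: log2 intensities with
#' independent Gaussian noise per gene per sample, and a planted fraction of
#' genes whose case-group mean is shifted upward.
#'
#' Defaults mirror the designs the package is built to exercise: a
#' lymph-node-metastasis-style contrast of 25 vs 25 samples, per-gene noise
#' of 0.5 on the log2 scale, a planted effect of 2.0 log2 units, and a
#' planted fraction of 0.34 (the ratio of a ~6,800-gene up-list to a
#' ~20,000-gene array universe). Other cohort shapes from the same family
#' (53 vs 38, 11 vs 42) are a matter of changing `n_group1`/`n_group2`.
#'
#' @param n_genes number of genes (rows).
#' @param n_group1 number of case samples (>= 2).
#' @param n_group2 number of control samples (>= 2).
#' @param baseline_mean baseline log2 intensity for every gene.
#' @param noise_sd per-gene, per-sample Gaussian noise SD (log2 units).
#' @param frac_up fraction of genes planted upregulated in the case group,
#'   in \[0, 1\].
#' @param effect mean log2 shift added to planted genes in the case group
#'   (> 0 unless `frac_up` is 0).
#' @param shared_frac for [simulate_paired_studies()]: fraction of planted
#'   genes common to both studies, in \[0, 1\].
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output. Per-study sub-streams are derived deterministically from it.
#' @param baseline_hyper_sd optional SD of a Gaussian hyperprior on per-gene
#'   baseline means (0 = all genes share `baseline_mean`).
#' @return a validated object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_group1 = 25, n_group2 = 25,
                       baseline_mean = 6, noise_sd = 0.5, frac_up = 0.34,
                       effect = 2, shared_frac = 0.5, seed = 1,
                       baseline_hyper_sd = 0) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(is.numeric(n_genes) && n_genes >= 1, "n_genes must be >= 1")
  chk(n_group1 >= 2 && n_group2 >= 2, "each group needs >= 2 samples")
  chk(noise_sd > 0, "noise_sd must be > 0")
  chk(frac_up >= 0 && frac_up <= 1, "frac_up must be in [0, 1]")
  chk(shared_frac >= 0 && shared_frac <= 1, "shared_frac must be in [0, 1]")
  chk(frac_up == 0 || effect >= 0, "effect must be >= 0")
  chk(baseline_hyper_sd >= 0, "baseline_hyper_sd must be >= 0")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
      "seed must be a single integer")
  structure(list(n_genes = as.integer(n_genes),
                 n_group1 = as.integer(n_group1),
                 n_group2 = as.integer(n_group2),
                 baseline_mean = baseline_mean, noise_sd = noise_sd,
                 frac_up = frac_up, effect = effect,
                 shared_frac = shared_frac, seed = as.integer(seed),
                 baseline_hyper_sd = baseline_hyper_sd),
            class = "sim_config")
}

# deterministic sub-stream seed for study k under a global seed
.substream_seed <- function(seed, k) {
  (as.integer(seed) * 7919L + k * 104729L) %% 2147483587L
}

.gene_ids <- function(n) sprintf("G%05d", seq_len(n))

.simulate_one <- function(cfg, truth_up, stream_seed, prefix) {
  n <- cfg$n_genes
  ns <- cfg$n_group1 + cfg$n_group2
  set.seed(stream_seed)
  base <- rep(cfg$baseline_mean, n)
  if (cfg$baseline_hyper_sd > 0)
    base <- base + stats::rnorm(n, 0, cfg$baseline_hyper_sd)
  vals <- base + matrix(stats::rnorm(n * ns, 0, cfg$noise_sd), n, ns)
  gid <- .gene_ids(n)
  idx <- match(truth_up, gid)
  if (length(idx))
    vals[idx, seq_len(cfg$n_group1)] <- vals[idx, seq_len(cfg$n_group1)] +
      cfg$effect
  sid <- c(sprintf("%s_case_%02d", prefix, seq_len(cfg$n_group1)),
           sprintf("%s_ctrl_%02d", prefix, seq_len(cfg$n_group2)))
  dimnames(vals) <- list(gid, sid)
  groups <- stats::setNames(rep(c("case", "control"),
                                c(cfg$n_group1, cfg$n_group2)), sid)
  structure(list(matrix = expression_matrix(vals, groups),
                 truth_up = truth_up, config = cfg),
            class = "simulated_study")
}

#' Simulate one two-group study with planted upregulated genes
#'
#' Non-planted genes are drawn from the identical Gaussian distribution in
#' both groups; planted genes get a case-group mean of
#' `baseline_mean + effect`. The planted set is a uniform random sample of
#' `round(frac_up * n_genes)` gene identifiers.
#'
#' @param config a [sim_config()].
#' @return an object of class `simulated_study`: list with `matrix` (an
#'   [expression_matrix()]), `truth_up` (character vector of planted gene
#'   identifiers) and `config`.
#' @examples
#' st <- simulate_study(sim_config(n_genes = 100, frac_up = 0.1, seed = 7))
#' length(st$truth_up)  # 10
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gid <- .gene_ids(config$n_genes)
  n_up <- round(config$frac_up * config$n_genes)
  set.seed(.substream_seed(config$seed, 0L))
  truth <- sort(sample(gid, n_up))
  .simulate_one(config, truth, .substream_seed(config$seed, 1L), "s1")
}

#' Simulate a pair of studies sharing a planted up-module
#'
#' Both studies live on the same gene universe. Each gets
#' `round(frac_up * n_genes)` planted genes; their truth sets share exactly
#' `round(shared_frac * n_up)` identifiers, with the remainders disjoint.
#' Noise draws are independent between the studies.
#'
#' @param config a [sim_config()]; `shared_frac` controls the overlap.
#' @return a list of two `simulated_study` objects (`study1`, `study2`).
#' @export
simulate_paired_studies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gid <- .gene_ids(config$n_genes)
  n_up <- round(config$frac_up * config$n_genes)
  n_shared <- round(config$shared_frac * n_up)
  n_solo <- n_up - n_shared
  if (n_shared + 2L * n_solo > config$n_genes)
    stop("n_genes too small for disjoint planted remainders ",
         "(need shared + 2*(n_up - shared) <= n_genes)", call. = FALSE)
  set.seed(.substream_seed(config$seed, 0L))
  pool <- sample(gid, n_shared + 2L * n_solo)
  shared <- pool[seq_len(n_shared)]
  solo1 <- pool[n_shared + seq_len(n_solo)]
  solo2 <- pool[n_shared + n_solo + seq_len(n_solo)]
  s1 <- .simulate_one(config, sort(c(shared, solo1)),
                      .substream_seed(config$seed, 1L), "s1")
  s2 <- .simulate_one(config, sort(c(shared, solo2)),
                      .substream_seed(config$seed, 2L), "s2")
  list(study1 = s1, study2 = s2)
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("simulated_study: %d genes, %d+%d samples, %d planted up\n",
              x$config$n_genes, x$config$n_group1, x$config$n_group2,
              length(x$truth_up)))
  invisible(x)
}

#' Write a simulated study to a directory
#'
#' Emits the expression TSV, the group-label TSV, and the planted truth set
#' as one identifier per line.
#'
#' @param study a `simulated_study` from [simulate_study()].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir, prefix = "study") {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(study$matrix,
                          file.path(dir, paste0(prefix, "_matrix.tsv")),
                          file.path(dir, paste0(prefix, "_groups.tsv")))
  writeLines(study$truth_up, file.path(dir, paste0(prefix, "_truth_up.txt")))
  invisible(dir)
}
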