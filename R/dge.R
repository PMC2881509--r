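#' Per-gene one-sided upregulation t-test
#'
#' For every gene, tests the alternative hypothesis that the case-group mean
#' exceeds the control-group mean (upper-tail p-value). Welch's
#' unequal-variance statistic is the default, the safer choice for the
#' unequal cohort sizes typical of stromal contrasts (53 vs 38, 11 vs 42);
#' a pooled-variance statistic is available with `var_equal = TRUE`.
#'
#' Degenerate genes (zero variance in both groups) cannot support a t
#' statistic. They are assigned p = 0.5 when the group means are equal,
#' p = 0 when case > control, and p = 1 when case < control, and flagged in
#' the `degenerate` column. This keeps the ranking sensible without
#' inventing a variance floor.
#'
#' @param em an [expression_matrix()] with >= 2 samples per group.
#' @param var_equal use the pooled-variance (classic two-sample) statistic
#'   instead of Welch.
#' @return a data.frame of class `gene_stats` with one row per gene:
#'   `gene_id`, `mean_case`, `mean_control`, `log_fc` (case minus control,
#'   log2 units), `fold_change` (`2^log_fc`), `t`, `df`, `p_value`
#'   (one-sided, upper tail), `degenerate`.
#' @export
one_sided_up_test <- function(em, var_equal = FALSE) {
  stopifnot(inherits(em, "expr_matrix"))
  icase <- which(em$groups == "case")
  ictrl <- which(em$groups == "control")
  n1 <- length(icase); n2 <- length(ictrl)
  if (n1 < 2 || n2 < 2)
    stop("each group needs >= 2 samples (got ", n1, " case, ", n2,
         " control)", call. = FALSE)
  x <- em$values[, icase, drop = FALSE]
  y <- em$values[, ictrl, drop = FALSE]
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    a <- v1 / n1; b <- v2 / n2
    se2 <- a + b
    df <- se2^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  degen <- se2 == 0
  tstat <- (m1 - m2) / sqrt(se2)            # Inf/NaN where degenerate
  p <- stats::pt(tstat, df, lower.tail = FALSE)
  if (any(degen)) {
    d <- m1[degen] - m2[degen]
    tstat[degen] <- sign(d) * ifelse(d == 0, 0, Inf)
    df[degen] <- NA_real_
    p[degen] <- ifelse(d > 0, 0, ifelse(d < 0, 1, 0.5))
  }
  out <- data.frame(gene_id = rownames(em$values),
                    mean_case = m1, mean_control = m2,
                    log_fc = m1 - m2, fold_change = 2^(m1 - m2),
                    t = tstat, df = df, p_value = p,
                    degenerate = degen, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_stats", "data.frame")
  out
}

#' Build an upregulated gene list from per-gene statistics
#'
#' Members are exactly the genes with `p_value < alpha` (strict inequality)
#' and, when `fc_threshold` is supplied, a fold-change ratio strictly above
#' it. No multiple-testing correction is applied by default; the
#' Benjamini-Hochberg flag thresholds the adjusted p-value instead. Members
#' are ordered by ascending p-value; an empty result is legal.
#'
#' @param stats a `gene_stats` data.frame from [one_sided_up_test()] (any
#'   data.frame with `gene_id`, `p_value` and, if `fc_threshold` is used,
#'   `fold_change` columns works).
#' @param alpha significance cutoff in (0, 1); membership needs p < alpha.
#' @param fc_threshold optional fold-change cutoff on the ratio scale
#'   (e.g. `2.0` keeps genes with case/control ratio > 2).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param name name for the resulting list.
#' @param contrast free-form contrast description stored in provenance.
#' @return a [gene_list()] with provenance (`contrast`, `alpha`,
#'   `fc_threshold`, `adjust`, `n_tested`) and per-member p-values.
#' @export
build_up_list <- function(stats, alpha = 0.05, fc_threshold = NULL,
                          adjust = c("none", "BH"), name = "up_list",
                          contrast = "case_vs_control") {
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (!all(c("gene_id", "p_value") %in% names(stats)))
    stop("stats must have gene_id and p_value columns", call. = FALSE)
  p <- stats$p_value
  pcrit <- if (adjust == "BH") stats::p.adjust(p, method = "BH") else p
  keep <- pcrit < alpha
  if (!is.null(fc_threshold)) {
    if (!"fold_change" %in% names(stats))
      stop("fold-change filtering needs a fold_change column", call. = FALSE)
    keep <- keep & stats$fold_change > fc_threshold
  }
  keep[is.na(keep)] <- FALSE
  sel <- stats[keep, , drop = FALSE]
  sel <- sel[order(sel$p_value, sel$gene_id), , drop = FALSE]
  gene_list(sel$gene_id, name = name,
            provenance = list(contrast = contrast, alpha = alpha,
                              fc_threshold = if (is.null(fc_threshold))
                                NA_real_ else fc_threshold,
                              adjust = adjust, n_tested = nrow(stats)),
            p_values = stats::setNames(sel$p_value, sel$gene_id))
}

#' Write a per-gene statistics table as TSV
#'
#' @param stats a `gene_stats` data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_gene_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-gene statistics table written by [write_gene_stats()]
#'
#' @param path TSV path.
#' @return a `gene_stats` data.frame.
#' @export
read_gene_stats <- function(path) {
  out <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  class(out) <- c("gene_stats", "data.frame")
  out
}
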