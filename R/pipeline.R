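#' Select heatmap rows by fold change, significance, and list membership
#'
#' Restricts an expression matrix to the genes that pass a fold-change and
#' a p-value filter in the supplied per-gene statistics AND belong to
#' another gene list (after symbol harmonization) — the selection a
#' cross-study heatmap displays. Rows are ordered by ascending p-value.
#'
#' Passing `fc_threshold = 0` disables the fold-change filter and
#' `alpha = 1` disables the p-value filter, so permissive settings return
#' the membership-restricted (or full) matrix unchanged.
#'
#' @param em an [expression_matrix()].
#' @param stats `gene_stats` covering the matrix genes (from
#'   [one_sided_up_test()]).
#' @param other a [gene_list()] (or character vector) the selection must
#'   intersect.
#' @param fc_threshold fold-change cutoff on the ratio scale (strict,
#'   `> fc_threshold`); 0 disables.
#' @param alpha p-value cutoff (strict, `< alpha`); 1 disables.
#' @return an [expression_matrix()] restricted to the selected rows
#'   (possibly zero rows), ordered by ascending p.
#' @export
heatmap_selection <- function(em, stats, other, fc_threshold = 1.5,
                              alpha = 0.05) {
  stopifnot(inherits(em, "expr_matrix"))
  gid <- rownames(em$values)
  if (!all(gid %in% stats$gene_id))
    stop("stats must cover every matrix gene", call. = FALSE)
  st <- stats[match(gid, stats$gene_id), ]
  pass <- rep(TRUE, length(gid))
  if (fc_threshold > 0) pass <- pass & st$fold_change > fc_threshold
  if (alpha < 1) pass <- pass & st$p_value < alpha
  oth <- harmonize_symbols(other, quiet = TRUE)$ids
  pass <- pass & toupper(gid) %in% oth
  pass[is.na(pass)] <- FALSE
  sel <- which(pass)[order(st$p_value[pass])]
  out <- em
  out$values <- em$values[sel, , drop = FALSE]
  out
}

#' Configuration for an end-to-end pipeline run
#'
#' Either supply file paths (`matrix1`/`groups1`, optionally
#' `matrix2`/`groups2`) or a [sim_config()] from which a pair of studies
#' is simulated. Thresholds mirror the two-stage published design: one
#' alpha for up-list construction, a separate fold-change/alpha pair for
#' the heatmap selection.
#'
#' @param sim optional [sim_config()]; if given, input paths are ignored
#'   and a paired simulation provides the two studies.
#' @param matrix1,groups1 TSV paths for study 1 (contrast of interest).
#' @param matrix2,groups2 optional TSV paths for study 2 (the list study 1
#'   is intersected with).
#' @param alpha up-list p cutoff (default 0.05).
#' @param fc_threshold optional up-list fold-change cutoff (ratio scale).
#' @param heatmap_fc,heatmap_alpha heatmap selection thresholds (default
#'   1.5 and 0.05).
#' @param gmt optional GMT path for an enrichment scan of the study-1
#'   up-list.
#' @param gmt_pattern optional regex restricting the scanned sub-collection.
#' @param panels character vector of fixture panel names to cross-tabulate
#'   against the study-1 up-list (default none).
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest and used for any
#'   simulation.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, matrix1 = NULL, groups1 = NULL,
                            matrix2 = NULL, groups2 = NULL, alpha = 0.05,
                            fc_threshold = NULL, heatmap_fc = 1.5,
                            heatmap_alpha = 0.05, gmt = NULL,
                            gmt_pattern = NULL, panels = character(),
                            out_dir = "overlap_run", seed = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (!is.null(fc_threshold) && fc_threshold <= 0)
    stop("fc_threshold must be positive", call. = FALSE)
  if (heatmap_fc < 0 || heatmap_alpha <= 0 || heatmap_alpha > 1)
    stop("invalid heatmap thresholds", call. = FALSE)
  if (is.null(sim) && is.null(matrix1) && !length(panels) && is.null(gmt))
    stop("need a simulation config, input paths, or a fixture-only ",
         "configuration (panels/gmt)", call. = FALSE)
  structure(list(sim = sim, matrix1 = matrix1, groups1 = groups1,
                 matrix2 = matrix2, groups2 = groups2, alpha = alpha,
                 fc_threshold = fc_threshold, heatmap_fc = heatmap_fc,
                 heatmap_alpha = heatmap_alpha, gmt = gmt,
                 gmt_pattern = gmt_pattern, panels = panels,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full simulate/test/list/overlap/enrich/panel pipeline
#'
#' Executes every configured stage, writes all intermediate tables to the
#' output directory (TSV/plain text, each recomputable by the underlying
#' module function), and returns the result bundle. Identical config and
#' seed give identical outputs; the only timestamp lives in the manifest.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage progress messages.
#' @return a list bundle with (as configured) `study1`, `study2`, `stats1`,
#'   `stats2`, `list1`, `list2`, `overlap`, `venn`, `enrichment`,
#'   `crosstabs`, `heatmap`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[overlapEnrich] ", ...)
  bundle <- list()
  manifest <- list(seed = config$seed, alpha = config$alpha,
                   fc_threshold = config$fc_threshold,
                   heatmap_fc = config$heatmap_fc,
                   heatmap_alpha = config$heatmap_alpha,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  em1 <- em2 <- NULL
  if (!is.null(config$sim)) {
    say("simulating paired studies")
    pair <- .stage("simulate", simulate_paired_studies(config$sim))
    bundle$study1 <- pair$study1; bundle$study2 <- pair$study2
    write_study(pair$study1, config$out_dir, "study1")
    write_study(pair$study2, config$out_dir, "study2")
    em1 <- pair$study1$matrix; em2 <- pair$study2$matrix
    manifest$input <- "simulated"
    manifest$sim <- unclass(config$sim)
  } else if (!is.null(config$matrix1)) {
    say("reading expression input")
    em1 <- .stage("read", read_expression_matrix(config$matrix1,
                                                 config$groups1))
    if (!is.null(config$matrix2))
      em2 <- .stage("read", read_expression_matrix(config$matrix2,
                                                   config$groups2))
    manifest$input <- c(config$matrix1, config$matrix2)
  }

  universe <- NULL
  if (!is.null(em1)) {
    universe <- gene_list(unique(c(rownames(em1$values),
                                   if (!is.null(em2))
                                     rownames(em2$values))),
                          name = "universe")
    write_gene_list(universe, file.path(config$out_dir, "universe.txt"))

    say("per-gene one-sided tests, study 1")
    bundle$stats1 <- .stage("dge", one_sided_up_test(em1))
    write_gene_stats(bundle$stats1,
                     file.path(config$out_dir, "stats1.tsv"))
    bundle$list1 <- build_up_list(bundle$stats1, alpha = config$alpha,
                                  fc_threshold = config$fc_threshold,
                                  name = "up_study1", contrast = "study1")
    write_gene_list(bundle$list1, file.path(config$out_dir, "up_study1.txt"))
    say("up-list study 1: ", length(bundle$list1), " genes")

    if (!is.null(em2)) {
      say("per-gene one-sided tests, study 2")
      bundle$stats2 <- .stage("dge", one_sided_up_test(em2))
      write_gene_stats(bundle$stats2,
                       file.path(config$out_dir, "stats2.tsv"))
      bundle$list2 <- build_up_list(bundle$stats2, alpha = config$alpha,
                                    fc_threshold = config$fc_threshold,
                                    name = "up_study2", contrast = "study2")
      write_gene_list(bundle$list2,
                      file.path(config$out_dir, "up_study2.txt"))
      say("up-list study 2: ", length(bundle$list2), " genes")

      say("intersection over N = ", length(universe))
      bundle$overlap <- .stage("overlap",
        intersect_lists(bundle$list1, bundle$list2, universe, quiet = quiet))
      write_overlap_result(bundle$overlap,
                           file.path(config$out_dir, "overlap.tsv"))
      manifest$overlap_p <- bundle$overlap$p_value
      say(sprintf("overlap k = %d, p = %.3g", bundle$overlap$overlap_size,
                  bundle$overlap$p_value))
      bundle$venn <- venn_regions(list(bundle$list1, bundle$list2),
                                  universe)
      utils::write.table(bundle$venn,
                         file.path(config$out_dir, "venn.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)

      say("heatmap selection")
      bundle$heatmap <- heatmap_selection(em1, bundle$stats1, bundle$list2,
                                          fc_threshold = config$heatmap_fc,
                                          alpha = config$heatmap_alpha)
      write_expression_matrix(bundle$heatmap,
                              file.path(config$out_dir, "heatmap.tsv"))
      manifest$heatmap_rows <- nrow(bundle$heatmap$values)
    }
  }

  if (!is.null(config$gmt)) {
    say("enrichment scan")
    collection <- .stage("enrich", read_gmt(config$gmt))
    query <- if (!is.null(bundle$list1)) bundle$list1 else NULL
    if (is.null(query))
      stop("pipeline stage 'enrich': enrichment needs an expression input ",
           "to build the query list", call. = FALSE)
    bundle$enrichment <- .stage("enrich",
      enrich(query, collection, universe, pattern = config$gmt_pattern))
    write_enrichment_table(bundle$enrichment,
                           file.path(config$out_dir, "enrichment.tsv"))
  }

  if (length(config$panels)) {
    say("panel cross-tabs")
    reference <- if (!is.null(bundle$list1)) bundle$list1
                 else load_fixture_reference()
    bundle$crosstabs <- lapply(config$panels, function(nm) {
      ct <- .stage("panel",
                   cross_tabulate(load_fixture_panel(nm), reference))
      write_crosstab(ct, file.path(config$out_dir,
                                   paste0("crosstab_", nm, ".tsv")))
      ct
    })
    names(bundle$crosstabs) <- config$panels
  }

  manifest_lines <- vapply(names(manifest), function(k)
    paste0(k, "\t", paste(format(unlist(manifest[[k]])), collapse = ",")),
    character(1))
  writeLines(manifest_lines, file.path(config$out_dir, "manifest.tsv"))
  bundle$manifest <- manifest
  say("done: ", config$out_dir)
  invisible(bundle)
}
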