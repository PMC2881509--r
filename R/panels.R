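#' Curated gene panel
#'
#' A small named table of genes with descriptions, optional per-list
#' p-value columns (carried verbatim as printed strings, with parsed
#' numeric companions), and optional logical annotation columns. The
#' package ships five such panels transcribed from published
#' cross-tabulations of breast-cancer stromal up-lists; see
#' [load_fixture_panel()].
#'
#' @param table data.frame with a `gene` column (unique), a `description`
#'   column, and any further columns. Columns whose name starts with `p_`
#'   are treated as printed p-value strings; a parsed numeric column
#'   `<name>_num` is added for each (blank cells become `NA`, meaning
#'   "missing", not zero).
#' @param name panel name.
#' @return an object of class `panel`: list with `name` and `table`.
#' @export
panel <- function(table, name = "panel") {
  if (!is.data.frame(table) || !"gene" %in% names(table))
    stop("panel table needs a 'gene' column", call. = FALSE)
  if (anyDuplicated(table$gene))
    stop("panel gene identifiers must be unique", call. = FALSE)
  pcols <- grep("^p_", names(table), value = TRUE)
  pcols <- pcols[!endsWith(pcols, "_num")]
  for (pc in pcols) {
    s <- as.character(table[[pc]])
    s[is.na(s)] <- ""
    table[[pc]] <- s
    num <- suppressWarnings(as.numeric(s))  # accepts 1.51E-73 and 4.18e-38
    table[[paste0(pc, "_num")]] <- num
  }
  structure(list(name = name, table = table), class = "panel")
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf("panel '%s': %d genes\n", x$name, nrow(x$table)))
  invisible(x)
}

.fixture_panels <- c(collagen_tumor = "panel_collagen_tumor.tsv",
                     collagen_recurrence = "panel_collagen_recurrence.tsv",
                     collagen_metastasis = "panel_collagen_metastasis.tsv",
                     glial = "panel_glial.tsv",
                     proteomic = "panel_proteomic.tsv")

#' Load one of the packaged curated panels
#'
#' Five panels transcribed from published stromal cross-tabulations ship
#' with the package:
#' \describe{
#'   \item{collagen_tumor}{35 collagen genes upregulated in tumor vs normal
#'     stroma, with printed p-values and the reference membership flag
#'     (`in_reference`, the published bold marking against the Cav-1 (-/-)
#'     stromal list).}
#'   \item{collagen_recurrence}{16 collagen genes from the recurrence-prone
#'     stroma contrast.}
#'   \item{collagen_metastasis}{the single collagen gene (Col6a1) from the
#'     metastasis-prone stroma contrast.}
#'   \item{glial}{8 glial-related genes with p-values per stromal list
#'     (blank cells are missing, stored as `NA`).}
#'   \item{proteomic}{30 proteomically upregulated genes cross-tabbed
#'     against the three stromal lists; `metabolism` flags the
#'     metabolism-associated entries.}
#' }
#'
#' @param name one of the panel names above.
#' @return a [panel()].
#' @examples
#' load_fixture_panel("collagen_metastasis")$table$gene  # "Col6a1"
#' @export
load_fixture_panel <- function(name) {
  if (length(name) != 1 || !name %in% names(.fixture_panels))
    stop("unknown panel '", paste(name, collapse = ","),
         "'; available: ", paste(names(.fixture_panels), collapse = ", "),
         call. = FALSE)
  path <- system.file("extdata", .fixture_panels[[name]],
                      package = "overlapEnrich", mustWork = TRUE)
  read_panel(path, name = name)
}

#' The packaged reference membership set behind the collagen bold flags
#'
#' The collagen cross-tab fixtures flag genes by membership in a reference
#' list (the Cav-1 (-/-) stromal up-genes, whose full content is
#' unpublished). This returns the reconstructed membership set shipped
#' with the package, sufficient to reproduce every flag in the collagen
#' panels.
#'
#' @return a [gene_list()].
#' @export
load_fixture_reference <- function() {
  path <- system.file("extdata", "cav1_collagen_reference.txt",
                      package = "overlapEnrich", mustWork = TRUE)
  read_gene_list(path, name = "cav1_collagen_reference")
}

#' Read a panel from TSV
#'
#' @param path TSV with a header; must include `gene` and `description`
#'   columns. Logical columns (`TRUE`/`FALSE`) are parsed as such;
#'   `p_`-prefixed columns are kept as printed strings.
#' @param name panel name; defaults to the file name.
#' @return a [panel()].
#' @export
read_panel <- function(path, name = NULL) {
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           na.strings = NULL, comment.char = "#")
  for (j in seq_along(tab)) {
    v <- tab[[j]]
    if (all(v %in% c("TRUE", "FALSE"))) tab[[j]] <- as.logical(v)
  }
  panel(tab, name = name)
}

#' Write a panel to TSV (round-trip safe)
#'
#' Printed p-value strings are written verbatim; derived `_num` columns
#' are omitted so that write-then-read reproduces the panel exactly.
#'
#' @param x a [panel()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_panel <- function(x, path) {
  stopifnot(inherits(x, "panel"))
  tab <- x$table
  tab <- tab[, !endsWith(names(tab), "_num"), drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Cross-tabulate a panel against one or more reference gene lists
#'
#' Recomputes, for every panel gene, whether it belongs to each reference
#' list after symbol harmonization (uppercasing), i.e. the membership flags
#' a published table would print in bold. Summary counts (flagged / total)
#' are reported per list.
#'
#' @param pan a [panel()].
#' @param reference a [gene_list()] (or character vector), or a named list
#'   of them for a multi-list cross-tab.
#' @return an object of class `panel_crosstab`: list with `panel_name`,
#'   `table` (panel genes plus one logical `in_<list>` column per
#'   reference) and `counts` (data.frame of `list`, `flagged`, `total`).
#' @examples
#' ct <- cross_tabulate(load_fixture_panel("collagen_metastasis"),
#'                      load_fixture_reference())
#' ct$counts  # 1 flagged of 1
#' @export
cross_tabulate <- function(pan, reference) {
  stopifnot(inherits(pan, "panel"))
  refs <- if (inherits(reference, "gene_list") || is.character(reference))
    list(reference) else reference
  if (is.null(names(refs)) || any(!nzchar(names(refs))))
    names(refs) <- vapply(seq_along(refs), function(i) {
      r <- refs[[i]]
      if (inherits(r, "gene_list")) r$name else paste0("list", i)
    }, character(1))
  genes_h <- toupper(pan$table$gene)
  tab <- pan$table
  counts <- data.frame(list = character(), flagged = integer(),
                       total = integer(), stringsAsFactors = FALSE)
  for (nm in names(refs)) {
    rid <- harmonize_symbols(refs[[nm]], quiet = TRUE)$ids
    flag <- genes_h %in% rid
    tab[[paste0("in_", nm)]] <- flag
    counts <- rbind(counts, data.frame(list = nm, flagged = sum(flag),
                                       total = length(flag),
                                       stringsAsFactors = FALSE))
  }
  structure(list(panel_name = pan$name, table = tab, counts = counts),
            class = "panel_crosstab")
}

#' @export
print.panel_crosstab <- function(x, ...) {
  cat(sprintf("panel_crosstab '%s':\n", x$panel_name))
  for (i in seq_len(nrow(x$counts)))
    cat(sprintf("  %s: %d flagged of %d\n", x$counts$list[i],
                x$counts$flagged[i], x$counts$total[i]))
  invisible(x)
}

#' Write a panel cross-tab as TSV
#'
#' @param x a `panel_crosstab`.
#' @param path output TSV; summary counts go into `#` header comments.
#' @return `path`, invisibly.
#' @export
write_crosstab <- function(x, path) {
  stopifnot(inherits(x, "panel_crosstab"))
  hdr <- c(sprintf("# panel: %s", x$panel_name),
           sprintf("# %s: %d flagged of %d", x$counts$list,
                   x$counts$flagged, x$counts$total))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  tab <- x$table[, !endsWith(names(x$table), "_num"), drop = FALSE]
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
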