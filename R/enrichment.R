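#' Read a gene-set collection from a GMT file
#'
#' Standard GMT semantics: one set per line, tab-separated, with the set
#' name in column 1, a free-form description in column 2, and member
#' identifiers from column 3 on. Blank member fields are dropped and
#' members are deduplicated within each set.
#'
#' @param path GMT file. An empty file yields an empty collection; a line
#'   with fewer than 3 fields or a duplicated set name is an error naming
#'   the offending line.
#' @return an object of class `gene_set_collection`: list with `names`,
#'   `descriptions` and `sets` (named list of character vectors).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(structure(list(names = character(), descriptions = character(),
                          sets = list()), class = "gene_set_collection"))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  nm <- vapply(parts, `[[`, character(1), 1L)
  dup <- which(duplicated(nm))
  if (length(dup))
    stop("duplicate set name '", nm[dup[1]], "' at GMT line ", dup[1],
         call. = FALSE)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nm
  structure(list(names = nm, descriptions = stats::setNames(desc, nm),
                 sets = sets),
            class = "gene_set_collection")
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection$names, function(nm)
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets\n", length(x$names)))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$names)

#' Overlap-based enrichment scan of a query list against a collection
#'
#' For each gene set, members are harmonized and intersected with the
#' universe; the overlap with the (harmonized, universe-restricted) query
#' is scored by [hypergeometric_overlap_p()]. Sets with no in-universe
#' members are excluded. This is pure overlap counting — no rank-based
#' statistic.
#'
#' Rows are sorted by ascending p-value; ties are broken by larger overlap
#' and then lexicographic set name, so output files are deterministic.
#'
#' @param query a [gene_list()] (or character vector); must be non-empty
#'   after restriction to the universe.
#' @param collection a `gene_set_collection` from [read_gmt()].
#' @param universe the gene universe as [gene_list()] or character vector.
#' @param pattern optional regular expression; only sets whose names match
#'   are scanned (the caller-selected "sub-collection").
#' @param adjust `"none"` (default, raw overlap p-values) or `"BH"` to add
#'   a Benjamini-Hochberg adjusted column.
#' @return a data.frame of class `enrichment_table` with columns
#'   `set_name`, `description`, `set_size`, `overlap_size`, `p_value`,
#'   (optionally `p_adjust`), `overlap_genes` (comma-separated).
#' @export
enrich <- function(query, collection, universe, pattern = NULL,
                   adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(collection, "gene_set_collection"))
  uni <- harmonize_symbols(universe, quiet = TRUE)$ids
  if (!length(uni)) stop("empty universe", call. = FALSE)
  q <- if (inherits(query, "gene_list")) query else gene_list(query, "query")
  hq <- harmonize_symbols(q, quiet = TRUE)$ids
  hq <- hq[hq %in% uni]
  if (!length(hq)) stop("empty query after universe restriction",
                        call. = FALSE)
  nm <- collection$names
  if (!is.null(pattern)) nm <- nm[grepl(pattern, nm)]
  rows <- lapply(nm, function(s) {
    mem <- toupper(collection$sets[[s]])
    mem <- unique(mem[mem %in% uni])
    if (!length(mem)) return(NULL)
    ov <- mem[mem %in% hq]
    data.frame(set_name = s,
               description = unname(collection$descriptions[[s]]),
               set_size = length(mem), overlap_size = length(ov),
               p_value = hypergeometric_overlap_p(length(uni), length(mem),
                                                  length(hq), length(ov)),
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set_name = character(), description = character(),
                      set_size = integer(), overlap_size = integer(),
                      p_value = numeric(), overlap_genes = character(),
                      stringsAsFactors = FALSE)
  if (adjust == "BH" && nrow(out))
    out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  if (nrow(out)) {
    out <- out[order(out$p_value, -out$overlap_size, out$set_name), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "universe_size") <- length(uni)
  attr(out, "query_size") <- length(hq)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Write an enrichment table as TSV
#'
#' @param x an `enrichment_table`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
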