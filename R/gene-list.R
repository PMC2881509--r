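#' Named gene list with provenance
#'
#' A deduplicated, ordered set of gene identifiers carrying provenance
#' (which contrast produced it, at which thresholds) and, optionally, a
#' per-gene p-value map. Lists built by [build_up_list()] keep genes in
#' ascending-p order.
#'
#' @param ids character vector of gene identifiers; duplicates are removed
#'   keeping first occurrence (order preserved).
#' @param name short label for the list.
#' @param provenance named list of free-form provenance fields (contrast,
#'   alpha, fc_threshold, ...).
#' @param p_values optional numeric vector of per-gene p-values, either
#'   named by identifier or aligned to `ids` before deduplication.
#' @return an object of class `gene_list`.
#' @examples
#' gl <- gene_list(c("COL1A1", "GFAP", "COL1A1"), name = "demo")
#' length(gl)  # 2
#' @export
gene_list <- function(ids, name = "gene_list", provenance = list(),
                      p_values = NULL) {
  ids <- as.character(ids)
  ids <- ids[nzchar(ids)]
  if (!is.null(p_values)) {
    if (is.null(names(p_values))) {
      if (length(p_values) != length(ids))
        stop("unnamed 'p_values' must align with 'ids'", call. = FALSE)
      names(p_values) <- ids
    }
    p_values <- p_values[!duplicated(names(p_values))]
  }
  keep <- !duplicated(ids)
  structure(list(ids = ids[keep], name = name, provenance = provenance,
                 p_values = p_values),
            class = "gene_list")
}

#' @export
length.gene_list <- function(x) length(x$ids)

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("gene_list '%s': %d identifiers\n", x$name, length(x$ids)))
  if (length(x$ids))
    cat("  ", paste(utils::head(x$ids, 8), collapse = " "),
        if (length(x$ids) > 8) "..." else "", "\n")
  if (length(x$provenance))
    cat("  provenance:",
        paste(names(x$provenance), unlist(lapply(x$provenance, format)),
              sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.character.gene_list <- function(x, ...) x$ids

#' Read a gene list from a one-identifier-per-line text file
#'
#' Lines starting with `#` are treated as provenance comments and ignored
#' for membership. An optional second tab-separated column is read as a
#' p-value.
#'
#' @param path input file.
#' @param name list name; defaults to the file name without extension.
#' @return a [gene_list()].
#' @export
read_gene_list <- function(path, name = NULL) {
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (!length(lines)) return(gene_list(character(), name = name))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  pv <- NULL
  if (all(lengths(parts) >= 2L)) {
    pv <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
    if (anyNA(pv)) pv <- NULL else names(pv) <- ids
  }
  gene_list(ids, name = name, p_values = pv)
}

#' Write a gene list as one identifier per line
#'
#' Provenance is recorded as `#`-prefixed header comments; if the list
#' carries p-values they are written as a second tab-separated column.
#'
#' @param x a [gene_list()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(x, path) {
  stopifnot(inherits(x, "gene_list"))
  hdr <- c(sprintf("# gene_list: %s", x$name),
           sprintf("# n: %d", length(x$ids)))
  if (length(x$provenance))
    hdr <- c(hdr, sprintf("# %s: %s", names(x$provenance),
                          vapply(x$provenance, function(v)
                            paste(format(v), collapse = ","), character(1))))
  body <- x$ids
  if (!is.null(x$p_values) && all(x$ids %in% names(x$p_values)))
    body <- paste(x$ids, format(x$p_values[x$ids], digits = 15, trim = TRUE),
                  sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Harmonize gene symbols across species conventions
#'
#' Case-folds identifiers to uppercase (so mouse-style `Col1a1` and human
#' `COL1A1` collapse), optionally translates them through a two-column
#' ortholog map, and deduplicates. Identifiers absent from a supplied map
#' are dropped; the drop count is attached as attribute `n_dropped` and
#' reported via a message.
#'
#' @param x a [gene_list()] or character vector.
#' @param ortholog_map optional mapping: a named character vector
#'   (`from -> to`) or a two-column data.frame (`from`, `to`). Matching is
#'   case-insensitive on the `from` side; the `to` side is uppercased.
#' @param quiet suppress the dropped-identifier message.
#' @return a [gene_list()] of harmonized identifiers with attribute
#'   `n_dropped`.
#' @examples
#' harmonize_symbols(c("Col1a1", "COL1A1"))  # one member, COL1A1
#' @export
harmonize_symbols <- function(x, ortholog_map = NULL, quiet = FALSE) {
  gl <- if (inherits(x, "gene_list")) x else gene_list(x)
  ids <- toupper(gl$ids)
  pv <- gl$p_values
  if (!is.null(pv)) names(pv) <- toupper(names(pv))
  n_dropped <- 0L
  if (!is.null(ortholog_map)) {
    if (is.data.frame(ortholog_map)) {
      if (ncol(ortholog_map) < 2)
        stop("ortholog map must have two columns (from, to)", call. = FALSE)
      bad <- !nzchar(as.character(ortholog_map[[1]])) |
             !nzchar(as.character(ortholog_map[[2]])) |
             is.na(ortholog_map[[1]]) | is.na(ortholog_map[[2]])
      if (any(bad))
        stop("malformed ortholog map row(s): ",
             paste(which(bad), collapse = ", "), call. = FALSE)
      map <- stats::setNames(toupper(as.character(ortholog_map[[2]])),
                             toupper(as.character(ortholog_map[[1]])))
    } else {
      if (is.null(names(ortholog_map)))
        stop("ortholog map vector must be named (from -> to)", call. = FALSE)
      map <- stats::setNames(toupper(as.character(ortholog_map)),
                             toupper(names(ortholog_map)))
    }
    hit <- ids %in% names(map)
    n_dropped <- sum(!hit)
    if (n_dropped && !quiet)
      message(n_dropped, " identifier(s) absent from ortholog map dropped")
    if (!is.null(pv)) {
      pv <- pv[names(pv) %in% names(map)]
      names(pv) <- unname(map[names(pv)])
    }
    ids <- unname(map[ids[hit]])
  }
  out <- gene_list(ids, name = gl$name,
                   provenance = c(gl$provenance, list(harmonized = TRUE)),
                   p_values = pv)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read a two-column ortholog map from TSV
#'
#' @param path TSV with columns `from` and `to` (header optional but
#'   recommended); malformed rows (missing either field) raise an error
#'   naming the row.
#' @return a two-column data.frame usable as `ortholog_map` in
#'   [harmonize_symbols()].
#' @export
read_ortholog_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           comment.char = "#")
  if (ncol(tab) < 2)
    stop("ortholog map must have two columns", call. = FALSE)
  tab[, 1:2]
}
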