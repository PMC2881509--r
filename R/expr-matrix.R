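#' Two-group expression matrix
#'
#' Container for a genes x samples matrix of log-scale expression values
#' together with a case/control group label per sample. This is the input
#' object for [one_sided_up_test()].
#'
#' @param values numeric matrix, genes as rows and samples as columns, with
#'   unique non-empty rownames (gene identifiers) and colnames (sample
#'   identifiers). Values are assumed to be on a log2 scale (already
#'   normalized/summarized expression, as on a microarray).
#' @param groups character vector mapping samples to groups. Either named by
#'   sample identifier or in column order; every element must be `"case"` or
#'   `"control"`, both groups non-empty.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `groups` (named character vector aligned to columns).
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
#' em <- expression_matrix(m, c("case", "case", "case", "control", "control"))
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || anyDuplicated(gid) || any(!nzchar(gid)))
    stop("rownames must be unique non-empty gene identifiers", call. = FALSE)
  if (is.null(sid) || anyDuplicated(sid) || any(!nzchar(sid)))
    stop("colnames must be unique non-empty sample identifiers", call. = FALSE)
  groups <- as.character(groups)
  if (is.null(names(groups))) {
    if (length(groups) != ncol(values))
      stop("unnamed 'groups' must have one label per column", call. = FALSE)
    names(groups) <- sid
  }
  if (!all(sid %in% names(groups)))
    stop("every sample needs a group label; missing: ",
         paste(utils::head(setdiff(sid, names(groups)), 5), collapse = ", "),
         call. = FALSE)
  groups <- groups[sid]
  bad <- !groups %in% c("case", "control")
  if (any(bad))
    stop("group labels must be 'case' or 'control'; got: ",
         paste(unique(groups[bad]), collapse = ", "), call. = FALSE)
  if (!all(c("case", "control") %in% groups))
    stop("both groups must be non-empty", call. = FALSE)
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its group labels from TSV
#'
#' The matrix file is tab-separated with a header row of sample identifiers
#' and gene identifiers in the first column. The groups file is two-column
#' TSV (`sample`, `group`) with a header, `group` being `case` or `control`.
#'
#' @param matrix_path path to the genes x samples TSV.
#' @param groups_path path to the two-column sample/group TSV.
#' @return an [expression_matrix()] object.
#' @export
read_expression_matrix <- function(matrix_path, groups_path) {
  tab <- utils::read.delim(matrix_path, header = TRUE, row.names = 1,
                           check.names = FALSE, comment.char = "#")
  grp <- utils::read.delim(groups_path, header = TRUE,
                           colClasses = "character", comment.char = "#")
  if (ncol(grp) < 2)
    stop("groups file must have two columns (sample, group)", call. = FALSE)
  g <- grp[[2]]
  names(g) <- grp[[1]]
  expression_matrix(as.matrix(tab), g)
}

#' Write an expression matrix and its group labels as TSV
#'
#' @param em an [expression_matrix()].
#' @param matrix_path,groups_path output file paths (groups file optional:
#'   pass `NULL` to skip).
#' @return `matrix_path`, invisibly.
#' @export
write_expression_matrix <- function(em, matrix_path, groups_path = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(groups_path)) {
    utils::write.table(
      data.frame(sample = names(em$groups), group = unname(em$groups)),
      groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(matrix_path)
}
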