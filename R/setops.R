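#' Hypergeometric upper-tail overlap p-value
#'
#' Probability that a uniformly random subset of size `size_y` drawn from a
#' universe of `universe_size` genes overlaps a fixed set of `size_x` genes
#' in at least `overlap` members: `P(K >= overlap)` with
#' `K ~ Hypergeometric(universe_size, size_x, size_y)`. This is the
#' enrichment tail — large observed overlaps give small p — and the score
#' used throughout the package for list intersections and gene-set scans.
#'
#' The tail sum is accumulated in log space from log-gamma binomial
#' coefficients, so genome-scale arguments (N ~ 2e4, overlaps in the
#' thousands) neither overflow nor underflow.
#'
#' @param universe_size total number of available genes, N.
#' @param size_x,size_y sizes of the two sets (each <= N).
#' @param overlap observed intersection size, k. Must satisfy
#'   `max(0, size_x + size_y - N) <= k <= min(size_x, size_y)`.
#' @return the upper-tail probability, in (0, 1]. `overlap = 0` gives
#'   exactly 1. Arguments are recycled, so vector input is allowed.
#' @examples
#' hypergeometric_overlap_p(10, 4, 4, 4)  # 1 / choose(10, 4)
#' hypergeometric_overlap_p(100, 10, 10, 0)  # 1
#' @export
hypergeometric_overlap_p <- function(universe_size, size_x, size_y, overlap) {
  n <- max(length(universe_size), length(size_x), length(size_y),
           length(overlap))
  N <- rep_len(as.numeric(universe_size), n)
  nx <- rep_len(as.numeric(size_x), n)
  ny <- rep_len(as.numeric(size_y), n)
  k <- rep_len(as.numeric(overlap), n)
  bad <- is.na(N) | is.na(nx) | is.na(ny) | is.na(k) |
    N < 1 | nx < 0 | ny < 0 | k < 0 | nx > N | ny > N |
    k > pmin(nx, ny) | k < pmax(0, nx + ny - N) |
    N != floor(N) | nx != floor(nx) | ny != floor(ny) | k != floor(k)
  if (any(bad))
    stop("impossible overlap configuration at index ",
         paste(utils::head(which(bad), 5), collapse = ", "),
         " (need sizes <= N and max(0, |X|+|Y|-N) <= k <= min(|X|,|Y|))",
         call. = FALSE)
  vapply(seq_len(n), function(i)
    .hyper_upper_tail(N[i], nx[i], ny[i], k[i]), numeric(1))
}

# log-space sum of C(nx, j) C(N-nx, ny-j) / C(N, ny) over j = k..min(nx, ny)
.hyper_upper_tail <- function(N, nx, ny, k) {
  if (k <= max(0, nx + ny - N)) return(1)
  j <- seq.int(k, min(nx, ny))
  lp <- lchoose(nx, j) + lchoose(N - nx, ny - j) - lchoose(N, ny)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))  # clamp log-sum roundoff
}

#' Intersect two gene lists over a universe and score the overlap
#'
#' Both lists (and the universe) are symbol-harmonized first; list members
#' absent from the universe are dropped with a logged count rather than
#' silently enlarging N, keeping the hypergeometric null coherent. The
#' overlap is then scored with [hypergeometric_overlap_p()].
#'
#' @param x,y [gene_list()] objects (or character vectors).
#' @param universe the gene universe as a [gene_list()] or character vector
#'   — typically every identifier present in the expression input.
#' @param quiet suppress dropped-member messages.
#' @return an object of class `overlap_result`: list with `name_x`,
#'   `name_y`, `size_x`, `size_y`, `universe_size`, `overlap_size`,
#'   `overlap_genes`, `p_value`, `dropped_x`, `dropped_y`.
#' @export
intersect_lists <- function(x, y, universe, quiet = FALSE) {
  x <- if (inherits(x, "gene_list")) x else gene_list(x, name = "x")
  y <- if (inherits(y, "gene_list")) y else gene_list(y, name = "y")
  uni <- harmonize_symbols(universe, quiet = TRUE)$ids
  if (!length(uni)) stop("empty universe", call. = FALSE)
  hx <- harmonize_symbols(x, quiet = TRUE)$ids
  hy <- harmonize_symbols(y, quiet = TRUE)$ids
  dropped_x <- sum(!hx %in% uni)
  dropped_y <- sum(!hy %in% uni)
  if ((dropped_x || dropped_y) && !quiet)
    message("dropped members outside universe: ", dropped_x, " from '",
            x$name, "', ", dropped_y, " from '", y$name, "'")
  hx <- hx[hx %in% uni]
  hy <- hy[hy %in% uni]
  ov <- hx[hx %in% hy]
  structure(list(name_x = x$name, name_y = y$name,
                 size_x = length(hx), size_y = length(hy),
                 universe_size = length(uni), overlap_size = length(ov),
                 overlap_genes = ov,
                 p_value = hypergeometric_overlap_p(length(uni), length(hx),
                                                    length(hy), length(ov)),
                 dropped_x = dropped_x, dropped_y = dropped_y),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap '%s' (n=%d) x '%s' (n=%d) over N=%d: k=%d, p = %.3g\n",
    x$name_x, x$size_x, x$name_y, x$size_y, x$universe_size,
    x$overlap_size, x$p_value))
  invisible(x)
}

#' Write an overlap result as TSV (plus the overlap member list)
#'
#' @param x an `overlap_result`.
#' @param path output TSV for the summary row; the overlap members go to
#'   `<path>` with suffix `_genes.txt` unless `genes_path` is given.
#' @param genes_path optional explicit path for the member list.
#' @return `path`, invisibly.
#' @export
write_overlap_result <- function(x, path, genes_path = NULL) {
  stopifnot(inherits(x, "overlap_result"))
  df <- data.frame(name_x = x$name_x, name_y = x$name_y, size_x = x$size_x,
                   size_y = x$size_y, universe_size = x$universe_size,
                   overlap_size = x$overlap_size, p_value = x$p_value,
                   dropped_x = x$dropped_x, dropped_y = x$dropped_y)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(genes_path))
    genes_path <- paste0(tools::file_path_sans_ext(path), "_genes.txt")
  writeLines(x$overlap_genes, genes_path)
  invisible(path)
}

#' Disjoint Venn region counts for two or three gene lists
#'
#' Every list is harmonized and restricted to the universe, then each gene
#' in the union is assigned to exactly one membership region (e.g. `"110"`
#' = in lists 1 and 2 but not 3). Counts over regions sum to the union
#' size. Rendering is left to the user; this returns the count table a
#' Venn diagram would display.
#'
#' @param lists a list of 2 or 3 [gene_list()] objects (or character
#'   vectors); more are unsupported.
#' @param universe the gene universe.
#' @return a data.frame of class `venn_summary` with columns `region`
#'   (membership bit-string in list order), `sets` (readable label) and
#'   `count`; list names in attribute `set_names`.
#' @export
venn_regions <- function(lists, universe) {
  if (!is.list(lists) || inherits(lists, "gene_list"))
    stop("'lists' must be a list of 2 or 3 gene lists", call. = FALSE)
  if (length(lists) < 2 || length(lists) > 3)
    stop("venn_regions supports 2 or 3 lists, got ", length(lists),
         call. = FALSE)
  uni <- harmonize_symbols(universe, quiet = TRUE)$ids
  if (!length(uni)) stop("empty universe", call. = FALSE)
  gls <- lapply(seq_along(lists), function(i) {
    g <- lists[[i]]
    g <- if (inherits(g, "gene_list")) g else gene_list(g, paste0("list", i))
    ids <- harmonize_symbols(g, quiet = TRUE)$ids
    list(name = g$name, ids = ids[ids %in% uni])
  })
  nm <- vapply(gls, `[[`, character(1), "name")
  union_ids <- unique(unlist(lapply(gls, `[[`, "ids")))
  memb <- vapply(gls, function(g) union_ids %in% g$ids,
                 logical(length(union_ids)))
  if (length(union_ids) == 1L) memb <- matrix(memb, nrow = 1L)
  patt <- expand.grid(rep(list(c(TRUE, FALSE)), length(gls)))[
    , rev(seq_along(gls)), drop = FALSE]  # natural bit order
  patt <- patt[rowSums(patt) > 0, , drop = FALSE]
  region <- apply(patt, 1, function(r) paste(as.integer(r), collapse = ""))
  label <- apply(patt, 1, function(r)
    paste(nm[as.logical(r)], collapse = " & "))
  cnt <- apply(patt, 1, function(r) {
    if (length(union_ids) == 0) return(0L)
    sum(apply(memb, 1, function(m) all(m == as.logical(r))))
  })
  out <- data.frame(region = region, sets = label, count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  attr(out, "set_names") <- nm
  class(out) <- c("venn_summary", "data.frame")
  out
}
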