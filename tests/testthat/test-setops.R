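test_that("hypergeometric tail handles forced combinatorial cases", {
  expect_equal(hypergeometric_overlap_p(100, 10, 20, 0), 1)
  # only one 4-subset of 10 achieves full overlap with a fixed 4-set
  expect_equal(hypergeometric_overlap_p(10, 4, 4, 4), 1 / choose(10, 4),
               tolerance = 1e-12)
  # value frozen from the exhaustive-enumeration oracle (2036 / 15504)
  expect_equal(hypergeometric_overlap_p(20, 6, 5, 3), 2036 / 15504,
               tolerance = 1e-12)
  expect_equal(enum_overlap_p(20, 6, 5, 3), 2036 / 15504, tolerance = 1e-12)
  # disjoint lists covering the whole universe force k = 0, p = 1
  expect_equal(hypergeometric_overlap_p(10, 6, 4, 0), 1)
})

test_that("impossible configurations are rejected", {
  expect_error(hypergeometric_overlap_p(10, 4, 4, 5), "impossible")
  expect_error(hypergeometric_overlap_p(10, 11, 4, 2), "impossible")
  expect_error(hypergeometric_overlap_p(10, 6, 6, 1), "impossible")  # k < max(0, 12-10)
  expect_error(hypergeometric_overlap_p(10, 4, 4, -1), "impossible")
})

test_that("tail probability matches exhaustive enumeration for small N", {
  for (N in c(5, 7, 9)) {
    for (ny in 1:N) {
      subs <- utils::combn(N, ny)
      for (nx in 1:N) {
        cnt <- colSums(subs <= nx)
        for (k in max(0, nx + ny - N):min(nx, ny)) {
          expect_equal(hypergeometric_overlap_p(N, nx, ny, k),
                       mean(cnt >= k), tolerance = 1e-12,
                       label = sprintf("N=%d nx=%d ny=%d k=%d", N, nx, ny, k))
        }
      }
    }
  }
})

test_that("tail probability is symmetric in the set sizes and monotone in k", {
  set.seed(10)
  for (i in 1:50) {
    N <- sample(10:2000, 1)
    nx <- sample(1:N, 1); ny <- sample(1:N, 1)
    lo <- max(0, nx + ny - N); hi <- min(nx, ny)
    k <- if (lo == hi) lo else sample(lo:hi, 1)
    expect_equal(hypergeometric_overlap_p(N, nx, ny, k),
                 hypergeometric_overlap_p(N, ny, nx, k), tolerance = 1e-12)
    ks <- lo:hi
    p <- hypergeometric_overlap_p(N, nx, ny, ks)
    # non-increasing in k up to log-sum roundoff
    expect_true(all(diff(p) <= 1e-12 * pmax(p[-length(p)], 1e-300)))
    # mathematically 0 < p <= 1; deep tails may underflow double precision
    expect_true(all(p >= 0 & p <= 1))
    expect_true(p[1] > 0)  # at k = lo the tail is the whole mass
  }
})

test_that("log-space sum survives genome-scale arguments", {
  p <- hypergeometric_overlap_p(20000, 6777, 3500, 2000)
  expect_true(is.finite(p) && p > 0 && p < 1e-100)
})

test_that("intersect_lists scores, drops outsiders, and validates", {
  uni <- gene_list(sprintf("G%02d", 1:20), "uni")
  x <- gene_list(sprintf("G%02d", 1:6), "x")
  y <- gene_list(sprintf("G%02d", 4:8), "y")
  res <- intersect_lists(x, y, uni)
  expect_equal(res$overlap_size, 3)
  expect_setequal(res$overlap_genes, c("G04", "G05", "G06"))
  expect_equal(res$p_value, 2036 / 15504, tolerance = 1e-12)

  # x = y: overlap is the full list, minimal p for that configuration
  res <- intersect_lists(x, x, uni)
  expect_equal(res$overlap_size, 6)
  expect_equal(res$p_value, 1 / choose(20, 6), tolerance = 1e-12)

  # members outside the universe are dropped with a count, not added to N
  z <- gene_list(c("G01", "G02", "XX1", "XX2"), "z")
  expect_message(res <- intersect_lists(z, x, uni), "dropped")
  expect_equal(res$dropped_x, 2)
  expect_equal(res$size_x, 2)
  expect_equal(res$universe_size, 20)

  expect_error(intersect_lists(x, y, character()), "empty universe")
})

test_that("null-overlap p-values are super-uniform at N = 1000", {
  N <- 1000
  uni <- gene_list(sprintf("G%04d", 1:N))
  x <- gene_list(sprintf("G%04d", 1:100), "x")
  set.seed(123)
  p <- replicate(400, {
    y <- gene_list(sample(uni$ids, 80), "y")
    intersect_lists(x, y, uni, quiet = TRUE)$p_value
  })
  for (alpha in c(0.01, 0.05, 0.1, 0.25))
    # 3-sigma binomial slack on P(p <= alpha) <= alpha
    expect_lte(mean(p <= alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / length(p)))
})

test_that("venn regions partition the union for 2 and 3 lists", {
  uni <- gene_list(sprintf("G%02d", 1:10))
  a <- gene_list(sprintf("G%02d", 1:5), "a")
  b <- gene_list(sprintf("G%02d", 4:8), "b")
  c3 <- gene_list(sprintf("G%02d", c(1, 5, 8, 9)), "c")

  # two identical lists: only the intersection region is occupied
  vs <- venn_regions(list(a, a), uni)
  expect_equal(vs$count[vs$region == "11"], 5)
  expect_equal(sum(vs$count), 5)

  # disjoint lists: exclusive regions carry full list sizes
  d <- gene_list(sprintf("G%02d", 6:8), "d")
  vs <- venn_regions(list(a, d), uni)
  expect_equal(vs$count[vs$region == "10"], 5)
  expect_equal(vs$count[vs$region == "01"], 3)
  expect_equal(vs$count[vs$region == "11"], 0)

  # three lists against a brute-force membership tabulation
  vs <- venn_regions(list(a, b, c3), uni)
  for (r in seq_len(nrow(vs))) {
    bits <- as.logical(as.integer(strsplit(vs$region[r], "")[[1]]))
    manual <- sum(vapply(uni$ids, function(g)
      identical(c(g %in% a$ids, g %in% b$ids, g %in% c3$ids), bits),
      logical(1)))
    expect_equal(vs$count[r], manual, label = vs$region[r])
  }
  union_n <- length(unique(c(a$ids, b$ids, c3$ids)))
  expect_equal(sum(vs$count), union_n)

  expect_error(venn_regions(list(a, b, c3, d), uni), "2 or 3")
  expect_error(venn_regions(list(a), uni), "2 or 3")
})

test_that("symbol harmonization case-folds, maps, and reports drops", {
  gl <- harmonize_symbols(c("Col1a1", "COL1A1"))
  expect_equal(gl$ids, "COL1A1")
  expect_equal(attr(gl, "n_dropped"), 0)

  gl <- harmonize_symbols(gene_list("Gfap"), c(Gfap = "GFAP"))
  expect_equal(gl$ids, "GFAP")

  # identifier absent from a provided map is dropped and counted
  expect_message(
    gl <- harmonize_symbols(gene_list(c("Gfap", "Zzz9")),
                            c(Gfap = "GFAP")),
    "1 identifier")
  expect_equal(gl$ids, "GFAP")
  expect_equal(attr(gl, "n_dropped"), 1)

  bad_map <- data.frame(from = c("A", ""), to = c("B", "C"))
  expect_error(harmonize_symbols(gene_list("A"), bad_map),
               "malformed ortholog map row\\(s\\): 2")
})

test_that("overlap results and gene lists round-trip through files", {
  dir <- withr::local_tempdir()
  uni <- gene_list(sprintf("G%02d", 1:20))
  res <- intersect_lists(gene_list(sprintf("G%02d", 1:6), "x"),
                         gene_list(sprintf("G%02d", 4:8), "y"), uni)
  path <- file.path(dir, "ov.tsv")
  write_overlap_result(res, path)
  back <- utils::read.delim(path)
  expect_equal(back$p_value, res$p_value, tolerance = 1e-9)
  expect_identical(readLines(file.path(dir, "ov_genes.txt")),
                   res$overlap_genes)

  gl <- gene_list(c("COL1A1", "GFAP"), "demo",
                  provenance = list(alpha = 0.05),
                  p_values = c(COL1A1 = 0.01, GFAP = 0.002))
  gpath <- file.path(dir, "gl.txt")
  write_gene_list(gl, gpath)
  back <- read_gene_list(gpath)
  expect_identical(back$ids, gl$ids)
  expect_equal(back$p_values[back$ids], gl$p_values[gl$ids],
               tolerance = 1e-12)
})
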