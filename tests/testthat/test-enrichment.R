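test_that("GMT parsing follows standard semantics", {
  path <- write_tmp_gmt(c("SETA\tdesc a\tG1\tG2",
                          "SETB\tdesc b\tG2\tG2\tG3\t"))
  col <- read_gmt(path)
  expect_length(col, 2)
  expect_equal(col$sets$SETA, c("G1", "G2"))
  # duplicate members collapse; trailing blank fields are dropped
  expect_equal(col$sets$SETB, c("G2", "G3"))
  expect_equal(unname(col$descriptions["SETA"]), "desc a")

  empty <- write_tmp_gmt(character())
  expect_length(read_gmt(empty), 0)

  short <- write_tmp_gmt(c("SETA\tdesc\tG1", "ONLYNAME\tdesc"))
  expect_error(read_gmt(short), "line 2")
  dup <- write_tmp_gmt(c("SETA\td\tG1", "SETA\td\tG2"))
  expect_error(read_gmt(dup), "duplicate set name")
  expect_error(read_gmt("/nonexistent/x.gmt"), "no such file")
})

test_that("GMT files round-trip", {
  path <- write_tmp_gmt(c("SETA\tdesc a\tG1\tG2", "SETB\tdesc b\tG3"))
  col <- read_gmt(path)
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(col, out)
  expect_identical(read_gmt(out), col)
})

test_that("a query identical to one set ranks that set first", {
  uni <- gene_list(sprintf("G%02d", 1:50))
  path <- write_tmp_gmt(c(
    "TARGET\tmatches the query\tG01\tG02\tG03\tG04\tG05",
    "OTHER\tdisjoint from the query\tG20\tG21\tG22",
    "PARTIAL\thalf overlap\tG01\tG02\tG30\tG31"))
  tab <- enrich(gene_list(sprintf("G%02d", 1:5), "q"), read_gmt(path), uni)
  expect_equal(tab$set_name[1], "TARGET")
  expect_equal(tab$overlap_size[1], 5)
  expect_lt(tab$p_value[1], tab$p_value[2])
})

test_that("sets with no in-universe members are excluded", {
  uni <- gene_list(sprintf("G%02d", 1:20))
  path <- write_tmp_gmt(c("IN\td\tG01\tG02", "OUT\td\tZZ1\tZZ2"))
  tab <- enrich(gene_list(c("G01", "G03")), read_gmt(path), uni)
  expect_equal(tab$set_name, "IN")
})

test_that("every row's p equals the setops computation on its quadruple", {
  set.seed(5)
  uni <- gene_list(sprintf("G%03d", 1:200))
  lines <- vapply(1:20, function(i)
    paste(c(sprintf("SET%02d", i), "random set",
            sample(uni$ids, sample(5:40, 1))), collapse = "\t"),
    character(1))
  query <- gene_list(sample(uni$ids, 30), "q")
  tab <- enrich(query, read_gmt(write_tmp_gmt(lines)), uni)
  expect_equal(nrow(tab), 20)
  for (r in seq_len(nrow(tab)))
    expect_equal(tab$p_value[r],
                 hypergeometric_overlap_p(200, tab$set_size[r], 30,
                                          tab$overlap_size[r]),
                 tolerance = 1e-12)
  # deterministic sort: ascending p, ties by larger overlap then name
  expect_true(!is.unsorted(tab$p_value))
})

test_that("universe restriction only moves rows that lose members", {
  uni <- gene_list(sprintf("G%02d", 1:40))
  path <- write_tmp_gmt(c("LOW\td\tG01\tG02\tG03",
                          "HIGH\td\tG35\tG36\tG37\tG38"))
  q <- gene_list(c("G01", "G02", "G10"), "q")
  full <- enrich(q, read_gmt(path), uni)
  # drop G38 from the universe: LOW's quadruple is unchanged
  uni2 <- gene_list(setdiff(uni$ids, "G38"))
  restr <- enrich(q, read_gmt(path), uni2)
  lo_full <- full[full$set_name == "LOW", c("set_size", "overlap_size")]
  lo_restr <- restr[restr$set_name == "LOW", c("set_size", "overlap_size")]
  expect_equal(lo_restr, lo_full, ignore_attr = TRUE)
  expect_equal(restr[restr$set_name == "HIGH", "set_size"], 3)
})

test_that("pattern filter and BH flag behave", {
  uni <- gene_list(sprintf("G%02d", 1:30))
  path <- write_tmp_gmt(c("KEGG_A\td\tG01\tG02", "GO_B\td\tG03",
                          "KEGG_C\td\tG01\tG05\tG06"))
  q <- gene_list(c("G01", "G02", "G03"), "q")
  tab <- enrich(q, read_gmt(path), uni, pattern = "^KEGG_")
  expect_setequal(tab$set_name, c("KEGG_A", "KEGG_C"))
  tab <- enrich(q, read_gmt(path), uni, adjust = "BH")
  expect_true(all(diff(tab$p_adjust[order(tab$p_value)]) >= -1e-15))
  expect_true(all(tab$p_adjust >= tab$p_value - 1e-15))
})

test_that("empty query or universe is an input error", {
  path <- write_tmp_gmt("SETA\td\tG01")
  expect_error(enrich(gene_list(character()), read_gmt(path),
                      gene_list("G01")), "empty query")
  expect_error(enrich(gene_list("G01"), read_gmt(path),
                      gene_list(character())), "empty universe")
  # a query entirely outside the universe is also empty after restriction
  expect_error(enrich(gene_list("ZZ"), read_gmt(path), gene_list("G01")),
               "empty query")
})

test_that("null minimum p over a random collection behaves as expected", {
  # min over m independent super-uniform draws: P(min <= a) <= 1-(1-a)^m
  set.seed(77)
  N <- 2000
  uni <- gene_list(sprintf("G%04d", 1:N))
  query <- gene_list(sample(uni$ids, 100), "q")
  mins <- replicate(30, {
    lines <- vapply(1:25, function(i)
      paste(c(sprintf("S%02d", i), "r", sample(uni$ids, 50)),
            collapse = "\t"), character(1))
    gmt <- withr::local_tempfile(fileext = ".gmt")
    writeLines(lines, gmt)
    min(enrich(query, read_gmt(gmt), uni)$p_value)
  })
  bound <- 1 - (1 - 0.05)^25        # ~0.72
  expect_lte(mean(mins <= 0.05), bound + 3 * sqrt(bound * (1 - bound) / 30))
})
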