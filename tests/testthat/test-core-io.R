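test_that("expression matrix round-trips and transposes", {
  m <- small_expr()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, f)
  expect_equal(read_expression_matrix(f), m)
  # transposed layout reads back to the same matrix with the flag
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(t(m), ft)
  expect_equal(read_expression_matrix(ft, transpose = TRUE), m)
})

test_that("malformed expression files fail descriptively", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1.0\t2.0", "gB\t1.5\toops"), f)
  expect_error(read_expression_matrix(f), "gB.*s2|s2.*gB")
  writeLines(c("gene_id\ts1\ts2", "gA\t1.0\t2.0", "gB\t1.5"), f)
  expect_error(read_expression_matrix(f), "ragged")
  writeLines(c("gene_id\ts1", "gA\t1.0", "gB\t1.5"), f)
  expect_error(read_expression_matrix(f), "2 samples")
})

test_that("pair_list canonicalizes, rejects self-pairs, round-trips", {
  pl <- pair_list(c("z", "b", "q", "a", "k", "c", "d", "e", "f", "h"),
                  c("a", "c", "p", "x", "j", "x", "x", "x", "x", "x"),
                  c("pp", "mm", "pm", rep("pp", 7)),
                  c(5L, 3L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  expect_true(all(pl$gene1[pl$relation != "pm"] <
                  pl$gene2[pl$relation != "pm"]))
  expect_identical(pl$gene1[pl$relation == "pm"], "q")  # pm kept directed
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pairlist(pl, f)
  expect_equal(read_pairlist(f), pl)
  expect_error(pair_list("a", "a", "pp", 1L), "self-pairs")
})

test_that("pair-list and regnet parsers reject unknown tokens by line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene1\tgene2\trelation\tsupport", "a\tb\tpp\t3",
               "c\td\tqq\t1"), f)
  expect_error(read_pairlist(f), "qq.*line 3|line 3.*qq")
  writeLines(c("G1\tG2\tac", "G1\tG3\txx"), f)
  expect_error(read_regnet(f), "xx")
  writeLines("G1\tG2\tac", f)
  net <- read_regnet(f)
  expect_equal(net$interactions,
               data.frame(regulator = "G1", target = "G2", type = "ac",
                          stringsAsFactors = FALSE))
})

test_that("regnet round-trips including non-interacting universe genes", {
  net <- signed_regnet(
    data.frame(regulator = c("G1", "G2"), target = c("G2", "G3"),
               type = c("ac", "re"), stringsAsFactors = FALSE),
    gene_universe = c("G1", "G2", "G3", "bgr_001", "bgr_002"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_regnet(net, f)
  back <- read_regnet(f)
  expect_equal(back$interactions, net$interactions)
  expect_setequal(back$gene_universe, net$gene_universe)
})

test_that("collapse_to_genes de-duplicates pair-lists at the symbol level", {
  mapping <- c(p1 = "GENEA", p3 = "GENEA", p2 = "GENEB", p4 = "GENEB")
  pl <- pair_list(c("p1", "p3"), c("p2", "p4"), c("pp", "pp"), c(4L, 6L))
  out <- collapse_to_genes(pl, mapping)
  expect_equal(nrow(out), 1L)
  expect_equal(out$gene1, "GENEA")
  expect_equal(out$gene2, "GENEB")
  expect_equal(out$support, 6L)  # max support kept
  # identity mapping leaves a pair-list unchanged
  idm <- c(a = "a", b = "b", c = "c", d = "d")
  pl2 <- pair_list(c("a", "c"), c("b", "d"), c("pp", "pm"), c(1L, 2L))
  expect_equal(collapse_to_genes(pl2, idm), pl2)
  # pm direction is preserved: both symbol directions survive
  plm <- pair_list(c("p1", "p4"), c("p2", "p3"), c("pm", "pm"), c(2L, 3L))
  outm <- collapse_to_genes(plm, mapping)
  expect_equal(nrow(outm), 2L)
  expect_setequal(paste(outm$gene1, outm$gene2),
                  c("GENEA GENEB", "GENEB GENEA"))
  # idempotent: symbols pass through a second application unchanged
  expect_equal(collapse_to_genes(out, mapping), out)
  expect_error(collapse_to_genes(pl, character()), "non-empty")
})

test_that("collapse_to_genes on a matrix keeps duplicate-symbol rows", {
  m <- small_expr()
  mapping <- c(gA = "SYM1", gB = "SYM1", gC = "SYM2")
  out <- collapse_to_genes(m, mapping)
  expect_equal(rownames(out), c("SYM1", "SYM1", "SYM2"))
  expect_equal(unname(out), unname(m))
})

test_that("pair-lists from up/down gene sets are the full cross product", {
  pl <- build_pairlist_from_sets(gene_set("up", c("a", "b")),
                                 gene_set("down", c("c", "d")))
  expect_equal(nrow(pl), 4L)
  expect_true(all(pl$relation == "pm"))
  expect_setequal(paste(pl$gene1, pl$gene2),
                  c("a c", "a d", "b c", "b d"))
  expect_equal(nrow(build_pairlist_from_sets("a", "a")), 0L)
  expect_error(build_pairlist_from_sets(character(), "a"), "non-empty")
  # counting rule at the scale used for published up/down gene lists
  up <- sprintf("u%04d", 1:504)
  down <- sprintf("d%04d", 1:512)
  expect_equal(nrow(build_pairlist_from_sets(up, down)), 504L * 512L)
})

test_that("gene sets and identifier mappings read from disk", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# a comment", "TP53", "MYC", "TP53"), f)
  gs <- read_gene_set(f, name = "demo")
  expect_equal(gs$genes, c("TP53", "MYC"))
  fm <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe\tsymbol", "p1\tTP53", "p2\tMYC"), fm)
  expect_equal(read_mapping(fm), c(p1 = "TP53", p2 = "MYC"))
})
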