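test_that("GMT files round-trip", {
  sets <- list(A = c("g1", "g2", "g3"), B = c("g2", "g4"))
  path <- withr::local_tempfile()
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
})

test_that("hypergeometric ORA matches an explicit tail-sum oracle", {
  universe <- sprintf("g%04d", 1:1000)
  sets <- list(S = universe[1:10], all = universe)
  coll <- gene_set_collection(sets, universe)
  gene_list <- c(universe[1:5], universe[101:195])  # overlap 5, n = 100
  res <- hypergeometric_ora(gene_list, coll)
  # oracle: sum_{j >= 5} C(10,j) C(990,100-j) / C(1000,100)
  oracle <- sum(vapply(5:10, function(j) {
    exp(lchoose(10, j) + lchoose(990, 100 - j) - lchoose(1000, 100))
  }, numeric(1)))
  expect_equal(res$p[res$set == "S"], oracle, tolerance = 1e-12)
  # set == universe: overlap forced to |list|, p = 1
  expect_equal(res$p[res$set == "all"], 1)
  # zero overlap: p = 1
  res0 <- hypergeometric_ora(universe[500:520],
                             gene_set_collection(list(S = universe[1:10]),
                                                 universe))
  expect_equal(res0$p, 1)
})

test_that("ranked lists keep one entry per significant peak", {
  records <- data.frame(peak_id = c("p1", "p2", "p3", "p4"),
                        log2FC = c(2, -1, 1.5, 0.5),
                        padj = c(0.01, 0.2, 0.01, 0.04))
  ann <- data.frame(peak_id = c("p1", "p2", "p3", "p4"),
                    gene_id = c("gA", "gB", "gA", "gA"))
  ranked <- build_ranked_list(records, ann)
  expect_equal(nrow(ranked), sum(records$padj < 0.05))
  # three significant peaks on gene gA stay separate entries
  expect_equal(sum(ranked$gene_id == "gA"), 3)
  expect_equal(ranked$stat, sort(ranked$stat, decreasing = TRUE))
  # nothing significant -> empty with a warning
  records$padj <- 0.9
  expect_warning(empty <- build_ranked_list(records, ann), "no significant")
  expect_equal(nrow(empty), 0)
})

test_that("the running-sum score matches fgsea on duplicate-free lists", {
  withr::local_seed(10)
  N <- 150
  stats <- sort(rnorm(N, 0, 1.5), decreasing = TRUE)
  genes <- sprintf("g%03d", 1:N)
  for (i in 1:15) {
    idx <- sort(sample(N, sample(5:25, 1)))
    es1 <- atacwave:::gsea_es_from_positions(idx, abs(stats), N)
    es2 <- fgsea::calcGseaStat(setNames(stats, genes), idx, gseaParam = 1)
    expect_equal(es1, es2, tolerance = 1e-12)
  }
})

test_that("enrichment scores obey the symmetry and weight invariances", {
  withr::local_seed(11)
  N <- 120
  stats <- sort(rnorm(N, 0, 2), decreasing = TRUE)
  for (i in 1:10) {
    idx <- sample(N, 12)
    es <- atacwave:::gsea_es_from_positions(idx, abs(stats), N)
    # reversing the list and negating the statistics negates the score
    es_rev <- atacwave:::gsea_es_from_positions(N + 1 - idx,
                                                rev(abs(stats)), N)
    expect_equal(es_rev, -es, tolerance = 1e-12)
    # weight 0: any monotone rescaling of |stat| leaves the score unchanged
    w0 <- rep(1, N)
    expect_equal(atacwave:::gsea_es_from_positions(idx, w0, N),
                 atacwave:::gsea_es_from_positions(idx, 5 * w0 + 0, N),
                 tolerance = 1e-12)
  }
})

test_that("a top-loaded set scores positive and significant", {
  withr::local_seed(12)
  N <- 200
  genes <- sprintf("g%03d", 1:N)
  ranked <- data.frame(peak_id = genes, gene_id = genes,
                       stat = sort(rnorm(N, 0, 1), decreasing = TRUE))
  coll <- gene_set_collection(list(top = genes[1:15],
                                   rand = sample(genes, 15)), genes)
  res <- preranked_gsea(ranked, coll, n_perm = 500, seed = 1)
  top <- res[res$set == "top", ]
  expect_gt(top$ES, 0)
  expect_lte(top$perm_p, 0.05)
  expect_equal(top$direction, "increased")
  # structural invariants
  expect_true(all(res$FDR >= 0 & res$FDR <= 1))
  expect_true(all(sign(res$NES) == sign(res$ES)))
  # determinism
  res2 <- preranked_gsea(ranked, coll, n_perm = 500, seed = 1)
  expect_identical(res, res2)
})

test_that("duplicate handling collapses entries only on request", {
  ranked <- data.frame(peak_id = c("p1", "p2", "p3", "p4", "p5"),
                       gene_id = c("gA", "gA", "gB", "gC", "gD"),
                       stat = c(3, 2.5, 1, -1, -2))
  coll <- gene_set_collection(list(S = c("gA", "gB", "gC")),
                              c("gA", "gB", "gC", "gD"))
  full <- preranked_gsea(ranked, coll, n_perm = 100, seed = 2)
  expect_equal(full$n_hits, 4)  # both gA peaks count
  collapsed <- preranked_gsea(ranked, coll, n_perm = 100, seed = 2,
                              collapse = TRUE)
  expect_equal(collapsed$n_hits, 3)
})

test_that("reversibility flags require opposite signs in both comparisons", {
  a <- data.frame(set = c("S1", "S2", "S3"), NES = c(2, -1.5, 1),
                  significant = c(TRUE, FALSE, TRUE))
  b <- data.frame(set = c("S1", "S2", "S4"), NES = c(-1.8, -2, 1),
                  significant = c(TRUE, TRUE, FALSE))
  rev <- flag_reversible_sets(a, b)
  expect_equal(rev$reversible[rev$set == "S1"], TRUE)
  expect_equal(rev$reversible[rev$set == "S2"], FALSE)
  expect_false("S3" %in% rev$set)  # present in only one table
  expect_false("S4" %in% rev$set)
})

test_that("top_sets returns the extremes of each direction", {
  res <- data.frame(set = sprintf("S%d", 1:8),
                    NES = c(3, 2, 1, 0.5, -0.4, -1, -2, -3))
  ts <- top_sets(res, n = 2)
  expect_setequal(ts$set, c("S1", "S2", "S7", "S8"))
})
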