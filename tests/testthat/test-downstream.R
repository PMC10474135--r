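test_that("positional mapping respects the 10 kb window exactly", {
  genes <- data.frame(gene_id = "G1", chrom = "1",
                      start = 50000L, end = 60000L, symbol = "G1")
  snps <- data.frame(snp = c("in_window", "too_far", "in_body", "edge"),
                     chrom = "1",
                     pos = c(45000L, 39999L, 55000L, 40000L))
  got <- map_genes_positional(snps, genes, window_bp = 1e4)
  expect_setequal(got$snp, c("in_window", "in_body", "edge"))
  expect_equal(got[got$snp == "in_body"]$distance, 0L)
  expect_equal(got[got$snp == "in_window"]$distance, 5000L)
  # other chromosome never maps
  snps2 <- data.frame(snp = "x", chrom = "2", pos = 55000L)
  expect_equal(nrow(map_genes_positional(snps2, genes)), 0)
})

test_that("mapping grows monotonically with the window", {
  set.seed(71)
  genes <- data.frame(gene_id = paste0("G", 1:20), chrom = "1",
                      start = sort(sample.int(1e6, 20)), symbol = "x")
  genes$end <- genes$start + 5000L
  snps <- data.frame(snp = paste0("s", 1:100), chrom = "1",
                     pos = sample.int(1e6, 100))
  n0 <- nrow(map_genes_positional(snps, genes, window_bp = 0))
  n1 <- nrow(map_genes_positional(snps, genes, window_bp = 1e4))
  n2 <- nrow(map_genes_positional(snps, genes, window_bp = 5e4))
  expect_lte(n0, n1); expect_lte(n1, n2)
  # window 0 keeps only gene-body hits
  body <- map_genes_positional(snps, genes, window_bp = 0)
  expect_true(all(body$distance == 0))
})

test_that("multi-strategy gene union requires the minimum support", {
  pos <- data.frame(snp = "s1", gene_id = c("A", "B"))
  eq <- data.frame(snp = "s1", gene_id = c("B", "C"))
  got <- map_genes_union(pos, eqtl = eq, min_strategies = 2)
  expect_equal(got$gene_id, "B")
  all1 <- map_genes_union(pos, min_strategies = 1)
  expect_setequal(all1$gene_id, c("A", "B"))
})

test_that("hypergeometric tail matches exact enumeration", {
  # worked example: universe 20, set 5, drawn 5, overlap 3
  got <- hypergeometric_enrichment(paste0("g", 1:5),
                                   c(paste0("g", 1:3), "h1", "h2"),
                                   c(paste0("g", 1:5), paste0("h", 1:15)))
  expect_equal(got$overlap, 3)
  expect_equal(got$p, 1126 / 15504, tolerance = 1e-12)
  expect_equal(got$p, oracle_hyper_tail(20, 5, 5, 3), tolerance = 1e-12)
  # random instances against the enumeration oracle
  set.seed(72)
  for (rep in 1:30) {
    N <- sample(5:25, 1)
    uni <- paste0("u", seq_len(N))
    set <- sample(uni, sample.int(N, 1))
    mapped <- sample(uni, sample.int(N, 1))
    got <- hypergeometric_enrichment(mapped, set, uni)
    expect_equal(got$p, oracle_hyper_tail(N, length(set), length(mapped),
                                          got$overlap),
                 tolerance = 1e-12)
  }
})

test_that("hypergeometric degenerate cases and errors", {
  uni <- paste0("u", 1:10)
  # zero overlap: P(X >= 0) = 1
  expect_equal(hypergeometric_enrichment(uni[1:3], uni[8:10], uni)$p, 1)
  # gene set equal to the universe: overlap forced, p = 1
  expect_equal(hypergeometric_enrichment(uni[1:4], uni, uni)$p, 1)
  expect_error(hypergeometric_enrichment("x", "y", character()), "empty")
  expect_error(hypergeometric_enrichment("zzz", uni[1], uni), "outside")
})

test_that("Bonferroni adjustment caps at one and flags monotonically", {
  got <- bonferroni_adjust(c(0.0005, 0.01, 1), alpha = 0.05)
  expect_equal(got$p_adjusted, c(0.0015, 0.03, 1))
  expect_equal(got$significant, c(TRUE, TRUE, FALSE))
  # the per-test threshold for 65 tests
  expect_equal(0.05 / 65, 7.6923e-4, tolerance = 1e-4)
  expect_true(bonferroni_adjust(7e-4 * 65 / 65, alpha = 0.05)$significant)
  # single test: identity
  expect_equal(bonferroni_adjust(0.04)$p_adjusted, 0.04)
  # significance at m tests implies significance at any m' < m
  set.seed(73)
  p <- runif(50, 1e-6, 1)
  big <- bonferroni_adjust(p)
  small <- bonferroni_adjust(p[1:10])
  expect_true(all(!big$significant[1:10] | small$significant))
})

test_that("synthetic gene annotation is valid and mappable", {
  p <- sim_params(m = 2000, seed = 74)
  genes <- simulate_gene_annotation(p, n_genes = 50, seed = 2)
  expect_equal(nrow(genes), 50)
  expect_true(all(genes$start <= genes$end))
  expect_false(anyDuplicated(genes$gene_id) > 0)
  sim <- simulate_pair(p)
  mapped <- map_genes_positional(as.data.frame(sim$a)[1:200, ], genes)
  expect_true(all(mapped$gene_id %in% genes$gene_id))
})
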