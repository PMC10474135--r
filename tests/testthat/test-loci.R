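test_that("pairwise r2 has unit diagonal, allele-flip invariance, errors", {
  p <- sim_params(m = 100, block_size = 10, seed = 61)
  panel <- simulate_ld_panel(p, n_ref = 80)
  r2 <- pairwise_r2(panel, c("rs000001", "rs000002", "rs000011"))
  expect_equal(diag(r2), c(rs000001 = 1, rs000002 = 1, rs000011 = 1))
  expect_equal(r2, t(r2))
  # flipping the coded allele (dosage -> 2 - dosage) leaves r2 unchanged
  g <- panel$geno[, 1]
  expect_equal(cor(g, 2 - g)^2, 1)
  expect_error(pairwise_r2(panel, "nope"), "not present")
})

test_that("independent panel columns have near-null r2", {
  p <- sim_params(m = 50, block_size = 1, r_within = 0, seed = 62)
  panel <- simulate_ld_panel(p, n_ref = 1000)
  r2 <- pairwise_r2(panel, panel$snps$snp)
  off <- r2[upper.tri(r2)]
  expect_lt(median(off), 0.01)
  expect_lt(mean(off), 3 / 1000)
})

test_that("worked five-SNP instance clumps as expected", {
  snps <- paste0("s", 1:5)
  r2 <- diag(5)
  rownames(r2) <- colnames(r2) <- snps
  r2["s1", "s2"] <- r2["s2", "s1"] <- 0.8
  r2["s1", "s4"] <- r2["s4", "s1"] <- 0.05
  r2["s2", "s4"] <- r2["s4", "s2"] <- 0.05
  df <- data.frame(snp = snps, chrom = "1",
                   pos = c(1.0e6, 1.05e6, 1.1e6, 2.0e6, 2.1e6),
                   fdr = c(0.01, 0.02, 0.2, 0.04, 0.5))
  panel <- ld_panel_from_r2(df[, 1:3], r2)
  s <- make_ss(df$snp, df$chrom, df$pos, z = rep(1, 5))
  loci <- define_loci(df$fdr, s, panel, window_bp = Inf)
  expect_equal(nrow(loci), 2)
  expect_setequal(unlist(loci$ind_sig), c("s1", "s4"))
  expect_setequal(unlist(loci$leads), c("s1", "s4"))
  l1 <- loci[loci$lead_snp == "s1"]
  expect_setequal(unlist(l1$candidates), c("s1", "s2"))
  expect_false("s3" %in% unlist(loci$candidates))
})

test_that("lead SNPs within 250 kb merge into one locus, beyond stay apart", {
  snps <- c("a", "b")
  r2 <- diag(2); dimnames(r2) <- list(snps, snps)
  mk <- function(gap) {
    df <- data.frame(snp = snps, chrom = "1", pos = c(1e6, 1e6 + gap),
                     fdr = c(0.01, 0.02))
    panel <- ld_panel_from_r2(df[, 1:3], r2)
    s <- make_ss(df$snp, df$chrom, df$pos, z = c(3, 3))
    define_loci(df$fdr, s, panel, window_bp = Inf)
  }
  expect_equal(nrow(mk(2e5)), 1)   # 200 kb apart -> merged
  expect_equal(nrow(mk(3e5)), 2)   # 300 kb apart -> separate
  merged <- mk(2e5)
  expect_equal(merged$start, 1e6)
  expect_equal(merged$end, 1.2e6)
  expect_equal(merged$lead_snp, "a")
})

test_that("a lone significant SNP forms a singleton locus", {
  r2 <- matrix(1, 1, 1, dimnames = list("solo", "solo"))
  df <- data.frame(snp = "solo", chrom = "2", pos = 5e5, fdr = 0.01)
  panel <- ld_panel_from_r2(df[, 1:3], r2)
  s <- make_ss("solo", "2", 5e5, z = 4)
  loci <- define_loci(df$fdr, s, panel)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$start, loci$end)
  expect_equal(loci$start, 5e5)
})

test_that("define_loci matches the brute-force oracle on random instances", {
  for (seed in 1:120) {
    inst <- random_locus_instance(sample(4:12, 1), seed)
    s <- make_ss(inst$df$snp, inst$df$chrom, inst$df$pos,
                 z = rep(1, nrow(inst$df)))
    got <- define_loci(inst$df$fdr, s, inst$panel, window_bp = Inf)
    want <- oracle_loci(inst$df, inst$r2)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
      next
    }
    expect_equal(nrow(got), length(want), info = paste("seed", seed))
    for (i in seq_along(want)) {
      expect_equal(got$start[i], want[[i]]$start, info = paste("seed", seed))
      expect_equal(got$end[i], want[[i]]$end, info = paste("seed", seed))
      expect_setequal(got$leads[[i]], want[[i]]$leads)
      expect_setequal(got$candidates[[i]], want[[i]]$members)
      expect_equal(got$min_fdr[i], want[[i]]$min_fdr)
    }
  }
})

test_that("results do not depend on the input row order", {
  inst <- random_locus_instance(10, 999)
  s <- make_ss(inst$df$snp, inst$df$chrom, inst$df$pos, z = rep(1, 10))
  ref <- define_loci(inst$df$fdr, s, inst$panel, window_bp = Inf)
  set.seed(1); perm <- sample(10)
  s2 <- sumstats(as.data.frame(s)[perm, ])
  got <- define_loci(inst$df$fdr[perm], s2, inst$panel, window_bp = Inf)
  expect_equal(as.data.frame(ref[, .(chrom, start, end, lead_snp, min_fdr)]),
               as.data.frame(got[, .(chrom, start, end, lead_snp, min_fdr)]))
})

test_that("every significant SNP lands in exactly one candidate set", {
  for (seed in c(5, 17, 23)) {
    inst <- random_locus_instance(12, seed)
    s <- make_ss(inst$df$snp, inst$df$chrom, inst$df$pos, z = rep(1, 12))
    loci <- define_loci(inst$df$fdr, s, inst$panel, window_bp = Inf)
    sig <- inst$df$snp[inst$df$fdr < 0.05]
    if (!nrow(loci)) next
    membership <- table(unlist(loci$candidates))
    expect_true(all(sig %in% names(membership)))
    expect_true(all(membership == 1))
  }
})

test_that("locus overlap pairing and unique-locus merging work", {
  mk_loci <- function(chrom, start, end, lead) {
    structure(data.table::data.table(
      chrom = chrom, start = start, end = end, lead_snp = lead,
      min_fdr = 0.01, n_ind_sig = 1L, n_candidates = 1L,
      leads = as.list(lead), ind_sig = as.list(lead),
      candidates = as.list(lead), label = "x"),
      class = c("loci", class(data.table::data.table())))
  }
  a <- mk_loci("1", 100L, 200L, "la")
  b <- mk_loci("1", 150L, 300L, "lb")
  ov <- overlap_loci(a, b)
  expect_equal(nrow(ov$pairs), 1)
  expect_equal(ov$unique$start, 100L)
  expect_equal(ov$unique$end, 300L)
  # different chromosomes never overlap
  b2 <- mk_loci("2", 100L, 200L, "lb2")
  expect_equal(nrow(overlap_loci(a, b2)$pairs), 0)
  expect_equal(nrow(overlap_loci(a, b2)$unique), 2)
  # three pairwise-overlapping analyses reduce to one unique locus
  c3 <- mk_loci("1", 180L, 260L, "lc")
  u <- unique_loci(list(a, b, c3))
  expect_equal(nrow(u), 1)
  expect_equal(u$n_analyses, 3L)
})

test_that("effect-direction concordance counts and excludes correctly", {
  loci <- structure(data.table::data.table(
    chrom = "1", start = c(1L, 100L, 200L, 300L),
    end = c(50L, 150L, 250L, 350L),
    lead_snp = c("l1", "l2", "l3", "l4"),
    min_fdr = 0.01, n_ind_sig = 1L, n_candidates = 1L,
    leads = list("l1", "l2", "l3", "l4"),
    ind_sig = list("l1", "l2", "l3", "l4"),
    candidates = list("l1", "l2", "l3", "l4"), label = "x"),
    class = c("loci", class(data.table::data.table())))
  a <- make_ss(c("l1", "l2", "l3", "l4"), "1", c(1, 100, 200, 300),
               z = c(3, -2, 1, 2))
  b <- make_ss(c("l1", "l2", "l3"), "1", c(1, 100, 200),
               z = c(2, -1, -2))
  cc <- suppressMessages(effect_concordance(loci, a, b))
  expect_equal(cc$table$status, c("concordant", "concordant", "discordant",
                                  "indeterminate"))
  expect_equal(cc$summary$n_concordant, 2L)
  expect_equal(cc$summary$n_determinate, 3L)
  expect_equal(cc$summary$percent, 67)
  # the reported style: 19 of 20 concordant = 95%
  expect_equal(round(100 * 19 / 20), 95)
})

test_that("locus truth scoring flags intervals without shared causals", {
  truth <- data.table::data.table(
    snp = c("t1", "t2"), chrom = "1", pos = c(120L, 500L), block = 1L,
    causal1 = c(TRUE, TRUE), causal2 = c(TRUE, FALSE),
    beta1 = 0.1, beta2 = 0.1)
  loci <- structure(data.table::data.table(
    chrom = "1", start = c(100L, 400L), end = c(200L, 600L),
    lead_snp = c("l1", "l2"), min_fdr = 0.01, n_ind_sig = 1L,
    n_candidates = 1L, leads = list("l1", "l2"),
    ind_sig = list("l1", "l2"), candidates = list("l1", "l2"),
    label = "x"), class = c("loci", class(data.table::data.table())))
  sc <- locus_fdp(loci, truth, require = "both")
  expect_equal(sc$is_true, c(TRUE, FALSE))
  expect_equal(sc$fdp, 0.5)
  expect_equal(locus_fdp(loci, truth, require = "trait1")$fdp, 0)
  empty <- loci[0]
  expect_equal(locus_fdp(empty, truth)$fdp, 0)
})
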