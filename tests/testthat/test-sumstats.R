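test_that("reading reconstructs z from beta and p, and filters bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "SNP\tCHR\tBP\tA1\tA2\tBETA\tP\tN",
    "rs1\t1\t1000\tA\tG\t0.1\t0.0455\t1000",
    "rs2\t1\t2000\tC\tT\t-0.2\t0.0455\t1000",
    "rs3\t1\t3000\tA\tG\t0.3\t1.0\t1000",
    "rs4\t1\t4000\tA\tG\t0.3\t0\t1000",
    "rs5\t1\t5000\tA\tN\t0.3\t0.5\t1000",
    "rs6\t1\t6000\tA\tA\t0.3\t0.5\t1000"
  ), f)
  s <- suppressMessages(read_sumstats(f))
  expect_setequal(s$snp, c("rs1", "rs2", "rs3"))
  expect_equal(s[s$snp == "rs1"]$z, 2.0, tolerance = 1e-3)
  expect_equal(s[s$snp == "rs2"]$z, -2.0, tolerance = 1e-3)
  expect_equal(s[s$snp == "rs3"]$z, 0)
  log <- attr(s, "filter_log")
  expect_equal(log$dropped_bad_alleles, 2L)
  expect_equal(log$dropped_bad_stat, 1L)
  # p/z consistency invariant after construction
  expect_equal(s$p, 2 * pnorm(-abs(s$z)), tolerance = 1e-6)
})

test_that("reading fails hard on missing mandatory columns and empty files", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tA1\tA2\tP", "rs1\t1\tA\tG\t0.5"), f)
  expect_error(read_sumstats(f), "BP")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("SNP\tCHR\tBP\tA1\tA2\tZ", f2)
  expect_error(read_sumstats(f2), "empty")
})

test_that("round trip through write_sumstats preserves content", {
  s <- ss_from_z(c(1.5, -0.5, 2.5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(s, f)
  s2 <- read_sumstats(f)
  expect_equal(as.data.frame(s2), as.data.frame(s), tolerance = 1e-12)
})

test_that("allele harmonization handles swaps, strand flips, palindromes", {
  a <- sumstats(data.frame(
    snp = c("r1", "r2", "r3", "r4", "r5"), chrom = "1",
    pos = 1:5 * 1000,
    a1 = c("A", "A", "A", "A", "A"),
    a2 = c("G", "G", "G", "T", "G"),
    z = c(2, 2, 2, 1, 2), n = 100))
  b <- sumstats(data.frame(
    snp = c("r1", "r2", "r3", "r4", "r5"), chrom = "1",
    pos = 1:5 * 1000,
    a1 = c("G", "T", "C", "A", "A"),
    a2 = c("A", "C", "T", "T", "C"),
    z = c(2, 2, 2, 1, 2), n = 100))
  h <- harmonize_pair(a, b)
  # r1: swap -> sign flips; r2: strand complement, same orientation;
  # r3: swap + complement -> sign flips; r4: palindromic, removed;
  # r5: irreconcilable alleles, removed
  expect_setequal(h$a$snp, c("r1", "r2", "r3"))
  expect_equal(h$b[h$b$snp == "r1"]$z, -2)
  expect_equal(h$b[h$b$snp == "r2"]$z, 2)
  expect_equal(h$b[h$b$snp == "r3"]$z, -2)
  expect_equal(h$b$a1, h$a$a1)
  expect_equal(h$log$removed_ambiguous, 1L)
  expect_equal(h$log$removed_mismatch, 1L)
})

test_that("harmonization is symmetric up to ordering", {
  set.seed(11)
  n <- 200
  alle <- t(replicate(n, sample(c("A", "C", "G", "T"), 2)))
  a <- sumstats(data.frame(snp = paste0("s", 1:n), chrom = "1",
                           pos = 1:n * 100, a1 = alle[, 1], a2 = alle[, 2],
                           z = rnorm(n), n = 100))
  flip <- runif(n) < 0.5
  b1 <- ifelse(flip, alle[, 2], alle[, 1])
  b2 <- ifelse(flip, alle[, 1], alle[, 2])
  b <- sumstats(data.frame(snp = paste0("s", 1:n), chrom = "1",
                           pos = 1:n * 100, a1 = b1, a2 = b2,
                           z = rnorm(n), n = 100))
  h1 <- harmonize_pair(a, b)
  h2 <- harmonize_pair(b, a)
  expect_setequal(h1$a$snp, h2$a$snp)
  k <- match(h1$a$snp, h2$a$snp)
  expect_equal(h1$a$z * h1$b$z, (h2$b$z * h2$a$z)[k])
})

test_that("harmonization errors when almost no SNPs are shared", {
  a <- ss_from_z(rnorm(200))
  b <- make_ss(paste0("other", 1:200), "1", 1:200 * 1e4, rnorm(200))
  expect_error(harmonize_pair(a, b), "shared")
})

test_that("exclusion regions drop MHC and 8p23.1 SNPs with closed bounds", {
  s <- sumstats(data.frame(
    snp = paste0("e", 1:6),
    chrom = c("6", "6", "6", "6", "8", "8"),
    pos = c(26e6, 25119105, 25119106, 33854734, 1e7, 12483983),
    a1 = "A", a2 = "G", z = 1, n = 100))
  out <- apply_exclusions(s)
  expect_setequal(out$snp, c("e2", "e4", "e6"))
  expect_equal(attr(out, "exclusion_log")$n_removed, 3L)
  # idempotent, and counts add up
  again <- apply_exclusions(out)
  expect_identical(again$snp, out$snp)
  expect_equal(attr(again, "exclusion_log")$n_removed, 0L)
  expect_equal(nrow(out) + 3L, nrow(s))
})

test_that("effective sample size follows the harmonic formula", {
  expect_equal(effective_sample_size(100, 100), 200)
  expect_equal(effective_sample_size(40675, 64643),
               4 / (1 / 40675 + 1 / 64643))
  expect_lt(abs(effective_sample_size(40675, 64643) - 99863.5), 1)
  expect_equal(effective_sample_size(1, 1e9), 4, tolerance = 1e-6)
  # symmetry and arithmetic-mean bound
  for (xy in list(c(3, 7), c(10, 1000), c(500, 500))) {
    expect_equal(effective_sample_size(xy[1], xy[2]),
                 effective_sample_size(xy[2], xy[1]))
    expect_lte(effective_sample_size(xy[1], xy[2]), sum(xy))
  }
  expect_equal(effective_sample_size(500, 500), 1000)
  expect_error(effective_sample_size(0, 10), "positive")
})
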