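test_that("the hand-computable stratum example matches the oracle exactly", {
  # stratum p2 <= 0.02 contains primary p-values {0.005, 0.2};
  # condFDR(0.005) = 0.005 / (1/2) = 0.01
  p1 <- c(0.005, 0.2, 0.9)
  p2 <- c(0.01, 0.02, 0.5)
  got <- condfdr_exact(p1, p2, t = 0.02)
  expect_identical(got, oracle_condfdr(p1, p2, 0.02))
  expect_equal(got[1], 0.01)
  expect_equal(got[2], 0.2)   # p / Fhat = 0.2 / 1
  expect_true(is.na(got[3]))
})

test_that("exact condFDR agrees with the brute-force oracle on random data", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    p1 <- runif(n)^2
    p2 <- runif(n)
    t <- runif(1, 0.05, 1)
    expect_equal(condfdr_exact(p1, p2, t), oracle_condfdr(p1, p2, t))
  }
  # largest p-value in a full stratum always gets condFDR 1
  expect_equal(condfdr_exact(c(1, 0.5), c(0.1, 0.1), 1)[1], 1)
})

test_that("the unconditional grid column reproduces p / Fhat(p)", {
  set.seed(42)
  z <- rnorm(4000)
  s <- ss_from_z(z)
  grid <- build_condfdr_grid(s, conditional = NULL,
                             opts = fdr_grid_opts(min_stratum = 10,
                                                  prune_iter = 0))
  assigned <- assign_condfdr(grid, s, conditional = NULL)
  exact <- condfdr_exact(s$p, rep(0.5, length(z)), t = 1)
  # grid nodes are 0.1 apart in -log10 p, so interpolation error is small
  expect_equal(assigned, exact, tolerance = 0.02)
})

test_that("a full conditioning threshold reproduces the unconditional grid", {
  set.seed(43)
  a <- ss_from_z(rnorm(3000))
  b <- ss_from_z(rnorm(3000))
  opts <- fdr_grid_opts(min_stratum = 10, prune_iter = 0)
  g_cond <- build_condfdr_grid(a, b, opts = opts)
  g_unc <- build_condfdr_grid(a, NULL, opts = opts)
  expect_equal(g_cond$values[, 1], g_unc$values[, 1])
})

test_that("grid values are monotone in both -log10 p axes", {
  p <- sim_params(m = 2e4, seed = 31)
  s <- simulate_pair(p)
  g <- build_condfdr_grid(s$a, s$b, opts = fdr_grid_opts(prune_iter = 0))
  expect_true(all(diff(g$values) <= 1e-12))        # down each column
  expect_true(all(t(diff(t(g$values))) <= 1e-12))  # along each row
  expect_true(all(g$values > 0 & g$values <= 1))
})

test_that("grid interpolation is exact on nodes and linear between them", {
  p <- sim_params(m = 2e4, seed = 32)
  s <- simulate_pair(p)
  g <- build_condfdr_grid(s$a, s$b, opts = fdr_grid_opts(prune_iter = 0))
  mk_at <- function(lp1, lp2) {
    list(a = make_ss("q1", "1", 100, qnorm(10^(-lp1) / 2) * -1),
         b = make_ss("q1", "1", 100, qnorm(10^(-lp2) / 2) * -1))
  }
  at <- mk_at(g$edges[31], g$edges[11])
  expect_equal(assign_condfdr(g, at$a, at$b), g$values[31, 11])
  mid <- mk_at((g$edges[31] + g$edges[32]) / 2, g$edges[11])
  expect_equal(assign_condfdr(g, mid$a, mid$b),
               mean(g$values[31:32, 11]))
})

test_that("conjunctional FDR is the element-wise maximum", {
  expect_equal(conjunctional_fdr(0.01, 0.03), 0.03)
  expect_equal(conjunctional_fdr(0.2, 0.2), 0.2)
  expect_error(conjunctional_fdr(1:3 / 10, 1:2 / 10), "length")
  set.seed(44)
  for (rep in 1:1000) {
    n <- sample(1:20, 1)
    x <- runif(n); y <- runif(n)
    cj <- conjunctional_fdr(x, y)
    expect_identical(cj, conjunctional_fdr(y, x))
    expect_true(all(cj >= x & cj >= y))
    expect_true(all(cj == pmax(x, y)))
  }
})

test_that("no excess discoveries under the global null", {
  p <- sim_params(m = 5e4, pi10 = 0, pi01 = 0, pi11 = 0, seed = 77)
  s <- simulate_pair(p)
  panel <- simulate_ld_panel(p, n_ref = 150)
  res <- cross_trait_fdr(s$a, s$b, panel = panel,
                         opts = fdr_grid_opts(prune_iter = 10, seed = 7))
  expect_lt(mean(res$table$conjfdr < 0.05), 2e-4)
  expect_lt(mean(res$table$condfdr_ab < 0.05), 1e-3)
})

test_that("condFDR reranks enriched strata below the unconditional FDR", {
  p <- sim_params(m = 3e4, pi11 = 0.01, pi10 = 0, pi01 = 0,
                  rho_shared = 0.9, seed = 78)
  s <- simulate_pair(p)
  panel <- simulate_ld_panel(p, n_ref = 150)
  opts <- fdr_grid_opts(prune_iter = 10, seed = 9)
  res <- cross_trait_fdr(s$a, s$b, panel = panel, opts = opts)
  unc <- empirical_fdr(s$a, panel = panel, opts = opts)
  enriched <- s$b$p < 0.01
  expect_lte(median(res$table$condfdr_ab[enriched]),
             median(unc[enriched]))
})
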