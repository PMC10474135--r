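#!/usr/bin/env Rscript
# LD score regression: per-trait SNP heritability and the cross-trait
# genetic correlation, with delete-one-block jackknife standard errors.
# The bivariate intercept is free, so correlated noise from sample overlap
# loads there instead of biasing rg.

suppressMessages(library(pleiocond))

params <- readRDS("results/data/params.rds")$params
a <- read_sumstats("results/data/trait1.sumstats.tsv")
b <- read_sumstats("results/data/trait2.sumstats.tsv")
h <- harmonize_pair(a, b)
panel <- simulate_ld_panel(params, n_ref = 200L)
scores <- compute_ld_scores(panel)

h2_1 <- estimate_h2(h$a, scores)
h2_2 <- estimate_h2(h$b, scores)
rg <- estimate_rg(h$a, h$b, scores)

dir.create("results/rg", showWarnings = FALSE, recursive = TRUE)
out <- data.table::data.table(
  quantity = c("h2_trait1", "h2_trait2", "gcov", "rg", "intercept_1",
               "intercept_2", "intercept_bivariate"),
  estimate = c(h2_1$h2, h2_2$h2, rg$gcov, rg$rg, h2_1$intercept,
               h2_2$intercept, rg$intercept_biv),
  se = c(h2_1$se_h2, h2_2$se_h2, NA, rg$se_rg, h2_1$se_intercept,
         h2_2$se_intercept, rg$se_intercept_biv),
  truth = c(true_h2(params, 1), true_h2(params, 2),
            true_rg(params) * sqrt(true_h2(params, 1) * true_h2(params, 2)),
            true_rg(params), 1, 1, params$rho_overlap))
data.table::fwrite(out, "results/rg/ldsc_estimates.tsv", sep = "\t")

cat(sprintf("h2 trait 1: %.3f (SE %.3f; truth %.3f)\n",
            h2_1$h2, h2_1$se_h2, true_h2(params, 1)))
cat(sprintf("h2 trait 2: %.3f (SE %.3f; truth %.3f)\n",
            h2_2$h2, h2_2$se_h2, true_h2(params, 2)))
cat(sprintf("rg = %.3f (SE %.3f; truth %.2f), bivariate intercept %.3f\n",
            rg$rg, rg$se_rg, true_rg(params), rg$intercept_biv))
cat("Table in results/rg/ldsc_estimates.tsv\n")
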