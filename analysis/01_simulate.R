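#!/usr/bin/env Rscript
# Generate the study dataset: a pair of GWAS summary statistics for two
# polygenic traits with a shared causal component (true rg = 0.3), block
# AR(1) LD, and a matching reference panel. Files go to results/data/.

suppressMessages(library(pleiocond))

params <- sim_params(m = 1e5, n1 = 5e4, n2 = 5e4,
                     pi10 = 3e-3, pi01 = 3e-3, pi11 = 2e-3,
                     rho_shared = 0.75, block_size = 50L, r_within = 0.9,
                     n_chrom = 2L, seed = 2026L)
sim <- simulate_pair(params)
panel <- simulate_ld_panel(params, n_ref = 200L)

paths <- write_simulation(sim, panel, dir = "results/data")
saveRDS(list(params = params), "results/data/params.rds")

cat(sprintf("Simulated %d SNPs on %d chromosomes (%d LD blocks)\n",
            params$m, params$n_chrom, length(panel$sizes)))
cat(sprintf("Trait 1: %d causal SNPs (h2 = %.2f), mean chi2 = %.2f\n",
            sum(sim$truth$causal1), true_h2(params, 1), mean(sim$a$z^2)))
cat(sprintf("Trait 2: %d causal SNPs (h2 = %.2f), mean chi2 = %.2f\n",
            sum(sim$truth$causal2), true_h2(params, 2), mean(sim$b$z^2)))
cat(sprintf("Shared causal SNPs: %d; true genetic correlation = %.2f\n",
            sum(sim$truth$causal1 & sim$truth$causal2), true_rg(params)))
cat("Files written:\n"); print(paths)
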