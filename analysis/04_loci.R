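#!/usr/bin/env Rscript
# Genomic risk loci from the per-SNP FDR values: FUMA-style clumping
# (independent significant SNPs FDR < 0.05 at r2 < 0.6; leads at r2 < 0.1;
# candidates FDR < 0.1 at r2 >= 0.6; 250 kb merge), overlap between the
# conditional and conjunctional analyses, unique loci, and lead-SNP
# effect-direction concordance, scored against the simulation truth.

suppressMessages(library(pleiocond))

params <- readRDS("results/data/params.rds")$params
truth <- data.table::fread("results/data/truth.tsv")
a <- read_sumstats("results/data/trait1.sumstats.tsv")
b <- read_sumstats("results/data/trait2.sumstats.tsv")
h <- harmonize_pair(a, b)
a <- apply_exclusions(h$a); b <- apply_exclusions(h$b)
panel <- simulate_ld_panel(params, n_ref = 200L)
tab <- data.table::fread("results/fdr/fdr_table.tsv")
stopifnot(identical(tab$snp, a$snp))

loci <- list(
  cond_ab = define_loci(tab$condfdr_ab, a, panel, label = "condfdr_ab"),
  cond_ba = define_loci(tab$condfdr_ba, b, panel, label = "condfdr_ba"),
  conj = define_loci(tab$conjfdr, a, panel, label = "conjfdr"))

dir.create("results/loci", showWarnings = FALSE, recursive = TRUE)
for (nm in names(loci)) {
  flat <- loci[[nm]][, .(chrom, start, end, lead_snp, min_fdr,
                         n_ind_sig, n_candidates)]
  data.table::fwrite(flat, sprintf("results/loci/loci_%s.tsv", nm),
                     sep = "\t")
  write_loci_bed(loci[[nm]], sprintf("results/loci/loci_%s.bed", nm))
}

cat(sprintf("condFDR loci: %d (A|B), %d (B|A); conjFDR shared loci: %d\n",
            nrow(loci$cond_ab), nrow(loci$cond_ba), nrow(loci$conj)))
uniq <- unique_loci(loci)
data.table::fwrite(uniq, "results/loci/unique_loci.tsv", sep = "\t")
cat(sprintf("Unique loci after merging across analyses: %d\n", nrow(uniq)))

ov <- overlap_loci(loci$cond_ab, loci$conj)
cat(sprintf("condFDR(A|B) loci overlapping a shared locus: %d of %d\n",
            ov$n_overlap_a, nrow(loci$cond_ab)))

cc <- effect_concordance(loci$conj, a, b)
data.table::fwrite(cc$table, "results/loci/concordance.tsv", sep = "\t")
cat(sprintf("Concordant lead-SNP effect directions: %d of %d (%d%%)\n",
            cc$summary$n_concordant, cc$summary$n_determinate,
            cc$summary$percent))

sc <- locus_fdp(loci$conj, truth, require = "both")
cat(sprintf("Truth check: %d of %d shared loci contain a shared causal SNP (FDP %.2f)\n",
            sc$n_true, sc$n_loci, sc$fdp))
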