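# Independent brute-force oracles and small fixture builders. These are
# deliberately naive (loops, exact enumeration) and share no code with the
# package implementations they check.

make_ss <- function(snp, chrom, pos, z, a1 = "A", a2 = "G", n = 1e4) {
  sumstats(data.frame(snp = snp, chrom = chrom, pos = pos,
                      a1 = a1, a2 = a2, z = z, n = n))
}

# z-vector -> sumstats on one synthetic chromosome at 10 kb spacing
ss_from_z <- function(z, chrom = "1", spacing = 1e4) {
  make_ss(sprintf("s%04d", seq_along(z)), chrom,
          seq_along(z) * spacing, z)
}

# brute-force conditional FDR: inclusive empirical CDF on the stratum
oracle_condfdr <- function(p1, p2, t) {
  in_s <- which(p2 <= t)
  out <- rep(NA_real_, length(p1))
  for (i in in_s) {
    F <- sum(p1[in_s] <= p1[i]) / length(in_s)
    out[i] <- min(1, p1[i] / F)
  }
  out
}

# exact hypergeometric upper tail by enumeration of the support
oracle_hyper_tail <- function(n_universe, n_set, n_draw, k_obs) {
  js <- k_obs:min(n_set, n_draw)
  js <- js[js >= max(0, n_draw - (n_universe - n_set))]
  sum(choose(n_set, js) * choose(n_universe - n_set, n_draw - js)) /
    choose(n_universe, n_draw)
}

# brute-force locus definition following the clumping rules step by step:
# greedy independent significant SNPs (FDR < sig, mutual r2 < r2_indep) in
# ascending (fdr, chrom, pos, snp) order; leads at mutual r2 < r2_lead;
# candidates (FDR < cand) attached to their max-r2 independent SNP; locus
# interval per lead from its candidates; intervals within merge_kb merged.
oracle_loci <- function(df, r2,
                        thr = list(sig = 0.05, cand = 0.1, r2_indep = 0.6,
                                   r2_lead = 0.1, merge_kb = 250)) {
  ord <- order(df$fdr, df$chrom, df$pos, df$snp)
  sig <- ord[df$fdr[ord] < thr$sig]
  indep <- integer(0)
  for (i in sig) {
    clash <- FALSE
    for (j in indep) {
      if (df$chrom[i] == df$chrom[j] &&
          r2[df$snp[i], df$snp[j]] >= thr$r2_indep) clash <- TRUE
    }
    if (!clash) indep <- c(indep, i)
  }
  leads <- integer(0)
  for (i in indep) {
    clash <- FALSE
    for (j in leads) {
      if (df$chrom[i] == df$chrom[j] &&
          r2[df$snp[i], df$snp[j]] >= thr$r2_lead) clash <- TRUE
    }
    if (!clash) leads <- c(leads, i)
  }
  if (!length(indep)) return(NULL)

  cand_owner <- list()
  for (k in which(df$fdr < thr$cand)) {
    best <- NA; best_r2 <- -1
    for (j in indep) {
      v <- if (df$chrom[k] == df$chrom[j]) r2[df$snp[k], df$snp[j]] else 0
      if (v > best_r2) { best_r2 <- v; best <- j }
    }
    if (best_r2 >= thr$r2_indep) cand_owner[[as.character(k)]] <- best
  }
  lead_of <- integer(0)
  for (j in indep) {
    best <- NA; best_r2 <- -1
    for (L in leads) {
      v <- if (df$chrom[j] == df$chrom[L]) r2[df$snp[j], df$snp[L]] else 0
      if (v > best_r2) { best_r2 <- v; best <- L }
    }
    lead_of[as.character(j)] <- best
  }
  loci <- list()
  for (L in leads) {
    mem <- as.integer(names(cand_owner))[
      vapply(cand_owner, function(o) lead_of[as.character(o)] == L, NA)]
    loci[[length(loci) + 1]] <- list(
      chrom = df$chrom[L], start = min(df$pos[mem]), end = max(df$pos[mem]),
      leads = df$snp[L], members = sort(df$snp[mem]),
      min_fdr = min(df$fdr[mem]))
  }
  o <- order(vapply(loci, `[[`, "", "chrom"),
             vapply(loci, `[[`, 0, "start"),
             vapply(loci, `[[`, 0, "end"))
  loci <- loci[o]
  merged <- list(loci[[1]])
  for (x in loci[-1]) {
    last <- merged[[length(merged)]]
    if (x$chrom == last$chrom &&
        x$start - max(last$end) <= thr$merge_kb * 1000) {
      last$end <- max(last$end, x$end)
      last$start <- min(last$start, x$start)
      last$leads <- c(last$leads, x$leads)
      last$members <- sort(unique(c(last$members, x$members)))
      last$min_fdr <- min(last$min_fdr, x$min_fdr)
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1]] <- x
    }
  }
  merged
}

# random small locus-definition instance: one chromosome, valid r2 matrix
# built from random dosage vectors so it is a true correlation structure
random_locus_instance <- function(n_snp, seed) {
  set.seed(seed)
  n_ind <- 80
  base <- matrix(rnorm(n_ind * n_snp), n_ind, n_snp)
  # induce LD by mixing neighbouring columns with random weights
  for (j in seq_len(n_snp)[-1]) {
    w <- runif(1)
    if (runif(1) < 0.6) base[, j] <- w * base[, j - 1] +
        (1 - w) * base[, j]
  }
  snp <- sprintf("v%02d", seq_len(n_snp))
  colnames(base) <- snp
  r2 <- cor(base)^2
  pos <- sort(sample.int(2e6, n_snp))
  df <- data.frame(snp = snp, chrom = "1", pos = pos,
                   fdr = runif(n_snp, 0, 0.2))
  panel <- ld_panel_from_r2(df[, c("snp", "chrom", "pos")], r2)
  list(df = df, r2 = r2, panel = panel)
}
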