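#' Parameters for the bivariate GWAS simulator
#'
#' Defines a pair of polygenic traits under a four-component causal mixture:
#' a fraction `pi10` of SNPs is causal for trait 1 only, `pi01` for trait 2
#' only, `pi11` for both (with per-SNP effect correlation `rho_shared`),
#' and the remainder is null for both. Effects are on the
#' standardized-genotype scale, so a trait's SNP heritability is
#' `(pi10 + pi11) * m * sigma1_sq` (and analogously for trait 2). LD is
#' block-diagonal with an AR(1) correlation `r_within^|i-j|` inside each
#' block of `block_size` SNPs and independence between blocks.
#' `rho_overlap` adds cross-trait correlated noise, the signature of shared
#' samples between the two GWAS.
#'
#' Defaults describe a moderately polygenic pair: `m = 1e5` SNPs, 0.5%
#' causal per trait with `sigma_sq = 6e-4` (per-trait h2 of 0.3), and
#' `rho_shared = 0.75` so the implied genetic correlation
#' `pi11 * rho_shared / sqrt((pi10 + pi11) * (pi01 + pi11))` is 0.30.
#'
#' @param m number of SNPs.
#' @param n1,n2 effective sample sizes of the two GWAS.
#' @param pi10,pi01,pi11 causal mixture fractions (sum must be <= 1).
#' @param sigma1_sq,sigma2_sq per-causal-SNP effect variances.
#' @param rho_shared effect correlation within the shared component, in
#'   \[-1, 1\].
#' @param block_size SNPs per LD block (>= 1).
#' @param r_within AR(1) LD correlation parameter in \[0, 1).
#' @param rho_overlap residual z-score correlation from sample overlap.
#' @param n_chrom chromosomes to tile the blocks over.
#' @param spacing_bp fixed SNP spacing in bp.
#' @param seed integer RNG seed; all simulator randomness derives from it.
#' @return a validated `sim_params` list.
#' @export
sim_params <- function(m = 1e5L, n1 = 5e4, n2 = 5e4,
                       pi10 = 3e-3, pi01 = 3e-3, pi11 = 2e-3,
                       sigma1_sq = 6e-4, sigma2_sq = 6e-4,
                       rho_shared = 0.75, block_size = 50L,
                       r_within = 0.9, rho_overlap = 0,
                       n_chrom = 2L, spacing_bp = 1e4L, seed = 42L) {
  p <- list(m = as.integer(m), n1 = n1, n2 = n2, pi10 = pi10, pi01 = pi01,
            pi11 = pi11, sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq,
            rho_shared = rho_shared, block_size = as.integer(block_size),
            r_within = r_within, rho_overlap = rho_overlap,
            n_chrom = as.integer(n_chrom), spacing_bp = as.integer(spacing_bp),
            seed = as.integer(seed))
  stopifnot(p$m >= 1, p$block_size >= 1, p$n1 > 0, p$n2 > 0,
            p$pi10 >= 0, p$pi01 >= 0, p$pi11 >= 0,
            p$pi10 + p$pi01 + p$pi11 <= 1,
            p$sigma1_sq >= 0, p$sigma2_sq >= 0,
            abs(p$rho_shared) <= 1, p$r_within >= 0, p$r_within < 1,
            abs(p$rho_overlap) <= 1, p$n_chrom >= 1, p$spacing_bp >= 1)
  class(p) <- "sim_params"
  p
}

# SNP map implied by sim_params: ids, chromosome tiling, positions at fixed
# spacing, block membership. Blocks never straddle a chromosome boundary.
snp_layout <- function(params) {
  m <- params$m
  n_full <- m %/% params$block_size
  rem <- m %% params$block_size
  sizes <- c(rep(params$block_size, n_full), if (rem > 0) rem)
  n_blocks <- length(sizes)
  chrom_of_block <- sort(rep_len(seq_len(min(params$n_chrom, n_blocks)),
                                 n_blocks))
  block_of_snp <- rep(seq_len(n_blocks), sizes)
  chrom <- as.character(chrom_of_block[block_of_snp])
  dt <- data.table(
    snp = sprintf("rs%06d", seq_len(m)),
    chrom = chrom,
    block = block_of_snp
  )
  dt[, pos := seq_len(.N) * params$spacing_bp, by = chrom]
  list(snps = dt[, .(snp, chrom, pos, block)], sizes = sizes)
}

ar1_cor <- function(k, rho) {
  rho ^ abs(outer(seq_len(k), seq_len(k), "-"))
}

# Apply an AR(1) per-block k x k transform (correlation matrix R, or its
# lower Cholesky factor L) to the rows of X, block by block. X is m x q with
# rows ordered by block; blocks of equal size are batched into one matrix
# multiply.
ar1_block_transform <- function(X, sizes, rho, type = c("R", "L")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  q <- ncol(X)
  out <- matrix(0, nrow(X), q)
  offsets <- cumsum(c(0L, sizes))
  for (k in unique(sizes)) {
    Tm <- ar1_cor(k, rho)
    if (type == "L") Tm <- t(chol(Tm))
    blocks <- which(sizes == k)
    rows <- unlist(lapply(blocks, function(b) offsets[b] + seq_len(k)),
                   use.names = FALSE)
    nb <- length(blocks)
    Xb <- array(X[rows, , drop = FALSE], dim = c(k, nb, q))
    res <- Tm %*% matrix(Xb, k, nb * q)
    out[rows, ] <- matrix(array(res, dim = c(k, nb, q)), k * nb, q)
  }
  out
}

#' Simulate an LD reference panel matching a simulation's SNP map
#'
#' Draws `n_ref` reference individuals whose standardized dosages follow the
#' block AR(1) correlation structure of `params` (Gaussian latent scale, so
#' the dosage correlation between SNPs at in-block distance d is exactly
#' `r_within^d` in expectation and cross-block correlation is zero).
#' Empirical pairwise r2 computed from the panel therefore estimates
#' `r_within^(2d)` with the usual `~1/n_ref` sampling noise floor.
#'
#' @param params a [sim_params()] object.
#' @param n_ref number of reference individuals (>= 50).
#' @return an `ld_panel`: list with `geno` (n_ref x m matrix, columns named
#'   by SNP id), `snps` (SNP map), `sizes` (block sizes), `r_within`.
#' @export
simulate_ld_panel <- function(params, n_ref = 200L) {
  stopifnot(inherits(params, "sim_params"), n_ref >= 50)
  layout <- snp_layout(params)
  set.seed(params$seed + 10007L)
  Z <- matrix(rnorm(params$m * n_ref), params$m, n_ref)
  G <- ar1_block_transform(Z, layout$sizes, params$r_within, type = "L")
  geno <- t(G)
  colnames(geno) <- layout$snps$snp
  structure(list(geno = geno, r2 = NULL, snps = layout$snps,
                 sizes = layout$sizes, r_within = params$r_within),
            class = "ld_panel")
}

#' Build an LD panel from a precomputed pairwise r2 matrix
#'
#' For small worked examples and user-supplied LD references: `r2` must be
#' symmetric with unit diagonal and entries in \[0, 1\], with rows/columns
#' named by SNP id.
#'
#' @param snps data.frame with `snp`, `chrom`, `pos` (and optionally
#'   `block`).
#' @param r2 square symmetric matrix of pairwise r2, dimnames = SNP ids.
#' @return an `ld_panel`.
#' @export
ld_panel_from_r2 <- function(snps, r2) {
  snps <- as.data.table(snps)
  r2 <- as.matrix(r2)
  stopifnot(nrow(r2) == ncol(r2), nrow(r2) == nrow(snps),
            all(abs(r2 - t(r2)) < 1e-8), all(r2 >= 0), all(r2 <= 1 + 1e-8),
            all(abs(diag(r2) - 1) < 1e-8))
  if (is.null(rownames(r2))) dimnames(r2) <- list(snps$snp, snps$snp)
  if (!("block" %in% names(snps))) snps[, block := 1L]
  structure(list(geno = NULL, r2 = pmin(r2, 1), snps = snps[, .(snp, chrom, pos, block)],
                 sizes = as.integer(table(snps$block)), r_within = NA_real_),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("LD panel: %d SNPs in %d block(s)%s\n",
              nrow(x$snps), length(x$sizes),
              if (is.null(x$geno)) " (precomputed r2)"
              else sprintf(", %d reference individuals", nrow(x$geno))))
  invisible(x)
}

# Per-block empirical r2 matrices from panel dosages (or slices of a
# precomputed r2 matrix). `adjust` applies the small-sample correction
# r2 - (1 - r2)/(n_ref - 2), used for LD scores.
block_r2 <- function(panel, adjust = FALSE) {
  stopifnot(inherits(panel, "ld_panel"))
  offsets <- cumsum(c(0L, panel$sizes))
  lapply(seq_along(panel$sizes), function(b) {
    idx <- offsets[b] + seq_len(panel$sizes[b])
    if (!is.null(panel$geno)) {
      r2 <- cor(panel$geno[, idx, drop = FALSE])^2
      if (adjust) {
        nr <- nrow(panel$geno)
        r2 <- r2 - (1 - r2) / (nr - 2)
        diag(r2) <- 1
      }
      r2
    } else {
      panel$r2[idx, idx, drop = FALSE]
    }
  })
}

#' Simulate a pair of GWAS summary statistics with known causal truth
#'
#' Causal status per SNP is drawn from the four-component mixture of
#' `params`; shared-component effect pairs have correlation `rho_shared`.
#' Marginal z-scores follow `z_t = sqrt(n_t) * R beta_t + e_t`, where `R`
#' is the block AR(1) LD correlation matrix and the noise vectors `e_1,
#' e_2` each have correlation `R` within a trait and cross-trait covariance
#' `rho_overlap * R` (the sample-overlap channel). Two-sided p-values are
#' `2 * pnorm(-|z|)`. Fully deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return list with `a`, `b` (harmonized-ready [sumstats()] objects) and
#'   `truth` (data.table: snp, chrom, pos, block, causal1, causal2, beta1,
#'   beta2).
#' @export
simulate_pair <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  layout <- snp_layout(params)
  m <- params$m
  set.seed(params$seed)

  u <- runif(m)
  c11 <- u < params$pi11
  c10 <- !c11 & u < params$pi11 + params$pi10
  c01 <- !c11 & !c10 & u < params$pi11 + params$pi10 + params$pi01
  causal1 <- c11 | c10
  causal2 <- c11 | c01

  beta1 <- numeric(m)
  beta2 <- numeric(m)
  beta1[c10] <- rnorm(sum(c10), sd = sqrt(params$sigma1_sq))
  beta2[c01] <- rnorm(sum(c01), sd = sqrt(params$sigma2_sq))
  k11 <- sum(c11)
  if (k11 > 0) {
    g1 <- rnorm(k11)
    g2 <- params$rho_shared * g1 +
      sqrt(1 - params$rho_shared^2) * rnorm(k11)
    beta1[c11] <- sqrt(params$sigma1_sq) * g1
    beta2[c11] <- sqrt(params$sigma2_sq) * g2
  }

  Rb <- ar1_block_transform(cbind(beta1, beta2), layout$sizes,
                            params$r_within, type = "R")
  u1 <- rnorm(m)
  u2 <- params$rho_overlap * u1 +
    sqrt(1 - params$rho_overlap^2) * rnorm(m)
  E <- ar1_block_transform(cbind(u1, u2), layout$sizes,
                           params$r_within, type = "L")
  z1 <- sqrt(params$n1) * Rb[, 1] + E[, 1]
  z2 <- sqrt(params$n2) * Rb[, 2] + E[, 2]

  base <- layout$snps[, .(snp, chrom, pos)]
  mk <- function(zv, nv) {
    sumstats(data.table(base, a1 = "A", a2 = "G", z = zv, n = nv))
  }
  truth <- data.table(layout$snps,
                      causal1 = causal1, causal2 = causal2,
                      beta1 = beta1, beta2 = beta2)
  list(a = mk(z1, params$n1), b = mk(z2, params$n2), truth = truth)
}

#' True heritability and genetic correlation implied by simulation settings
#'
#' `true_h2` returns `(pi_causal) * m * sigma_sq` for one trait;
#' `true_rg` returns
#' `pi11 * rho_shared / sqrt((pi10 + pi11) * (pi01 + pi11))`.
#'
#' @param params a [sim_params()] object.
#' @param trait 1 or 2.
#' @return scalar.
#' @export
true_h2 <- function(params, trait = 1) {
  if (trait == 1) (params$pi10 + params$pi11) * params$m * params$sigma1_sq
  else (params$pi01 + params$pi11) * params$m * params$sigma2_sq
}

#' @rdname true_h2
#' @export
true_rg <- function(params) {
  denom <- sqrt((params$pi10 + params$pi11) * (params$pi01 + params$pi11))
  if (denom == 0) return(NA_real_)
  params$pi11 * params$rho_shared / denom
}

#' Analytic LD scores of the AR(1) block design
#'
#' For a SNP at within-block index i of a block of size k, the LD score is
#' `sum_j r_within^(2 |i - j|)` (self term included). Used as the
#' noise-free reference for the empirical scores of
#' [compute_ld_scores()].
#'
#' @param params a [sim_params()] object.
#' @return numeric vector of length `m`.
#' @export
analytic_ld_scores <- function(params) {
  layout <- snp_layout(params)
  rho2 <- params$r_within^2
  unlist(lapply(layout$sizes, function(k) {
    vapply(seq_len(k), function(i) sum(rho2 ^ abs(i - seq_len(k))), 0)
  }), use.names = FALSE)
}

#' Write a simulated dataset to disk in the package's exchange formats
#'
#' Writes the two sumstats tables (TSV), the truth table (TSV), the panel
#' dosage matrix (TSV) and the LD-block spans as BED (0-based half-open).
#'
#' @param sim result of [simulate_pair()].
#' @param panel optional [simulate_ld_panel()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, panel = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    trait1 = file.path(dir, "trait1.sumstats.tsv"),
    trait2 = file.path(dir, "trait2.sumstats.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_sumstats(sim$a, paths[["trait1"]])
  write_sumstats(sim$b, paths[["trait2"]])
  fwrite(sim$truth, paths[["truth"]], sep = "\t")
  if (!is.null(panel) && !is.null(panel$geno)) {
    paths[["panel"]] <- file.path(dir, "panel.dosages.tsv")
    fwrite(as.data.table(round(panel$geno, 4)), paths[["panel"]], sep = "\t")
    bed <- panel$snps[, .(start = min(pos) - 1L, end = max(pos)),
                      by = .(chrom, block)]
    paths[["blocks"]] <- file.path(dir, "blocks.bed")
    fwrite(bed[, .(chrom, start, end, name = paste0("block", block))],
           paths[["blocks"]], sep = "\t", col.names = FALSE)
  }
  invisible(paths)
}
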