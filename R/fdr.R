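#' Options for the empirical condFDR grid
#'
#' @param bin grid resolution on both `-log10 p` axes.
#' @param max_log10 axis cap; more significant p-values are clamped to the
#'   boundary cell.
#' @param min_stratum conditional strata with fewer SNPs fall back to the
#'   nearest less-strict stratum's values.
#' @param prune_iter number of LD random-pruning iterations to average the
#'   grid over (0 disables pruning; requires an LD panel otherwise).
#' @param r2_prune pruning threshold: within a clump of SNPs with pairwise
#'   r2 above this, one random SNP is kept per iteration.
#' @param seed RNG seed for the pruning iterations (NULL = current RNG
#'   state).
#' @return an options list.
#' @export
fdr_grid_opts <- function(bin = 0.1, max_log10 = 20, min_stratum = 100L,
                          prune_iter = 20L, r2_prune = 0.1, seed = NULL) {
  stopifnot(bin > 0, max_log10 > bin, min_stratum >= 1,
            prune_iter >= 0, r2_prune > 0, r2_prune < 1)
  list(bin = bin, max_log10 = max_log10, min_stratum = as.integer(min_stratum),
       prune_iter = as.integer(prune_iter), r2_prune = r2_prune, seed = seed)
}

# C[i, j] = number of SNPs with lp1 >= edges[i] and lp2 >= edges[j]
tail_counts_2d <- function(lp1, lp2, edges) {
  nb <- length(edges)
  bin <- edges[2] - edges[1]
  i <- pmin(floor(lp1 / bin), nb - 1) + 1
  j <- pmin(floor(lp2 / bin), nb - 1) + 1
  cnt <- matrix(tabulate(i + (j - 1) * nb, nbins = nb * nb), nb, nb)
  A <- apply(cnt[nb:1, , drop = FALSE], 2, cumsum)[nb:1, , drop = FALSE]
  t(apply(A[, nb:1, drop = FALSE], 1, cumsum))[, nb:1, drop = FALSE]
}

# Raw (single-subset) condFDR grid: cell (i, j) holds
# min(1, p1_i / Fhat(p1_i | p2 <= t_j)) with the inclusive empirical CDF
# evaluated at the grid nodes. Empty cells above the data range are filled
# by the running minimum along the primary axis (values can only shrink as
# p1 becomes more significant).
condfdr_grid_raw <- function(lp1, lp2, edges, min_stratum) {
  C <- tail_counts_2d(lp1, lp2, edges)
  sizes <- C[1, ]
  p1_nodes <- 10^(-edges)
  Fhat <- sweep(C, 2, pmax(sizes, 1), "/")
  v <- p1_nodes / Fhat
  v[C == 0] <- Inf
  # small-stratum fallback: carry the last adequately sized column forward
  last_ok <- 1L
  for (j in seq_along(sizes)[-1]) {
    if (sizes[j] < min_stratum) v[, j] <- v[, last_ok] else last_ok <- j
  }
  v <- apply(v, 2, cummin)
  pmin(v, 1)
}

#' Build the condFDR lookup grid for a primary trait given a conditional one
#'
#' Estimates, on a regular grid over `(-log10 p_primary, -log10
#' p_conditional)`, the conditional FDR `min(1, p1 / Fhat(p1 | p2 <= t))`,
#' the conservative (`pi0 = 1`) empirical-Bayes bound on the posterior
#' probability that a SNP is null for the primary trait given that both its
#' p-values are at least as small as observed. Empirical CDFs are inclusive
#' ("as small as or smaller"). When an LD panel is supplied, the grid is
#' averaged over `prune_iter` random-pruning iterations, each keeping one
#' random SNP per clump of SNPs in LD above `r2_prune`, which corrects the
#' stratum CDFs for LD-induced dependence. Monotone regularization (running
#' minima along both axes) is applied last so the surface is non-increasing
#' in both `-log10 p` coordinates.
#'
#' @param primary,conditional harmonized `sumstats` in identical SNP order;
#'   `conditional = NULL` gives the unconditional empirical-FDR grid
#'   (single stratum containing every SNP).
#' @param panel optional `ld_panel` covering the same SNPs (required when
#'   `opts$prune_iter > 0`).
#' @param opts see [fdr_grid_opts()].
#' @return an `fdr_grid`: list with `edges`, `values` (primary axis in
#'   rows, conditional in columns), `strata_sizes` (full-data stratum
#'   sizes), `n_iter`, `opts`.
#' @export
build_condfdr_grid <- function(primary, conditional = NULL, panel = NULL,
                               opts = fdr_grid_opts()) {
  stopifnot(inherits(primary, "sumstats"))
  lp1 <- -log10(primary$p)
  if (is.null(conditional)) {
    lp2 <- rep(0, nrow(primary))
  } else {
    stopifnot(inherits(conditional, "sumstats"),
              nrow(primary) == nrow(conditional),
              all(primary$snp == conditional$snp))
    lp2 <- -log10(conditional$p)
  }
  edges <- seq(0, opts$max_log10, by = opts$bin)

  use_prune <- opts$prune_iter > 0 && !is.null(panel)
  if (use_prune) {
    stopifnot(inherits(panel, "ld_panel"))
    idx_map <- match(primary$snp, panel$snps$snp)
    if (anyNA(idx_map)) stop("panel does not cover all SNPs")
    blocks <- block_r2(panel)
    if (!is.null(opts$seed)) set.seed(opts$seed)
    acc <- 0
    for (it in seq_len(opts$prune_iter)) {
      keep_panel <- random_prune_indices(blocks, opts$r2_prune)
      keep <- which(idx_map %in% keep_panel)
      acc <- acc + condfdr_grid_raw(lp1[keep], lp2[keep], edges,
                                    opts$min_stratum)
    }
    v <- acc / opts$prune_iter
    n_iter <- opts$prune_iter
  } else {
    v <- condfdr_grid_raw(lp1, lp2, edges, opts$min_stratum)
    n_iter <- 1L
  }
  # definitional monotonicity of the posterior-null surface
  v <- apply(v, 2, cummin)
  v <- t(apply(v, 1, cummin))
  sizes <- tail_counts_2d(lp1, lp2, edges)[1, ]
  structure(list(edges = edges, values = v, strata_sizes = sizes,
                 n_iter = n_iter, opts = opts),
            class = "fdr_grid")
}

#' @export
print.fdr_grid <- function(x, ...) {
  cat(sprintf("condFDR grid: %d x %d nodes (bin %.2g), %d pruning iteration(s)\n",
              length(x$edges), length(x$edges), x$opts$bin, x$n_iter))
  invisible(x)
}

# One LD random-pruning pass over per-block r2 matrices; returns kept
# global SNP indices. Greedy over a random order: a SNP is kept iff its r2
# with every already-kept SNP of its block is <= threshold.
random_prune_indices <- function(blocks_r2, r2_threshold) {
  offset <- 0L
  kept_all <- vector("list", length(blocks_r2))
  for (b in seq_along(blocks_r2)) {
    r2m <- blocks_r2[[b]]
    k <- nrow(r2m)
    if (k == 1L) {
      kept_all[[b]] <- offset + 1L
    } else {
      ord <- sample.int(k)
      kept <- integer(0)
      for (jj in ord) {
        if (!length(kept) || all(r2m[jj, kept] <= r2_threshold)) {
          kept <- c(kept, jj)
        }
      }
      kept_all[[b]] <- offset + sort(kept)
    }
    offset <- offset + k
  }
  unlist(kept_all, use.names = FALSE)
}

#' Assign per-SNP condFDR values from a grid
#'
#' Bilinear interpolation of the grid at each SNP's `(-log10 p1, -log10
#' p2)`; coordinates beyond the grid range are clamped to the boundary and
#' values clipped to (0, 1].
#'
#' @param grid an `fdr_grid` from [build_condfdr_grid()].
#' @param primary,conditional harmonized `sumstats`; `conditional = NULL`
#'   evaluates at `-log10 p2 = 0` (unconditional column).
#' @return numeric vector of condFDR values, one per SNP.
#' @export
assign_condfdr <- function(grid, primary, conditional = NULL) {
  stopifnot(inherits(grid, "fdr_grid"), inherits(primary, "sumstats"))
  x <- -log10(primary$p)
  y <- if (is.null(conditional)) rep(0, nrow(primary)) else -log10(conditional$p)
  edges <- grid$edges
  nb <- length(edges)
  bin <- edges[2] - edges[1]
  xi <- pmin(pmax(x / bin, 0), nb - 1)
  yi <- pmin(pmax(y / bin, 0), nb - 1)
  i0 <- pmin(floor(xi) + 1L, nb - 1L)
  j0 <- pmin(floor(yi) + 1L, nb - 1L)
  fx <- xi - (i0 - 1L)
  fy <- yi - (j0 - 1L)
  v <- grid$values
  out <- v[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    v[cbind(i0 + 1L, j0)] * fx * (1 - fy) +
    v[cbind(i0, j0 + 1L)] * (1 - fx) * fy +
    v[cbind(i0 + 1L, j0 + 1L)] * fx * fy
  pmax(pmin(out, 1), .Machine$double.xmin)
}

#' Exact (ungridded) conditional FDR on a stratum
#'
#' Direct evaluation of `min(1, p1 / Fhat(p1 | p2 <= t))` with the
#' inclusive empirical CDF computed on the stratum itself — the
#' hand-computable form of the estimator, suitable for small worked
#' examples and as a cross-check of the grid. Elements outside the stratum
#' get `NA`.
#'
#' @param p1,p2 primary and conditional p-value vectors (same length).
#' @param t conditional cutoff defining the stratum `p2 <= t`.
#' @return numeric vector of condFDR values (NA outside the stratum).
#' @export
condfdr_exact <- function(p1, p2, t = 1) {
  stopifnot(length(p1) == length(p2), t > 0, t <= 1)
  in_s <- p2 <= t
  out <- rep(NA_real_, length(p1))
  ps <- p1[in_s]
  if (length(ps)) {
    Fhat <- vapply(ps, function(x) mean(ps <= x), 0)
    out[in_s] <- pmin(1, ps / Fhat)
  }
  out
}

#' Conjunctional FDR of two reciprocal condFDR vectors
#'
#' The element-wise maximum of condFDR(trait A | trait B) and
#' condFDR(trait B | trait A): a conservative estimate of the posterior
#' probability that a SNP is null for either trait.
#'
#' @param cond_ab,cond_ba aligned per-SNP condFDR vectors.
#' @return per-SNP conjFDR vector.
#' @export
conjunctional_fdr <- function(cond_ab, cond_ba) {
  if (length(cond_ab) != length(cond_ba)) {
    stop("condFDR vectors have different lengths (",
         length(cond_ab), " vs ", length(cond_ba), ")")
  }
  pmax(cond_ab, cond_ba)
}

#' Unconditional empirical FDR per SNP
#'
#' The single-stratum special case of the condFDR machinery:
#' `min(1, p / Fhat(p))` with optional LD random-pruning averaging,
#' assigned back to every SNP through the same grid interpolation. Used as
#' the baseline when quantifying the power gained by conditioning.
#'
#' @inheritParams build_condfdr_grid
#' @return numeric vector of empirical FDR values, one per SNP.
#' @export
empirical_fdr <- function(primary, panel = NULL, opts = fdr_grid_opts()) {
  grid <- build_condfdr_grid(primary, conditional = NULL, panel = panel,
                             opts = opts)
  assign_condfdr(grid, primary, conditional = NULL)
}

#' Full cross-trait FDR table for a harmonized pair
#'
#' Builds both directional condFDR grids (A|B and B|A), assigns per-SNP
#' values, and combines them into the conjunctional FDR.
#'
#' @param a,b harmonized `sumstats` in identical SNP order.
#' @param panel optional `ld_panel` for pruning-aware grids.
#' @param opts see [fdr_grid_opts()].
#' @return list with `table` (data.table: snp, chrom, pos, p1, p2, z1, z2,
#'   condfdr_ab, condfdr_ba, conjfdr) and the two grids (`grid_ab`,
#'   `grid_ba`).
#' @export
cross_trait_fdr <- function(a, b, panel = NULL, opts = fdr_grid_opts()) {
  grid_ab <- build_condfdr_grid(a, b, panel = panel, opts = opts)
  grid_ba <- build_condfdr_grid(b, a, panel = panel, opts = opts)
  cond_ab <- assign_condfdr(grid_ab, a, b)
  cond_ba <- assign_condfdr(grid_ba, b, a)
  tab <- data.table(snp = a$snp, chrom = a$chrom, pos = a$pos,
                    p1 = a$p, p2 = b$p, z1 = a$z, z2 = b$z,
                    condfdr_ab = cond_ab, condfdr_ba = cond_ba,
                    conjfdr = conjunctional_fdr(cond_ab, cond_ba))
  list(table = tab, grid_ab = grid_ab, grid_ba = grid_ba)
}
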