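#' LD scores from a reference panel
#'
#' The LD score of SNP j is the sum of its squared correlations with every
#' panel SNP within `window_bp` of it (self term included, so scores are
#' at least ~1). Because the simulated panel has independent LD blocks,
#' sums are taken within blocks; with `adjust = TRUE` the small-sample
#' bias correction `r2 - (1 - r2) / (n_ref - 2)` is applied to off-diagonal
#' terms so that truly uncorrelated pairs contribute zero in expectation.
#'
#' @param panel an `ld_panel` with dosages.
#' @param window_bp window radius in bp.
#' @param adjust apply the small-sample r2 bias correction.
#' @return an `ld_scores` list: `l` (per-SNP scores), `snps`, `M`
#'   (number of SNPs).
#' @export
compute_ld_scores <- function(panel, window_bp = 1e6, adjust = TRUE) {
  stopifnot(inherits(panel, "ld_panel"))
  blocks <- block_r2(panel, adjust = adjust)
  pos <- panel$snps$pos
  offsets <- cumsum(c(0L, panel$sizes))
  spacing <- if (nrow(panel$snps) > 1) min(diff(sort(unique(pos)))) else window_bp
  if (window_bp < spacing) {
    warning("window smaller than SNP spacing; LD scores reduce to the self term")
  }
  l <- unlist(lapply(seq_along(blocks), function(b) {
    r2 <- blocks[[b]]
    bp <- pos[offsets[b] + seq_len(nrow(r2))]
    within <- abs(outer(bp, bp, "-")) <= window_bp
    rowSums(r2 * within)
  }), use.names = FALSE)
  structure(list(l = pmax(l, 1), snps = panel$snps$snp,
                 M = nrow(panel$snps)),
            class = "ld_scores")
}

# delete-one-block jackknife SE over B contiguous SNP blocks
jackknife_se <- function(estimates) {
  B <- length(estimates)
  sqrt((B - 1) / B * sum((estimates - mean(estimates))^2))
}

ldsc_wls <- function(y, x, w) {
  fit <- lm.wfit(cbind(1, x), y, w)
  fit$coefficients
}

#' SNP heritability by LD score regression
#'
#' Weighted least-squares fit of the model `E[z^2] = 1 + N h2 l / M` (free
#' intercept) with 1/l weights; the slope on `N l / M` is the heritability
#' estimate and the intercept captures confounding inflation. Standard
#' errors come from a delete-one block jackknife over `n_blocks`
#' contiguous genomic blocks.
#'
#' @param s a `sumstats` object with per-SNP `n`.
#' @param scores `ld_scores` aligned to `s` (matched by SNP id).
#' @param n_blocks jackknife blocks (default 20; must not exceed the SNP
#'   count).
#' @return an `h2_estimate` list: `h2`, `intercept`, `se_h2`,
#'   `se_intercept`, `M`, `n_blocks`.
#' @export
estimate_h2 <- function(s, scores, n_blocks = 20L) {
  stopifnot(inherits(s, "sumstats"), inherits(scores, "ld_scores"))
  l <- scores$l[match(s$snp, scores$snps)]
  if (anyNA(l)) stop("LD scores missing for some SNPs")
  if (nrow(s) < n_blocks) stop("fewer SNPs than jackknife blocks")
  x <- s$n * l / scores$M
  y <- s$z^2
  w <- 1 / pmax(l, 1)
  coefs <- ldsc_wls(y, x, w)
  blk <- ceiling(seq_along(y) / (length(y) / n_blocks))
  jk <- vapply(seq_len(n_blocks), function(b) {
    k <- blk != b
    ldsc_wls(y[k], x[k], w[k])
  }, c(0, 0))
  structure(list(h2 = coefs[2], intercept = coefs[1],
                 se_h2 = jackknife_se(jk[2, ]),
                 se_intercept = jackknife_se(jk[1, ]),
                 M = scores$M, n_blocks = n_blocks),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("h2 = %.4f (SE %.4f), intercept = %.4f (SE %.4f)\n",
              x$h2, x$se_h2, x$intercept, x$se_intercept))
  invisible(x)
}

#' Cross-trait genetic correlation by LD score regression
#'
#' Fits the two univariate models and the bivariate model
#' `E[z1 z2] = rho_overlap-type intercept + sqrt(N1 N2) gcov l / M`; the
#' free bivariate intercept absorbs correlated noise from sample overlap.
#' The genetic correlation is `rg = gcov / sqrt(h2_1 h2_2)` (clipped to
#' \[-1, 1\]), with a joint delete-one-block jackknife SE that
#' re-estimates all three regressions per block.
#'
#' @param a,b harmonized `sumstats` in identical SNP order.
#' @param scores `ld_scores` covering the SNPs.
#' @param n_blocks jackknife blocks.
#' @return an `rg_estimate` list: `rg`, `se_rg`, `gcov`, `h2_1`, `h2_2`,
#'   `intercept_1`, `intercept_2`, `intercept_biv`, `se_intercept_biv`,
#'   `defined` (FALSE when either h2 estimate is non-positive, in which
#'   case `rg` is NA).
#' @export
estimate_rg <- function(a, b, scores, n_blocks = 20L) {
  stopifnot(inherits(a, "sumstats"), inherits(b, "sumstats"),
            nrow(a) == nrow(b), all(a$snp == b$snp))
  l <- scores$l[match(a$snp, scores$snps)]
  if (anyNA(l)) stop("LD scores missing for some SNPs")
  if (nrow(a) < n_blocks) stop("fewer SNPs than jackknife blocks")
  w <- 1 / pmax(l, 1)
  x1 <- a$n * l / scores$M
  x2 <- b$n * l / scores$M
  x12 <- sqrt(a$n * b$n) * l / scores$M
  fit_all <- function(k) {
    c1 <- ldsc_wls(a$z[k]^2, x1[k], w[k])
    c2 <- ldsc_wls(b$z[k]^2, x2[k], w[k])
    c12 <- ldsc_wls((a$z * b$z)[k], x12[k], w[k])
    rg <- if (c1[2] > 0 && c2[2] > 0) {
      max(-1, min(1, c12[2] / sqrt(c1[2] * c2[2])))
    } else NA_real_
    c(h2_1 = unname(c1[2]), h2_2 = unname(c2[2]), gcov = unname(c12[2]),
      int1 = unname(c1[1]), int2 = unname(c2[1]), int12 = unname(c12[1]),
      rg = rg)
  }
  full <- fit_all(rep(TRUE, nrow(a)))
  blk <- ceiling(seq_len(nrow(a)) / (nrow(a) / n_blocks))
  jk <- vapply(seq_len(n_blocks), function(bb) fit_all(blk != bb),
               full)
  defined <- !is.na(full["rg"])
  # a jackknife replicate can lose positivity of an h2 estimate in noisy
  # fits; the SE then uses the defined replicates (NA if fewer than half)
  jk_rg <- jk["rg", !is.na(jk["rg", ])]
  se_rg <- if (defined && length(jk_rg) >= max(3, n_blocks / 2)) {
    jackknife_se(jk_rg)
  } else NA_real_
  if (!defined) {
    message("estimate_rg: non-positive heritability estimate; rg undefined")
  }
  structure(list(rg = unname(full["rg"]), se_rg = se_rg,
                 gcov = unname(full["gcov"]),
                 h2_1 = unname(full["h2_1"]), h2_2 = unname(full["h2_2"]),
                 intercept_1 = unname(full["int1"]),
                 intercept_2 = unname(full["int2"]),
                 intercept_biv = unname(full["int12"]),
                 se_intercept_biv = if (!anyNA(jk["int12", ]))
                   jackknife_se(jk["int12", ]) else NA_real_,
                 defined = defined, n_blocks = n_blocks),
            class = "rg_estimate")
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf(
    "rg = %.3f (SE %.3f); h2_1 = %.4f, h2_2 = %.4f, bivariate intercept = %.3f\n",
    x$rg, x$se_rg, x$h2_1, x$h2_2, x$intercept_biv))
  invisible(x)
}
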