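#' Conditional Q-Q enrichment of one trait stratified by another
#'
#' For each conditional p-value cutoff `t` (default 1, 0.1, 0.01, 0.001),
#' takes the stratum of SNPs with `p_conditional <= t` and computes the
#' empirical quantiles of `-log10 p_primary` against the theoretical
#' `-log10` quantiles expected under uniformity (plotting positions
#' `rank / (k + 1)` within the stratum). Successive leftward/upward
#' deflection of the curves with stricter conditioning indicates
#' cross-trait polygenic enrichment. The per-stratum scalar summary is the
#' observed `-log10 p_primary` at the empirical 0.1 p-value quantile (the
#' 90th percentile of `-log10 p`).
#'
#' The `t = 1` stratum is the unconditional Q-Q curve. The reverse analysis
#' is the same call with the two traits exchanged.
#'
#' @param primary,conditional harmonized `sumstats` objects in identical
#'   SNP order (see [harmonize_pair()]).
#' @param thresholds conditional p-value cutoffs in (0, 1].
#' @param min_stratum strata with fewer SNPs are flagged (`ok = FALSE`)
#'   and should not be plotted.
#' @return a `qq_strata` list: `curves` (long data.table: stratum,
#'   expected, observed), `summary` (data.table: stratum, n, enrichment,
#'   ok), `thresholds`.
#' @export
conditional_qq <- function(primary, conditional,
                           thresholds = c(1, 0.1, 0.01, 0.001),
                           min_stratum = 100L) {
  stopifnot(inherits(primary, "sumstats"), inherits(conditional, "sumstats"),
            nrow(primary) == nrow(conditional),
            all(primary$snp == conditional$snp),
            all(thresholds > 0), all(thresholds <= 1))
  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  lp1 <- -log10(primary$p)
  curves <- list()
  summ <- list()
  for (t in thresholds) {
    in_stratum <- conditional$p <= t
    k <- sum(in_stratum)
    lab <- format(t, trim = TRUE)
    if (k > 0) {
      obs <- sort(lp1[in_stratum], decreasing = TRUE)
      expd <- -log10(seq_len(k) / (k + 1))
      curves[[lab]] <- data.table(stratum = lab, expected = expd,
                                  observed = obs)
      enr <- as.numeric(quantile(obs, 0.9, type = 1))
    } else {
      enr <- NA_real_
    }
    summ[[lab]] <- data.table(stratum = lab, threshold = t, n = k,
                              enrichment = enr, ok = k >= min_stratum)
  }
  structure(list(curves = rbindlist(curves),
                 summary = rbindlist(summ),
                 thresholds = thresholds),
            class = "qq_strata")
}

#' @export
print.qq_strata <- function(x, ...) {
  cat("Conditional Q-Q strata:\n")
  print(x$summary)
  invisible(x)
}

#' Plot conditional Q-Q curves
#'
#' Expected vs observed `-log10 p` of the primary trait per conditioning
#' stratum, with the identity as the global null reference. Strata flagged
#' as too small are omitted.
#'
#' @param x a `qq_strata` object.
#' @param max_points per-stratum curve points are thinned to roughly this
#'   many for plotting.
#' @return a ggplot object.
#' @export
plot_conditional_qq <- function(x, max_points = 2000L) {
  stopifnot(inherits(x, "qq_strata"))
  ok <- x$summary$stratum[x$summary$ok]
  dt <- x$curves[stratum %in% ok]
  dt <- dt[, .SD[unique(round(seq(1L, .N, length.out = min(.N, max_points))))],
           by = stratum]
  ggplot2::ggplot(dt, ggplot2::aes(x = expected, y = observed,
                                   colour = stratum)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  colour = "p_cond <=") +
    ggplot2::theme_minimal()
}
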