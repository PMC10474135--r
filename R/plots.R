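#' Manhattan-style plot of -log10 conjFDR
#'
#' Genomic positions against `-log10` of the conjunctional FDR, with the
#' reporting threshold as a dotted line and lead SNPs circled.
#'
#' @param fdr_table per-SNP table from [cross_trait_fdr()].
#' @param loci optional `loci` table whose lead SNPs are highlighted.
#' @param fdr_level threshold line (default 0.05).
#' @return a ggplot object.
#' @export
plot_conjfdr_manhattan <- function(fdr_table, loci = NULL,
                                   fdr_level = 0.05) {
  dt <- as.data.table(fdr_table)[, .(snp, chrom, pos, y = -log10(conjfdr))]
  chr_order <- unique(dt$chrom[order(suppressWarnings(as.integer(dt$chrom)),
                                     dt$chrom)])
  offs <- c(0, cumsum(vapply(chr_order, function(cc) max(dt[chrom == cc]$pos),
                             0)))
  names(offs) <- c(chr_order, "end")
  dt[, x := pos + offs[chrom]]
  g <- ggplot2::ggplot(dt, ggplot2::aes(x = x, y = y, colour = chrom)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(fdr_level), linetype = 3) +
    ggplot2::labs(x = "genomic position", y = expression(-log[10](conjFDR))) +
    ggplot2::theme_minimal()
  if (!is.null(loci) && nrow(loci)) {
    lead <- dt[snp %in% loci$lead_snp]
    g <- g + ggplot2::geom_point(data = lead, shape = 1, size = 2,
                                 colour = "black")
  }
  g
}

utils::globalVariables(c("x", "y", "strategy", "p_adjusted", "significant",
                         "max_pos", "threshold", "conjfdr"))
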