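#' Positional SNP-to-gene mapping
#'
#' Maps each SNP to every gene whose body, extended by `window_bp` on both
#' sides, contains the SNP position (same chromosome). A SNP may map to
#' several genes.
#'
#' @param candidate_snps data.frame/`sumstats` subset with `snp`, `chrom`,
#'   `pos`.
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive) and optionally `symbol`; gene ids must be unique.
#' @param window_bp flanking window in bp (default 10 kb).
#' @return data.table of (snp, gene_id, chrom, pos, distance) pairs, where
#'   distance is 0 inside the gene body.
#' @export
map_genes_positional <- function(candidate_snps, genes, window_bp = 1e4) {
  snps <- as.data.table(candidate_snps)[, .(snp, chrom = as.character(chrom), pos)]
  genes <- as.data.table(genes)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
            !anyDuplicated(genes$gene_id), all(genes$start <= genes$end),
            window_bp >= 0)
  if (!nrow(snps) || !nrow(genes)) {
    return(data.table(snp = character(), gene_id = character(),
                      chrom = character(), pos = integer(),
                      distance = integer()))
  }
  lvls <- unique(c(snps$chrom, as.character(genes$chrom)))
  gr_snp <- GenomicRanges::GRanges(factor(snps$chrom, lvls),
                                   IRanges::IRanges(snps$pos, snps$pos))
  gr_gene <- GenomicRanges::GRanges(
    factor(as.character(genes$chrom), lvls),
    IRanges::IRanges(pmax(1, genes$start - window_bp),
                     genes$end + window_bp))
  hits <- GenomicRanges::findOverlaps(gr_snp, gr_gene)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  dist <- pmax(0L, pmax(genes$start[sh] - snps$pos[qh],
                        snps$pos[qh] - genes$end[sh]))
  out <- data.table(snp = snps$snp[qh], gene_id = genes$gene_id[sh],
                    chrom = snps$chrom[qh], pos = snps$pos[qh],
                    distance = as.integer(dist))
  setorder(out, chrom, pos, gene_id)
  out[]
}

#' Combine SNP-to-gene evidence from multiple mapping strategies
#'
#' Takes the positional mapping plus optional precomputed eQTL and
#' chromatin-interaction SNP-to-gene tables (each with columns `snp`,
#' `gene_id`) and keeps genes supported by at least `min_strategies`
#' strategies. With only the positional table supplied,
#' `min_strategies = 1` returns it unchanged.
#'
#' @param positional data.table from [map_genes_positional()].
#' @param eqtl,chromatin optional data.frames with `snp`, `gene_id`.
#' @param min_strategies minimum number of supporting strategies per gene.
#' @return data.table (gene_id, n_strategies, strategies).
#' @export
map_genes_union <- function(positional, eqtl = NULL, chromatin = NULL,
                            min_strategies = 2L) {
  tabs <- list(positional = positional, eqtl = eqtl, chromatin = chromatin)
  tabs <- Filter(Negate(is.null), tabs)
  per <- rbindlist(lapply(names(tabs), function(nm) {
    dt <- as.data.table(tabs[[nm]])
    unique(dt[, .(gene_id)])[, strategy := nm]
  }))
  out <- per[, .(n_strategies = .N,
                 strategies = paste(sort(strategy), collapse = ",")),
             by = gene_id][n_strategies >= min_strategies]
  setorder(out, gene_id)
  out[]
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= overlap)` of drawing at least the
#' observed number of gene-set members when `|mapped_genes|` genes are
#' drawn without replacement from a universe containing `|gene_set|`
#' members.
#'
#' @param mapped_genes character vector of mapped genes (subset of
#'   `universe`).
#' @param gene_set character vector defining the set to test (subset of
#'   `universe`).
#' @param universe character vector of all background genes (non-empty).
#' @return list with `p` (upper-tail p-value), `overlap`, `n_mapped`,
#'   `n_set`, `n_universe`.
#' @export
hypergeometric_enrichment <- function(mapped_genes, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("gene universe is empty")
  mapped_genes <- unique(mapped_genes)
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% universe)) {
    stop("gene_set contains genes outside the universe")
  }
  if (!all(mapped_genes %in% universe)) {
    stop("mapped_genes contains genes outside the universe")
  }
  k <- length(intersect(mapped_genes, gene_set))
  p <- if (k == 0) 1 else {
    phyper(k - 1, length(gene_set), length(universe) - length(gene_set),
           length(mapped_genes), lower.tail = FALSE)
  }
  list(p = p, overlap = k, n_mapped = length(mapped_genes),
       n_set = length(gene_set), n_universe = length(universe))
}

#' Bonferroni multiple-testing correction
#'
#' @param p_values vector of p-values in (0, 1].
#' @param alpha family-wise significance level.
#' @return data.table with `p`, `p_adjusted` (= `min(1, m * p)`), and
#'   `significant` (`p_adjusted < alpha`).
#' @export
bonferroni_adjust <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values > 0), all(p_values <= 1), alpha > 0, alpha <= 1)
  adj <- p.adjust(p_values, method = "bonferroni")
  data.table(p = p_values, p_adjusted = adj, significant = adj < alpha)
}

#' Simulate a gene annotation aligned to a simulated SNP map
#'
#' Places synthetic non-overlapping genes of fixed length at random
#' positions along the simulated chromosomes; useful for exercising
#' positional mapping and over-representation analysis on simulated loci.
#'
#' @param params a [sim_params()] object (defines the chromosome spans).
#' @param n_genes number of genes.
#' @param gene_length_bp gene body length.
#' @param seed RNG seed.
#' @return data.table (gene_id, symbol, chrom, start, end).
#' @export
simulate_gene_annotation <- function(params, n_genes = 200L,
                                     gene_length_bp = 2e4L, seed = 1L) {
  layout <- snp_layout(params)
  spans <- layout$snps[, .(max_pos = max(pos)), by = chrom]
  set.seed(seed)
  pick <- spans[sample.int(nrow(spans), n_genes, replace = TRUE)]
  start <- vapply(pick$max_pos, function(mx) {
    sample.int(max(1L, mx - gene_length_bp), 1L)
  }, 0L)
  out <- data.table(
    gene_id = sprintf("GENE%04d", seq_len(n_genes)),
    symbol = sprintf("G%d", seq_len(n_genes)),
    chrom = pick$chrom, start = start,
    end = start + gene_length_bp - 1L)
  setorder(out, chrom, start)
  out[]
}
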