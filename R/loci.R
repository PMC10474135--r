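#' Pairwise LD r-squared for a set of SNPs
#'
#' Squared Pearson correlation of reference-panel dosages (or a slice of a
#' precomputed r2 map). The diagonal is 1 and the result is invariant to
#' flipping the coded allele of any SNP.
#'
#' @param panel an `ld_panel`.
#' @param snps character vector of SNP ids; all must be present in the
#'   panel.
#' @return symmetric matrix of r2 values with `snps` as dimnames.
#' @export
pairwise_r2 <- function(panel, snps) {
  stopifnot(inherits(panel, "ld_panel"))
  idx <- match(snps, panel$snps$snp)
  if (anyNA(idx)) {
    stop("SNP id(s) not present in LD panel: ",
         paste(head(snps[is.na(idx)], 5), collapse = ", "))
  }
  if (!is.null(panel$geno)) {
    r2 <- cor(panel$geno[, idx, drop = FALSE])^2
    dimnames(r2) <- list(snps, snps)
  } else {
    r2 <- panel$r2[idx, idx, drop = FALSE]
    dimnames(r2) <- list(snps, snps)
  }
  r2
}

#' Default locus-definition thresholds
#'
#' The FUMA-style rules: independent significant SNPs at FDR < 0.05 with
#' mutual r2 < 0.6; lead SNPs in approximate linkage equilibrium (mutual
#' r2 < 0.1); candidate SNPs at FDR < 0.1 with r2 >= 0.6 to an independent
#' significant SNP; loci closer than 250 kb merged.
#'
#' @return named list of thresholds.
#' @export
locus_thresholds <- function() {
  list(sig = 0.05, cand = 0.1, r2_indep = 0.6, r2_lead = 0.1,
       merge_kb = 250)
}

#' Define genomic risk loci from per-SNP FDR values
#'
#' Greedy clumping in ascending FDR order (ties broken by chromosome,
#' position, then id): SNPs with FDR below `sig` that are mutually in LD
#' below `r2_indep` become independent significant SNPs; the subset of
#' those in approximate linkage equilibrium (`r2 < r2_lead`) become lead
#' SNPs. Candidate SNPs are all SNPs with FDR below `cand` and r2 at least
#' `r2_indep` with some independent significant SNP (each candidate is
#' attached to the independent significant SNP it is most correlated
#' with). A locus is the interval spanned by the candidate sets of one
#' lead SNP; loci whose intervals are within `merge_kb` kb of each other
#' (or, with `merge_by = "lead"`, whose lead SNPs are) are merged into one
#' genomic risk locus.
#'
#' @param scores numeric per-SNP FDR values aligned with `sumstats`.
#' @param sumstats a `sumstats` object.
#' @param panel an `ld_panel` covering (at least) all SNPs with FDR below
#'   `cand`.
#' @param thresholds see [locus_thresholds()].
#' @param merge_by `"interval"` (gap between locus intervals, the default)
#'   or `"lead"` (distance between lead SNPs).
#' @param window_bp r2 between SNPs farther apart than this (or on
#'   different chromosomes) is treated as 0.
#' @param label analysis label stored with each locus.
#' @return a `loci` data.table: chrom, start, end (1-based inclusive),
#'   lead_snp (smallest-FDR lead), min_fdr, n_ind_sig, n_candidates, plus
#'   list-columns `leads`, `ind_sig`, `candidates`, and `label`. Zero rows
#'   when nothing passes `sig`.
#' @export
define_loci <- function(scores, sumstats, panel,
                        thresholds = locus_thresholds(),
                        merge_by = c("interval", "lead"),
                        window_bp = 1e6, label = "fdr") {
  merge_by <- match.arg(merge_by)
  stopifnot(inherits(sumstats, "sumstats"),
            length(scores) == nrow(sumstats))
  dt <- data.table(snp = sumstats$snp, chrom = sumstats$chrom,
                   pos = sumstats$pos, fdr = as.numeric(scores))
  pool <- dt[fdr < thresholds$cand]
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), lead_snp = character(),
                      min_fdr = numeric(), n_ind_sig = integer(),
                      n_candidates = integer(), leads = list(),
                      ind_sig = list(), candidates = list(),
                      label = character())
  if (!nrow(pool) || !any(pool$fdr < thresholds$sig)) {
    return(structure(empty, class = c("loci", class(data.table()))))
  }
  setorder(pool, fdr, chrom, pos, snp)
  r2 <- pairwise_r2(panel, pool$snp)
  far <- outer(pool$chrom, pool$chrom, "!=") |
    abs(outer(pool$pos, pool$pos, "-")) > window_bp
  r2[far] <- 0
  diag(r2) <- 1

  sig_idx <- which(pool$fdr < thresholds$sig)  # already in greedy order
  indep <- integer(0)
  for (i in sig_idx) {
    if (!length(indep) || all(r2[i, indep] < thresholds$r2_indep)) {
      indep <- c(indep, i)
    }
  }
  leads <- integer(0)
  for (i in indep) {
    if (!length(leads) || all(r2[i, leads] < thresholds$r2_lead)) {
      leads <- c(leads, i)
    }
  }

  # candidates: pool SNPs tagging an independent significant SNP; each is
  # attached to the most-correlated one (greedy order breaks exact ties)
  r2_ind <- r2[, indep, drop = FALSE]
  best <- apply(r2_ind, 1, which.max)
  best_r2 <- r2_ind[cbind(seq_len(nrow(pool)), best)]
  cand_rows <- which(best_r2 >= thresholds$r2_indep)
  cand_owner <- indep[best[cand_rows]]

  # attach each independent significant SNP to its most-correlated lead
  r2_lead_m <- r2[indep, leads, drop = FALSE]
  owner_lead <- leads[apply(r2_lead_m, 1, which.max)]
  owner_lead[indep %in% leads] <- indep[indep %in% leads]
  lead_of_indep <- setNames(owner_lead, indep)

  lead_of_cand <- lead_of_indep[as.character(cand_owner)]
  loci_list <- lapply(leads, function(L) {
    members <- cand_rows[lead_of_cand == L]
    list(lead = L, members = members)
  })

  mk <- function(lead_rows, member_rows) {
    mem <- pool[member_rows]
    lead_dt <- pool[lead_rows]
    is_rows <- intersect(indep, member_rows)
    best_lead <- lead_dt[order(fdr, pos, snp)]$snp[1]
    data.table(chrom = mem$chrom[1], start = min(mem$pos),
               end = max(mem$pos), lead_snp = best_lead,
               min_fdr = min(mem$fdr), n_ind_sig = length(is_rows),
               n_candidates = nrow(mem),
               leads = list(lead_dt$snp),
               ind_sig = list(pool[is_rows]$snp),
               candidates = list(mem$snp), label = label)
  }
  loci <- rbindlist(lapply(loci_list, function(x) mk(x$lead, x$members)))
  lead_pos <- vapply(loci_list, function(x) pool$pos[x$lead], 0L)
  ord <- order(suppressWarnings(as.integer(loci$chrom)), loci$chrom,
               loci$start, loci$end)
  loci <- loci[ord]
  loci_list <- loci_list[ord]
  lead_pos <- lead_pos[ord]

  # 250 kb merge rule
  merged <- list()
  cur_rows <- integer(0)
  cur_group <- integer(0)
  flush <- function() {
    if (length(cur_group)) {
      lead_rows <- unlist(lapply(loci_list[cur_group], `[[`, "lead"))
      member_rows <- unique(unlist(lapply(loci_list[cur_group], `[[`,
                                          "members")))
      merged[[length(merged) + 1]] <<- mk(lead_rows, member_rows)
    }
  }
  for (i in seq_len(nrow(loci))) {
    if (!length(cur_group)) {
      cur_group <- i
      next
    }
    prev <- cur_group[length(cur_group)]
    same_chrom <- loci$chrom[i] == loci$chrom[prev]
    gap <- if (merge_by == "interval") {
      loci$start[i] - max(loci$end[cur_group])
    } else {
      lead_pos[i] - lead_pos[prev]
    }
    if (same_chrom && gap <= thresholds$merge_kb * 1000) {
      cur_group <- c(cur_group, i)
    } else {
      flush()
      cur_group <- i
    }
  }
  flush()
  out <- rbindlist(merged)
  setorder(out, chrom, start)
  structure(out, class = c("loci", class(data.table())))
}

loci_to_granges <- function(loci, seqlevels = NULL) {
  if (!nrow(loci)) {
    return(GenomicRanges::GRanges(seqlengths = setNames(
      rep(NA_integer_, length(seqlevels)), seqlevels)))
  }
  GenomicRanges::GRanges(
    seqnames = factor(loci$chrom, levels = seqlevels %||% unique(loci$chrom)),
    ranges = IRanges::IRanges(start = loci$start, end = loci$end)
  )
}

#' Pair physically overlapping loci between two analyses
#'
#' Interval intersection (>= 1 bp shared, same chromosome) between two
#' locus tables, plus the union of both sets reduced to unique
#' non-overlapping intervals.
#'
#' @param a,b `loci` tables from [define_loci()].
#' @return list with `pairs` (data.table: index and lead SNP of each
#'   overlapping pair), `n_overlap_a`, `n_overlap_b`, and `unique`
#'   (reduced intervals across both analyses, with a count attribute).
#' @export
overlap_loci <- function(a, b) {
  lvls <- unique(c(a$chrom, b$chrom))
  ga <- loci_to_granges(a, lvls)
  gb <- loci_to_granges(b, lvls)
  hits <- GenomicRanges::findOverlaps(ga, gb)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  pairs <- if (length(qh)) {
    data.table(i_a = qh, i_b = sh,
               lead_a = a$lead_snp[qh], lead_b = b$lead_snp[sh])
  } else {
    data.table(i_a = integer(), i_b = integer(),
               lead_a = character(), lead_b = character())
  }
  list(pairs = pairs,
       n_overlap_a = length(unique(qh)),
       n_overlap_b = length(unique(sh)),
       unique = unique_loci(list(a, b)))
}

#' Unique loci across several analyses
#'
#' Iteratively merges physically overlapping locus intervals from any
#' number of analyses into unique non-overlapping genomic regions.
#'
#' @param loci_list list of `loci` tables.
#' @return data.table of reduced intervals (chrom, start, end,
#'   n_analyses = number of input analyses touching each region);
#'   `nrow()` is the unique-locus count.
#' @export
unique_loci <- function(loci_list) {
  keep <- Filter(nrow, loci_list)
  if (!length(keep)) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), n_analyses = integer()))
  }
  lvls <- unique(unlist(lapply(keep, function(l) l$chrom)))
  gr_all <- do.call(c, unname(lapply(keep, loci_to_granges,
                                     seqlevels = lvls)))
  red <- GenomicRanges::reduce(gr_all)
  n_an <- vapply(seq_along(red), function(i) {
    sum(vapply(keep, function(l) {
      length(GenomicRanges::findOverlaps(
        red[i], loci_to_granges(l, lvls))) > 0
    }, NA))
  }, 0L)
  data.table(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red),
             end = GenomicRanges::end(red),
             n_analyses = n_an)
}

#' Effect-direction concordance of shared loci
#'
#' For each locus, compares the sign of the lead SNP's z-score in the two
#' (harmonized) traits: concordant iff `sign(z_a) * sign(z_b) > 0`. Loci
#' whose lead SNP is missing from either trait, or has a zero z-score, are
#' flagged indeterminate and excluded from the summary denominator.
#'
#' @param loci a `loci` table.
#' @param a,b harmonized `sumstats` objects.
#' @return list with `table` (per-locus: lead_snp, z_a, z_b, status) and
#'   `summary` (n_concordant, n_determinate, fraction, percent).
#' @export
effect_concordance <- function(loci, a, b) {
  stopifnot(inherits(a, "sumstats"), inherits(b, "sumstats"))
  za <- a$z[match(loci$lead_snp, a$snp)]
  zb <- b$z[match(loci$lead_snp, b$snp)]
  status <- ifelse(is.na(za) | is.na(zb) | za == 0 | zb == 0,
                   "indeterminate",
                   ifelse(sign(za) * sign(zb) > 0, "concordant",
                          "discordant"))
  n_ind <- sum(status == "indeterminate")
  if (n_ind) {
    message("effect_concordance: ", n_ind,
            " locus/loci indeterminate (lead SNP missing or z = 0)")
  }
  tab <- data.table(lead_snp = loci$lead_snp, chrom = loci$chrom,
                    start = loci$start, end = loci$end,
                    z_a = za, z_b = zb, status = status)
  n_det <- sum(status != "indeterminate")
  n_con <- sum(status == "concordant")
  list(table = tab,
       summary = data.table(
         n_concordant = n_con, n_determinate = n_det,
         fraction = if (n_det) n_con / n_det else NA_real_,
         percent = if (n_det) round(100 * n_con / n_det) else NA_real_))
}

#' Score loci against simulation truth
#'
#' A locus counts as a true discovery iff its interval contains at least
#' one SNP that is causal for the required trait(s) in the simulator's
#' truth table; otherwise it is a false discovery. The false-discovery
#' proportion is 0 when there are no loci.
#'
#' @param loci a `loci` table.
#' @param truth truth table from [simulate_pair()].
#' @param require `"both"` (shared-locus scoring), `"trait1"` or
#'   `"trait2"`.
#' @return list with `is_true` (logical per locus), `fdp`, `n_loci`,
#'   `n_true`.
#' @export
locus_fdp <- function(loci, truth, require = c("both", "trait1", "trait2")) {
  require <- match.arg(require)
  truth <- as.data.table(truth)
  causal <- switch(require,
                   both = truth$causal1 & truth$causal2,
                   trait1 = truth$causal1,
                   trait2 = truth$causal2)
  ct <- truth[causal]
  is_true <- vapply(seq_len(nrow(loci)), function(i) {
    any(ct$chrom == loci$chrom[i] & ct$pos >= loci$start[i] &
          ct$pos <= loci$end[i])
  }, NA)
  n <- nrow(loci)
  list(is_true = is_true,
       fdp = if (n) mean(!is_true) else 0,
       n_loci = n, n_true = sum(is_true))
}

#' Export loci as BED intervals
#'
#' Converts the package's 1-based inclusive locus intervals to BED's
#' 0-based half-open convention.
#'
#' @param loci a `loci` table.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_loci_bed <- function(loci, path) {
  bed <- data.table(chrom = loci$chrom, start = loci$start - 1L,
                    end = loci$end, name = loci$lead_snp,
                    score = signif(loci$min_fdr, 4),
                    n_candidates = loci$n_candidates)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
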