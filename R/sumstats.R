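#' GWAS summary statistics container
#'
#' A `sumstats` object is a `data.table` with one row per SNP and columns
#' `snp` (identifier), `chrom` (character, e.g. `"1"`..`"22"`), `pos`
#' (1-based bp), `a1` (effect allele), `a2` (other allele), `z` (signed
#' z-score), `p` (two-sided p-value in (0, 1]) and `n` (effective sample
#' size). Construction validates the rows and guarantees that `p` and `z`
#' are mutually consistent (`p = 2 * pnorm(-abs(z))`), that there are no
#' duplicated SNP identifiers, and that alleles are single A/C/G/T bases
#' with `a1 != a2`. Invalid rows are dropped and counted in the filtering
#' log stored in `attr(x, "filter_log")`.
#'
#' @param x data.frame with at least `snp`, `chrom`, `pos`, `a1`, `a2` and
#'   either `z` or (`p` plus a signed `beta`). If `z` is absent it is
#'   reconstructed as `sign(beta) * qnorm(p / 2, lower.tail = FALSE)`; if
#'   `z` is present, `p` is (re)derived from it.
#' @param n_default effective sample size to fill in when no `n` column is
#'   present (optional).
#' @return a validated `sumstats` object.
#' @export
sumstats <- function(x, n_default = NULL) {
  dt <- as.data.table(x)
  required <- c("snp", "chrom", "pos", "a1", "a2")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(dt)) stop("summary statistics table is empty")
  if (!("z" %in% names(dt)) && !("p" %in% names(dt))) {
    stop("missing mandatory column(s): z (or p with beta)")
  }

  log <- list(n_input = nrow(dt))
  dt[, snp := as.character(snp)]
  dt[, chrom := sub("^chr", "", as.character(chrom))]
  dt[, pos := as.integer(pos)]
  dt[, a1 := toupper(as.character(a1))]
  dt[, a2 := toupper(as.character(a2))]

  bases <- c("A", "C", "G", "T")
  bad_allele <- !(dt$a1 %in% bases) | !(dt$a2 %in% bases) | dt$a1 == dt$a2
  log$dropped_bad_alleles <- sum(bad_allele)
  bad_pos <- is.na(dt$pos) | dt$pos < 1L
  log$dropped_bad_position <- sum(bad_pos & !bad_allele)

  if ("z" %in% names(dt)) {
    dt[, z := as.numeric(z)]
    bad_stat <- is.na(dt$z)
  } else {
    if (!("beta" %in% names(dt))) {
      stop("missing mandatory column(s): beta (needed for effect sign when z is absent)")
    }
    dt[, p := as.numeric(p)]
    bad_stat <- is.na(dt$p) | dt$p <= 0 | dt$p > 1 | is.na(as.numeric(dt$beta))
    dt[, z := sign(as.numeric(beta)) * qnorm(pmin(p, 1) / 2, lower.tail = FALSE)]
  }
  log$dropped_bad_stat <- sum(bad_stat & !bad_allele & !bad_pos)

  dt <- dt[!(bad_allele | bad_pos | bad_stat)]
  dup <- duplicated(dt$snp)
  log$dropped_duplicate_id <- sum(dup)
  dt <- dt[!dup]
  if (!nrow(dt)) stop("no valid rows left after filtering")

  # p is always (re)derived from z so the pair is exactly consistent
  dt[, p := pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)]

  if (!("n" %in% names(dt))) {
    dt[, n := if (is.null(n_default)) NA_real_ else as.numeric(n_default)]
  } else {
    dt[, n := as.numeric(n)]
  }
  keep_cols <- c("snp", "chrom", "pos", "a1", "a2", "z", "p", "n")
  dt <- dt[, keep_cols, with = FALSE]
  setattr(dt, "filter_log", log)
  setattr(dt, "class", c("sumstats", class(data.table())))
  dt[]
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Reads a header-ed TSV, renames columns according to `column_map`, and
#' validates through [sumstats()]. If the file provides `BETA` (and no `Z`)
#' the z-score is reconstructed from the p-value and the sign of beta.
#'
#' @param path file path.
#' @param column_map named character vector mapping internal names
#'   (`snp, chrom, pos, a1, a2, z, beta, se, p, n`) to the file's column
#'   names; defaults to the conventional `SNP, CHR, BP, A1, A2, Z, BETA,
#'   SE, P, N`.
#' @param n_default passed to [sumstats()].
#' @return a `sumstats` object; dropped-row counts in `attr(, "filter_log")`.
#' @export
read_sumstats <- function(path, column_map = NULL, n_default = NULL) {
  defaults <- c(snp = "SNP", chrom = "CHR", pos = "BP", a1 = "A1", a2 = "A2",
                z = "Z", beta = "BETA", se = "SE", p = "P", n = "N")
  if (!is.null(column_map)) defaults[names(column_map)] <- column_map
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, data.table = TRUE)
  if (!nrow(dt)) stop("empty summary statistics file: ", path)
  present <- defaults[defaults %in% names(dt)]
  setnames(dt, unname(present), names(present))
  mandatory <- c("snp", "chrom", "pos", "a1", "a2")
  miss <- setdiff(mandatory, names(dt))
  if (length(miss)) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(defaults[miss], collapse = ", "))
  }
  s <- sumstats(dt, n_default = n_default)
  log <- attr(s, "filter_log")
  dropped <- log$n_input - nrow(s)
  if (dropped > 0) {
    message("read_sumstats: dropped ", dropped, " of ", log$n_input,
            " rows during validation")
  }
  s
}

#' Write summary statistics in the canonical tab-separated layout
#'
#' @param s a `sumstats` object.
#' @param path output file path.
#' @export
write_sumstats <- function(s, path) {
  out <- copy(as.data.table(s))
  setnames(out, c("snp", "chrom", "pos", "a1", "a2", "z", "p", "n"),
           c("SNP", "CHR", "BP", "A1", "A2", "Z", "P", "N"))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

#' Harmonize a pair of summary-statistics tables to shared SNPs and alleles
#'
#' Intersects two traits on SNP id, aligns trait b's effect allele to trait
#' a's (allele swaps negate `z`; strand complements are matched without a
#' sign change), removes strand-ambiguous palindromic SNPs (A/T and C/G),
#' and drops SNPs whose alleles cannot be reconciled. Outputs are returned
#' in identical (chrom, pos) order.
#'
#' @param a,b `sumstats` objects on the same genome build.
#' @param min_shared minimum fraction of the smaller input that must be
#'   shared; below this a build mismatch is assumed and an error is thrown.
#' @return list with elements `a` and `b` (harmonized `sumstats`) and
#'   `log` (counts of removed SNPs by reason).
#' @export
harmonize_pair <- function(a, b, min_shared = 0.01) {
  stopifnot(inherits(a, "sumstats"), inherits(b, "sumstats"))
  shared <- intersect(a$snp, b$snp)
  if (length(shared) < min_shared * min(nrow(a), nrow(b))) {
    stop("fewer than ", format(100 * min_shared),
         "% of SNPs shared between the two traits; likely a genome-build ",
         "or identifier mismatch")
  }
  da <- as.data.table(a)[snp %in% shared]
  db <- as.data.table(b)[snp %in% shared]
  setkey(da, snp); setkey(db, snp)
  db <- db[da$snp]

  log <- list(n_shared = length(shared))
  ambiguous <- da$a1 == complement_base(da$a2) |
    db$a1 == complement_base(db$a2)
  log$removed_ambiguous <- sum(ambiguous)

  same <- da$a1 == db$a1 & da$a2 == db$a2
  swap <- da$a1 == db$a2 & da$a2 == db$a1
  comp <- da$a1 == complement_base(db$a1) & da$a2 == complement_base(db$a2)
  swap_comp <- da$a1 == complement_base(db$a2) & da$a2 == complement_base(db$a1)
  matched <- same | swap | comp | swap_comp
  log$removed_mismatch <- sum(!matched & !ambiguous)

  keep <- matched & !ambiguous
  da <- da[keep]; db <- db[keep]
  flip <- (swap | swap_comp)[keep]
  db[flip, z := -z]
  db[, p := pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)]
  db[, `:=`(a1 = da$a1, a2 = da$a2, chrom = da$chrom, pos = da$pos)]

  ord <- order(suppressWarnings(as.integer(da$chrom)), da$chrom, da$pos, da$snp)
  da <- da[ord]; db <- db[ord]
  out_a <- sumstats(da); out_b <- sumstats(db)
  list(a = out_a, b = out_b, log = log)
}

#' Default complex-LD exclusion regions (hg19)
#'
#' The extended major histocompatibility complex (chr6:25119106-33854733)
#' and the 8p23.1 inversion region (chr8:7242715-12483982), both excluded
#' from cond/conjFDR analyses because their long-range LD biases the
#' empirical enrichment estimates. Coordinates are 1-based inclusive.
#'
#' @return data.table with columns `chrom`, `start`, `end`, `label`.
#' @export
default_exclusion_regions <- function() {
  data.table(
    chrom = c("6", "8"),
    start = c(25119106L, 7242715L),
    end   = c(33854733L, 12483982L),
    label = c("MHC", "8p23.1")
  )
}

#' Remove SNPs falling in exclusion regions
#'
#' Drops every SNP with `start <= pos <= end` on a listed chromosome
#' (bounds inclusive at both ends). The removed count is recorded in
#' `attr(, "exclusion_log")`.
#'
#' @param s a `sumstats` object.
#' @param regions data.table/data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive); defaults to [default_exclusion_regions()].
#' @return filtered `sumstats`; an empty result is allowed.
#' @export
apply_exclusions <- function(s, regions = default_exclusion_regions()) {
  stopifnot(inherits(s, "sumstats"))
  regions <- as.data.table(regions)
  stopifnot(all(regions$start <= regions$end))
  drop <- rep(FALSE, nrow(s))
  for (i in seq_len(nrow(regions))) {
    drop <- drop | (s$chrom == sub("^chr", "", as.character(regions$chrom[i])) &
                      s$pos >= regions$start[i] & s$pos <= regions$end[i])
  }
  out <- as.data.table(s)[!drop]
  setattr(out, "filter_log", attr(s, "filter_log"))
  setattr(out, "exclusion_log",
          list(n_input = nrow(s), n_removed = sum(drop)))
  setattr(out, "class", class(s))
  out[]
}

#' Effective sample size of a case-control GWAS
#'
#' The equivalent balanced-design size, `4 / (1/n_cases + 1/n_controls)`.
#'
#' @param n_cases,n_controls positive case and control counts.
#' @return effective sample size (real).
#' @export
effective_sample_size <- function(n_cases, n_controls) {
  if (any(n_cases <= 0) || any(n_controls <= 0)) {
    stop("case and control counts must be positive")
  }
  4 / (1 / n_cases + 1 / n_controls)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %d SNPs, %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  NextMethod()
  invisible(x)
}
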