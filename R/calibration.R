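#' Re-seed a simulation parameter set
#'
#' @param params a [sim_params()] object.
#' @param seed replacement seed.
#' @return the parameter set with the new seed.
#' @export
with_seed <- function(params, seed) {
  stopifnot(inherits(params, "sim_params"))
  params$seed <- as.integer(seed)
  params
}

#' Does each SNP tag a causal SNP for a trait?
#'
#' A discovery in LD with a causal SNP is not a false positive at the SNP
#' level. Under the AR(1) block design, a SNP tags a causal SNP iff some
#' causal SNP for the trait lies in the same block within the distance at
#' which `r_within^(2 d) >= r2_tag` (the SNP itself included).
#'
#' @param truth truth table from [simulate_pair()].
#' @param params the [sim_params()] that generated it.
#' @param trait 1 or 2.
#' @param r2_tag tagging r2 threshold.
#' @return logical vector, one per SNP.
#' @export
truth_tags_causal <- function(truth, params, trait = 1, r2_tag = 0.6) {
  truth <- as.data.table(truth)
  causal <- if (trait == 1) truth$causal1 else truth$causal2
  if (params$r_within == 0) return(causal)
  d_max <- floor(log(r2_tag) / (2 * log(params$r_within)))
  out <- causal
  if (d_max >= 1) {
    for (d in seq_len(d_max)) {
      m <- length(causal)
      same_fwd <- truth$block[seq_len(m - d)] == truth$block[seq_len(m - d) + d]
      out[seq_len(m - d)] <- out[seq_len(m - d)] |
        (causal[seq_len(m - d) + d] & same_fwd)
      out[seq_len(m - d) + d] <- out[seq_len(m - d) + d] |
        (causal[seq_len(m - d)] & same_fwd)
    }
  }
  out
}

#' One simulated replicate of the cross-trait FDR analysis, scored
#'
#' Simulates a pair of GWAS plus an LD panel from `params` (re-seeded with
#' `seed`), runs the condFDR/conjFDR machinery, defines conjFDR shared
#' loci, and scores them against the simulation truth. Optionally also
#' computes SNP-level true-discovery counts for condFDR versus the
#' unconditional empirical FDR (the power comparison) and the conditional
#' Q-Q enrichment summaries.
#'
#' @param params a [sim_params()] object.
#' @param seed replicate seed.
#' @param n_ref reference-panel individuals.
#' @param fdr_level declaration threshold (0.05).
#' @param opts grid options; the pruning seed is derived from `seed`.
#' @param what subset of `c("fdp", "power", "qq")`.
#' @return list of replicate metrics (see details in the source; always
#'   includes `seed`).
#' @export
replicate_metrics <- function(params, seed, n_ref = 200L,
                              fdr_level = 0.05,
                              opts = fdr_grid_opts(),
                              what = c("fdp", "power", "qq")) {
  what <- match.arg(what, several.ok = TRUE)
  params <- with_seed(params, seed)
  sim <- simulate_pair(params)
  out <- list(seed = seed)
  if (any(c("fdp", "power") %in% what)) {
    panel <- simulate_ld_panel(params, n_ref = n_ref)
    opts$seed <- seed + 500009L
    res <- cross_trait_fdr(sim$a, sim$b, panel = panel, opts = opts)
  }

  if ("fdp" %in% what) {
    conj_loci <- define_loci(res$table$conjfdr, sim$a, panel,
                             label = "conjfdr")
    sc <- locus_fdp(conj_loci, sim$truth, require = "both")
    out$fdp <- sc$fdp
    out$n_loci <- sc$n_loci
    out$n_true_loci <- sc$n_true
  }
  if ("power" %in% what) {
    uncond <- empirical_fdr(sim$a, panel = panel, opts = opts)
    tags1 <- truth_tags_causal(sim$truth, params, trait = 1)
    out$tp_cond <- sum(res$table$condfdr_ab < fdr_level & tags1)
    out$tp_uncond <- sum(uncond < fdr_level & tags1)
    out$n_cond <- sum(res$table$condfdr_ab < fdr_level)
    out$n_uncond <- sum(uncond < fdr_level)
  }
  if ("qq" %in% what) {
    qq <- conditional_qq(sim$a, sim$b)
    out$qq_enrichment <- setNames(qq$summary$enrichment,
                                  qq$summary$stratum)
  }
  out
}

#' Replicate study of locus-level FDP, power and Q-Q enrichment
#'
#' Runs [replicate_metrics()] over a vector of seeds and assembles the
#' per-replicate results into a data.table (Q-Q enrichment summaries
#' become one column per stratum).
#'
#' @inheritParams replicate_metrics
#' @param seeds integer vector of replicate seeds.
#' @return data.table with one row per replicate.
#' @export
replicate_study <- function(params, seeds, n_ref = 200L, fdr_level = 0.05,
                            opts = fdr_grid_opts(),
                            what = c("fdp", "power", "qq")) {
  rows <- lapply(seeds, function(s) {
    r <- replicate_metrics(params, s, n_ref = n_ref,
                           fdr_level = fdr_level, opts = opts, what = what)
    if (!is.null(r$qq_enrichment)) {
      qe <- as.list(r$qq_enrichment)
      names(qe) <- paste0("qq_", names(qe))
      r$qq_enrichment <- NULL
      r <- c(r, qe)
    }
    as.data.table(r)
  })
  rbindlist(rows, fill = TRUE)
}

#' Replicate study of genetic-correlation recovery
#'
#' For each seed, simulates a pair and panel, computes LD scores and the
#' LD score regression estimates, and records the rg point estimate, its
#' jackknife SE, whether the true rg of the parameter set falls within
#' +/- 2 SE, and the bivariate intercept.
#'
#' @inheritParams replicate_metrics
#' @param seeds integer vector of replicate seeds.
#' @return data.table with one row per replicate and the true rg as an
#'   attribute `true_rg`.
#' @export
rg_recovery_study <- function(params, seeds, n_ref = 200L) {
  target <- true_rg(params)
  rows <- lapply(seeds, function(s) {
    p <- with_seed(params, s)
    sim <- simulate_pair(p)
    panel <- simulate_ld_panel(p, n_ref = n_ref)
    scores <- compute_ld_scores(panel)
    est <- estimate_rg(sim$a, sim$b, scores)
    data.table(seed = s, rg = est$rg, se_rg = est$se_rg,
               covered = !is.na(est$rg) &&
                 abs(est$rg - target) <= 2 * est$se_rg,
               intercept_biv = est$intercept_biv,
               h2_1 = est$h2_1, h2_2 = est$h2_2)
  })
  out <- rbindlist(rows)
  setattr(out, "true_rg", target)
  out
}
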