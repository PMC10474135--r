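#' Assemble a run configuration
#'
#' Collects every tunable of the end-to-end analysis: input tables (file
#' paths or in-memory objects), FDR reporting level (0.05 per pairwise
#' comparison), candidate threshold (0.1), LD thresholds (r2 0.6 / 0.1),
#' 250 kb locus merging, conditional Q-Q strata (0.1, 0.01, 0.001), 10 kb
#' positional-mapping window, exclusion regions (MHC and 8p23.1 by
#' default), and the master seed from which all stage seeds are derived by
#' fixed offsets.
#'
#' @param primary,conditional `sumstats` objects or TSV paths readable by
#'   [read_sumstats()].
#' @param panel optional `ld_panel` (enables pruning-aware grids, locus
#'   definition and LD score regression).
#' @param genes optional gene-annotation table for positional mapping.
#' @param gene_sets optional named list of gene-id vectors for
#'   over-representation testing.
#' @param fdr_level per-comparison FDR reporting level.
#' @param qq_thresholds conditional Q-Q strata cutoffs.
#' @param locus see [locus_thresholds()].
#' @param window_bp positional-mapping window.
#' @param exclusions exclusion-region table.
#' @param fdr_opts see [fdr_grid_opts()].
#' @param seed master seed.
#' @param out_dir output directory (NULL = no files written).
#' @return a `run_config` list.
#' @export
run_config <- function(primary, conditional, panel = NULL, genes = NULL,
                       gene_sets = NULL, fdr_level = 0.05,
                       qq_thresholds = c(1, 0.1, 0.01, 0.001),
                       locus = locus_thresholds(), window_bp = 1e4,
                       exclusions = default_exclusion_regions(),
                       fdr_opts = fdr_grid_opts(), seed = 42L,
                       out_dir = NULL) {
  stopifnot(fdr_level > 0, fdr_level < 1,
            all(qq_thresholds > 0), all(qq_thresholds <= 1))
  structure(list(primary = primary, conditional = conditional,
                 panel = panel, genes = genes, gene_sets = gene_sets,
                 fdr_level = fdr_level, qq_thresholds = qq_thresholds,
                 locus = locus, window_bp = window_bp,
                 exclusions = exclusions, fdr_opts = fdr_opts,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read or write the serializable part of a run configuration as YAML
#'
#' Only scalar settings and file paths are serialized; in-memory objects
#' (panels, sumstats) must be referenced by path. A round trip through
#' [save_run_config()] and [load_run_config()] preserves the
#' configuration.
#'
#' @param config a `run_config` whose `primary`/`conditional` are paths.
#' @param path YAML file path.
#' @return `load_run_config()` returns a `run_config`.
#' @export
save_run_config <- function(config, path) {
  ser <- list(primary = config$primary, conditional = config$conditional,
              fdr_level = config$fdr_level,
              qq_thresholds = as.numeric(config$qq_thresholds),
              locus = config$locus, window_bp = config$window_bp,
              exclusions = lapply(seq_len(nrow(config$exclusions)),
                                  function(i) as.list(config$exclusions[i])),
              fdr_opts = config$fdr_opts[c("bin", "max_log10", "min_stratum",
                                           "prune_iter", "r2_prune")],
              seed = config$seed, out_dir = config$out_dir)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  excl <- if (!is.null(y$exclusions)) {
    rbindlist(lapply(y$exclusions, as.data.table))
  } else default_exclusion_regions()
  fo <- do.call(fdr_grid_opts, y$fdr_opts %||% list())
  run_config(primary = y$primary, conditional = y$conditional,
             fdr_level = y$fdr_level %||% 0.05,
             qq_thresholds = y$qq_thresholds %||% c(1, 0.1, 0.01, 0.001),
             locus = y$locus %||% locus_thresholds(),
             window_bp = y$window_bp %||% 1e4,
             exclusions = excl, fdr_opts = fo,
             seed = y$seed %||% 42L, out_dir = y$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_sumstats_input <- function(x) {
  if (inherits(x, "sumstats")) x else read_sumstats(x)
}

#' Run the full cross-trait analysis
#'
#' Executes, in order: harmonization, exclusion-region filtering,
#' conditional Q-Q in both directions, condFDR grids and per-SNP values in
#' both directions, conjunctional FDR, locus definition (condFDR loci per
#' direction and conjFDR shared loci), overlap/unique-locus summaries,
#' lead-SNP effect-direction concordance, and (when a panel is available)
#' LD score regression heritability and genetic correlation; optional
#' positional gene mapping and over-representation tests when annotations
#' are supplied. A manifest records inputs, SNP counts at each stage,
#' thresholds, seed and package version. Stage failures abort with the
#' stage name; previously written outputs are preserved.
#'
#' @param config a [run_config()].
#' @return a `pipeline_report` list with all stage results and the
#'   manifest; if `config$out_dir` is set, stage TSVs plus
#'   `manifest.json` are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  emit <- function(dt, name) {
    if (!is.null(out_dir)) fwrite(dt, file.path(out_dir, name), sep = "\t")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  counts <- list()

  h <- stage("harmonize", {
    a <- as_sumstats_input(config$primary)
    b <- as_sumstats_input(config$conditional)
    counts$input_a <- nrow(a); counts$input_b <- nrow(b)
    harmonize_pair(a, b)
  })
  ab <- stage("exclusions", {
    a <- apply_exclusions(h$a, config$exclusions)
    b <- apply_exclusions(h$b, config$exclusions)
    b <- as.data.table(b)[snp %in% a$snp]
    b <- sumstats(b)
    counts$harmonized <- nrow(h$a)
    counts$after_exclusions <- nrow(a)
    list(a = a, b = b)
  })

  qq <- stage("conditional_qq", {
    thr <- sort(unique(c(1, config$qq_thresholds)), decreasing = TRUE)
    res <- list(ab = conditional_qq(ab$a, ab$b, thr),
                ba = conditional_qq(ab$b, ab$a, thr))
    emit(res$ab$curves, "qq_ab.tsv"); emit(res$ba$curves, "qq_ba.tsv")
    res
  })

  fdr_opts <- config$fdr_opts
  fdr_opts$seed <- config$seed + 1L
  fdr <- stage("condfdr", {
    res <- cross_trait_fdr(ab$a, ab$b, panel = config$panel,
                           opts = fdr_opts)
    emit(res$table, "fdr_table.tsv")
    res
  })

  loci <- stage("loci", {
    if (is.null(config$panel)) {
      NULL
    } else {
      tab <- fdr$table
      res <- list(
        cond_ab = define_loci(tab$condfdr_ab, ab$a, config$panel,
                              config$locus, label = "condfdr_ab"),
        cond_ba = define_loci(tab$condfdr_ba, ab$b, config$panel,
                              config$locus, label = "condfdr_ba"),
        conj = define_loci(tab$conjfdr, ab$a, config$panel,
                           config$locus, label = "conjfdr"))
      for (nm in names(res)) {
        emit(res[[nm]][, .(chrom, start, end, lead_snp, min_fdr,
                           n_ind_sig, n_candidates)],
             paste0("loci_", nm, ".tsv"))
        if (!is.null(out_dir)) {
          write_loci_bed(res[[nm]], file.path(out_dir,
                                              paste0("loci_", nm, ".bed")))
        }
      }
      res
    }
  })

  summary_tabs <- stage("overlap", {
    if (is.null(loci)) NULL else {
      ov <- overlap_loci(loci$cond_ab, loci$conj)
      uniq <- unique_loci(loci)
      emit(uniq, "unique_loci.tsv")
      list(cond_vs_conj = ov, unique = uniq)
    }
  })

  concordance <- stage("concordance", {
    if (is.null(loci) || !nrow(loci$conj)) NULL else {
      cc <- effect_concordance(loci$conj, ab$a, ab$b)
      emit(cc$table, "concordance.tsv")
      cc
    }
  })

  rg <- stage("rg", {
    if (is.null(config$panel) || is.null(config$panel$geno)) NULL else {
      scores <- compute_ld_scores(config$panel)
      estimate_rg(ab$a, ab$b, scores)
    }
  })

  annotation <- stage("annotate", {
    if (is.null(config$genes) || is.null(loci) || !nrow(loci$conj)) NULL
    else {
      cand <- unique(unlist(loci$conj$candidates))
      snps <- as.data.table(ab$a)[snp %in% cand]
      mapped <- map_genes_positional(snps, config$genes,
                                     window_bp = config$window_bp)
      emit(mapped, "gene_mapping.tsv")
      enr <- NULL
      if (!is.null(config$gene_sets)) {
        universe <- unique(config$genes$gene_id)
        tests <- lapply(config$gene_sets, function(gs) {
          hypergeometric_enrichment(unique(mapped$gene_id), gs, universe)
        })
        enr <- data.table(gene_set = names(tests),
                          overlap = vapply(tests, `[[`, 0, "overlap"),
                          p = vapply(tests, `[[`, 0, "p"))
        enr <- cbind(enr, bonferroni_adjust(enr$p)[, .(p_adjusted,
                                                       significant)])
        emit(enr, "gene_set_enrichment.tsv")
      }
      list(mapped = mapped, enrichment = enr)
    }
  })

  manifest <- list(
    package_version = as.character(packageVersion("pleiocond")),
    seed = config$seed,
    fdr_level = config$fdr_level,
    qq_thresholds = config$qq_thresholds,
    locus_thresholds = config$locus,
    snp_counts = counts,
    n_loci = if (is.null(loci)) NULL else lapply(loci, nrow),
    n_unique_loci = if (is.null(summary_tabs)) NULL
      else nrow(summary_tabs$unique),
    concordance = if (is.null(concordance)) NULL
      else as.list(concordance$summary),
    rg = if (is.null(rg)) NULL else rg[c("rg", "se_rg", "intercept_biv")]
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(harmonized = ab, qq = qq, fdr = fdr, loci = loci,
                 overlap = summary_tabs, concordance = concordance,
                 rg = rg, annotation = annotation, manifest = manifest),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Cross-trait pipeline report\n")
  cat("  SNPs after harmonization/exclusions:",
      x$manifest$snp_counts$after_exclusions, "\n")
  if (!is.null(x$loci)) {
    cat(sprintf("  loci: condFDR A|B %d, condFDR B|A %d, conjFDR %d\n",
                nrow(x$loci$cond_ab), nrow(x$loci$cond_ba),
                nrow(x$loci$conj)))
  }
  if (!is.null(x$concordance)) {
    s <- x$concordance$summary
    cat(sprintf("  concordant lead-SNP effects: %d of %d (%d%%)\n",
                s$n_concordant, s$n_determinate, s$percent))
  }
  if (!is.null(x$rg)) {
    cat(sprintf("  rg = %.3f (SE %.3f)\n", x$rg$rg, x$rg$se_rg))
  }
  invisible(x)
}
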