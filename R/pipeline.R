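#' Run the full eQTL study pipeline on a set of inputs
#'
#' Chains expression QC, genotype filtering and LD pruning, kinship,
#' effective-test thresholds, optional permutation FDR calibration,
#' per-transcript mixed-model mapping with local/distant classification,
#' common-divergent consolidation and hotspot detection.
#'
#' @param study A [sim_study()] or a list with the same elements
#'   (`genotypes`, `counts`, `tpm`, `annotation`, `masks`).
#' @param maf_min MAF filter (default 0.05).
#' @param prune_window,prune_step,prune_r2 LD-pruning parameters
#'   (defaults 50/10/0.8).
#' @param min_strains_retained Divergent-mask retention rule (default 100).
#' @param fdr `"none"` maps at the raw eigen threshold; `"eigen"`/`"bf"` run
#'   [permutation_fdr()] first.
#' @param fdr_traits,fdr_perm Permutation design when `fdr != "none"`.
#' @param gap,interval_pad Passed to [map_trait()].
#' @param seed Seed for the permutation stage.
#' @return A list of class `eqtl_study`: `traits`, `qc_report`, `G` (pruned),
#'   `K`, `thresholds`, `fdr` (or NULL), `threshold_used`, `eqtl`,
#'   `common_divergent`, `hotspots`.
#' @export
run_eqtl_study <- function(study, maf_min = 0.05, prune_window = 50,
                           prune_step = 10, prune_r2 = 0.8,
                           min_strains_retained = 100,
                           fdr = c("none", "eigen", "bf"),
                           fdr_traits = 100, fdr_perm = 100,
                           gap = 1000, interval_pad = 100, seed = 1L) {
  fdr <- match.arg(fdr)
  qc <- qc_pipeline(study$counts, study$tpm, study$annotation, study$masks,
                    min_strains_retained = min_strains_retained)
  G <- ld_prune(filter_markers(study$genotypes, maf_min),
                window = prune_window, step = prune_step, r2_max = prune_r2)
  K <- kinship(G)
  meff <- meff_li_ji(G)
  thresholds <- make_thresholds(meff, ncol(G$dosage))
  fdr_fit <- NULL
  threshold_used <- thresholds$eigen_threshold
  if (fdr != "none") {
    fdr_fit <- permutation_fdr(qc$traits, G, K, thresholds,
                               n_traits = min(fdr_traits, nrow(qc$traits)),
                               n_perm = fdr_perm, mode = fdr, seed = seed)
    threshold_used <- fdr_fit$cutoff
    if (fdr == "eigen") thresholds$fdr5_eigen <- fdr_fit$cutoff
    if (fdr == "bf") thresholds$fdr5_bf <- fdr_fit$cutoff
  }
  common_div <- consolidate_common_divergent(
    study$masks, n_strains = length(strains(study$genotypes)),
    genome = dplyr::distinct(
      dplyr::summarise(dplyr::group_by(study$genotypes$map, .data$chrom),
                       length = max(.data$bp), .groups = "drop")))
  eqtl <- map_eqtl(qc$traits, G, K, threshold_used, study$annotation,
                   common_divergent = common_div, gap = gap,
                   interval_pad = interval_pad)
  hotspots <- detect_hotspots(
    bin_distant_eqtl(eqtl, G$map, common_div))
  structure(list(traits = qc$traits, qc_report = qc$report, G = G, K = K,
                 thresholds = thresholds, fdr = fdr_fit,
                 threshold_used = threshold_used, eqtl = eqtl,
                 common_divergent = common_div, hotspots = hotspots),
            class = "eqtl_study")
}

#' @export
print.eqtl_study <- function(x, ...) {
  cat("<eqtl_study> ", nrow(x$traits), " traits x ", ncol(x$G$dosage),
      " pruned markers; threshold ", round(x$threshold_used, 3), "\n", sep = "")
  if (nrow(x$eqtl) > 0) {
    cat("  eQTL: ", nrow(x$eqtl), " (",
        sum(x$eqtl$classification == "local"), " local / ",
        sum(x$eqtl$classification == "distant"), " distant); hotspots: ",
        nrow(x$hotspots$hotspots), "\n", sep = "")
  } else cat("  no eQTL detected\n")
  invisible(x)
}
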