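classify_positions <- function(peak_chrom, peak_bp, tss_chrom, tss_bp,
                               window = 1e6) {
  ifelse(peak_chrom == tss_chrom & abs(peak_bp - tss_bp) <= window,
         "local", "distant")
}

#' Map QTL for one trait
#'
#' Runs [gls_scan()], groups markers above the threshold into QTL (markers on
#' one chromosome separated by at most `gap` pruned-marker indices belong to
#' the same QTL), takes the peak as the most significant marker (ties go to
#' the leftmost), and sets the interval to the markers `interval_pad` indices
#' beyond the group's outermost significant markers, clamped to the
#' chromosome ends. Variance explained is the squared Pearson correlation
#' between the peak dosage and the trait.
#'
#' @param y Named strain-level trait vector.
#' @param G A (pruned) [geno_matrix()].
#' @param K Kinship matrix or [kinship_eigen()].
#' @param threshold Significance threshold on the -log10 p scale.
#' @param vc Optional precomputed [reml_null()] fit.
#' @param gap Maximum within-chromosome index gap inside one QTL
#'   (default 1000).
#' @param interval_pad Markers added beyond the outermost significant
#'   markers (default 100).
#' @param trait Trait id.
#' @return Tibble of QTL records (possibly empty): trait, chrom, peak_marker,
#'   peak_bp, neglog10p, interval_left_bp, interval_right_bp, ve.
#' @export
map_trait <- function(y, G, K, threshold, vc = NULL, gap = 1000,
                      interval_pad = 100, trait = "trait") {
  scan <- gls_scan(y, G, K, vc = vc, trait = trait)
  empty <- tibble::tibble(trait = character(), chrom = character(),
                          peak_marker = character(), peak_bp = numeric(),
                          neglog10p = numeric(), interval_left_bp = numeric(),
                          interval_right_bp = numeric(), ve = numeric())
  sig <- which(scan$neglog10p >= threshold & !scan$monomorphic)
  if (length(sig) == 0) return(empty)
  map <- G$map
  out <- list()
  for (chrom in unique(map$chrom[sig])) {
    cidx <- which(map$chrom == chrom)
    s <- sig[map$chrom[sig] == chrom]
    within <- match(s, cidx)
    grp <- cumsum(c(1, diff(within) > gap))
    for (g in unique(grp)) {
      members <- s[grp == g]
      peak <- members[which.max(scan$neglog10p[members])]
      lo <- cidx[max(min(match(members, cidx)) - interval_pad, 1)]
      hi <- cidx[min(max(match(members, cidx)) + interval_pad, length(cidx))]
      yv <- y[rownames(G$dosage)]
      ve <- suppressWarnings(cor(G$dosage[, peak], yv, use = "complete.obs")^2)
      out[[length(out) + 1]] <- tibble::tibble(
        trait = trait, chrom = chrom,
        peak_marker = map$marker[peak], peak_bp = map$bp[peak],
        neglog10p = scan$neglog10p[peak],
        interval_left_bp = map$bp[lo], interval_right_bp = map$bp[hi],
        ve = ve)
    }
  }
  dplyr::bind_rows(out)
}

#' Classify QTL as local or distant
#'
#' Local iff the peak is on the transcript's chromosome and within
#' `window` bp of its TSS (<=, so exactly 1 Mb away is still local); all
#' other QTL are distant. Transcripts absent from the annotation are
#' `unclassified` with a warning.
#'
#' @param qtl Tibble of QTL records from [map_trait()] / [map_eqtl()].
#' @param annotation Transcript annotation.
#' @param window Half-width of the local window in bp (default 1e6).
#' @return `qtl` with a `classification` column.
#' @export
classify_eqtl <- function(qtl, annotation, window = 1e6) {
  annotation <- validate_annotation(annotation)
  i <- match(qtl$trait, annotation$transcript)
  cls <- rep("unclassified", nrow(qtl))
  known <- !is.na(i)
  if (any(!known)) warn("classify_eqtl: ", sum(!known), " trait(s) missing from the annotation.")
  cls[known] <- classify_positions(qtl$chrom[known], qtl$peak_bp[known],
                                   annotation$chrom[i[known]],
                                   annotation$tss_bp[i[known]], window)
  qtl$classification <- cls
  qtl
}

#' Map eQTL for a trait matrix
#'
#' Loops [map_trait()] over the rows of a strain-mean trait matrix, reusing
#' one kinship eigendecomposition for traits without missing strains, then
#' classifies peaks as local/distant and flags peaks inside common
#' hyper-divergent regions.
#'
#' @param traits Transcripts x strains matrix (e.g. from [qc_pipeline()]).
#' @param G A pruned [geno_matrix()].
#' @param K Kinship matrix.
#' @param threshold Significance threshold (-log10 p).
#' @param annotation Transcript annotation (for classification); `NULL` skips
#'   classification.
#' @param common_divergent Optional common-divergent intervals for the
#'   `divergent_flag` column.
#' @param gap,interval_pad Passed to [map_trait()].
#' @return Tibble of QTL records across all traits.
#' @export
map_eqtl <- function(traits, G, K, threshold, annotation = NULL,
                     common_divergent = NULL, gap = 1000, interval_pad = 100) {
  keig <- kinship_eigen(K)
  strain_ids <- strains(G)
  res <- vector("list", nrow(traits))
  for (i in seq_len(nrow(traits))) {
    y <- traits[i, strain_ids]
    names(y) <- strain_ids
    trait_id <- rownames(traits)[i] %||% paste0("trait", i)
    if (sd(y, na.rm = TRUE) == 0 || sum(is.finite(y)) < 30) next
    if (anyNA(y)) {
      ok <- names(y)[is.finite(y)]
      vc <- tryCatch(reml_null(y[ok], K[ok, ok]), error = function(e) NULL)
      if (is.null(vc)) next
      Gi <- subset_geno(G, strain_ids = ok)
      res[[i]] <- map_trait(y[ok], Gi, K[ok, ok], threshold, vc = vc,
                            gap = gap, interval_pad = interval_pad,
                            trait = trait_id)
    } else {
      vc <- reml_null(y, keig)
      res[[i]] <- map_trait(y, G, keig, threshold, vc = vc, gap = gap,
                            interval_pad = interval_pad, trait = trait_id)
    }
  }
  qtl <- dplyr::bind_rows(res)
  if (nrow(qtl) > 0 && !is.null(annotation)) qtl <- classify_eqtl(qtl, annotation)
  if (nrow(qtl) > 0) {
    qtl$divergent_flag <- in_intervals(qtl$chrom, qtl$peak_bp, common_divergent)
  }
  qtl
}

#' Permutation-calibrated 5% FDR significance cutoff
#'
#' Samples `n_traits` traits without replacement, permutes each one's strain
#' labels `n_perm` times, maps every permuted trait at the raw (eigen or
#' Bonferroni) threshold, pools the peak significances of all detected QTL,
#' and returns their 95th percentile (type-7 linear interpolation) as the
#' FDR cutoff. If no permuted trait yields a QTL the raw threshold is
#' returned with a warning.
#'
#' @param traits Transcripts x strains trait matrix with at least `n_traits`
#'   rows.
#' @param G A pruned [geno_matrix()].
#' @param K Kinship matrix.
#' @param thresholds A [make_thresholds()] object.
#' @param n_traits,n_perm Permutation design (defaults 200 x 200).
#' @param mode `"eigen"` or `"bf"`: which raw threshold to calibrate.
#' @param seed Integer seed for trait sampling and permutations.
#' @param probs Pool quantile (default 0.95).
#' @return A list of class `perm_fdr`: `cutoff`, `raw_threshold`, `pool`
#'   (peak significances), `n_qtl`, `mode`.
#' @export
permutation_fdr <- function(traits, G, K, thresholds, n_traits = 200,
                            n_perm = 200, mode = c("eigen", "bf"),
                            seed = 1L, probs = 0.95) {
  mode <- match.arg(mode)
  raw <- if (mode == "eigen") thresholds$eigen_threshold else thresholds$bf_threshold
  if (nrow(traits) < n_traits) abort("trait matrix has fewer than n_traits rows.")
  set.seed(seed)
  keig <- kinship_eigen(K)
  strain_ids <- strains(G)
  pick <- sample(nrow(traits), n_traits)
  pool <- numeric(0)
  for (i in pick) {
    y0 <- traits[i, strain_ids]
    names(y0) <- strain_ids
    ok <- names(y0)[is.finite(y0)]
    if (length(ok) < 30 || sd(y0[ok]) == 0) next
    if (length(ok) < length(y0)) {
      keig_i <- kinship_eigen(K[ok, ok])
      G_i <- subset_geno(G, strain_ids = ok)
    } else {
      keig_i <- keig
      G_i <- G
    }
    y0 <- y0[ok]
    for (p in seq_len(n_perm)) {
      y <- setNames(sample(y0), ok)
      vc <- reml_null(y, keig_i)
      q <- map_trait(y, G_i, keig_i, raw, vc = vc)
      if (nrow(q) > 0) pool <- c(pool, q$neglog10p)
    }
  }
  if (length(pool) == 0) {
    warn("permutation_fdr: no QTL detected in any permutation; returning the raw threshold.")
    cutoff <- raw
  } else {
    cutoff <- fdr_cutoff_from_pool(pool, probs)
  }
  structure(list(cutoff = cutoff, raw_threshold = raw, pool = pool,
                 n_qtl = length(pool), mode = mode,
                 n_traits = n_traits, n_perm = n_perm),
            class = "perm_fdr")
}

#' @export
print.perm_fdr <- function(x, ...) {
  cat("<perm_fdr> ", x$n_qtl, " QTL from ", x$n_traits, " x ", x$n_perm,
      " permutations (", x$mode, " raw ", round(x$raw_threshold, 3),
      "); 5% FDR cutoff = ", round(x$cutoff, 3), "\n", sep = "")
  invisible(x)
}

#' FDR cutoff from a pool of permutation peak significances
#'
#' The 95th percentile (type-7 linear interpolation) of the pooled peak
#' -log10 p values of all QTL detected on permuted traits.
#'
#' @param pool Numeric vector of peak significances.
#' @param probs Quantile (default 0.95).
#' @return The cutoff on the -log10 p scale.
#' @export
fdr_cutoff_from_pool <- function(pool, probs = 0.95) {
  if (length(pool) == 0) abort("empty pool.")
  as.numeric(quantile(pool, probs, type = 7))
}

#' Linkage disequilibrium among the QTL of one trait
#'
#' @param qtl Tibble of >= 2 QTL records for one trait.
#' @param G The [geno_matrix()] containing the peak markers.
#' @return Tibble (marker1, marker2, r2); r2 is the squared Pearson
#'   correlation of peak dosages.
#' @export
qtl_ld <- function(qtl, G) {
  if (nrow(qtl) < 2) abort("qtl_ld needs at least 2 QTL.")
  ids <- qtl$peak_marker
  d <- G$dosage[, ids, drop = FALSE]
  pairs <- utils::combn(seq_along(ids), 2)
  tibble::tibble(
    marker1 = ids[pairs[1, ]],
    marker2 = ids[pairs[2, ]],
    r2 = apply(pairs, 2, function(p) cor(d[, p[1]], d[, p[2]])^2)
  )
}

#' Fine-mapping candidate filter within a QTL region of interest
#'
#' Scans the unpruned markers of the region with the same GLS machinery,
#' then retains markers that are simultaneously (1) among the top
#' `top_frac` most significant, (2) outside common hyper-divergent regions,
#' and (3) annotated with a negative BLOSUM score.
#'
#' @param y Named strain-level trait vector.
#' @param G_roi Unpruned [geno_matrix()] restricted to the region of
#'   interest.
#' @param K Kinship matrix or [kinship_eigen()].
#' @param common_divergent Tibble (chrom, start, end) or `NULL`.
#' @param variant_annotation Tibble with columns `marker` and `blosum_score`
#'   (one row per (marker, consequence); any negative score qualifies).
#' @param top_frac Fraction of most significant markers kept (default 0.05;
#'   `ceiling(top_frac * m)` markers).
#' @param vc Optional precomputed [reml_null()] fit.
#' @return Tibble of candidate markers with their significance.
#' @export
finemap <- function(y, G_roi, K, common_divergent = NULL,
                    variant_annotation = NULL, top_frac = 0.05, vc = NULL) {
  scan <- gls_scan(y, G_roi, K, vc = vc)
  m <- nrow(scan)
  k <- ceiling(top_frac * m)
  ord <- order(-scan$neglog10p, seq_len(m))
  top <- scan[ord[seq_len(k)], ]
  top <- top[!in_intervals(top$chrom, top$bp, common_divergent), ]
  if (is.null(variant_annotation) || nrow(variant_annotation) == 0) {
    warn("finemap: empty variant annotation; no candidates.")
    return(top[0, ])
  }
  neg <- unique(variant_annotation$marker[variant_annotation$blosum_score < 0 &
                                            !is.na(variant_annotation$blosum_score)])
  top[top$marker %in% neg, ]
}
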