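test_that("QTL grouping, peak and interval follow the index arithmetic", {
  # one chromosome of 700 markers; make indices 500..510 significant by
  # planting a strong effect in a tight LD block
  set.seed(40)
  n <- 120
  block <- rbinom(n, 1, 0.4)
  d <- matrix(rbinom(n * 700, 1, 0.3), n, 700)
  for (j in 500:510) {
    flip <- rbinom(n, 1, 0.02)
    d[, j] <- ifelse(flip == 1, 1 - block, block)
  }
  rownames(d) <- sprintf("S%03d", 1:n)
  map <- tibble::tibble(marker = sprintf("mk%04d", 1:700), chrom = "chr1",
                        bp = 1e4 * (1:700))
  colnames(d) <- map$marker
  G <- geno_matrix(d, map)
  K <- kinship(G)
  y <- setNames(block * 2 + rnorm(n, 0, 0.3), strains(G))
  qtl <- map_trait(y, G, K, threshold = 6, interval_pad = 100)
  expect_equal(nrow(qtl), 1)
  peak_idx <- match(qtl$peak_marker, map$marker)
  expect_true(peak_idx %in% 500:510)
  scan <- gls_scan(y, G, K)
  sig <- which(scan$neglog10p >= 6)
  expect_equal(qtl$interval_left_bp, map$bp[max(min(sig) - 100, 1)])
  expect_equal(qtl$interval_right_bp, map$bp[min(max(sig) + 100, 700)])

  # trait equal to a marker dosage: that marker is the peak, VE = 1
  y2 <- setNames(d[, 42] + rnorm(n, 0, 1e-8), strains(G))
  qtl2 <- map_trait(y2, G, K, threshold = 6)
  expect_equal(qtl2$peak_marker[1], "mk0042")
  expect_equal(qtl2$ve[1], 1, tolerance = 1e-6)

  # no significant marker: empty record set, not an error
  y3 <- setNames(rnorm(n), strains(G))
  expect_equal(nrow(map_trait(y3, G, K, threshold = 50)), 0)

  # lowering the threshold never removes a detected peak
  qtl_lo <- map_trait(y, G, K, threshold = 4)
  expect_true(all(qtl$peak_marker %in% qtl_lo$peak_marker))
})

test_that("local/distant classification uses the 1 Mb TSS window", {
  ann <- tibble::tibble(transcript = c("t1", "t2", "t3"),
                        gene = c("g1", "g2", "g3"),
                        chrom = c("II", "II", "IV"),
                        tss_bp = c(1.2e6, 1e6, 2e6),
                        strand = "+")
  qtl <- tibble::tibble(trait = c("t1", "t2", "t3"),
                        chrom = c("II", "II", "II"),
                        peak_bp = c(2e6, 2000001, 2e6))
  out <- classify_eqtl(qtl, ann)
  expect_equal(out$classification, c("local", "distant", "distant"))
  # missing transcript: unclassified with a warning
  qtl4 <- tibble::tibble(trait = "nope", chrom = "II", peak_bp = 1)
  expect_warning(out4 <- classify_eqtl(qtl4, ann), "missing")
  expect_equal(out4$classification, "unclassified")
})

test_that("FDR pool quantile follows type-7 interpolation with fallback", {
  pool <- c(rep(6, 95), rep(9, 5))
  expect_equal(fdr_cutoff_from_pool(pool),
               unname(quantile(pool, 0.95, type = 7)))
  expect_equal(fdr_cutoff_from_pool(pool), 6.15)

  # no permutation QTL at an unreachable raw threshold: raw returned, warning
  G <- tiny_geno(n = 50, m = 40, seed = 41)
  K <- kinship(G)
  set.seed(42)
  traits <- matrix(rnorm(6 * 50), 6, 50, dimnames = list(paste0("t", 1:6),
                                                         strains(G)))
  th <- make_thresholds(1e6, 40)   # raw threshold ~7.3, unreachable at n=50
  expect_warning(
    fdr <- permutation_fdr(traits, G, K, th, n_traits = 3, n_perm = 3,
                           mode = "eigen", seed = 1),
    "no QTL")
  expect_equal(fdr$cutoff, th$eigen_threshold)
})

test_that("permutation FDR cutoff exceeds the raw threshold on null traits", {
  cfg <- fast_config(seed = 44, n_strains = 80)
  G <- ld_prune(filter_markers(sim_genotypes(cfg)))
  K <- kinship(G)
  set.seed(45)
  traits <- sim_polygenic_traits(G, h2 = 0, n_traits = 12)
  rownames(traits) <- paste0("t", 1:12)
  th <- make_thresholds(meff_li_ji(G), ncol(G$dosage))
  fdr <- permutation_fdr(traits, G, K, th, n_traits = 10, n_perm = 15,
                         mode = "eigen", seed = 2)
  expect_s3_class(fdr, "perm_fdr")
  expect_gte(fdr$cutoff, th$eigen_threshold)
  expect_equal(fdr$cutoff, fdr_cutoff_from_pool(fdr$pool))
  expect_equal(glance(fdr)$n_qtl, length(fdr$pool))
})

test_that("LD among a trait's QTL matches the correlation oracle", {
  G <- tiny_geno(n = 80, m = 10, seed = 46)
  G$dosage[, 2] <- G$dosage[, 1]          # identical peaks -> r2 = 1
  qtl <- tibble::tibble(trait = "t", peak_marker = c("mk0001", "mk0002", "mk0007"))
  ld <- qtl_ld(qtl, G)
  expect_equal(nrow(ld), 3)
  expect_equal(ld$r2[ld$marker1 == "mk0001" & ld$marker2 == "mk0002"], 1)
  for (k in seq_len(nrow(ld))) {
    expect_equal(ld$r2[k],
                 cor(G$dosage[, ld$marker1[k]], G$dosage[, ld$marker2[k]])^2,
                 tolerance = 1e-12)
  }
  expect_error(qtl_ld(qtl[1, ], G), "at least 2")
})

test_that("fine-mapping composes the three filters exactly", {
  set.seed(47)
  n <- 100
  G <- tiny_geno(n = n, m = 100, seed = 47)
  K <- kinship(G)
  y <- setNames(G$dosage[, 50] * 1.5 + rnorm(n, 0, 0.5), strains(G))
  scan <- gls_scan(y, G, K)
  ord <- order(-scan$neglog10p, seq_len(100))
  top5 <- scan$marker[ord[1:5]]
  # declare 2 of the top 5 divergent, and give exactly 1 of the remaining 3 a
  # negative BLOSUM score
  div_bp <- G$map$bp[match(top5[1:2], G$map$marker)]
  common_div <- tibble::tibble(chrom = "chr1", start = div_bp - 1, end = div_bp)
  vann <- tibble::tibble(marker = c(top5[3], "mk0099"),
                         consequence = "missense",
                         blosum_score = c(-2L, 3L))
  cand <- finemap(y, G, K, common_div, vann, top_frac = 0.05)
  expect_equal(cand$marker, top5[3])

  # brute-force three-filter oracle
  oracle <- top5[!top5 %in% top5[1:2] &
                   top5 %in% vann$marker[vann$blosum_score < 0]]
  expect_equal(cand$marker, oracle)

  # all BLOSUM >= 0: empty set
  vann2 <- dplyr::mutate(vann, blosum_score = abs(blosum_score))
  expect_equal(nrow(finemap(y, G, K, common_div, vann2)), 0)
  # empty annotation: warning + empty
  expect_warning(out <- finemap(y, G, K, common_div, NULL), "empty")
  expect_equal(nrow(out), 0)
})

test_that("planted single eQTL is recovered at the right locus", {
  hits <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_strains = 150, n_chrom = 3, markers_per_chrom = 80,
                      n_transcripts = 10, n_local_eqtl = 1, n_distant_eqtl = 0,
                      h2_local = 0.5,
                      hotspot_spec = list(marker = 1, n_targets = 0, h2 = 0),
                      seed = 100 + s)
    G0 <- sim_genotypes(cfg)
    ex <- sim_expression(G0, cfg)
    G <- ld_prune(filter_markers(G0))
    K <- kinship(G)
    tm <- strain_means(log_transform(ex$tpm))
    planted <- ex$truth[ex$truth$role == "local", ][1, ]
    y <- tm[planted$transcript, strains(G)]
    names(y) <- strains(G)
    th <- make_thresholds(meff_li_ji(G), ncol(G$dosage))
    qtl <- map_trait(y, G, K, th$eigen_threshold, trait = planted$transcript)
    if (nrow(qtl) == 0) next
    causal_bp <- G0$map$bp[match(planted$marker, G0$map$marker)]
    causal_chrom <- G0$map$chrom[match(planted$marker, G0$map$marker)]
    # within the causal LD block (block span = ld_block_len * spacing)
    span <- cfg$ld_block_len * floor(cfg$chrom_bp / cfg$markers_per_chrom)
    if (any(qtl$chrom == causal_chrom & abs(qtl$peak_bp - causal_bp) <= span)) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})
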