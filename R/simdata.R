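#' Configuration for the synthetic study generator
#'
#' The defaults emulate the statistical structure of a species-wide eQTL
#' panel of wild inbred strains: ~200 genetically distinct strains falling
#' into three population groups, two to three biological replicates each,
#' LD-blocked biallelic markers with minor allele frequency >= 5%, planted
#' local and distant eQTL with local effects drawn larger, one
#' master-regulator hotspot, per-strain hyper-divergent missingness, and one
#' organism-level trait mediated by a transcript.
#'
#' @param n_strains Number of inbred strains.
#' @param n_pops Number of population groups.
#' @param pop_divergence Fst-like differentiation of group allele
#'   frequencies, in `[0, 1)`; 0 gives a panmictic panel.
#' @param n_chrom,markers_per_chrom Genome shape.
#' @param ld_block_len Markers per LD block; within a block markers are
#'   mutation-flipped copies of a founder column, so adjacent-marker r^2 is
#'   high and decays across block boundaries.
#' @param ld_flip_rate Per-(strain, marker) probability of flipping the
#'   block-founder allele.
#' @param maf_range Ancestral allele-frequency range `(low, high)` in
#'   `(0, 0.5]`, `low < high`.
#' @param chrom_bp,chrom_cM Physical and genetic length of each chromosome;
#'   markers are regularly spaced in bp and the genetic map is linear.
#' @param n_transcripts Number of transcripts.
#' @param n_local_eqtl,n_distant_eqtl Numbers of planted local (within 1 Mb
#'   of the TSS) and distant single-eQTL transcripts.
#' @param h2_local,h2_distant Target strain-level variance fraction
#'   explained by the planted effect, in `[0, 1)`. Local defaults exceed
#'   distant ones, mirroring the larger effects of local regulatory
#'   variation.
#' @param hotspot_spec List with `marker` (master-regulator marker index or
#'   `NULL` to pick one), `n_targets` (transcripts it regulates) and `h2`
#'   (per-target variance fraction).
#' @param n_reps_per_strain 2 or 3 biological replicates per strain.
#' @param replicate_noise_sd Standard deviation of replicate-level noise on
#'   the log2 latent scale.
#' @param divergent_frac Fraction of (strain, region) pairs masked as
#'   hyper-divergent.
#' @param mediation_spec List with `exposure_marker` (index or `NULL`),
#'   `mediator` (transcript id or `NULL` to plant one), `proportion`
#'   (proportion of the total genotype effect on the organismal trait that is
#'   mediated by the transcript, in `[0, 1]`), `total_effect` and
#'   `noise_ratio` (var(noise)/var(signal) of the trait).
#' @param seed Integer seed; all sub-generators derive their streams from it
#'   deterministically.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 200,
                       n_pops = 3,
                       pop_divergence = 0.1,
                       n_chrom = 6,
                       markers_per_chrom = 200,
                       ld_block_len = 10,
                       ld_flip_rate = 0.05,
                       maf_range = c(0.05, 0.5),
                       chrom_bp = 2e7,
                       chrom_cM = 50,
                       n_transcripts = 400,
                       n_local_eqtl = 50,
                       n_distant_eqtl = 50,
                       h2_local = 0.45,
                       h2_distant = 0.25,
                       hotspot_spec = list(marker = NULL, n_targets = 30, h2 = 0.3),
                       n_reps_per_strain = 3,
                       replicate_noise_sd = 0.3,
                       divergent_frac = 0.05,
                       mediation_spec = list(exposure_marker = NULL, mediator = NULL,
                                             proportion = 0.26, total_effect = 1,
                                             noise_ratio = 1),
                       seed = 1L) {
  cfg <- list(n_strains = n_strains, n_pops = n_pops,
              pop_divergence = pop_divergence, n_chrom = n_chrom,
              markers_per_chrom = markers_per_chrom,
              ld_block_len = ld_block_len, ld_flip_rate = ld_flip_rate,
              maf_range = maf_range, chrom_bp = chrom_bp, chrom_cM = chrom_cM,
              n_transcripts = n_transcripts, n_local_eqtl = n_local_eqtl,
              n_distant_eqtl = n_distant_eqtl, h2_local = h2_local,
              h2_distant = h2_distant, hotspot_spec = hotspot_spec,
              n_reps_per_strain = n_reps_per_strain,
              replicate_noise_sd = replicate_noise_sd,
              divergent_frac = divergent_frac,
              mediation_spec = mediation_spec, seed = as.integer(seed))
  counts <- c("n_strains", "n_pops", "n_chrom", "markers_per_chrom",
              "ld_block_len", "n_transcripts")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1 || cfg[[nm]] < 1) abort("invalid config: ", nm, " must be a positive count.")
  }
  if (pop_divergence < 0 || pop_divergence >= 1) abort("invalid config: pop_divergence must be in [0, 1).")
  if (length(maf_range) != 2 || maf_range[1] >= maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    abort("invalid config: maf_range must be (low, high) with 0 < low < high <= 0.5.")
  }
  for (h in c(h2_local, h2_distant, hotspot_spec$h2)) {
    if (h < 0 || h >= 1) abort("invalid config: heritabilities must be in [0, 1).")
  }
  if (!n_reps_per_strain %in% c(2, 3)) abort("invalid config: n_reps_per_strain must be 2 or 3.")
  if (replicate_noise_sd < 0) abort("invalid config: replicate_noise_sd must be >= 0.")
  if (divergent_frac < 0 || divergent_frac > 1) abort("invalid config: divergent_frac must be in [0, 1].")
  p <- mediation_spec$proportion
  if (is.null(p) || p < 0 || p > 1) abort("invalid config: mediation proportion must be in [0, 1].")
  if (hotspot_spec$n_targets > n_transcripts) abort("invalid config: hotspot targets exceed n_transcripts.")
  if (n_local_eqtl + n_distant_eqtl + hotspot_spec$n_targets > n_transcripts) {
    abort("invalid config: planted transcripts exceed n_transcripts.")
  }
  structure(cfg, class = "sim_config")
}

chrom_names <- function(n) {
  if (n <= 6) c("I", "II", "III", "IV", "V", "X")[seq_len(n)] else paste0("chr", seq_len(n))
}

#' Simulate genotypes for a panel of inbred strains
#'
#' Dosages are 0/1 (no heterozygotes). Linkage disequilibrium is created by
#' copying a per-strain block founder allele down each LD block and flipping
#' it with a small per-site probability; population structure enters through
#' Balding-Nichols group-specific allele frequencies.
#'
#' @param cfg A [sim_config()].
#' @return A [geno_matrix()] whose map carries `bp` (regular spacing) and
#'   `cM` (linear map). The strainwise population assignment is stored in
#'   `attr(, "pops")`.
#' @export
sim_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_strains
  m_c <- cfg$markers_per_chrom
  chroms <- chrom_names(cfg$n_chrom)
  pops <- rep_len(seq_len(cfg$n_pops), n)
  strain_ids <- sprintf("ST%03d", seq_len(n))
  Fst <- cfg$pop_divergence

  dosage <- matrix(NA_real_, n, m_c * cfg$n_chrom)
  for (ci in seq_len(cfg$n_chrom)) {
    block_starts <- seq(1, m_c, by = cfg$ld_block_len)
    for (bs in block_starts) {
      idx <- bs:min(bs + cfg$ld_block_len - 1, m_c)
      p_anc <- runif(1, cfg$maf_range[1], cfg$maf_range[2])
      if (Fst > 0) {
        a <- p_anc * (1 - Fst) / Fst
        b <- (1 - p_anc) * (1 - Fst) / Fst
        p_pop <- pmin(pmax(stats::rbeta(cfg$n_pops, a, b), 0.01), 0.99)
      } else {
        p_pop <- rep(p_anc, cfg$n_pops)
      }
      founder <- rbinom(n, 1, p_pop[pops])
      for (j in idx) {
        flip <- rbinom(n, 1, cfg$ld_flip_rate)
        dosage[, (ci - 1) * m_c + j] <- ifelse(flip == 1, 1 - founder, founder)
      }
    }
  }
  spacing <- floor(cfg$chrom_bp / m_c)
  map <- tibble::tibble(
    marker = sprintf("M%05d", seq_len(m_c * cfg$n_chrom)),
    chrom = rep(chroms, each = m_c),
    bp = rep(spacing * (seq_len(m_c) - 1) + spacing %/% 2, cfg$n_chrom),
    cM = rep(cfg$chrom_cM * (seq_len(m_c) - 0.5) / m_c, cfg$n_chrom)
  )
  rownames(dosage) <- strain_ids
  colnames(dosage) <- map$marker
  G <- geno_matrix(dosage, map)
  attr(G, "pops") <- setNames(pops, strain_ids)
  G
}

# pick the planted architecture: which transcript gets which causal marker
plan_architecture <- function(G, cfg) {
  map <- G$map
  n_t <- cfg$n_transcripts
  chroms <- unique(map$chrom)
  ann <- tibble::tibble(
    transcript = sprintf("T%05d", seq_len(n_t)),
    gene = sprintf("G%05d", seq_len(n_t)),
    chrom = sample(chroms, n_t, replace = TRUE),
    tss_bp = round(runif(n_t, 1, cfg$chrom_bp)),
    strand = sample(c("+", "-"), n_t, replace = TRUE)
  )
  hs <- cfg$hotspot_spec
  master <- hs$marker %||% sample(nrow(map), 1)
  med <- cfg$mediation_spec
  exposure <- med$exposure_marker %||% {
    cand <- which(map$chrom != map$chrom[master])
    cand[sample(length(cand), 1)]
  }

  roles <- rep("null", n_t)
  ord <- sample(n_t)
  i_local <- ord[seq_len(cfg$n_local_eqtl)]
  i_dist <- ord[cfg$n_local_eqtl + seq_len(cfg$n_distant_eqtl)]
  i_hot <- ord[cfg$n_local_eqtl + cfg$n_distant_eqtl + seq_len(hs$n_targets)]
  roles[i_local] <- "local"; roles[i_dist] <- "distant"; roles[i_hot] <- "hotspot"

  pick_local <- function(chrom, tss) {
    cand <- which(map$chrom == chrom & abs(map$bp - tss) <= 8e5)
    if (length(cand) == 0) cand <- which(map$chrom == chrom)[which.min(abs(map$bp[map$chrom == chrom] - tss))]
    cand[sample.int(length(cand), 1)]
  }
  pick_distant <- function(chrom) {
    cand <- which(map$chrom != chrom)
    cand[sample.int(length(cand), 1)]
  }
  causal <- rep(NA_integer_, n_t)
  for (i in i_local) causal[i] <- pick_local(ann$chrom[i], ann$tss_bp[i])
  for (i in i_dist) causal[i] <- pick_distant(ann$chrom[i])
  # hotspot targets live on chromosomes other than the master's so the
  # planted effect is unambiguously distant
  master_chrom <- map$chrom[master]
  for (i in i_hot) {
    if (ann$chrom[i] == master_chrom) {
      ann$chrom[i] <- sample(setdiff(chroms, master_chrom), 1)
    }
    causal[i] <- master
  }
  # the mediator transcript gets a dedicated eQTL at the exposure marker
  mediator <- med$mediator
  if (is.null(mediator)) {
    i_med <- ord[cfg$n_local_eqtl + cfg$n_distant_eqtl + hs$n_targets + 1]
    if (is.na(i_med)) abort("invalid config: no free transcript left for the mediator.")
    if (ann$chrom[i_med] == map$chrom[exposure]) {
      ann$chrom[i_med] <- sample(setdiff(chroms, map$chrom[exposure]), 1)
    }
    roles[i_med] <- "mediator"
    causal[i_med] <- exposure
    mediator <- ann$transcript[i_med]
  }
  list(annotation = ann, roles = roles, causal = causal,
       master = master, exposure = exposure, mediator = mediator)
}

#' Simulate transcript expression with planted eQTL
#'
#' Per transcript, the strain-level genetic value is the planted effect times
#' the (centered) causal dosage, rescaled so the strain-level variance
#' fraction hits the target heritability exactly; replicates add independent
#' Gaussian noise on the log2 latent scale. TPM is `2^latent` (a positive
#' monotone transform, so the downstream `log2(TPM + 0.5)` recovers an
#' approximately linear-Gaussian trait) and counts rescale TPM to per-sample
#' library sizes.
#'
#' @param G A [geno_matrix()] from [sim_genotypes()].
#' @param cfg The same [sim_config()].
#' @return A list with `counts` and `tpm` ([expr_matrix()] objects),
#'   `annotation` (transcript, gene, chrom, tss_bp, strand), and `truth`
#'   (tibble: transcript, marker, class, effect, h2, role).
#' @export
sim_expression <- function(G, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  plan <- plan_architecture(G, cfg)
  ann <- plan$annotation
  map <- G$map
  n <- cfg$n_strains
  n_t <- cfg$n_transcripts
  reps <- cfg$n_reps_per_strain
  strain_ids <- strains(G)

  h2_of <- c(local = cfg$h2_local, distant = cfg$h2_distant,
             hotspot = cfg$hotspot_spec$h2, mediator = 0.5, null = 0)
  mu <- rnorm(n_t, 5, 2)                       # baseline log2 abundance

  latent_strain <- matrix(0, n_t, n)           # genetic + strain-level env, unit var
  eff <- rep(0, n_t)
  for (i in seq_len(n_t)) {
    h2 <- h2_of[[plan$roles[i]]]
    e <- rnorm(n)
    e <- e / sd(e) * sqrt(1 - h2)
    g <- 0
    if (h2 > 0) {
      x <- G$dosage[, plan$causal[i]]
      x <- x - mean(x)
      if (sd(x) > 0) {
        g <- x / sd(x) * sqrt(h2)
        eff[i] <- sqrt(h2) / sd(G$dosage[, plan$causal[i]])
      } else {
        e <- rnorm(n); e <- e / sd(e)           # monomorphic causal: pure noise
      }
    }
    latent_strain[i, ] <- mu[i] + g + e
  }

  sample_meta <- tibble::tibble(
    strain = rep(strain_ids, each = reps),
    replicate = rep(seq_len(reps), n)
  )
  sample_meta$sample <- paste0(sample_meta$strain, "_r", sample_meta$replicate)
  latent <- latent_strain[, rep(seq_len(n), each = reps)] +
    matrix(rnorm(n_t * n * reps, 0, cfg$replicate_noise_sd), n_t, n * reps)
  tpm <- 2^latent
  dimnames(tpm) <- list(ann$transcript, sample_meta$sample)
  lib <- exp(rnorm(ncol(tpm), 0, 0.2))         # per-sample library-size factor
  counts <- round(sweep(tpm, 2, lib, `*`))
  dimnames(counts) <- dimnames(tpm)

  planted <- plan$roles != "null"
  truth <- tibble::tibble(
    transcript = ann$transcript[planted],
    marker = map$marker[plan$causal[planted]],
    effect = eff[planted],
    h2 = unname(h2_of[plan$roles[planted]]),
    role = plan$roles[planted]
  )
  truth$class <- classify_positions(
    map$chrom[match(truth$marker, map$marker)],
    map$bp[match(truth$marker, map$marker)],
    ann$chrom[match(truth$transcript, ann$transcript)],
    ann$tss_bp[match(truth$transcript, ann$transcript)]
  )
  list(
    counts = expr_matrix(counts, sample_meta),
    tpm = expr_matrix(tpm, sample_meta),
    annotation = ann,
    truth = truth,
    master_marker = map$marker[plan$master],
    exposure_marker = map$marker[plan$exposure],
    mediator = plan$mediator
  )
}

#' Simulate per-strain hyper-divergent region masks
#'
#' The genome is split into a fixed grid of candidate regions (ten per
#' chromosome) and each (strain, region) pair is masked independently with
#' probability `divergent_frac`, emulating strain-specific hyper-divergent
#' intervals.
#'
#' @param cfg A [sim_config()].
#' @param G The matching [geno_matrix()].
#' @return Tibble (strain, chrom, start, end), BED-style 0-based half-open.
#' @export
sim_divergent_masks <- function(cfg, G) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  chroms <- unique(G$map$chrom)
  n_reg <- 10L
  grid <- tidyr::expand_grid(chrom = chroms, reg = seq_len(n_reg) - 1L)
  grid$start <- grid$reg * floor(cfg$chrom_bp / n_reg)
  grid$end <- (grid$reg + 1L) * floor(cfg$chrom_bp / n_reg)
  out <- tidyr::expand_grid(strain = strains(G), grid)
  keep <- runif(nrow(out)) < cfg$divergent_frac
  out <- out[keep, c("strain", "chrom", "start", "end")]
  if (nrow(out) == 0) return(tibble::tibble(strain = character(), chrom = character(),
                                            start = integer(), end = integer()))
  validate_masks(out)
}

#' Simulate an organism-level trait mediated by a transcript
#'
#' The trait is `Y = c'X + bM + e` where `X` is the exposure-marker dosage,
#' `M` the mediator transcript's strain-mean expression on the log2 scale,
#' and the coefficients are solved so that the indirect effect `a*b` (with
#' `a` the fitted slope of `M ~ X` in the simulated data) is the requested
#' proportion of the total effect.
#'
#' @param G A [geno_matrix()].
#' @param expr The list returned by [sim_expression()].
#' @param cfg The same [sim_config()].
#' @return A list with `phenotype` (tibble: strain, value) and `truth`
#'   (tibble: exposure marker, mediator, proportion, total_effect).
#' @export
sim_mediated_trait <- function(G, expr, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  spec <- cfg$mediation_spec
  exposure <- expr$exposure_marker
  mediator <- expr$mediator %||% spec$mediator
  X <- G$dosage[, exposure]
  tpmv <- expr$tpm$values[mediator, ]
  Ml <- log_transform(tpmv)
  M <- tapply(Ml, expr$tpm$samples$strain, mean)[strains(G)]
  a <- cov(X, M) / var(X)
  if (abs(a) < 1e-8) abort("mediator has no association with the exposure marker.")
  total <- spec$total_effect
  p <- spec$proportion
  b <- p * total / a
  c_direct <- (1 - p) * total
  signal <- c_direct * X + b * M
  noise_ratio <- spec$noise_ratio %||% 1
  e <- rnorm(length(X), 0, sd(signal) * sqrt(noise_ratio))
  y <- signal + e
  list(
    phenotype = tibble::tibble(strain = strains(G), value = as.numeric(y)),
    truth = tibble::tibble(exposure = exposure, mediator = mediator,
                           proportion = p, total_effect = total)
  )
}

#' Simulate a complete study
#'
#' Runs [sim_genotypes()], [sim_expression()], [sim_divergent_masks()] and
#' [sim_mediated_trait()] under one configuration and returns all pieces plus
#' the ground truth.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_study` with elements `genotypes`, `counts`,
#'   `tpm`, `annotation`, `masks`, `phenotype`, `truth`, `mediation_truth`,
#'   `master_marker`, `exposure_marker`, `mediator`, `config`.
#' @export
sim_study <- function(cfg = sim_config()) {
  G <- sim_genotypes(cfg)
  ex <- sim_expression(G, cfg)
  masks <- sim_divergent_masks(cfg, G)
  med <- sim_mediated_trait(G, ex, cfg)
  structure(list(
    genotypes = G, counts = ex$counts, tpm = ex$tpm,
    annotation = ex$annotation, masks = masks,
    phenotype = med$phenotype, truth = ex$truth,
    mediation_truth = med$truth,
    master_marker = ex$master_marker,
    exposure_marker = ex$exposure_marker,
    mediator = ex$mediator, config = cfg
  ), class = "sim_study")
}

#' Simulate strain-level polygenic traits at a target heritability
#'
#' Every marker receives a small effect; the genetic and environmental parts
#' are rescaled so the realized strain-level genetic variance fraction equals
#' `h2` exactly. Useful for calibrating variance-component estimators.
#'
#' @param G A [geno_matrix()].
#' @param h2 Target narrow-sense heritability in `[0, 1)`.
#' @param n_traits Number of traits.
#' @return Numeric matrix, traits x strains.
#' @export
sim_polygenic_traits <- function(G, h2, n_traits = 100) {
  stopifnot(h2 >= 0, h2 < 1)
  n <- nrow(G$dosage)
  m <- ncol(G$dosage)
  Z <- scale(G$dosage)
  Z[, apply(G$dosage, 2, sd) == 0] <- 0
  out <- matrix(NA_real_, n_traits, n, dimnames = list(NULL, strains(G)))
  for (t in seq_len(n_traits)) {
    g <- as.numeric(Z %*% rnorm(m))
    e <- rnorm(n)
    g <- if (sd(g) > 0 && h2 > 0) g / sd(g) * sqrt(h2) else 0 * g
    e <- e / sd(e) * sqrt(1 - h2)
    out[t, ] <- g + e
  }
  out
}
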