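# small in-code fixtures shared across test files

# independent random 0/1 dosages on one or more chromosomes
tiny_geno <- function(n = 40, m = 30, seed = 1, n_chrom = 1, maf = 0.3,
                      spacing = 1e5) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 1, maf), n, m)
  rownames(d) <- sprintf("S%03d", seq_len(n))
  m_c <- m / n_chrom
  map <- tibble::tibble(
    marker = sprintf("mk%04d", seq_len(m)),
    chrom = rep(paste0("chr", seq_len(n_chrom)), each = m_c),
    bp = rep(spacing * seq_len(m_c), n_chrom),
    cM = rep(0.05 * seq_len(m_c), n_chrom)
  )
  colnames(d) <- map$marker
  geno_matrix(d, map)
}

# expression matrix with explicit replicate structure
tiny_expr <- function(values, strains, reps) {
  samples <- tibble::tibble(
    strain = rep(strains, each = reps),
    replicate = rep(seq_len(reps), length(strains))
  )
  samples$sample <- paste0(samples$strain, "_r", samples$replicate)
  colnames(values) <- samples$sample
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("tx%03d", seq_len(nrow(values)))
  }
  expr_matrix(values, samples)
}

tiny_annotation <- function(transcripts, chrom = "chr1", tss = NULL) {
  n <- length(transcripts)
  tibble::tibble(
    transcript = transcripts,
    gene = paste0("g_", transcripts),
    chrom = rep_len(chrom, n),
    tss_bp = tss %||% (1e5 * seq_len(n)),
    strand = rep_len("+", n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# default small config for fast simulations; dots override the defaults
fast_config <- function(...) {
  args <- utils::modifyList(list(
    n_strains = 60, n_pops = 3, markers_per_chrom = 60, n_chrom = 3,
    n_transcripts = 60, n_local_eqtl = 8, n_distant_eqtl = 8,
    hotspot_spec = list(marker = NULL, n_targets = 6, h2 = 0.3),
    divergent_frac = 0.05), list(...))
  do.call(sim_config, args)
}
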