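#' Median-of-ratios normalization factors
#'
#' For each reference transcript with all-positive (and unmasked) values,
#' compute its geometric mean across samples; each sample's factor is the
#' median over reference transcripts of value / geometric mean. Dividing a
#' sample by its factor puts all samples on a common scale.
#'
#' @param x An [expr_matrix()] or plain transcripts x samples matrix
#'   (TPM or counts).
#' @param reference_transcripts Optional character vector restricting the
#'   reference set; defaults to all transcripts.
#' @return Named numeric vector of positive per-sample factors.
#' @export
norm_factors <- function(x, reference_transcripts = NULL) {
  v <- if (inherits(x, "expr_matrix")) expr_values(x) else as.matrix(x)
  if (!is.null(reference_transcripts)) {
    v <- v[rownames(v) %in% reference_transcripts, , drop = FALSE]
  }
  ok <- rowSums(is.na(v) | v <= 0) == 0
  if (!any(ok)) abort("normalization error: no reference transcript positive in all samples.")
  lv <- log(v[ok, , drop = FALSE])
  ratio <- exp(lv - rowMeans(lv))            # x / geomean, computed stably
  factors <- apply(ratio, 2, median)
  setNames(factors, colnames(v))
}

#' Apply per-sample normalization factors
#' @param x An [expr_matrix()] or matrix.
#' @param factors Output of [norm_factors()], named by sample.
#' @return Same type as `x`, values divided by the sample factor.
#' @export
apply_norm_factors <- function(x, factors) {
  if (inherits(x, "expr_matrix")) {
    x$values <- sweep(x$values, 2, factors[colnames(x$values)], `/`)
    x
  } else {
    sweep(x, 2, factors[colnames(x)], `/`)
  }
}

#' Select reliably expressed transcripts
#'
#' A transcript is kept iff at least `min_strains` strains have normalized
#' counts >= `min_count` in *all* of their replicates.
#'
#' @param norm_counts An [expr_matrix()] of normalized counts.
#' @param min_count Minimum normalized count (default 5).
#' @param min_strains Minimum number of qualifying strains (default 10).
#' @return Character vector of kept transcript ids.
#' @export
filter_reliable <- function(norm_counts, min_count = 5, min_strains = 10) {
  stopifnot(inherits(norm_counts, "expr_matrix"))
  v <- expr_values(norm_counts)
  strain <- norm_counts$samples$strain
  pass <- !is.na(v) & v >= min_count
  # per transcript, count strains whose every replicate passes
  strain_levels <- unique(strain)
  all_pass <- vapply(strain_levels, function(s) {
    cols <- strain == s
    rowSums(pass[, cols, drop = FALSE]) == sum(cols)
  }, logical(nrow(v)))
  if (nrow(v) == 1) all_pass <- matrix(all_pass, nrow = 1)
  keep <- rowSums(all_pass) >= min_strains
  rownames(v)[keep]
}

#' Mask expression in hyper-divergent regions and drop thin transcripts
#'
#' A transcript is masked for a strain iff its TSS falls inside one of that
#' strain's divergent intervals (BED 0-based half-open, TSS 1-based).
#' Transcripts with fewer than `min_strains_retained` unmasked strains are
#' dropped entirely.
#'
#' @param expr An [expr_matrix()].
#' @param masks Tibble (strain, chrom, start, end).
#' @param annotation Transcript annotation covering all transcripts of `expr`.
#' @param min_strains_retained Minimum strains with retained data
#'   (default 100).
#' @return An [expr_matrix()] with an updated mask and possibly fewer
#'   transcripts. Dropped transcript ids are in `attr(, "dropped")`.
#' @export
apply_divergent_mask <- function(expr, masks, annotation,
                                 min_strains_retained = 100) {
  stopifnot(inherits(expr, "expr_matrix"))
  annotation <- validate_annotation(annotation)
  tx <- rownames(expr$values)
  miss <- setdiff(tx, annotation$transcript)
  if (length(miss) > 0) abort("annotation does not cover transcript(s): ", paste(head(miss, 5), collapse = ", "))
  ann <- annotation[match(tx, annotation$transcript), ]
  mask <- expr$mask
  if (nrow(masks) > 0) {
    for (s in unique(masks$strain)) {
      ms <- masks[masks$strain == s, ]
      # TSS (1-based) in [start, end) 0-based half-open  <=>  start < tss <= end
      hit <- vapply(seq_along(tx), function(i) {
        any(ms$chrom == ann$chrom[i] & ms$start < ann$tss_bp[i] & ann$tss_bp[i] <= ms$end)
      }, logical(1))
      cols <- expr$samples$strain == s
      if (any(hit) && any(cols)) mask[hit, cols] <- TRUE
    }
  }
  strain <- expr$samples$strain
  retained <- apply(!mask, 1, function(ok) length(unique(strain[ok])))
  keep <- retained >= min_strains_retained
  out <- expr_matrix(expr$values[keep, , drop = FALSE], expr$samples,
                     mask[keep, , drop = FALSE])
  attr(out, "dropped") <- tx[!keep]
  out
}

#' Iterative selection of well-clustered samples
#'
#' Replicates of one strain should sit closer to each other than to other
#' strains' samples. Each iteration: (1) summarize counts to gene level (if
#' an annotation is given), normalize by median-of-ratios and take
#' `log2(x + 1)`; (2) compute all-pairs Euclidean distances between samples;
#' (3) per strain, compare each intra-strain replicate-pair distance with the
#' median of that strain's inter-strain distances (pooled over all of its
#' samples). Keep all replicates if every intra-pair passes (strict `<`);
#' drop the whole strain if none do; for 3-replicate strains with one or two
#' passing pairs keep the minimum-distance pair. Iterate on the reduced
#' sample set until a fixed point.
#'
#' @param counts An [expr_matrix()] of raw counts.
#' @param annotation Optional transcript annotation used to sum transcripts
#'   into gene-level abundances before the distance computation.
#' @param max_iter Iteration cap (default 20); exceeding it is an error.
#' @return A list with `kept` (sample ids), `report` (tibble: sample, strain,
#'   status, reason) and `iterations`.
#' @export
select_samples <- function(counts, annotation = NULL, max_iter = 20) {
  stopifnot(inherits(counts, "expr_matrix"))
  v0 <- counts$values
  if (!is.null(annotation)) {
    annotation <- validate_annotation(annotation)
    gene <- annotation$gene[match(rownames(v0), annotation$transcript)]
    gene[is.na(gene)] <- rownames(v0)[is.na(gene)]
    v0 <- rowsum(v0, gene)
  }
  meta <- counts$samples
  current <- meta$sample
  dropped <- tibble::tibble(sample = character(), strain = character(),
                            reason = character())
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    if (iterations > max_iter) abort("sample selection did not converge in ", max_iter, " iterations.")
    v <- v0[, current, drop = FALSE]
    f <- norm_factors(v)
    lv <- t(log2(apply_norm_factors(v, f) + 1))      # samples x features
    D <- as.matrix(dist(lv))
    strain <- meta$strain[match(current, meta$sample)]
    remove <- character()
    for (s in unique(strain)) {
      idx <- which(strain == s)
      if (length(idx) < 2) next
      inter <- D[idx, -idx, drop = FALSE]
      med_inter <- median(inter)
      pairs <- utils::combn(idx, 2)
      intra <- D[t(pairs)]
      pass <- intra < med_inter                      # ties fail
      if (all(pass)) next
      if (!any(pass)) {
        remove <- c(remove, current[idx])
      } else {
        # 3-replicate strain with 1-2 passing pairs: keep min-distance pair
        best <- pairs[, which.min(intra)]
        remove <- c(remove, current[setdiff(idx, best)])
      }
    }
    if (length(remove) == 0) break
    strain_of <- meta$strain[match(remove, meta$sample)]
    gone_strains <- tapply(remove, strain_of, length)
    n_had <- table(strain)[names(gone_strains)]
    reason <- ifelse(gone_strains == n_had, "strain_removed", "outlier_replicate")
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      sample = remove, strain = strain_of,
      reason = unname(reason[match(strain_of, names(gone_strains))])
    ))
    current <- setdiff(current, remove)
    if (length(current) < 3) abort("sample selection removed nearly all samples.")
  }
  report <- dplyr::bind_rows(
    tibble::tibble(sample = current,
                   strain = meta$strain[match(current, meta$sample)],
                   status = "kept", reason = NA_character_),
    dplyr::mutate(dropped, status = "dropped")
  )
  list(kept = current, report = report, iterations = iterations)
}

#' Log2 transform with pseudocount
#'
#' `log2(x + pseudocount)`; the default pseudocount of 0.5 maps a zero to -1.
#' @param x An [expr_matrix()] or numeric matrix/vector of normalized TPM.
#' @param pseudocount Added before the log (default 0.5).
#' @return Same shape as `x`.
#' @export
log_transform <- function(x, pseudocount = 0.5) {
  if (inherits(x, "expr_matrix")) {
    x$values <- log2(x$values + pseudocount)
    x
  } else {
    log2(x + pseudocount)
  }
}

#' Strain-mean trait matrix
#'
#' Averages each strain's kept replicates per transcript (transform first,
#' then average). Masked cells are excluded; a strain with no unmasked
#' replicate gets NA.
#'
#' @param expr An [expr_matrix()] on the transformed scale.
#' @return Numeric matrix, transcripts x strains.
#' @export
strain_means <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  v <- expr_values(expr)
  strain <- expr$samples$strain
  strain_levels <- unique(strain)
  out <- vapply(strain_levels, function(s) {
    rowMeans(v[, strain == s, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(v)))
  if (nrow(v) == 1) out <- matrix(out, nrow = 1)
  out[is.nan(out)] <- NA_real_
  dimnames(out) <- list(rownames(v), strain_levels)
  out
}

#' Full expression QC pipeline
#'
#' Chains normalization, reliable-transcript filtering, divergent masking,
#' iterative outlier-sample removal and strain-mean construction into one
#' call.
#'
#' @param counts,tpm Raw [expr_matrix()] objects (same transcripts/samples).
#' @param annotation Transcript annotation.
#' @param masks Divergent masks (strain, chrom, start, end), or `NULL`.
#' @param min_count,min_strains Passed to [filter_reliable()].
#' @param min_strains_retained Passed to [apply_divergent_mask()].
#' @return A list with `traits` (transcripts x strains matrix of strain-mean
#'   log2 normalized TPM), `expr` (the masked, transformed [expr_matrix()]),
#'   `report` (QC report tibble covering samples and transcripts) and
#'   `iterations`.
#' @export
qc_pipeline <- function(counts, tpm, annotation, masks = NULL,
                        min_count = 5, min_strains = 10,
                        min_strains_retained = 100) {
  annotation <- validate_annotation(annotation)
  # reliable transcripts on normalized counts
  fc <- norm_factors(counts)
  ncounts <- apply_norm_factors(counts, fc)
  reliable <- filter_reliable(ncounts, min_count, min_strains)
  dropped_tx <- tibble::tibble(
    transcript = setdiff(rownames(counts$values), reliable),
    reason = "low_expression"
  )
  counts_r <- subset_expr(counts, reliable)
  tpm_r <- subset_expr(tpm, reliable)

  # well-clustered samples on gene-level counts
  sel <- select_samples(counts_r, annotation)
  tpm_k <- subset_expr(tpm_r, samples = which(colnames(tpm_r$values) %in% sel$kept))

  # normalization factors from the kept samples before masking (masked cells
  # are data dropped later, not evidence against the sample's scale)
  ft <- norm_factors(tpm_k)
  tpm_n <- apply_norm_factors(tpm_k, ft)

  # divergent masking (after sample QC so the >=100-strain rule sees the
  # final strain set)
  if (!is.null(masks) && nrow(masks) > 0) {
    tpm_m <- apply_divergent_mask(tpm_n, masks, annotation, min_strains_retained)
    dropped_tx <- dplyr::bind_rows(dropped_tx, tibble::tibble(
      transcript = attr(tpm_m, "dropped"), reason = "too_few_strains"))
  } else {
    tpm_m <- tpm_n
  }
  traits <- strain_means(log_transform(tpm_m))
  report <- dplyr::bind_rows(
    dplyr::mutate(sel$report, unit = "sample", id = .data$sample) |>
      dplyr::select("unit", "id", "status", "reason"),
    tibble::tibble(unit = "transcript", id = rownames(tpm_m$values),
                   status = "kept", reason = NA_character_),
    dplyr::mutate(dropped_tx, unit = "transcript", id = .data$transcript,
                  status = "dropped") |>
      dplyr::select("unit", "id", "status", "reason")
  )
  list(traits = traits, expr = log_transform(tpm_m),
       report = report, iterations = sel$iterations)
}
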