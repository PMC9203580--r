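#' Genotype matrix container
#'
#' Bundles a strains x markers dosage matrix with its marker map. Strains are
#' fully inbred, so dosages are coded 0/1 (homozygous reference/alternative);
#' uncertain or heterozygous calls are `NA`.
#'
#' @param dosage Numeric matrix, strains in rows (rownames = strain ids),
#'   markers in columns (colnames = marker ids), values in `{0, 1, NA}`.
#' @param map Data frame with one row per marker: `marker`, `chrom`,
#'   `bp` (1-based physical position) and optionally `cM` (genetic position,
#'   monotone non-decreasing within chromosome).
#'
#' @return An object of class `geno_matrix`: a list with elements `dosage`
#'   and `map` (a tibble).
#' @export
geno_matrix <- function(dosage, map) {
  map <- tibble::as_tibble(map)
  if (!all(c("marker", "chrom", "bp") %in% names(map))) {
    abort("`map` needs columns marker, chrom, bp.")
  }
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)) || anyDuplicated(rownames(dosage))) {
    abort("`dosage` needs unique strain rownames.")
  }
  if (ncol(dosage) != nrow(map)) {
    abort("dosage has ", ncol(dosage), " markers but map has ", nrow(map), " rows.")
  }
  if (is.null(colnames(dosage))) colnames(dosage) <- map$marker
  if (!identical(colnames(dosage), as.character(map$marker))) {
    abort("dosage column names must match map$marker in order.")
  }
  bad <- dosage[!is.na(dosage) & dosage != 0 & dosage != 1]
  if (length(bad) > 0) abort("dosage values must be 0, 1 or NA.")
  # markers sorted by (chrom, bp), chromosome order = order of appearance
  ord <- order(match(map$chrom, unique(map$chrom)), map$bp)
  if (!identical(ord, seq_len(nrow(map)))) {
    map <- map[ord, ]
    dosage <- dosage[, ord, drop = FALSE]
  }
  if (!is.null(map[["cM"]])) {
    mono <- all(tapply(map$cM, map$chrom, function(x) !is.unsorted(x)))
    if (!mono) abort("cM must be monotone non-decreasing within chromosome.")
  }
  structure(list(dosage = dosage, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$dosage), " strains x ", ncol(x$dosage),
      " markers on ", length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Strain ids of a genotype matrix
#' @param G A `geno_matrix`.
#' @return Character vector of strain ids.
#' @export
strains <- function(G) rownames(G$dosage)

#' Subset a genotype matrix
#'
#' @param G A `geno_matrix`.
#' @param strain_ids Optional character vector of strains to keep (in order).
#' @param marker_ids Optional character vector or logical/integer index of
#'   markers to keep.
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(G, strain_ids = NULL, marker_ids = NULL) {
  d <- G$dosage
  map <- G$map
  if (!is.null(strain_ids)) {
    missing <- setdiff(strain_ids, rownames(d))
    if (length(missing) > 0) abort("unknown strains: ", paste(missing, collapse = ", "))
    d <- d[strain_ids, , drop = FALSE]
  }
  if (!is.null(marker_ids)) {
    if (is.character(marker_ids)) marker_ids <- match(marker_ids, map$marker)
    d <- d[, marker_ids, drop = FALSE]
    map <- map[marker_ids, ]
  }
  geno_matrix(d, map)
}

#' Expression matrix container
#'
#' Bundles a transcripts x samples expression matrix (counts or TPM) with
#' sample metadata and an optional missingness mask (used to blank out
#' transcripts falling in a strain's hyper-divergent regions).
#'
#' @param values Numeric matrix, transcripts in rows, samples in columns,
#'   non-negative where not masked.
#' @param samples Data frame with columns `sample`, `strain`, `replicate`
#'   covering every column of `values`.
#' @param mask Optional logical matrix of the same dimension; `TRUE` marks a
#'   (transcript, sample) cell as missing.
#'
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, samples, mask = NULL) {
  samples <- tibble::as_tibble(samples)
  if (!all(c("sample", "strain", "replicate") %in% names(samples))) {
    abort("`samples` needs columns sample, strain, replicate.")
  }
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- samples$sample
  missing_meta <- setdiff(colnames(values), samples$sample)
  if (length(missing_meta) > 0) {
    abort("samples missing from metadata: ", paste(missing_meta, collapse = ", "))
  }
  samples <- samples[match(colnames(values), samples$sample), ]
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(values)))
  } else {
    mask <- is.na(values)
    dimnames(mask) <- dimnames(values)
  }
  neg <- values[!mask & !is.na(values)] < 0
  if (any(neg)) abort("negative expression values.")
  structure(list(values = values, samples = samples, mask = mask),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " transcripts x ", ncol(x$values),
      " samples (", length(unique(x$samples$strain)), " strains)\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Expression values with masked cells set to NA
#' @param x An `expr_matrix`.
#' @return Numeric matrix.
#' @export
expr_values <- function(x) {
  v <- x$values
  v[x$mask] <- NA_real_
  v
}

#' Subset an expression matrix by transcripts and/or samples
#'
#' Keeps the class and mask without re-running raw-scale validation, so it
#' also works on transformed (log-scale) matrices.
#'
#' @param expr An [expr_matrix()].
#' @param transcripts Optional transcript ids or indices.
#' @param samples Optional sample ids or indices.
#' @return An [expr_matrix()].
#' @export
subset_expr <- function(expr, transcripts = NULL, samples = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  ti <- transcripts %||% seq_len(nrow(expr$values))
  si <- samples %||% seq_len(ncol(expr$values))
  if (is.character(si)) si <- match(si, expr$samples$sample)
  out <- list(values = expr$values[ti, si, drop = FALSE],
              samples = expr$samples[si, ],
              mask = expr$mask[ti, si, drop = FALSE])
  structure(out, class = "expr_matrix")
}

validate_annotation <- function(annotation) {
  annotation <- tibble::as_tibble(annotation)
  need <- c("transcript", "gene", "chrom", "tss_bp", "strand")
  if (!all(need %in% names(annotation))) {
    abort("annotation needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(annotation$transcript)) abort("duplicate transcript ids in annotation.")
  if (any(annotation$tss_bp < 1)) abort("tss_bp must be >= 1.")
  if (!all(annotation$strand %in% c("+", "-"))) abort("strand must be '+' or '-'.")
  annotation
}

validate_masks <- function(masks) {
  masks <- tibble::as_tibble(masks)
  need <- c("strain", "chrom", "start", "end")
  if (!all(need %in% names(masks))) {
    abort("masks need columns: ", paste(need, collapse = ", "))
  }
  if (any(masks$end < masks$start)) abort("mask intervals must have end >= start.")
  # normalize: sort and merge overlapping intervals per strain/chrom
  masks |>
    dplyr::arrange(.data$strain, .data$chrom, .data$start) |>
    dplyr::group_by(.data$strain, .data$chrom) |>
    dplyr::mutate(.grp = cumsum(.data$start > dplyr::lag(cummax(.data$end), default = -1L))) |>
    dplyr::group_by(.data$strain, .data$chrom, .data$.grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    dplyr::select("strain", "chrom", "start", "end")
}
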