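#' Filter markers on missingness and minor allele frequency
#'
#' Removes markers with *any* missing dosage, then markers with minor allele
#' frequency strictly below `maf_min` (MAF exactly at the cutoff is kept).
#'
#' @param G A [geno_matrix()].
#' @param maf_min MAF cutoff (default 0.05).
#' @return A filtered [geno_matrix()].
#' @export
filter_markers <- function(G, maf_min = 0.05) {
  d <- G$dosage
  complete <- colSums(is.na(d)) == 0
  p <- colMeans(d)
  maf <- pmin(p, 1 - p)
  keep <- complete & !is.na(maf) & maf >= maf_min
  if (!any(keep)) abort("all markers removed by the missingness/MAF filter.")
  subset_geno(G, marker_ids = which(keep))
}

marker_maf <- function(d) {
  p <- colMeans(d)
  pmin(p, 1 - p)
}

#' Windowed LD pruning
#'
#' Greedy pruning in the style of PLINK's `--indep-pairwise`: slide a
#' `window`-marker window along each chromosome in steps of `step`; within a
#' window, while any surviving pair has squared Pearson correlation above
#' `r2_max`, remove one member of the worst pair (the lower-MAF marker; on a
#' tie the one later in map order).
#'
#' @param G A filtered [geno_matrix()] (no missing dosages).
#' @param window Window size in markers (default 50).
#' @param step Slide in markers (default 10).
#' @param r2_max Pairwise r^2 ceiling (default 0.8).
#' @return A pruned [geno_matrix()].
#' @export
ld_prune <- function(G, window = 50, step = 10, r2_max = 0.8) {
  d <- G$dosage
  if (anyNA(d)) abort("ld_prune requires complete dosages; run filter_markers() first.")
  maf <- marker_maf(d)
  keep <- rep(TRUE, ncol(d))
  # passes repeat until a fixed point so that windows over the *surviving*
  # marker list contain no violating pair
  repeat {
    removed_any <- FALSE
    for (chrom in unique(G$map$chrom)) {
      cidx <- which(G$map$chrom == chrom & keep)
      if (length(cidx) < 2) next
      starts <- seq(1, max(length(cidx) - 1, 1), by = step)
      for (st in starts) {
        widx <- cidx[st:min(st + window - 1, length(cidx))]
        widx <- widx[keep[widx]]
        widx <- widx[apply(d[, widx, drop = FALSE], 2, sd) > 0]
        while (length(widx) >= 2) {
          r2 <- cor(d[, widx, drop = FALSE])^2
          diag(r2) <- 0
          if (max(r2) <= r2_max) break
          worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          pair <- widx[worst]
          drop_marker <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
            else if (maf[pair[2]] < maf[pair[1]]) pair[2]
            else max(pair)
          keep[drop_marker] <- FALSE
          removed_any <- TRUE
          widx <- setdiff(widx, drop_marker)
        }
      }
    }
    if (!removed_any) break
  }
  subset_geno(G, marker_ids = which(keep))
}

#' Kinship matrix from centered dosages
#'
#' `K = M M' / sum_j p_j (1 - p_j)` with `M` the column-centered dosage
#' matrix and `p_j` the allele frequency of marker `j`. Symmetric and
#' positive semi-definite by construction.
#'
#' @param G A pruned [geno_matrix()] without missing dosages.
#' @return A symmetric strains x strains matrix with strain dimnames.
#' @export
kinship <- function(G) {
  d <- if (inherits(G, "geno_matrix")) G$dosage else as.matrix(G)
  if (anyNA(d)) abort("kinship requires complete dosages.")
  p <- colMeans(d)
  denom <- sum(p * (1 - p))
  if (denom <= 0) abort("degenerate input: all markers monomorphic.")
  M <- sweep(d, 2, p)
  K <- tcrossprod(M) / denom
  dimnames(K) <- list(rownames(d), rownames(d))
  K
}

#' Pairwise Euclidean distance matrix
#' @param X Numeric matrix, units (strains/samples) in rows.
#' @return Symmetric distance matrix with dimnames from `rownames(X)`.
#' @export
distance_matrix <- function(X) {
  if (anyNA(X)) abort("distance_matrix requires complete data.")
  as.matrix(dist(X))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration via [ape::nj()]; negative branch
#' lengths are clipped at zero.
#'
#' @param D Symmetric distance matrix with zero diagonal and >= 3 taxa.
#' @return An unrooted `phylo` object.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) abort("neighbor joining needs at least 3 taxa.")
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12)) {
    abort("D must be symmetric with zero diagonal.")
  }
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Consolidate common divergent regions across strains
#'
#' Splits the genome into `bin_bp` bins; a bin is common-divergent iff the
#' fraction of strains whose mask overlaps it (by >= 1 bp) is at least
#' `frac`. Adjacent qualifying bins are merged.
#'
#' @param masks Tibble (strain, chrom, start, end), 0-based half-open.
#' @param n_strains Denominator for the strain fraction; defaults to the
#'   number of distinct strains present in `masks`.
#' @param bin_bp Bin width (default 1000).
#' @param frac Commonness cutoff (default 0.05, `>=`).
#' @param genome Optional tibble (chrom, length) fixing the binned extent;
#'   defaults to the maximal mask end per chromosome.
#' @return Tibble (chrom, start, end) of merged common-divergent intervals,
#'   0-based half-open.
#' @export
consolidate_common_divergent <- function(masks, n_strains = NULL,
                                         bin_bp = 1000, frac = 0.05,
                                         genome = NULL) {
  empty <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  if (is.null(masks) || nrow(masks) == 0) return(empty)
  n_strains <- n_strains %||% length(unique(masks$strain))
  if (is.null(genome)) {
    genome <- masks |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(length = max(.data$end), .groups = "drop")
  }
  out <- list()
  for (i in seq_len(nrow(genome))) {
    chrom <- genome$chrom[i]
    n_bins <- ceiling(genome$length[i] / bin_bp)
    if (n_bins < 1) next
    cover <- numeric(n_bins)
    ms <- masks[masks$chrom == chrom, ]
    for (s in unique(ms$strain)) {
      hit <- rep(FALSE, n_bins)
      rows <- ms[ms$strain == s, ]
      for (j in seq_len(nrow(rows))) {
        b1 <- floor(rows$start[j] / bin_bp) + 1
        b2 <- ceiling(rows$end[j] / bin_bp)
        if (b2 >= b1) hit[b1:min(b2, n_bins)] <- TRUE
      }
      cover <- cover + hit
    }
    common <- cover / n_strains >= frac
    if (!any(common)) next
    r <- rle(common)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1
    qual <- which(r$values)
    out[[chrom]] <- tibble::tibble(
      chrom = chrom,
      start = (starts[qual] - 1) * bin_bp,
      end = pmin(stops[qual] * bin_bp, genome$length[i])
    )
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}

in_intervals <- function(chrom, bp, intervals) {
  # bp 1-based, intervals 0-based half-open
  if (is.null(intervals) || nrow(intervals) == 0) return(rep(FALSE, length(bp)))
  vapply(seq_along(bp), function(i) {
    any(intervals$chrom == chrom[i] &
          intervals$start < bp[i] & bp[i] <= intervals$end)
  }, logical(1))
}
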