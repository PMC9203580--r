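#' Bin distant eQTL on the genetic map
#'
#' Distant eQTL whose peaks fall inside common hyper-divergent regions are
#' excluded; the remaining peaks are assigned to half-open `bin_cM` bins per
#' chromosome (anchored at each chromosome's minimum cM), with zero-count
#' bins kept across the covered range. Peaks without a genetic-map position
#' (e.g. mitochondrial markers) are dropped.
#'
#' @param eqtl Classified QTL table (needs `classification == "distant"`,
#'   `peak_marker`, `chrom`, `peak_bp`, `trait`).
#' @param marker_map Tibble (marker, chrom, bp, cM).
#' @param common_divergent Tibble (chrom, start, end) or `NULL`.
#' @param bin_cM Bin width in cM (default 0.5).
#' @return Tibble of bins: chrom, cm_start, cm_end, count, transcripts
#'   (list-column of member trait ids). Empty if there are no distant eQTL.
#' @export
bin_distant_eqtl <- function(eqtl, marker_map, common_divergent = NULL,
                             bin_cM = 0.5) {
  empty <- tibble::tibble(chrom = character(), cm_start = numeric(),
                          cm_end = numeric(), count = integer(),
                          transcripts = list())
  d <- eqtl[eqtl$classification == "distant", , drop = FALSE]
  if (nrow(d) == 0) return(empty)
  d <- d[!in_intervals(d$chrom, d$peak_bp, common_divergent), , drop = FALSE]
  i <- match(d$peak_marker, marker_map$marker)
  d$cM <- marker_map$cM[i]
  d <- d[!is.na(d$cM), , drop = FALSE]
  if (nrow(d) == 0) return(empty)
  out <- list()
  for (chrom in unique(marker_map$chrom[!is.na(marker_map$cM)])) {
    cm <- marker_map$cM[marker_map$chrom == chrom]
    cm <- cm[!is.na(cm)]
    if (length(cm) == 0) next
    lo <- min(cm)
    n_bins <- max(ceiling((max(cm) - lo) / bin_cM), 1)
    starts <- lo + bin_cM * (seq_len(n_bins) - 1)
    dc <- d[d$chrom == chrom, ]
    bin_of <- pmin(floor((dc$cM - lo) / bin_cM) + 1, n_bins)
    members <- lapply(seq_len(n_bins), function(b) dc$trait[bin_of == b])
    out[[chrom]] <- tibble::tibble(
      chrom = chrom, cm_start = starts, cm_end = starts + bin_cM,
      count = lengths(members), transcripts = members)
  }
  dplyr::bind_rows(out)
}

#' Detect distant-eQTL hotspots by Poisson exceedance
#'
#' The Poisson rate is the maximum-likelihood estimate (the mean count over
#' all bins, empty ones included); `q99` is the smallest integer `k` with
#' `P(X <= k) >= 0.99`. A bin qualifies iff its count is strictly greater
#' than `q99`; runs of adjacent qualifying bins on one chromosome merge into
#' a single hotspot.
#'
#' @param bins Output of [bin_distant_eqtl()].
#' @param prob Quantile for the exceedance rule (default 0.99).
#' @return A list of class `hotspot_model`: `lambda_hat`, `q99`, `bins`,
#'   `hotspots` (tibble: chrom, cm_start, cm_end, n_bins, count,
#'   transcripts).
#' @export
detect_hotspots <- function(bins, prob = 0.99) {
  if (nrow(bins) == 0) {
    return(structure(list(lambda_hat = NA_real_, q99 = NA_integer_,
                          bins = bins, hotspots = bins[0, ]),
                     class = "hotspot_model"))
  }
  lambda <- mean(bins$count)
  q99 <- qpois(prob, lambda)
  bins$hotspot <- bins$count > q99
  hs <- list()
  for (chrom in unique(bins$chrom)) {
    b <- bins[bins$chrom == chrom, ]
    b <- b[order(b$cm_start), ]
    r <- rle(b$hotspot)
    stops <- cumsum(r$lengths); starts <- stops - r$lengths + 1
    for (k in which(r$values)) {
      rows <- b[starts[k]:stops[k], ]
      hs[[length(hs) + 1]] <- tibble::tibble(
        chrom = chrom, cm_start = min(rows$cm_start),
        cm_end = max(rows$cm_end), n_bins = nrow(rows),
        count = sum(rows$count),
        transcripts = list(unlist(rows$transcripts)))
    }
  }
  hotspots <- if (length(hs) > 0) dplyr::bind_rows(hs) else
    tibble::tibble(chrom = character(), cm_start = numeric(),
                   cm_end = numeric(), n_bins = integer(), count = integer(),
                   transcripts = list())
  structure(list(lambda_hat = lambda, q99 = q99, bins = bins,
                 hotspots = hotspots),
            class = "hotspot_model")
}

#' @export
print.hotspot_model <- function(x, ...) {
  cat("<hotspot_model> lambda =", round(x$lambda_hat, 3), "q99 =", x$q99,
      "->", nrow(x$hotspots), "hotspot(s) over", nrow(x$bins), "bins\n")
  invisible(x)
}
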