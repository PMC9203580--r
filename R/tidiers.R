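#' Tidy a REML variance-component fit
#' @param x A `reml_fit` from [reml_null()].
#' @param ... Unused.
#' @return Tibble (term, estimate).
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble::tibble(term = c("sigma_g2", "sigma_e2", "delta"),
                 estimate = c(x$sigma_g2, x$sigma_e2, x$delta))
}

#' One-row summary of a REML fit
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @return Tibble (h2, loglik, n, boundary).
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, loglik = x$loglik, n = x$n, boundary = x$boundary)
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit> sigma_g2 =", signif(x$sigma_g2, 4),
      " sigma_e2 =", signif(x$sigma_e2, 4),
      " h2 =", round(x$h2, 3), " (n =", x$n, ")\n")
  invisible(x)
}

#' Tidy a hotspot model (one row per hotspot)
#' @param x A `hotspot_model` from [detect_hotspots()].
#' @param ... Unused.
#' @return Tibble of hotspots with member transcript counts.
#' @export
tidy.hotspot_model <- function(x, ...) {
  hs <- x$hotspots
  hs$n_transcripts <- lengths(hs$transcripts)
  hs[, c("chrom", "cm_start", "cm_end", "n_bins", "count", "n_transcripts")]
}

#' One-row summary of a hotspot model
#' @param x A `hotspot_model`.
#' @param ... Unused.
#' @return Tibble (lambda_hat, q99, n_bins, n_hotspots).
#' @export
glance.hotspot_model <- function(x, ...) {
  tibble::tibble(lambda_hat = x$lambda_hat, q99 = x$q99,
                 n_bins = nrow(x$bins), n_hotspots = nrow(x$hotspots))
}

#' Tidy a permutation-FDR calibration (the pooled peak significances)
#' @param x A `perm_fdr` from [permutation_fdr()].
#' @param ... Unused.
#' @return Tibble (neglog10p) of pooled permutation QTL peaks.
#' @export
tidy.perm_fdr <- function(x, ...) tibble::tibble(neglog10p = x$pool)

#' One-row summary of a permutation-FDR calibration
#' @param x A `perm_fdr`.
#' @param ... Unused.
#' @return Tibble (cutoff, raw_threshold, n_qtl, mode).
#' @export
glance.perm_fdr <- function(x, ...) {
  tibble::tibble(cutoff = x$cutoff, raw_threshold = x$raw_threshold,
                 n_qtl = x$n_qtl, mode = x$mode)
}

#' Manhattan plot of an association scan
#' @param object An `eqtl_scan` from [gls_scan()].
#' @param threshold Optional horizontal significance line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eqtl_scan <- function(object, threshold = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bp / 1e6, y = .data$neglog10p)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)),
                  title = attr(object, "trait")) +
    ggplot2::theme_bw()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' eQTL map: peak position against transcript position
#'
#' The classic diagonal map: local eQTL sit on the diagonal, distant eQTL
#' off it.
#'
#' @param eqtl Classified eQTL table.
#' @param annotation Transcript annotation.
#' @return A ggplot.
#' @export
plot_eqtl_map <- function(eqtl, annotation) {
  annotation <- validate_annotation(annotation)
  i <- match(eqtl$trait, annotation$transcript)
  df <- dplyr::mutate(eqtl,
                      tss_chrom = annotation$chrom[i],
                      tss_bp = annotation$tss_bp[i])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$peak_bp / 1e6,
                                   y = .data$tss_bp / 1e6,
                                   colour = .data$classification)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.8) +
    ggplot2::facet_grid(tss_chrom ~ chrom, scales = "free", space = "free") +
    ggplot2::scale_colour_manual(values = c(local = "goldenrod2",
                                            distant = "purple3",
                                            unclassified = "grey60")) +
    ggplot2::labs(x = "eQTL peak (Mb)", y = "transcript TSS (Mb)") +
    ggplot2::theme_bw()
}

#' Hotspot bin counts along the genetic map
#' @param x A `hotspot_model`.
#' @return A ggplot.
#' @export
plot_hotspots <- function(x) {
  stopifnot(inherits(x, "hotspot_model"))
  bins <- dplyr::mutate(x$bins,
                        status = ifelse(.data$count > x$q99, "hotspot", "background"))
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$cm_start, y = .data$count,
                                     fill = .data$status)) +
    ggplot2::geom_col(width = diff(range(bins$cm_start)) / nrow(bins)) +
    ggplot2::geom_hline(yintercept = x$q99 + 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(hotspot = "red3",
                                          background = "grey65")) +
    ggplot2::labs(x = "genetic position (cM)", y = "distant eQTL per bin") +
    ggplot2::theme_bw()
}

#' Mediation estimates with the significance quantile line
#' @param results Output of [med_test()], optionally after
#'   [call_significant()].
#' @param pct Quantile line (default 0.99).
#' @return A ggplot.
#' @export
plot_mediation <- function(results, pct = 0.99) {
  p99 <- as.numeric(quantile(results$estimate, pct, type = 7))
  df <- dplyr::mutate(results, idx = dplyr::row_number())
  if (!"significant" %in% names(df)) df$significant <- FALSE
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$estimate,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = p99, colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red3", `FALSE` = "grey60")) +
    ggplot2::labs(x = "mediator", y = "mediation estimate |a b|") +
    ggplot2::theme_bw()
}
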