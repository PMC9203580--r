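#' Narrow-sense heritability from kinship REML
#'
#' `h2 = sigma_g2 / (sigma_g2 + sigma_e2)` from the null mixed-model fit of
#' the strain-mean trait under the kinship covariance.
#'
#' @param y Named strain-level trait vector.
#' @param K Kinship matrix or [kinship_eigen()].
#' @param ... Passed to [reml_null()].
#' @return h2 in `[0, 1]`.
#' @export
narrow_h2 <- function(y, K, ...) {
  reml_null(y, K, ...)$h2
}

#' Broad-sense heritability from replicate variance
#'
#' Fits the one-way random-intercept model `value ~ 1 + (1 | strain)` by
#' REML (unbalanced designs handled by lme4) and returns the strain-level
#' variance fraction `H2 = sigma_strain^2 / (sigma_strain^2 + sigma_resid^2)`.
#'
#' @param y Replicate-level trait values.
#' @param strain Strain label per replicate (same length as `y`).
#' @return H2 in `[0, 1]`.
#' @export
broad_H2 <- function(y, strain) {
  ok <- is.finite(y)
  y <- y[ok]; strain <- strain[ok]
  if (length(unique(strain)) < 2 || !any(duplicated(strain))) {
    abort("broad_H2 needs >= 2 strains and replicated measurements.")
  }
  if (sd(y) == 0) abort("degenerate input: all replicate values identical.")
  fit <- suppressMessages(lme4::lmer(y ~ 1 + (1 | strain),
                                     data = data.frame(y = y, strain = strain),
                                     REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vs <- vc$vcov[vc$grp == "strain"]
  ve <- vc$vcov[vc$grp == "Residual"]
  vs / (vs + ve)
}

#' Heritability table for an expression study
#'
#' Broad-sense H2 from replicate-level expression and narrow-sense h2 from
#' strain means under the kinship, per transcript.
#'
#' @param expr Replicate-level [expr_matrix()] on the transformed scale.
#' @param traits Strain-mean matrix (transcripts x strains) for the same
#'   transcripts.
#' @param K Kinship matrix.
#' @return Tibble (trait, H2, h2); traits where a fit fails get NA.
#' @export
heritability_table <- function(expr, traits, K) {
  keig <- kinship_eigen(K)
  v <- expr_values(expr)
  strain <- expr$samples$strain
  tx <- intersect(rownames(v), rownames(traits))
  out <- purrr::map(tx, function(t) {
    H2 <- tryCatch(broad_H2(v[t, ], strain), error = function(e) NA_real_)
    y <- traits[t, ]
    names(y) <- colnames(traits)
    h2 <- if (anyNA(y)) {
      ok <- names(y)[is.finite(y)]
      tryCatch(narrow_h2(y[ok], K[ok, ok]), error = function(e) NA_real_)
    } else {
      tryCatch(narrow_h2(y, keig), error = function(e) NA_real_)
    }
    tibble::tibble(trait = t, H2 = H2, h2 = h2)
  })
  dplyr::bind_rows(out)
}
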