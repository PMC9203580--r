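#' Assemble exposure/mediator/outcome triples for mediation analysis
#'
#' Mediator candidates are transcripts whose eQTL interval overlaps the
#' organism-level QTL interval (closed intervals, 1 bp of overlap counts).
#' Strains are restricted to those with non-missing exposure genotype and
#' outcome; mediators whose remaining expression is constant are dropped.
#'
#' @param organism_qtl One QTL record (tibble row) for the organism trait,
#'   with `chrom`, `peak_marker`, `interval_left_bp`, `interval_right_bp`.
#' @param eqtl_table Classified eQTL table with intervals.
#' @param expr_means Transcripts x strains strain-mean expression matrix.
#' @param G A [geno_matrix()] containing the organism QTL peak marker.
#' @param phenotype Tibble (strain, value).
#' @return A list with `X` (named exposure dosage), `M` (strains x mediators
#'   matrix, NA where masked), `Y` (named outcome), `candidates` (the
#'   overlapping eQTL rows kept), `dropped` (mediators removed for zero
#'   variation).
#' @export
assemble_triples <- function(organism_qtl, eqtl_table, expr_means, G,
                             phenotype) {
  stopifnot(nrow(organism_qtl) == 1)
  ov <- eqtl_table$chrom == organism_qtl$chrom &
    eqtl_table$interval_left_bp <= organism_qtl$interval_right_bp &
    eqtl_table$interval_right_bp >= organism_qtl$interval_left_bp
  cand <- eqtl_table[ov & eqtl_table$trait %in% rownames(expr_means), ]
  if (nrow(cand) == 0) return(list(X = NULL, M = NULL, Y = NULL,
                                   candidates = cand, dropped = character()))
  strains_use <- Reduce(intersect, list(
    rownames(G$dosage), colnames(expr_means), phenotype$strain))
  X <- G$dosage[strains_use, organism_qtl$peak_marker]
  Y <- setNames(phenotype$value[match(strains_use, phenotype$strain)], strains_use)
  ok <- is.finite(X) & is.finite(Y)
  X <- X[ok]; Y <- Y[ok]
  M <- t(expr_means[cand$trait, names(X), drop = FALSE])
  keep <- apply(M, 2, function(m) {
    use <- is.finite(m)
    sum(use) >= 3 && sd(m[use]) > 0 && sd(X[use]) > 0 && sd(Y[use]) > 0
  })
  dropped <- colnames(M)[!keep]
  M <- M[, keep, drop = FALSE]
  list(X = X, M = M, Y = Y, candidates = cand[keep, ], dropped = dropped)
}

std <- function(v) (v - mean(v)) / sd(v)

# |a*b| on standardized variables from the pairwise correlations:
# a = r_XM; b = (r_MY - r_XY r_XM) / (1 - r_XM^2).
med_stat <- function(r_xm, r_my, r_xy, collinear_tol = 1e-10) {
  collinear <- abs(r_xm) >= 1 - collinear_tol
  b <- ifelse(collinear, r_my, (r_my - r_xy * r_xm) / (1 - r_xm^2))
  list(S = abs(r_xm * b), collinear = collinear)
}

#' Permutation mediation test over multiple mediators
#'
#' Per mediator, the mediation estimate is `S = |a * b|` on standardized
#' variables, with `a` the slope of `M ~ X` and `b` the slope of `M` in
#' `Y ~ X + M`. Family-wise adjusted p-values come from jointly permuting the
#' strain labels of the mediator matrix (the X-Y pairing is preserved, so the
#' null is "no mediation"): `p_adj_i = (1 + #{perm : max_j S*_j >= S_i}) /
#' (n_perm + 1)`. Mediators exactly collinear with the exposure are flagged
#' and scored through the degenerate path `b = r_MY`.
#'
#' @param X Named exposure dosage vector.
#' @param M Strains x mediators matrix (NA allowed per mediator).
#' @param Y Named outcome vector aligned with `X`.
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param seed Integer seed.
#' @return Tibble (mediator, estimate, p_adj, collinear, n_used).
#' @export
med_test <- function(X, M, Y, n_perm = 1000, seed = 1L) {
  if (n_perm < 100) warn("med_test: fewer than 100 permutations.")
  if (is.null(dim(M))) M <- matrix(M, ncol = 1, dimnames = list(names(X), "M1"))
  stopifnot(length(X) == nrow(M), length(Y) == nrow(M))
  set.seed(seed)
  n <- length(X)
  m <- ncol(M)
  complete <- !anyNA(M)
  stat_all <- function(Mmat) {
    if (complete) {
      Zx <- std(X); Zy <- std(Y)
      Zm <- scale(Mmat)
      r_xm <- as.numeric(crossprod(Zx, Zm)) / (n - 1)
      r_my <- as.numeric(crossprod(Zy, Zm)) / (n - 1)
      r_xy <- sum(Zx * Zy) / (n - 1)
      med_stat(r_xm, r_my, rep(r_xy, m))
    } else {
      r_xm <- numeric(m); r_my <- numeric(m); r_xy <- numeric(m)
      for (j in seq_len(m)) {
        use <- is.finite(Mmat[, j])
        r_xm[j] <- cor(X[use], Mmat[use, j])
        r_my[j] <- cor(Y[use], Mmat[use, j])
        r_xy[j] <- cor(X[use], Y[use])
      }
      med_stat(r_xm, r_my, r_xy)
    }
  }
  obs <- stat_all(M)
  n_used <- if (complete) rep(n, m) else colSums(is.finite(M))
  max_perm <- vapply(seq_len(n_perm), function(p) {
    max(stat_all(M[sample(n), , drop = FALSE])$S, na.rm = TRUE)
  }, numeric(1))
  p_adj <- vapply(obs$S, function(s) (1 + sum(max_perm >= s)) / (n_perm + 1),
                  numeric(1))
  tibble::tibble(mediator = colnames(M), estimate = obs$S, p_adj = p_adj,
                 collinear = obs$collinear, n_used = n_used)
}

#' Total, direct and indirect effect of an exposure through one mediator
#'
#' Difference method on linear least squares: total effect `c` from
#' `Y ~ X`, direct effect `c'` from `Y ~ X + M`, indirect `c - c'`,
#' proportion mediated `indirect / total`. For linear fits on the same
#' sample the difference equals the product `a * b` identically. The
#' proportion is interpretable iff it lies in `[0, 1]`.
#'
#' @param X,M,Y Aligned numeric vectors (rows with any NA are dropped).
#' @return One-row tibble: total, direct, indirect, proportion,
#'   interpretable, n_used.
#' @export
estimate_proportion <- function(X, M, Y) {
  use <- is.finite(X) & is.finite(M) & is.finite(Y)
  X <- X[use]; M <- M[use]; Y <- Y[use]
  if (sd(X) == 0 || sd(M) == 0 || sd(Y) == 0) {
    abort("estimate_proportion needs nonzero variance in X, M and Y.")
  }
  total <- coef(lm(Y ~ X))[["X"]]
  fit2 <- lm(Y ~ X + M)
  direct <- coef(fit2)[["X"]]
  indirect <- total - direct
  if (abs(total) < 1e-12) {
    proportion <- NA_real_; interpretable <- FALSE
  } else {
    proportion <- indirect / total
    interpretable <- proportion >= 0 && proportion <= 1
  }
  tibble::tibble(total = total, direct = direct, indirect = indirect,
                 proportion = proportion, interpretable = interpretable,
                 n_used = length(X))
}

#' Flag significant mediators
#'
#' Significant iff the adjusted p-value is below `alpha` OR the mediation
#' estimate strictly exceeds the `pct` quantile of all estimates in the
#' analysis. Where an `interpretable` column is present the final reported
#' flag additionally requires it.
#'
#' @param results Tibble from [med_test()] (optionally joined with
#'   [estimate_proportion()] columns).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param pct Estimate quantile (default 0.99, type-7).
#' @return `results` with `significant` (and `reported` when interpretable
#'   is available).
#' @export
call_significant <- function(results, alpha = 0.05, pct = 0.99) {
  if (nrow(results) == 0) abort("no mediation results to flag.")
  p99 <- as.numeric(quantile(results$estimate, pct, type = 7))
  results$significant <- results$p_adj < alpha | results$estimate > p99
  if ("interpretable" %in% names(results)) {
    results$reported <- results$significant & results$interpretable
  }
  results
}

#' Pseudo variant marker for a gene with allelic heterogeneity
#'
#' Collapses heterogeneous variants in one gene into a single presence
#' genotype: dosage 1 iff the strain carries at least one qualifying variant.
#'
#' @param variant_table Tibble with columns `gene`, `variant`, `strain`
#'   (one row per carrier strain per variant).
#' @param gene_id Gene to collapse.
#' @param strain_ids Strains of the output vector (in order).
#' @return Named 0/1 dosage vector; all-zero vectors carry
#'   `attr(, "monomorphic") = TRUE`.
#' @export
make_pseudo_marker <- function(variant_table, gene_id, strain_ids) {
  rows <- variant_table[variant_table$gene == gene_id, , drop = FALSE]
  if (nrow(rows) == 0) abort("gene ", gene_id, " absent from the variant table.")
  x <- as.numeric(strain_ids %in% rows$strain)
  names(x) <- strain_ids
  attr(x, "monomorphic") <- length(unique(x)) < 2
  x
}

#' Significance-drop scan: re-test a trait after regressing out expression
#'
#' For each transcript, the outcome is residualized on that transcript's
#' expression (ordinary least squares) and the residual trait is re-tested at
#' the pseudo marker with the kinship mixed model. A transcript that mediates
#' the genotype-phenotype path removes the association, so its regression
#' shows a large drop from the unregressed baseline.
#'
#' @param Y Named strain-level outcome.
#' @param expr_means Transcripts x strains expression matrix.
#' @param pseudo_marker Named dosage vector (e.g. [make_pseudo_marker()]).
#' @param K Kinship matrix.
#' @return Tibble (transcript, neglog10p, n_used) with the unregressed
#'   baseline in `attr(, "baseline")`. Constant-expression transcripts are
#'   skipped.
#' @export
regression_drop_scan <- function(Y, expr_means, pseudo_marker, K) {
  strains_use <- Reduce(intersect, list(names(Y), colnames(expr_means),
                                        names(pseudo_marker), rownames(K)))
  Y <- Y[strains_use]
  x <- pseudo_marker[strains_use]
  Km <- K[strains_use, strains_use]
  keig <- kinship_eigen(Km)
  Gx <- matrix(x, ncol = 1, dimnames = list(strains_use, "pseudo"))
  test_at_marker <- function(yv, ids) {
    if (length(ids) < length(strains_use)) {
      vc <- reml_null(yv, Km[ids, ids])
      gls_scan(yv, Gx[ids, , drop = FALSE], Km[ids, ids], vc = vc)$neglog10p
    } else {
      vc <- reml_null(yv, keig)
      gls_scan(yv, Gx, keig, vc = vc)$neglog10p
    }
  }
  baseline <- test_at_marker(Y, strains_use)
  out <- purrr::map(rownames(expr_means), function(t) {
    mvec <- expr_means[t, strains_use]
    use <- is.finite(mvec) & is.finite(Y)
    if (sum(use) < 30 || sd(mvec[use]) == 0) return(NULL)
    resid_y <- setNames(residuals(lm(Y[use] ~ mvec[use])), strains_use[use])
    p <- tryCatch(test_at_marker(resid_y, strains_use[use]),
                  error = function(e) NA_real_)
    tibble::tibble(transcript = t, neglog10p = p, n_used = sum(use))
  })
  res <- dplyr::bind_rows(out)
  attr(res, "baseline") <- baseline
  res
}
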