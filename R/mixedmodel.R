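#' Precompute the eigendecomposition of a kinship matrix
#'
#' The REML fit and the association scan both work in the eigenbasis of K;
#' computing it once and reusing it across traits/permutations is the main
#' speed lever of the population-parameters-previously-determined (P3D)
#' scheme.
#'
#' @param K Symmetric positive semi-definite kinship matrix with strain
#'   dimnames.
#' @return An object of class `kinship_eigen` with elements `U` (vectors),
#'   `lambda` (values, clipped at 0) and `strains`.
#' @export
kinship_eigen <- function(K) {
  if (inherits(K, "kinship_eigen")) return(K)
  if (max(abs(K - t(K))) > 1e-10) abort("K must be symmetric.")
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values))) {
    abort("K is not positive semi-definite within tolerance.")
  }
  structure(list(U = e$vectors, lambda = pmax(e$values, 0),
                 strains = rownames(K)), class = "kinship_eigen")
}

subset_keig <- function(keig, strain_ids) {
  if (identical(keig$strains, strain_ids)) return(keig)
  abort("internal: kinship eigen does not match the strain subset.")
}

#' REML variance components under a kinship covariance
#'
#' Fits the null model `y = mu + g + e` with `g ~ (0, sigma_g2 K)` and
#' `e ~ (0, sigma_e2 I)` by restricted maximum likelihood. The profile
#' restricted likelihood is maximized over `delta = sigma_e2 / sigma_g2` on a
#' 100-point log grid spanning `[1e-5, 1e5]`, followed by local refinement.
#' Exact likelihood ties along the grid (as arise when `K = I`, where the
#' profile is flat) resolve to the largest `delta`, i.e. toward zero genetic
#' variance.
#'
#' @param y Named numeric vector of strain-level trait values; strains with
#'   non-finite values are dropped (at least 30 must remain by default).
#' @param K Kinship matrix or a [kinship_eigen()] restricted to the strains
#'   of `y`.
#' @param min_strains Minimum strains with finite trait values (default 30).
#' @param grid_n Number of grid points for the delta search (default 100).
#' @return An object of class `reml_fit`: `sigma_g2`, `sigma_e2`, `delta`,
#'   `h2`, `loglik` (restricted), `n`, `boundary` flag, and the eigen pieces
#'   used (for reuse by [gls_scan()]).
#' @export
reml_null <- function(y, K, min_strains = 30, grid_n = 100) {
  if (is.null(names(y))) {
    if (inherits(K, "kinship_eigen")) names(y) <- K$strains else names(y) <- rownames(K)
  }
  ok <- is.finite(y)
  if (sum(ok) < min_strains) abort("need >= ", min_strains, " strains with finite trait values.")
  if (!all(ok)) {
    if (inherits(K, "kinship_eigen")) abort("pass K as a matrix when y has missing values.")
    K <- K[names(y)[ok], names(y)[ok]]
    y <- y[ok]
  }
  if (sd(y) == 0) abort("degenerate input: trait has zero variance.")
  keig <- kinship_eigen(K)
  if (!is.null(keig$strains) && !identical(keig$strains, names(y))) {
    y <- y[keig$strains]
    if (anyNA(y)) abort("strains of y and K do not match.")
  }
  n <- length(y)
  yt <- crossprod(keig$U, y)[, 1]
  xt <- crossprod(keig$U, rep(1, n))[, 1]
  lambda <- keig$lambda

  ll_reml <- function(log10_delta) {
    delta <- 10^log10_delta
    w <- 1 / (lambda + delta)
    xx <- sum(xt^2 * w)
    beta <- sum(xt * yt * w) / xx
    r <- yt - xt * beta
    q <- sum(r^2 * w)
    sg2 <- q / (n - 1)
    -0.5 * ((n - 1) * (log(2 * pi * sg2) + 1) + sum(log(lambda + delta)) + log(xx))
  }
  grid <- seq(-5, 5, length.out = grid_n)
  ll <- vapply(grid, ll_reml, numeric(1))
  best_ll <- max(ll)
  # ties (within 1e-6) resolve to the largest delta
  idx <- max(which(ll >= best_ll - 1e-6))
  lo <- grid[max(idx - 1, 1)]
  hi <- grid[min(idx + 1, grid_n)]
  opt <- optimize(ll_reml, c(lo, hi), maximum = TRUE, tol = 1e-6)
  if (opt$objective > ll[idx] + 1e-9) {
    log10_delta <- opt$maximum; loglik <- opt$objective
  } else {
    log10_delta <- grid[idx]; loglik <- ll[idx]
  }
  boundary <- idx %in% c(1, grid_n)   # flagged, not warned: routine for null traits
  delta <- 10^log10_delta
  w <- 1 / (lambda + delta)
  xx <- sum(xt^2 * w)
  beta <- sum(xt * yt * w) / xx
  q <- sum((yt - xt * beta)^2 * w)
  sigma_g2 <- q / (n - 1)
  sigma_e2 <- delta * sigma_g2
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, delta = delta,
                 h2 = 1 / (1 + delta), loglik = loglik, n = n,
                 boundary = boundary, grid_loglik = ll, grid = grid,
                 keig = keig, strains = names(y)),
            class = "reml_fit")
}

#' Generalized least-squares association scan (P3D)
#'
#' With the null-model covariance `V = sigma_g2 K + sigma_e2 I` held fixed
#' across markers, each marker is tested by fitting `y = mu + x beta` via GLS
#' in the whitened basis and comparing against the intercept-only fit with an
#' F statistic on (1, n - 2) degrees of freedom. Monomorphic markers (in the
#' used strain subset) are recorded with p = 1 and flagged.
#'
#' @param y Named strain-level trait vector.
#' @param G A [geno_matrix()] or plain strains x markers dosage matrix
#'   aligned to the strains of `y`.
#' @param K Kinship matrix or [kinship_eigen()].
#' @param vc Optional `reml_fit` from [reml_null()] on the same strain set;
#'   computed if missing.
#' @param trait Trait id carried into the result.
#' @return A tibble of class `eqtl_scan`: marker, chrom, bp, beta,
#'   neglog10p, monomorphic; attributes `trait`, `n_used`, `vc`.
#' @export
gls_scan <- function(y, G, K, vc = NULL, trait = "trait") {
  is_gm <- inherits(G, "geno_matrix")
  d <- if (is_gm) G$dosage else as.matrix(G)
  if (is.null(vc)) vc <- reml_null(y, K)
  use <- vc$strains
  d <- d[use, , drop = FALSE]
  y <- y[use]
  keig <- vc$keig
  n <- length(y)
  w <- 1 / (vc$sigma_g2 * keig$lambda + vc$sigma_e2)
  sw <- sqrt(w)
  Ut <- t(keig$U)
  z <- sw * (Ut %*% y)[, 1]
  a <- sw * (Ut %*% rep(1, n))[, 1]
  B <- sw * (Ut %*% d)

  saa <- sum(a^2); saz <- sum(a * z); szz <- sum(z^2)
  sbb <- colSums(B^2)
  sab <- as.numeric(crossprod(a, B))
  sbz <- as.numeric(crossprod(z, B))
  det <- saa * sbb - sab^2
  mono <- apply(d, 2, function(col) length(unique(col)) < 2) | det <= 1e-12 * saa * pmax(sbb, 1e-300)
  det[mono] <- NA
  beta <- (saa * sbz - sab * saz) / det
  beta0 <- (sbb * saz - sab * sbz) / det
  rss1 <- szz - (beta0 * saz + beta * sbz)
  rss0 <- szz - saz^2 / saa
  Fstat <- pmax(rss0 - rss1, 0) / pmax(rss1 / (n - 2), 1e-300)
  p <- pf(Fstat, 1, n - 2, lower.tail = FALSE)
  p <- pmax(p, 1e-300)
  p[mono] <- 1
  beta[mono] <- NA_real_

  map <- if (is_gm) G$map else tibble::tibble(marker = colnames(d),
                                              chrom = NA_character_,
                                              bp = NA_integer_)
  out <- tibble::tibble(marker = map$marker, chrom = map$chrom, bp = map$bp,
                        beta = unname(beta), neglog10p = unname(-log10(p)),
                        monomorphic = unname(mono))
  attr(out, "trait") <- trait
  attr(out, "n_used") <- n
  attr(out, "vc") <- vc[c("sigma_g2", "sigma_e2", "delta", "h2")]
  class(out) <- c("eqtl_scan", class(out))
  out
}

#' Effective number of independent tests
#'
#' Eigenvalue-based estimate from the marker correlation spectrum: with
#' eigenvalues `lambda_i` of the marker correlation matrix (computed via the
#' strain-side Gram matrix of standardized dosages, which shares the nonzero
#' spectrum), `Meff = sum_i [ 1(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`.
#'
#' @param G A pruned [geno_matrix()] or dosage matrix; no monomorphic
#'   markers.
#' @return `Meff`, a real number >= 1.
#' @export
meff_li_ji <- function(G) {
  d <- if (inherits(G, "geno_matrix")) G$dosage else as.matrix(G)
  if (ncol(d) < 2) abort("need at least 2 markers.")
  sds <- apply(d, 2, sd)
  if (any(sds == 0)) abort("monomorphic markers present; filter first.")
  Z <- scale(d)
  n <- nrow(Z); m <- ncol(Z)
  gram <- if (n <= m) tcrossprod(Z) / (n - 1) else crossprod(Z) / (n - 1)
  lambda <- pmax(eigen(gram, symmetric = TRUE, only.values = TRUE)$values, 0)
  # round before flooring: an eigenvalue numerically at an integer (e.g. a
  # duplicated marker pair, lambda = 2 - eps) must not leak a spurious
  # fractional part
  lambda <- round(lambda, 8)
  min(sum(ifelse(lambda >= 1, 1, 0) + (lambda - floor(lambda))), m)
}

#' Significance thresholds from test counts
#'
#' `eigen_threshold = -log10(0.05 / n_test)` using the effective number of
#' independent tests and `bf_threshold = -log10(0.05 / m)` over all markers;
#' slots for the permutation-calibrated 5% FDR cutoffs can be filled from
#' [permutation_fdr()].
#'
#' @param n_test Effective number of tests (>= 1).
#' @param m Number of markers.
#' @param fdr5_eigen,fdr5_bf Optional permutation-calibrated cutoffs.
#' @param alpha Family-wise level (default 0.05).
#' @return A list of class `threshold_spec`.
#' @export
make_thresholds <- function(n_test, m, fdr5_eigen = NA_real_,
                            fdr5_bf = NA_real_, alpha = 0.05) {
  if (n_test < 1) abort("n_test must be >= 1.")
  if (n_test > m) warn("n_test exceeds the marker count; thresholds computed anyway.")
  structure(list(n_test = n_test, m = m,
                 eigen_threshold = -log10(alpha / n_test),
                 bf_threshold = -log10(alpha / m),
                 fdr5_eigen = fdr5_eigen, fdr5_bf = fdr5_bf),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat("<threshold_spec> Meff =", round(x$n_test, 1), "of", x$m, "markers;",
      "EIGEN =", round(x$eigen_threshold, 3), "BF =", round(x$bf_threshold, 3), "\n")
  if (is.finite(x$fdr5_eigen)) cat("  5% FDR (eigen):", round(x$fdr5_eigen, 3), "\n")
  if (is.finite(x$fdr5_bf)) cat("  5% FDR (bf):", round(x$fdr5_bf, 3), "\n")
  invisible(x)
}
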