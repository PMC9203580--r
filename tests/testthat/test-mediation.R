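test_that("triple assembly uses closed-interval overlap and variation filters", {
  G <- tiny_geno(n = 60, m = 10, seed = 70)
  ph <- tibble::tibble(strain = strains(G), value = rnorm(60))
  em <- matrix(rnorm(3 * 60), 3, 60,
               dimnames = list(c("t1", "t2", "t3"), strains(G)))
  em["t3", ] <- 5                      # constant mediator: dropped
  eqtl <- tibble::tibble(trait = c("t1", "t2", "t3"),
                         chrom = c("chr1", "chr1", "chr1"),
                         interval_left_bp = c(1e6, 3.5e6, 1e6),
                         interval_right_bp = c(2e6, 4e6, 2e6))
  oq <- tibble::tibble(chrom = "chr1", peak_marker = "mk0005",
                       interval_left_bp = 2e6, interval_right_bp = 3e6)
  tr <- assemble_triples(oq, eqtl, em, G, ph)
  # t1 overlaps at the 2 Mb boundary (closed intervals); t2 does not;
  # t3 overlaps but has no variation
  expect_equal(colnames(tr$M), "t1")
  expect_equal(tr$dropped, "t3")
  expect_equal(length(tr$X), 60)

  # no overlap at all: empty
  oq2 <- dplyr::mutate(oq, interval_left_bp = 8e6, interval_right_bp = 9e6)
  tr2 <- assemble_triples(oq2, eqtl, em, G, ph)
  expect_null(tr2$M)
})

test_that("an overlap fixture reproduces the count bookkeeping", {
  # 1193 overlapping candidate mediators of which 36 fail the variation
  # filter leaves 1157 analyses
  set.seed(71)
  n <- 40
  G <- tiny_geno(n = n, m = 5, seed = 71)
  ph <- tibble::tibble(strain = strains(G), value = rnorm(n))
  ids <- sprintf("tx%04d", 1:1193)
  em <- matrix(rnorm(1193 * n), 1193, n, dimnames = list(ids, strains(G)))
  em[sample(1193, 36), ] <- 0          # no variation
  eqtl <- tibble::tibble(trait = ids, chrom = "chr1",
                         interval_left_bp = 1e5, interval_right_bp = 2e5)
  oq <- tibble::tibble(chrom = "chr1", peak_marker = "mk0001",
                       interval_left_bp = 1.5e5, interval_right_bp = 2.5e5)
  tr <- assemble_triples(oq, eqtl, em, G, ph)
  expect_equal(ncol(tr$M), 1157)
  expect_equal(length(tr$dropped), 36)
})

test_that("difference and product mediation estimates agree identically", {
  set.seed(72)
  for (k in 1:20) {
    n <- 50
    X <- rbinom(n, 1, 0.4)
    M <- 0.8 * X + rnorm(n)
    Y <- 0.5 * X + 0.7 * M + rnorm(n)
    est <- estimate_proportion(X, M, Y)
    a <- coef(lm(M ~ X))[["X"]]
    b <- coef(lm(Y ~ X + M))[["M"]]
    expect_equal(est$indirect, a * b, tolerance = 1e-10)
    expect_equal(est$total, est$direct + est$indirect, tolerance = 1e-10)
  }
})

test_that("proportion estimation covers the stated limiting cases", {
  n <- 60
  X <- rbinom(n, 1, 0.5)
  # Y = M, M = 0.5 X: full mediation
  # noiseless X-M collinearity is the degenerate case; jitter M slightly
  set.seed(173)
  M <- 0.5 * X + rnorm(n, 0, 0.01)
  Y <- M
  est <- estimate_proportion(X, M, Y)
  expect_equal(est$proportion, 1, tolerance = 1e-6)
  expect_true(est$interpretable)

  # M independent of X: proportion ~ 0
  set.seed(73)
  M2 <- rnorm(n)
  Y2 <- X + 0.01 * M2 + rnorm(n, 0, 0.1)
  est2 <- estimate_proportion(X, M2, Y2)
  expect_lt(abs(est2$proportion), 0.1)

  # zero-variance input is an error
  expect_error(estimate_proportion(rep(1, n), M2, Y2), "variance")
})

test_that("med_test ranks a perfect mediator first with minimal adjusted p", {
  set.seed(74)
  n <- 80
  X <- rbinom(n, 1, 0.5)
  names(X) <- sprintf("s%02d", 1:n)
  M <- cbind(matrix(rnorm(n * 5), n, 5), X)
  colnames(M) <- c(paste0("null", 1:5), "perfect")
  rownames(M) <- names(X)
  Y <- setNames(as.numeric(X), names(X))
  res <- med_test(X, M, Y, n_perm = 200, seed = 1)
  expect_equal(res$mediator[which.max(res$estimate)], "perfect")
  expect_true(res$collinear[res$mediator == "perfect"])
  expect_equal(res$p_adj[res$mediator == "perfect"], 1 / 201)
  expect_equal(max(res$estimate), 1)
  # p_adj monotone nonincreasing in the estimate
  ord <- order(-res$estimate)
  expect_true(all(diff(res$p_adj[ord]) >= 0))
})

test_that("med_test is calibrated under the null", {
  set.seed(75)
  n <- 60
  fp <- replicate(30, {
    X <- rbinom(n, 1, 0.5)
    M <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(NULL, paste0("m", 1:20)))
    Y <- rnorm(n) + 0.5 * X
    res <- suppressWarnings(med_test(X, M, Y, n_perm = 99,
                                     seed = sample.int(1e6, 1)))
    any(res$p_adj < 0.05)
  })
  expect_lte(mean(fp), 0.1)
})

test_that("a planted mediator is detected among many nulls", {
  set.seed(76)
  wins <- replicate(10, {
    n <- 150
    X <- rbinom(n, 1, 0.5)
    M_true <- 0.9 * X + rnorm(n)
    Y <- 0.5 * X + 0.5 * M_true + rnorm(n)
    M <- cbind(matrix(rnorm(n * 60), n, 60), M_true)
    colnames(M) <- c(paste0("null", 1:60), "planted")
    rownames(M) <- names(X) <- names(Y) <- sprintf("s%03d", 1:n)
    res <- med_test(X, M, Y, n_perm = 100, seed = sample.int(1e6, 1))
    res$mediator[which.max(res$estimate)] == "planted"
  })
  expect_gte(mean(wins), 0.9)
})

test_that("significance calling applies both arms with a strict quantile", {
  res <- tibble::tibble(mediator = paste0("m", 1:5),
                        estimate = c(0.5, 0.2, 0.1, 0.05, 0.01),
                        p_adj = c(0.2, 0.049, 0.5, 0.5, 0.5))
  out <- call_significant(res)
  p99 <- as.numeric(quantile(res$estimate, 0.99, type = 7))
  # m1 has the largest estimate but equals its own p99? strictly greater rule
  expect_equal(out$significant[1], res$estimate[1] > p99)
  expect_true(out$significant[2])   # p = 0.049 < 0.05
  expect_false(out$significant[3])
  # single mediator at its own 99th percentile: not significant
  one <- tibble::tibble(mediator = "m", estimate = 0.3, p_adj = 0.2)
  expect_false(call_significant(one)$significant)
  # interpretable gate
  res$interpretable <- c(TRUE, FALSE, TRUE, TRUE, TRUE)
  out2 <- call_significant(res)
  expect_false(out2$reported[2])
})

test_that("pseudo markers take the carrier union per gene", {
  vt <- tibble::tibble(gene = c("g1", "g1", "g2"),
                       variant = c("v1", "v2", "v3"),
                       strain = c("sA", "sB", "sC"))
  x <- make_pseudo_marker(vt, "g1", c("sA", "sB", "sC", "sD"))
  expect_equal(as.vector(x), c(1, 1, 0, 0))
  expect_false(attr(x, "monomorphic"))
  # every strain a carrier
  vt2 <- tibble::tibble(gene = "g", variant = "v", strain = c("sA", "sB"))
  x2 <- make_pseudo_marker(vt2, "g", c("sA", "sB"))
  expect_equal(as.vector(x2), c(1, 1))
  expect_true(attr(x2, "monomorphic"))
  expect_error(make_pseudo_marker(vt, "nope", "sA"), "absent")
  # fixture union vs set-union oracle
  set.seed(77)
  vt3 <- tibble::tibble(gene = "g",
                        variant = sample(paste0("v", 1:5), 30, TRUE),
                        strain = sample(sprintf("s%02d", 1:20), 30, TRUE))
  x3 <- make_pseudo_marker(vt3, "g", sprintf("s%02d", 1:20))
  expect_equal(as.vector(x3),
               as.numeric(sprintf("s%02d", 1:20) %in% unique(vt3$strain)))
})

test_that("regressing out the true mediator removes the marker association", {
  set.seed(78)
  n <- 120
  G <- tiny_geno(n = n, m = 60, seed = 78)
  K <- kinship(G)
  x <- G$dosage[, 30]
  M_true <- 1.2 * x + rnorm(n, 0, 0.4)
  Y <- setNames(0.9 * M_true + rnorm(n, 0, 0.3), strains(G))  # fully mediated
  em <- rbind(mediator = M_true,
              other1 = rnorm(n), other2 = rnorm(n), other3 = rnorm(n))
  colnames(em) <- strains(G)
  pm <- setNames(x, strains(G))
  res <- regression_drop_scan(Y, em, pm, K)
  baseline <- attr(res, "baseline")
  expect_gt(baseline, 3)
  # the true mediator shows much the largest drop
  drops <- baseline - res$neglog10p
  expect_equal(res$transcript[which.max(drops)], "mediator")
  # independent transcripts barely move
  expect_lt(max(abs(drops[res$transcript != "mediator"])), 1.5)
  # mediator's residual association collapses toward the null
  expect_lt(res$neglog10p[res$transcript == "mediator"], baseline / 3)
})
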