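# independent median-of-ratios oracle, coded from the definition
mor_oracle <- function(v) {
  ok <- apply(v, 1, function(r) all(r > 0))
  gm <- exp(rowMeans(log(v[ok, , drop = FALSE])))
  apply(v[ok, , drop = FALSE] / gm, 2, median)
}

test_that("norm_factors is scale-equivariant and matches the oracle", {
  set.seed(10)
  v <- matrix(rlnorm(50 * 5), 50, 5,
              dimnames = list(sprintf("t%02d", 1:50), sprintf("s%d", 1:5)))
  f <- norm_factors(v)
  expect_equal(unname(f), unname(mor_oracle(v)), tolerance = 1e-12)

  # sample B = 2 x sample A
  v2 <- cbind(A = v[, 1], B = 2 * v[, 1])
  f2 <- norm_factors(v2)
  expect_equal(unname(f2[2] / f2[1]), 2, tolerance = 1e-12)

  # identical samples -> equal factors
  v3 <- cbind(a = v[, 1], b = v[, 1], c = v[, 1])
  expect_equal(diff(range(norm_factors(v3))), 0, tolerance = 1e-14)

  # invariant to transcript reordering
  perm <- sample(nrow(v))
  expect_equal(unname(norm_factors(v[perm, ])), unname(f), tolerance = 1e-14)

  # no all-positive reference transcript
  v4 <- v; v4[cbind(1:5, rep(1:5, 1))] <- 0; v4[6:50, 2] <- 0
  expect_error(norm_factors(v4[1:6, , drop = FALSE]), "normalization error")
})

test_that("norm_factors agrees with the DESeq2 size-factor oracle", {
  skip_if_not_installed("DESeq2")
  set.seed(11)
  # odd number of all-positive reference rows: the linear- and log-space
  # medians coincide, so the two implementations must agree exactly
  v <- matrix(rlnorm(51 * 7, 4, 1), 51, 7,
              dimnames = list(sprintf("t%02d", 1:51), sprintf("s%d", 1:7)))
  f_ours <- norm_factors(v)
  f_deseq <- DESeq2::estimateSizeFactorsForMatrix(v)
  expect_equal(unname(f_ours), unname(f_deseq), tolerance = 1e-12)
})

test_that("filter_reliable implements the all-replicates rule", {
  # 12 strains x 2 reps; transcript passes in all reps of exactly 10 strains
  n_strains <- 12
  vals <- matrix(10, 3, n_strains * 2)
  ex <- tiny_expr(vals, sprintf("st%02d", 1:n_strains), reps = 2)
  # t1: >=5 in all reps of exactly 10 strains -> kept
  ex$values[1, ] <- 4
  ex$values[1, 1:20] <- 5
  # t2: >=5 in all reps of 9 strains and one of two reps of a 10th -> dropped
  ex$values[2, ] <- 4
  ex$values[2, 1:18] <- 5
  ex$values[2, 19] <- 5
  # t3: everywhere high -> kept
  kept <- filter_reliable(ex, min_count = 5, min_strains = 10)
  expect_true("tx001" %in% kept)
  expect_false("tx002" %in% kept)
  expect_true("tx003" %in% kept)
})

test_that("filter_reliable matches an exhaustive oracle and is monotone", {
  set.seed(20)
  n_strains <- 30
  vals <- matrix(rpois(40 * n_strains * 2, 6), 40, n_strains * 2)
  ex <- tiny_expr(vals, sprintf("st%02d", 1:n_strains), reps = 2)
  kept <- filter_reliable(ex, min_count = 5, min_strains = 10)
  # brute force
  strain <- ex$samples$strain
  oracle <- rownames(ex$values)[vapply(seq_len(nrow(ex$values)), function(i) {
    n_ok <- sum(vapply(unique(strain), function(s) {
      all(ex$values[i, strain == s] >= 5)
    }, logical(1)))
    n_ok >= 10
  }, logical(1))]
  expect_setequal(kept, oracle)
  # raising min_count never enlarges the kept set
  kept6 <- filter_reliable(ex, min_count = 6, min_strains = 10)
  expect_true(all(kept6 %in% kept))
})

test_that("divergent masking follows the TSS rule and the retention cutoff", {
  n_strains <- 120
  vals <- matrix(10, 2, n_strains * 2)
  ex <- tiny_expr(vals, sprintf("st%03d", 1:n_strains), reps = 2)
  ann <- tiny_annotation(rownames(ex$values), chrom = "chrI",
                         tss = c(5e5, 5e6))
  # mask transcript 1's TSS region in 25 strains: 120 - 25 = 95 < 100 -> dropped
  masks <- tibble::tibble(strain = sprintf("st%03d", 1:25), chrom = "chrI",
                          start = 4e5, end = 6e5)
  out <- apply_divergent_mask(ex, masks, ann, min_strains_retained = 100)
  expect_identical(rownames(out$values), "tx002")
  expect_identical(attr(out, "dropped"), "tx001")

  # at 20 masked strains (100 retained) the transcript survives, masked
  masks20 <- masks[1:20, ]
  out20 <- apply_divergent_mask(ex, masks20, ann, min_strains_retained = 100)
  expect_true("tx001" %in% rownames(out20$values))
  expect_true(all(out20$mask["tx001", out20$samples$strain %in% masks20$strain]))

  # empty mask set: identity
  out0 <- apply_divergent_mask(ex, masks[0, ], ann, min_strains_retained = 100)
  expect_identical(out0$values, ex$values)
  expect_identical(out0$mask, ex$mask)

  # TSS boundary: interval [start, end) covers tss = end but not tss = start
  ann_b <- tiny_annotation(rownames(ex$values), chrom = "chrI",
                           tss = c(4e5, 6e5))
  out_b <- apply_divergent_mask(ex, masks[1, , drop = FALSE], ann_b,
                                min_strains_retained = 1)
  expect_false(out_b$mask["tx001", 1])   # tss == start: outside
  expect_true(out_b$mask["tx002", 1])    # tss == end: inside
})

test_that("select_samples keeps tight replicates and drops planted outliers", {
  set.seed(30)
  n_strains <- 15
  base <- matrix(rlnorm(80 * n_strains, 3, 1), 80, n_strains)
  reps <- 3
  vals <- base[, rep(seq_len(n_strains), each = reps)] *
    matrix(exp(rnorm(80 * n_strains * reps, 0, 0.03)), 80)
  ex <- tiny_expr(vals, sprintf("st%02d", 1:n_strains), reps = reps)

  # all well clustered: nothing removed, one iteration (idempotence)
  sel <- select_samples(ex)
  expect_equal(sort(sel$kept), sort(ex$samples$sample))
  expect_equal(sel$iterations, 1)

  # one far outlier replicate in a 3-replicate strain: exactly it is dropped
  ex2 <- ex
  ex2$values[, 3] <- rlnorm(80, 6, 1)       # st01_r3
  sel2 <- select_samples(ex2)
  dropped <- sel2$report$sample[sel2$report$status == "dropped"]
  expect_identical(dropped, "st01_r3")
  expect_equal(sel2$report$reason[sel2$report$sample == "st01_r3"],
               "outlier_replicate")

  # a strain whose replicates are mutually distant: whole strain removed
  ex3 <- ex
  for (r in 1:3) ex3$values[, (2 - 1) * 3 + r] <- rlnorm(80, 3 + 2 * r, 1.5)
  sel3 <- select_samples(ex3)
  dropped3 <- sel3$report$sample[sel3$report$status == "dropped"]
  expect_setequal(dropped3, c("st02_r1", "st02_r2", "st02_r3"))
  expect_true(all(sel3$report$reason[sel3$report$status == "dropped"] ==
                    "strain_removed"))
})

test_that("select_samples is a contraction and idempotent at its fixed point", {
  set.seed(31)
  n_strains <- 12
  base <- matrix(rlnorm(60 * n_strains, 3, 1), 60, n_strains)
  vals <- base[, rep(seq_len(n_strains), each = 3)] *
    matrix(exp(rnorm(60 * n_strains * 3, 0, 0.4)), 60)
  ex <- tiny_expr(vals, sprintf("st%02d", 1:n_strains), reps = 3)
  sel <- select_samples(ex)
  expect_lte(length(sel$kept), ncol(ex$values))
  # rerun on the fixed point: nothing else removed
  keep_cols <- ex$samples$sample %in% sel$kept
  ex_fp <- expr_matrix(ex$values[, keep_cols], ex$samples[keep_cols, ])
  sel_fp <- select_samples(ex_fp)
  expect_setequal(sel_fp$kept, sel$kept)
  expect_equal(sel_fp$iterations, 1)
})

test_that("log transform and strain means use the stated closed forms", {
  expect_equal(log_transform(0), -1)
  expect_equal(log_transform(1.5), 1)
  # transform first, then average replicates
  vals <- matrix(c(2, 4), 1, 2)
  ex <- tiny_expr(vals, "stA", reps = 2)
  sm <- strain_means(log_transform(ex))
  expect_equal(unname(sm[1, "stA"]), mean(log2(c(2, 4) + 0.5)))
  # masked replicate excluded; fully masked strain is NA
  ex2 <- tiny_expr(matrix(c(2, 4, 8, 16), 1, 4), c("stA", "stB"), reps = 2)
  ex2$mask[1, 2] <- TRUE
  ex2$mask[1, 3:4] <- TRUE
  sm2 <- strain_means(log_transform(ex2))
  expect_equal(unname(sm2[1, "stA"]), log2(2.5))
  expect_true(is.na(sm2[1, "stB"]))
})
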