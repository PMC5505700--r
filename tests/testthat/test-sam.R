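test_that("unpaired SAM statistic matches hand-computed values", {
  # class1 = (0,1), class2 = (2,3): mean diff 2, s = sqrt(((1/2+1/2)/2) * 1)
  m <- make_matrix(matrix(c(0, 1, 2, 3), 1, 4), genes = "g1", scale = "log2p1")
  d <- sam_statistic_unpaired(m, class1 = c("s01", "s02"),
                              class2 = c("s03", "s04"), s0 = 0)
  expect_equal(unname(d), 2 / sqrt(0.5), tolerance = 1e-12)

  # identical classes: d = 0 for every gene
  m2 <- make_matrix(matrix(rep(c(1, 2, 3), 2), 3, 6,
                           dimnames = NULL), scale = "log2p1")
  d2 <- sam_statistic_unpaired(m2, 1:3, 4:6, s0 = 0.1)
  expect_equal(unname(d2), rep(0, 3))

  expect_error(sam_statistic_unpaired(m, "s01", c("s02", "s03")), ">= 2")
})

test_that("paired SAM statistic matches hand-computed values", {
  # pair differences (0, 1, 2): zbar = 1, s = sqrt(2/6)
  ref <- matrix(0, 1, 3, dimnames = list("g1", c("v1", "v2", "v3")))
  alt <- matrix(c(0, 1, 2), 1, 3, dimnames = list("g1", c("t1", "t2", "t3")))
  m <- make_matrix(cbind(ref, alt), genes = "g1",
                   samples = c(colnames(ref), colnames(alt)), scale = "log2p1")
  pairs <- data.frame(pair_id = c("p1", "p2", "p3"),
                      ref = c("v1", "v2", "v3"), alt = c("t1", "t2", "t3"))
  d <- sam_statistic_paired(m, pairs, s0 = 0)
  expect_equal(unname(d), 1 / sqrt(2 / 6), tolerance = 1e-12)

  # all differences zero
  m0 <- make_matrix(matrix(1, 1, 6), genes = "g1",
                    samples = c("v1", "v2", "v3", "t1", "t2", "t3"),
                    scale = "log2p1")
  expect_equal(unname(sam_statistic_paired(m0, pairs, s0 = 0.3)), 0)

  # constant differences (1,1,1) with s0 = 0.5: s_g = 0, d = 1/0.5
  mc <- make_matrix(cbind(matrix(0, 1, 3), matrix(1, 1, 3)), genes = "g1",
                    samples = c("v1", "v2", "v3", "t1", "t2", "t3"),
                    scale = "log2p1")
  expect_equal(unname(sam_statistic_paired(mc, pairs, s0 = 0.5)), 2)

  # incomplete pair named in the error
  bad <- data.frame(pair_id = c("p1", "pX"), ref = c("v1", "nope"),
                    alt = c("t1", "t2"))
  expect_error(sam_statistic_paired(m, bad), "pX")
})

test_that("unpaired d at s0 = 0 equals the pooled two-sample t statistic", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- matrix(rnorm(50 * 6), 50, 6)
    m <- make_matrix(v, scale = "log2p1")
    d <- sam_statistic_unpaired(m, 1:3, 4:6, s0 = 0)
    t_oracle <- apply(v, 1, function(row)
      t.test(row[4:6], row[1:3], var.equal = TRUE)$statistic)
    expect_lt(max(abs(d - t_oracle)), 1e-12)
  }
})

test_that("relabeling classes negates d; reversing pair contrasts negates paired d", {
  set.seed(11)
  m <- make_matrix(matrix(rnorm(40 * 6, 5), 40, 6), scale = "log2p1")
  d12 <- sam_statistic_unpaired(m, 1:3, 4:6, s0 = 0.2)
  d21 <- sam_statistic_unpaired(m, 4:6, 1:3, s0 = 0.2)
  expect_equal(d12, -d21)

  pairs <- data.frame(pair_id = c("a", "b", "c"),
                      ref = c("s01", "s02", "s03"), alt = c("s04", "s05", "s06"))
  rev_pairs <- transform(pairs, ref = alt, alt = ref)
  expect_equal(sam_statistic_paired(m, pairs, 0.2),
               -sam_statistic_paired(m, rev_pairs, 0.2))
})

test_that("s0 selection matches a brute-force grid oracle and handles edge cases", {
  set.seed(21)
  # heteroskedastic numerators/standard errors
  s <- rgamma(500, shape = 2, rate = 4)
  r <- rnorm(500, 0, s + 0.1)
  expect_equal(estimate_s0(r, s), oracle_s0(r, s), tolerance = 1e-12)

  # all s equal: every candidate ties; result is that common value
  s_const <- rep(0.5, 500)
  r2 <- rnorm(500)
  expect_equal(estimate_s0(r2, s_const), 0.5)

  # fewer than 100 genes: fallback to the 5th percentile with a warning
  s_small <- rgamma(50, 2, 4)
  expect_warning(s0_small <- estimate_s0(rnorm(50), s_small), "5th percentile")
  expect_equal(s0_small, unname(quantile(s_small, 0.05)))
})

test_that("permutation counts equal the closed forms", {
  m <- make_matrix(matrix(rnorm(20 * 6, 3), 20, 6), scale = "log2p1")
  null_33 <- permutation_null(m, list(type = "unpaired", class1 = 1:3,
                                      class2 = 4:6), s0 = 0.1)
  expect_equal(null_33$n_permutations, choose(6, 3))

  null_22 <- permutation_null(make_matrix(matrix(rnorm(20 * 4, 3), 20, 4),
                                          scale = "log2p1"),
                              list(type = "unpaired", class1 = 1:2, class2 = 3:4),
                              s0 = 0.1)
  expect_equal(null_22$n_permutations, choose(4, 2))

  pairs <- data.frame(pair_id = c("a", "b", "c"),
                      ref = c("s01", "s02", "s03"), alt = c("s04", "s05", "s06"))
  null_p <- permutation_null(m, list(type = "paired", pairs = pairs), s0 = 0.1)
  expect_equal(null_p$n_permutations, 2^3)
  # each null row is sorted and d_expected is the rank-wise mean
  expect_true(all(apply(null_p$null_sorted, 1, function(x) !is.unsorted(x))))
  expect_equal(null_p$d_expected, colMeans(null_p$null_sorted))
})

test_that("gene calling respects the FDR target and q monotonicity", {
  fib <- small_fibroblast(seed = 5)
  de <- differential_expression(fib$expression, fib$samples, "ko_vs_wt_vehicle")
  expect_true(all(de$q[de$called] <= attr(de, "fdr_target") + 1e-12))
  expect_true(all(de$direction[de$called] == sign(de$d[de$called])))
  # q non-increasing in |d - d_expected|
  strength <- abs(de$d - de$d_expected)
  o <- order(strength)
  expect_true(all(diff(de$q[o]) <= 1e-12))
  expect_true(all(de$q >= 0 & de$q <= 1))

  # degenerate: a pure-noise tiny matrix may call nothing, q stays defined
  set.seed(1)
  m <- make_matrix(matrix(rnorm(150 * 6, 5, 1), 150, 6), scale = "log2p1")
  d <- sam_statistic_unpaired(m, 1:3, 4:6, s0 = 0.2)
  null <- permutation_null(m, list(type = "unpaired", class1 = 1:3, class2 = 4:6),
                           s0 = 0.2)
  res <- call_significant(d, null, sam_config(fdr_target = 0.01))
  expect_true(all(is.finite(res$q)))
  if (!any(res$called)) expect_true(all(res$q >= 0))
})

test_that("differential_expression validates designs and is deterministic", {
  fib <- small_fibroblast(seed = 6)
  wt_only <- fib$samples[fib$samples$genotype == "WT", ]
  wt_expr <- expression_matrix(fib$expression$values[, wt_only$sample_id],
                               "raw")
  expect_error(differential_expression(wt_expr, wt_only, "ko_vs_wt_vehicle"),
               ">= 2 vehicle samples")

  de1 <- differential_expression(fib$expression, fib$samples, "ko_vs_wt_vehicle")
  de2 <- differential_expression(fib$expression, fib$samples, "ko_vs_wt_vehicle")
  expect_identical(de1, de2)
  expect_identical(attr(de1, "comparison"), "ko_vs_wt_vehicle")
  expect_equal(attr(de1, "n_permutations"), 20)
})
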