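test_that("build_signature keeps called genes with the sign of d", {
  de <- make_de(c("A", "B", "C"), d = c(2, -3, 1),
                called = c(TRUE, TRUE, FALSE))
  sig <- build_signature(de)
  expect_equal(sig$gene_id, c("A", "B"))
  expect_equal(sig$direction, c(1L, -1L))
  expect_equal(attr(sig, "meta")$n_up, 1)

  all_up <- make_de(letters[1:5], d = 1, called = TRUE)
  expect_equal(build_signature(all_up)$direction, rep(1L, 5))

  expect_warning(empty <- build_signature(make_de("A", d = 1, called = FALSE)),
                 "empty")
  expect_equal(nrow(empty), 0)
})

test_that("sirolimus reversal report reproduces the printed overlap arithmetic", {
  n_up <- 1387; n_up_rev <- 1275
  n_down <- 437; n_down_rev <- 349
  up <- sprintf("u%04d", seq_len(n_up))
  down <- sprintf("d%04d", seq_len(n_down))
  sig <- signature_set(c(up, down), c(rep(1L, n_up), rep(-1L, n_down)))
  # sirolimus DE: first 1275 up-genes called down, first 349 down-genes called up
  de_sir <- make_de(c(up, down),
                    d = c(rep(-1, n_up_rev), rep(0.1, n_up - n_up_rev),
                          rep(1, n_down_rev), rep(-0.1, n_down - n_down_rev)),
                    called = c(rep(TRUE, n_up_rev), rep(FALSE, n_up - n_up_rev),
                               rep(TRUE, n_down_rev), rep(FALSE, n_down - n_down_rev)))
  rep_ <- sirolimus_correction(sig, de_sir)
  expect_equal(rep_$n_up_reversed, 1275)
  expect_equal(rep_$pct_up_reversed, 92)
  expect_equal(rep_$n_down_reversed, 349)
  expect_equal(rep_$pct_down_reversed, 80)

  # no overlap: both percentages zero
  de_none <- make_de(c(up, down), d = 1, called = FALSE)
  rep0 <- sirolimus_correction(sig, de_none)
  expect_equal(rep0$pct_up_reversed, 0)
  expect_equal(rep0$pct_down_reversed, 0)

  # universe mismatch errors with examples
  expect_error(sirolimus_correction(sig, make_de("other")), "universe")
})

test_that("reversal requires an opposite-direction significant call", {
  sig <- signature_set(c("A", "B"), c(1L, 1L))
  # A: called but same direction; B: opposite sign but not called
  de <- make_de(c("A", "B"), d = c(2, -2), called = c(TRUE, FALSE))
  rep_ <- sirolimus_correction(sig, de)
  expect_equal(rep_$n_up_reversed, 0)
})

test_that("correction percentages always recompute from their own counts", {
  set.seed(30)
  for (i in 1:20) {
    n_up <- sample(1:200, 1); n_down <- sample(1:200, 1)
    k_up <- sample(0:n_up, 1); k_down <- sample(0:n_down, 1)
    up <- sprintf("u%03d", seq_len(n_up)); down <- sprintf("d%03d", seq_len(n_down))
    sig <- signature_set(c(up, down), c(rep(1L, n_up), rep(-1L, n_down)))
    de <- make_de(c(up, down),
                  d = c(rep(-1, k_up), rep(1, n_up - k_up),
                        rep(1, k_down), rep(-1, n_down - k_down)),
                  called = c(rep(TRUE, k_up), rep(FALSE, n_up - k_up),
                             rep(TRUE, k_down), rep(FALSE, n_down - k_down)))
    rp <- sirolimus_correction(sig, de)
    expect_equal(rp$pct_up_reversed, round_half_up(100 * rp$n_up_reversed / rp$n_up_in_ko))
    expect_equal(rp$pct_down_reversed,
                 round_half_up(100 * rp$n_down_reversed / rp$n_down_in_ko))
    expect_true(rp$n_up_reversed <= rp$n_up_in_ko)
  }
})

test_that("common_gene_fraction computes subset percentages", {
  a <- make_de(c("X", "Y", "Q"), d = 1, called = c(TRUE, TRUE, FALSE))
  b <- make_de(c("X", "Y", "Z", "Q"), d = 1, called = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(common_gene_fraction(a, b, 1L), 100)

  b2 <- make_de(c("X", "Y", "Q"), d = 1, called = c(TRUE, FALSE, FALSE))
  expect_equal(common_gene_fraction(a, b2, 1L), 50)

  none <- make_de(c("X", "Y", "Q"), d = 1, called = FALSE)
  out <- common_gene_fraction(none, b, 1L)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "no called genes")
})

test_that("annotation screen keeps genes in all required categories, order preserved", {
  ann <- data.frame(
    gene_id = c("Lgals3", "Lgals3", "Vegfa", "Actb"),
    category = c("extracellular region", "signaling", "signaling", "cytoskeleton"),
    stringsAsFactors = FALSE)
  out <- annotate_candidates(c("Actb", "Lgals3", "Vegfa", "Unknown"), ann,
                             c("extracellular region", "signaling"))
  expect_equal(out, "Lgals3")
  expect_equal(annotate_candidates(c("Vegfa", "Lgals3"), ann, "signaling"),
               c("Vegfa", "Lgals3"))
  expect_equal(annotate_candidates(character(), ann, "signaling"), character())
  expect_error(annotate_candidates("Lgals3", ann, character()), "non-empty")

  # filtering by a union of categories equals sequential filtering
  genes <- c("Lgals3", "Vegfa", "Actb")
  both <- annotate_candidates(genes, ann, c("extracellular region", "signaling"))
  seq_ <- annotate_candidates(annotate_candidates(genes, ann, "extracellular region"),
                              ann, "signaling")
  expect_equal(both, seq_)
})

test_that("reversal recovery on simulated data tracks the planted fraction", {
  # 4 lines give 16 sign-flip permutations, enough paired calling power for
  # the planted fractions (0.92 / 0.80) to show through the ~10% FDR
  # contamination of the signature and binomial noise at its realized size
  fib <- simulate_fibroblast_experiment(n_genes = 800, n_lines = 4, seed = 17)
  de_ko <- differential_expression(fib$expression, fib$samples, "ko_vs_wt_vehicle")
  de_sir <- differential_expression(fib$expression, fib$samples, "sir_vs_veh_in_ko")
  sig <- build_signature(de_ko)
  rp <- sirolimus_correction(sig, de_sir)
  expect_gt(rp$pct_up_reversed, 70)
  expect_gt(rp$pct_down_reversed, 60)
  expect_lt(rp$pct_up_reversed, 100)
})
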