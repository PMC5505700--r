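# Fixtures built in code: small matrices, hand-assembled DE results, and a
# brute-force re-implementation of the s0 selection grid used as an oracle.

make_matrix <- function(values, genes = NULL, samples = NULL,
                        scale = "raw") {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, scale)
}

random_matrix <- function(n_genes, n_samples, seed, scale = "raw") {
  set.seed(seed)
  v <- matrix(abs(rnorm(n_genes * n_samples, 5, 2)), n_genes, n_samples)
  make_matrix(v, scale = scale)
}

# Hand-assembled DE result for operations that consume one.
make_de <- function(gene_id, d = 0, called = FALSE, q = NULL,
                    fdr_target = 0.1) {
  n <- length(gene_id)
  d <- rep_len(d, n); called <- rep_len(called, n)
  if (is.null(q)) q <- ifelse(called, fdr_target / 2, 1)
  structure(data.frame(gene_id = gene_id, d = d, d_expected = 0,
                       q = q, direction = as.integer(sign(d)),
                       called = called, stringsAsFactors = FALSE),
            class = c("tsc_de", "data.frame"),
            fdr_target = fdr_target, comparison = "fixture")
}

# Independent re-implementation of the fudge-factor grid (the oracle for
# estimate_s0): percentile candidates, 100 s-quantile windows, CV of the
# windowed MADs, first minimizer.
oracle_s0 <- function(r, s) {
  cand <- unname(quantile(s, probs = seq(0, 1, by = 0.05), type = 7))
  breaks <- unique(quantile(s, probs = seq(0, 1, length.out = 101), type = 7))
  win <- cut(s, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  cvs <- vapply(cand, function(s0) {
    d <- ifelse(s + s0 == 0, 0, r / (s + s0))
    mads <- tapply(d, win, mad)
    sd(mads) / mean(mads)
  }, numeric(1))
  cand[which.min(cvs)]
}

# Three-genotype-pair fibroblast design small enough for fast tests.
small_fibroblast <- function(seed = 1, n_genes = 300, ...) {
  simulate_fibroblast_experiment(n_genes = n_genes, seed = seed, ...)
}
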