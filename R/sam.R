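# Significance analysis of microarrays (SAM): a moderated difference
# statistic d = (difference in means) / (s + s0), a permutation null built by
# relabeling (unpaired) or sign-flipping pair differences (paired), and gene
# calling by the asymmetric delta-threshold rule with a permutation-count
# FDR.  The fudge factor s0 is chosen over a percentile grid of the gene-wise
# standard errors by minimizing the coefficient of variation of windowed
# median absolute deviations of d.

#' SAM configuration
#'
#' @param fdr_target target median FDR for gene calling (default 0.10).
#' @param s0_mode `"auto"` (CV-of-window-MADs grid), `"percentile"` (a fixed
#'   percentile of the s distribution) or `"fixed"` (use `s0_value`).
#' @param s0_percentile percentile in \[0, 100\] used when
#'   `s0_mode = "percentile"`.
#' @param s0_value fudge factor used when `s0_mode = "fixed"`.
#' @param max_exhaustive_perms enumerate all distinct permutations when their
#'   count does not exceed this; otherwise sample.
#' @param n_sampled_perms number of sampled permutations when enumeration is
#'   infeasible.
#' @param n_delta size of the automatic delta grid.
#' @param delta_grid optional explicit grid of positive delta values.
#' @param fdr_stat aggregator of permutation false counts: `"mean"` (the
#'   original formulation; the identity permutation always contributes, so
#'   the estimate cannot claim 0% while genes are called) or `"median"`
#'   (samr-style, liberal at few permutations).
#' @param seed seed for sampled permutations.
#' @return a list of class `sam_config`.
#' @export
sam_config <- function(fdr_target = 0.10,
                       s0_mode = c("auto", "percentile", "fixed"),
                       s0_percentile = 5,
                       s0_value = NULL,
                       max_exhaustive_perms = 5000,
                       n_sampled_perms = 1000,
                       n_delta = 50,
                       delta_grid = NULL,
                       fdr_stat = c("mean", "median"),
                       seed = 1) {
  s0_mode <- match.arg(s0_mode)
  fdr_stat <- match.arg(fdr_stat)
  if (fdr_target <= 0 || fdr_target >= 1) stop_tsc("fdr_target must lie in (0, 1)")
  if (s0_mode == "fixed" && (is.null(s0_value) || s0_value < 0))
    stop_tsc("s0_mode = 'fixed' needs a non-negative s0_value")
  structure(list(fdr_target = fdr_target, s0_mode = s0_mode,
                 s0_percentile = s0_percentile, s0_value = s0_value,
                 max_exhaustive_perms = max_exhaustive_perms,
                 n_sampled_perms = n_sampled_perms,
                 n_delta = n_delta, delta_grid = delta_grid,
                 fdr_stat = fdr_stat,
                 seed = as.integer(seed)),
            class = "sam_config")
}

# Numerator (mean difference) and gene-wise standard error for the unpaired
# two-class design.  class2 is the designated test class (KO), so positive d
# means higher in class2.
sam_parts_unpaired <- function(values, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  if (n1 < 2 || n2 < 2) stop_tsc("each class needs >= 2 samples")
  m1 <- rowMeans(values[, idx1, drop = FALSE])
  m2 <- rowMeans(values[, idx2, drop = FALSE])
  ss1 <- rowSums((values[, idx1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((values[, idx2, drop = FALSE] - m2)^2)
  a <- (1 / n1 + 1 / n2) / (n1 + n2 - 2)
  list(r = m2 - m1, s = sqrt(a * (ss1 + ss2)))
}

# Numerator and standard error from a genes x pairs matrix of differences.
sam_parts_paired <- function(diffs) {
  n <- ncol(diffs)
  if (n < 2) stop_tsc("paired design needs >= 2 complete pairs")
  zbar <- rowMeans(diffs)
  s <- sqrt(rowSums((diffs - zbar)^2) / (n * (n - 1)))
  list(r = zbar, s = s)
}

sam_d_from_parts <- function(parts, s0) {
  den <- parts$s + s0
  d <- ifelse(den == 0 & parts$r == 0, 0, parts$r / den)
  if (any(!is.finite(d)))
    warning("zero gene-wise standard error with s0 = 0 gave infinite d for ",
            sum(!is.finite(d)), " gene(s)", call. = FALSE)
  d
}

#' Unpaired two-class SAM statistic
#'
#' `d_g = (mean_class2 - mean_class1) / (s_g + s0)` with the pooled gene-wise
#' standard error `s_g = sqrt(a (SS1 + SS2))`,
#' `a = (1/n1 + 1/n2) / (n1 + n2 - 2)`.  With `s0 = 0` this is exactly the
#' pooled-variance two-sample t statistic.  `class2` is the test class (KO).
#'
#' @param x log-scale `ExpressionMatrix` or plain numeric matrix (genes x
#'   samples).
#' @param class1,class2 sample identifiers (or column indices) of the two
#'   classes.
#' @param s0 non-negative fudge factor.
#' @return named numeric vector of d statistics.
#' @export
sam_statistic_unpaired <- function(x, class1, class2, s0 = 0) {
  values <- if (inherits(x, "ExpressionMatrix")) x$values else x
  parts <- sam_parts_unpaired(values, resolve_cols(values, class1),
                              resolve_cols(values, class2))
  d <- sam_d_from_parts(parts, s0)
  names(d) <- rownames(values)
  d
}

#' Paired two-class SAM statistic
#'
#' With per-pair differences `z_j` (treatment minus reference):
#' `d_g = mean(z) / (s_g + s0)`, `s_g = sqrt(sum((z - mean(z))^2) / (n(n-1)))`.
#'
#' @param x log-scale `ExpressionMatrix` or numeric matrix.
#' @param pairs data.frame with columns `pair_id`, `ref` and `alt` naming the
#'   reference (vehicle) and alternative (sirolimus) sample of each pair.
#' @param s0 non-negative fudge factor.
#' @return named numeric vector of d statistics.
#' @export
sam_statistic_paired <- function(x, pairs, s0 = 0) {
  values <- if (inherits(x, "ExpressionMatrix")) x$values else x
  diffs <- paired_differences(values, pairs)
  d <- sam_d_from_parts(sam_parts_paired(diffs), s0)
  names(d) <- rownames(values)
  d
}

resolve_cols <- function(values, ids) {
  if (is.numeric(ids)) return(as.integer(ids))
  idx <- match(ids, colnames(values))
  if (anyNA(idx))
    stop_tsc("sample(s) not in matrix: ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

paired_differences <- function(values, pairs) {
  need <- c("pair_id", "ref", "alt")
  if (!all(need %in% names(pairs)))
    stop_tsc("pairs needs columns pair_id, ref, alt")
  bad <- pairs$pair_id[is.na(match(pairs$ref, colnames(values))) |
                         is.na(match(pairs$alt, colnames(values)))]
  if (length(bad))
    stop_tsc("incomplete pair(s): ", paste(bad, collapse = ", "))
  d <- values[, pairs$alt, drop = FALSE] - values[, pairs$ref, drop = FALSE]
  colnames(d) <- pairs$pair_id
  d
}

#' Estimate the SAM fudge factor s0
#'
#' Candidate values are the percentiles 0, 5, ..., 100 of the gene-wise
#' standard-error distribution.  For each candidate the d statistics are
#' recomputed, genes are partitioned into 100 windows by s quantiles, the
#' median absolute deviation of d is taken within each window, and the
#' candidate minimizing the coefficient of variation of these MADs is chosen
#' (ties broken by the smallest candidate).  With fewer than 100 genes the
#' procedure falls back to the 5th percentile with a warning.
#'
#' @param r numeric vector of gene-wise numerators (mean differences).
#' @param s numeric vector of gene-wise standard errors.
#' @return the selected s0 (a scalar).
#' @export
estimate_s0 <- function(r, s) {
  stopifnot(length(r) == length(s))
  m <- length(s)
  cand <- unname(stats::quantile(s, probs = seq(0, 1, by = 0.05), type = 7))
  if (m < 100) {
    warning("fewer than 100 genes; falling back to the 5th percentile of s",
            call. = FALSE)
    return(cand[2])
  }
  breaks <- unique(stats::quantile(s, probs = seq(0, 1, length.out = 101), type = 7))
  win <- if (length(breaks) < 2) rep(1L, m)
  else cut(s, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- ifelse(s + s0 == 0, 0, r / (s + s0))
    mads <- tapply(d, win, stats::mad)
    mu <- mean(mads)
    if (!is.finite(mu) || mu == 0) return(Inf)
    stats::sd(mads) / mu
  }, numeric(1))
  cv[!is.finite(cv)] <- Inf
  cand[which.min(cv)]  # which.min returns the first (smallest) minimizer
}

resolve_s0 <- function(config, r, s) {
  switch(config$s0_mode,
         fixed = config$s0_value,
         percentile = unname(stats::quantile(s, config$s0_percentile / 100, type = 7)),
         auto = estimate_s0(r, s))
}

#' Build the SAM permutation null
#'
#' Unpaired designs enumerate all `choose(n1 + n2, n1)` distinct label
#' assignments (including the observed one) when that count does not exceed
#' `max_exhaustive_perms`, otherwise draw `n_sampled_perms` uniform
#' relabelings with the configured seed.  Paired designs enumerate all
#' `2^n_pairs` sign-flip patterns of the pair differences, or sample them.
#' Each permutation's d vector is sorted; the expected order statistics
#' `d_bar(i)` are the rank-wise means over permutations.
#'
#' @param x log-scale `ExpressionMatrix` or numeric matrix.
#' @param design list describing the design: for unpaired,
#'   `list(type = "unpaired", class1 = ids, class2 = ids)`; for paired,
#'   `list(type = "paired", pairs = data.frame(pair_id, ref, alt))`.
#' @param s0 fudge factor (held fixed across permutations).
#' @param config a [sam_config()].
#' @return list with `null_sorted` (permutations x genes matrix, each row
#'   sorted ascending), `d_expected` (rank-wise means) and `n_permutations`.
#' @export
permutation_null <- function(x, design, s0, config = sam_config()) {
  values <- if (inherits(x, "ExpressionMatrix")) x$values else x
  m <- nrow(values)
  if (design$type == "unpaired") {
    idx1 <- resolve_cols(values, design$class1)
    idx2 <- resolve_cols(values, design$class2)
    all_idx <- c(idx1, idx2)
    n <- length(all_idx); n2 <- length(idx2)
    n_total <- choose(n, n2)
    if (n_total <= config$max_exhaustive_perms) {
      picks <- utils::combn(n, n2, simplify = FALSE)
    } else {
      set.seed(config$seed)
      picks <- replicate(config$n_sampled_perms, sample(n, n2), simplify = FALSE)
    }
    observed <- vapply(picks, function(p)
      setequal(all_idx[p], idx2) || setequal(all_idx[p], idx1), logical(1))
    null <- t(vapply(picks, function(p) {
      i2 <- all_idx[p]; i1 <- all_idx[-p]
      sort(sam_d_from_parts(sam_parts_unpaired(values, i1, i2), s0))
    }, numeric(m)))
  } else if (design$type == "paired") {
    diffs <- paired_differences(values, design$pairs)
    np <- ncol(diffs)
    n_total <- 2^np
    if (n_total <= config$max_exhaustive_perms) {
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), np)))
    } else {
      set.seed(config$seed)
      signs <- matrix(sample(c(1, -1), config$n_sampled_perms * np, replace = TRUE),
                      ncol = np)
    }
    observed <- apply(signs, 1, function(sg) all(sg == 1) || all(sg == -1))
    null <- t(apply(signs, 1, function(sg) {
      sort(sam_d_from_parts(sam_parts_paired(sweep(diffs, 2, sg, `*`)), s0))
    }))
  } else stop_tsc("unknown design type: ", design$type)
  null[!is.finite(null)] <- 0
  list(null_sorted = null,
       d_expected = colMeans(null),
       n_permutations = nrow(null),
       observed_row = which(observed))
}

#' Call differentially expressed genes by the delta-threshold rule
#'
#' Genes are ranked by d and compared with the expected null order statistics
#' `d_bar(i)`.  For each delta in the grid the asymmetric SAM rule applies:
#' the positive cut is the smallest positive `d(i)` with
#' `d(i) - d_bar(i) > delta`, the negative cut the largest negative `d(i)`
#' with `d_bar(i) - d(i) > delta`; genes beyond a cut are called.  The
#' estimated FDR at delta is
#' `pi0 * agg_perm #null d beyond the cuts / #called`, where `agg` is the
#' mean over permutations (default; the original formulation) or the
#' samr-style median, and
#' `pi0 = min(1, #(d in [q25, q75] of null d) / (m / 2))`.  The smallest
#' delta with estimated FDR at or below the target is used; per-gene
#' q-values are the smallest estimated FDR at which the gene is called,
#' monotonized along the `|d - d_bar|` ranking.
#'
#' @param d named vector of observed statistics.
#' @param null result of [permutation_null()].
#' @param config a [sam_config()].
#' @param never_call optional logical mask of genes excluded from calling
#'   (e.g. zero variance in all groups).
#' @return a `tsc_de` data.frame with columns `gene_id`, `d`, `d_expected`,
#'   `q`, `direction`, `called`, and attributes `s0_used` (filled by
#'   [differential_expression()]), `n_permutations`, `pi0`, `delta_used` and
#'   `fdr_target`.
#' @export
call_significant <- function(d, null, config = sam_config(), never_call = NULL) {
  m <- length(d)
  if (is.null(never_call)) never_call <- rep(FALSE, m)
  ord <- order(d)
  d_sorted <- d[ord]
  dbar <- null$d_expected
  d_expected <- numeric(m)
  d_expected[ord] <- dbar

  qq <- stats::quantile(null$null_sorted, c(0.25, 0.75), type = 7)
  pi0 <- min(1, sum(d >= qq[1] & d <= qq[2]) / (0.5 * m))

  diffs <- d_sorted - dbar
  grid <- config$delta_grid
  if (is.null(grid)) {
    top <- max(abs(diffs), 1e-8)
    grid <- seq(0, top, length.out = config$n_delta + 1)[-1]
  }
  grid <- sort(grid)

  nc_sorted <- never_call[ord]
  eval_delta <- function(delta) {
    pos_ok <- diffs > delta & d_sorted > 0 & !nc_sorted
    neg_ok <- -diffs > delta & d_sorted < 0 & !nc_sorted
    cutup <- if (any(pos_ok)) min(d_sorted[pos_ok]) else Inf
    cutlow <- if (any(neg_ok)) max(d_sorted[neg_ok]) else -Inf
    called <- (d >= cutup | d <= cutlow) & !never_call
    n_called <- sum(called)
    if (n_called == 0) return(list(fdr = 0, called = called))
    null_counts <- rowSums(null$null_sorted >= cutup) +
      rowSums(null$null_sorted <= cutlow)
    # the observed partition (in either label orientation) is not a null
    # draw; leave it out of the false-count aggregation (it stays in the
    # enumeration and in d_bar)
    obs <- null$observed_row
    if (!is.null(obs) && length(obs) && length(null_counts) > length(obs))
      null_counts <- null_counts[-obs]
    agg <- if (config$fdr_stat == "median") stats::median(null_counts)
    else mean(null_counts)
    fdr <- min(1, pi0 * agg / n_called)
    list(fdr = fdr, called = called)
  }
  evals <- lapply(grid, eval_delta)
  fdrs <- vapply(evals, `[[`, numeric(1), "fdr")

  ok <- which(fdrs <= config$fdr_target)
  if (length(ok)) {
    use <- ok[1]
  } else {
    warning("no delta in the grid reaches the FDR target; using the largest",
            call. = FALSE)
    use <- length(grid)
  }
  delta_used <- grid[use]
  called <- evals[[use]]$called

  q <- rep(1, m)
  for (k in seq_along(grid)) {
    ck <- evals[[k]]$called
    q[ck] <- pmin(q[ck], fdrs[k])
  }
  # monotonize: q non-increasing in |d - d_expected|; running min from the
  # weak end only ever lowers q, so called genes keep q <= fdr_target
  strength <- abs(d - d_expected)
  so <- order(strength)          # ascending strength
  q[so] <- cummin(q[so])

  res <- data.frame(gene_id = names(d), d = unname(d),
                    d_expected = d_expected, q = q,
                    direction = as.integer(sign(d)),
                    called = called, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("tsc_de", "data.frame"),
            n_permutations = null$n_permutations, pi0 = pi0,
            delta_used = delta_used, fdr_target = config$fdr_target)
}

#' Run a full SAM differential-expression analysis
#'
#' Orchestrates the pipeline on a raw-scale matrix: log2(x + 1) transform,
#' fudge-factor selection, observed statistic, permutation null and
#' delta-threshold calling.  `comparison` selects the design:
#' `"ko_vs_wt_vehicle"` is unpaired two-class on vehicle samples (KO the test
#' class), `"sir_vs_veh_in_ko"` / `"sir_vs_veh_in_wt"` are paired two-class
#' on sirolimus-minus-vehicle differences within lines of one genotype.
#'
#' @param x raw-scale `ExpressionMatrix`.
#' @param samples sample table (`sample_id`, `genotype`, `treatment`,
#'   `pair_id`).
#' @param comparison one of `"ko_vs_wt_vehicle"`, `"sir_vs_veh_in_ko"`,
#'   `"sir_vs_veh_in_wt"`.
#' @param config a [sam_config()].
#' @return a `tsc_de` data.frame (see [call_significant()]), with attributes
#'   `s0_used` and `comparison` filled in.
#' @export
differential_expression <- function(x, samples,
                                    comparison = c("ko_vs_wt_vehicle",
                                                   "sir_vs_veh_in_ko",
                                                   "sir_vs_veh_in_wt"),
                                    config = sam_config()) {
  comparison <- match.arg(comparison)
  stopifnot(inherits(x, "ExpressionMatrix"))
  validate_sample_table(samples, x)
  logm <- log_transform(x)

  if (comparison == "ko_vs_wt_vehicle") {
    wt <- samples$sample_id[samples$genotype == "WT" & samples$treatment == "vehicle"]
    ko <- samples$sample_id[samples$genotype == "KO" & samples$treatment == "vehicle"]
    if (length(wt) < 2 || length(ko) < 2)
      stop_tsc("ko_vs_wt_vehicle needs >= 2 vehicle samples per genotype")
    parts <- sam_parts_unpaired(logm$values,
                                resolve_cols(logm$values, wt),
                                resolve_cols(logm$values, ko))
    design <- list(type = "unpaired", class1 = wt, class2 = ko)
  } else {
    gt <- if (comparison == "sir_vs_veh_in_ko") "KO" else "WT"
    sub <- samples[samples$genotype == gt, , drop = FALSE]
    veh <- sub[sub$treatment == "vehicle", c("pair_id", "sample_id")]
    sir <- sub[sub$treatment == "sirolimus", c("pair_id", "sample_id")]
    pairs <- merge(veh, sir, by = "pair_id", suffixes = c("_ref", "_alt"))
    lone <- setdiff(union(veh$pair_id, sir$pair_id), pairs$pair_id)
    if (length(lone))
      stop_tsc("incomplete pair(s) for ", comparison, ": ",
               paste(lone, collapse = ", "))
    if (nrow(pairs) < 2)
      stop_tsc(comparison, " needs >= 2 complete pairs")
    pairs <- data.frame(pair_id = pairs$pair_id,
                        ref = pairs$sample_id_ref, alt = pairs$sample_id_alt,
                        stringsAsFactors = FALSE)
    parts <- sam_parts_paired(paired_differences(logm$values, pairs))
    design <- list(type = "paired", pairs = pairs)
  }

  s0 <- resolve_s0(config, parts$r, parts$s)
  d <- suppressWarnings(sam_d_from_parts(parts, s0))
  never_call <- !is.finite(d) | (parts$s == 0 & parts$r == 0)
  d[!is.finite(d)] <- 0
  names(d) <- rownames(logm$values)

  null <- permutation_null(logm, design, s0, config)
  res <- call_significant(d, null, config, never_call = never_call)
  attr(res, "s0_used") <- unname(s0)
  attr(res, "comparison") <- comparison
  res
}

#' Write / read a differential-expression result table
#'
#' @param de a `tsc_de` data.frame.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_de_table <- function(de, path) {
  write_tsv_strict(as.data.frame(de), path)
}
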