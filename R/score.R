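# Projection of the mouse signature onto a human cohort and the per-tumor
# TSC2 expression score: log2(x + 1), per-gene z-scores across tumors,
# down-genes sign-flipped, mean over signature genes.  Tumors are stratified
# by non-silent TSC1/TSC2 mutation status and the groups compared.

#' Map a mouse signature into human gene space
#'
#' Each mapped mouse gene contributes its direction under the human symbol.
#' Mouse genes absent from the map are dropped (count reported in the
#' `dropped` attribute).  When several mouse genes map to one human gene with
#' the same direction a single entry is kept; conflicting directions drop the
#' human gene with a warning.
#'
#' @param signature mouse-space `tsc_signature`.
#' @param ortholog_map data.frame with columns `mouse_gene`, `human_gene`.
#' @return a human-space `tsc_signature` with attribute `dropped` (number of
#'   unmapped mouse genes).
#' @export
map_orthologs <- function(signature, ortholog_map) {
  stopifnot(inherits(signature, "tsc_signature"))
  idx <- match(signature$gene_id, ortholog_map$mouse_gene)
  dropped <- sum(is.na(idx))
  if (dropped)
    message(dropped, " signature gene(s) had no ortholog and were dropped")
  hum <- data.frame(human_gene = ortholog_map$human_gene[idx[!is.na(idx)]],
                    direction = signature$direction[!is.na(idx)],
                    stringsAsFactors = FALSE)
  agg <- unique(hum)
  conflicted <- unique(agg$human_gene[duplicated(agg$human_gene)])
  if (length(conflicted)) {
    warning("conflicting directions for human gene(s) ",
            paste(conflicted, collapse = ", "), "; dropped", call. = FALSE)
    agg <- agg[!agg$human_gene %in% conflicted, , drop = FALSE]
  }
  out <- signature_set(agg$human_gene, agg$direction,
                       meta = c(attr(signature, "meta"), list(space = "human")))
  attr(out, "dropped") <- dropped
  out
}

#' Classify tumors by non-silent mutation status
#'
#' A tumor is mutant iff it has at least one mutation record in a target
#' gene with a variant classification in the non-silent whitelist; every
#' other tumor in the cohort roster is wild type.  Records for tumors absent
#' from the roster are ignored with a warning.
#'
#' @param mutations data.frame from [read_mutation_table()].
#' @param roster character vector of all tumor ids in the cohort.
#' @param target_genes genes defining mutant status (default TSC1, TSC2).
#' @param nonsilent_classes whitelist of variant classifications (default
#'   [default_nonsilent_classes()]).
#' @return named character vector over the roster with values `"mutant"` /
#'   `"wildtype"`.
#' @export
classify_mutants <- function(mutations, roster,
                             target_genes = c("TSC1", "TSC2"),
                             nonsilent_classes = default_nonsilent_classes()) {
  if (!length(nonsilent_classes)) stop_tsc("nonsilent_classes must be non-empty")
  stray <- setdiff(unique(mutations$tumor_id), roster)
  if (length(stray))
    warning(length(stray), " mutation record tumor id(s) not in the cohort roster; ignored",
            call. = FALSE)
  hits <- mutations$tumor_id[mutations$gene_symbol %in% target_genes &
                               mutations$variant_classification %in% nonsilent_classes]
  status <- ifelse(roster %in% hits, "mutant", "wildtype")
  names(status) <- roster
  status
}

#' Compute per-tumor TSC2 expression scores
#'
#' Pipeline: `y = log2(x + 1)`; per gene, z-scores across all tumors using
#' the sample (n - 1) standard deviation; down-genes multiplied by -1; the
#' score is the mean of the direction-aligned z-scores over the signature
#' genes present in the matrix.  Genes missing from the matrix or with zero
#' standard deviation are dropped and counted.
#'
#' @param x raw-scale `ExpressionMatrix` of the cohort (genes x tumors,
#'   >= 2 tumors).
#' @param signature human-space `tsc_signature`.
#' @return data.frame with columns `tumor_id`, `score`, `n_genes_used`, plus
#'   attribute `n_genes_dropped`.
#' @export
score_tumors <- function(x, signature) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(signature, "tsc_signature"))
  if (ncol(x$values) < 2) stop_tsc("z-scores need >= 2 tumors")
  y <- if (x$scale == "raw") log2(x$values + 1) else x$values
  present <- signature$gene_id %in% rownames(y)
  if (!any(present)) stop_tsc("no signature genes present in the cohort matrix")
  sub <- y[signature$gene_id[present], , drop = FALSE]
  dir <- signature$direction[present]
  sds <- apply(sub, 1, stats::sd)
  keep <- sds > 0
  n_dropped <- sum(!present) + sum(!keep)
  sub <- sub[keep, , drop = FALSE]
  dir <- dir[keep]
  if (!nrow(sub)) stop_tsc("all signature genes have zero variance in the cohort")
  z <- (sub - rowMeans(sub)) / sds[keep]
  scores <- colMeans(z * dir)
  out <- data.frame(tumor_id = colnames(y), score = unname(scores),
                    n_genes_used = nrow(sub), stringsAsFactors = FALSE)
  attr(out, "n_genes_dropped") <- n_dropped
  out
}

#' Compare score distributions between tumor groups
#'
#' Two-sided Mann-Whitney U (normal approximation with tie correction; the
#' default) or Welch t test of the values in the two status groups.  Also
#' usable for single-gene contrasts such as LGALS3 z-scores.
#'
#' @param values numeric vector (e.g. per-tumor scores).
#' @param status factor/character vector of two group labels, aligned with
#'   `values`; the first level (or `"wildtype"` if present) is the reference.
#' @param test `"mann_whitney"` or `"welch_t"`.
#' @return list of class `comparison_result`: `statistic`, `p_value`, group
#'   sizes, means and medians.
#' @export
compare_groups <- function(values, status, test = c("mann_whitney", "welch_t")) {
  test <- match.arg(test)
  stopifnot(length(values) == length(status))
  groups <- unique(as.character(status))
  if (length(groups) != 2) stop_tsc("status must define exactly two non-empty groups")
  ref <- if ("wildtype" %in% groups) "wildtype" else groups[1]
  alt <- setdiff(groups, ref)
  v_ref <- values[status == ref]
  v_alt <- values[status == alt]
  if (!length(v_ref) || !length(v_alt)) stop_tsc("both groups must be non-empty")
  if (test == "mann_whitney") {
    ht <- stats::wilcox.test(v_alt, v_ref, exact = FALSE, correct = TRUE)
    stat_name <- "U"
  } else {
    ht <- stats::t.test(v_alt, v_ref)
    stat_name <- "t"
  }
  structure(list(test = test, statistic_name = stat_name,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 n = stats::setNames(c(length(v_ref), length(v_alt)), c(ref, alt)),
                 means = stats::setNames(c(mean(v_ref), mean(v_alt)), c(ref, alt)),
                 medians = stats::setNames(c(stats::median(v_ref), stats::median(v_alt)),
                                           c(ref, alt))),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, p = %.4g (n = %s)\n", x$test, x$statistic_name,
              x$statistic, x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}
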