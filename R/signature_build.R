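# Building the Tsc2 loss-of-function signature from the KO-vs-WT comparison,
# quantifying how much of it sirolimus reverses, and the annotation-category
# candidate screen.

#' Build a directional signature from a differential-expression result
#'
#' All called genes enter the signature with direction `sign(d)`: +1 for
#' genes over-expressed in the Tsc2-deficient (KO) state, -1 for genes
#' under-expressed.
#'
#' @param de a `tsc_de` result from the KO-vs-WT comparison.
#' @return a `tsc_signature`; empty (with a warning) if nothing was called.
#' @export
build_signature <- function(de) {
  stopifnot(inherits(de, "tsc_de"))
  hit <- de[de$called, , drop = FALSE]
  if (!nrow(hit)) warning("no called genes; signature is empty", call. = FALSE)
  signature_set(hit$gene_id, as.integer(sign(hit$d)),
                meta = list(source = attr(de, "comparison"),
                            fdr_target = attr(de, "fdr_target"),
                            n_up = sum(hit$d > 0), n_down = sum(hit$d < 0)))
}

#' Quantify sirolimus reversal of the signature
#'
#' A signature up-gene counts as reversed when the paired
#' sirolimus-vs-vehicle comparison calls it significantly *down*
#' (direction -1), and vice versa for down-genes: reversal requires a
#' significant opposite-direction call, not merely an opposite-sign
#' statistic.  Percentages are rounded half up to integers.
#'
#' @param signature a `tsc_signature`.
#' @param de_sirolimus a `tsc_de` from the sirolimus-vs-vehicle paired
#'   comparison over the same gene universe.
#' @return list of class `correction_report` with counts, gene lists and
#'   rounded percentages for both directions.
#' @export
sirolimus_correction <- function(signature, de_sirolimus) {
  stopifnot(inherits(signature, "tsc_signature"), inherits(de_sirolimus, "tsc_de"))
  missing <- setdiff(signature$gene_id, de_sirolimus$gene_id)
  if (length(missing))
    stop_tsc("gene universe mismatch; signature genes absent from DE result, e.g.: ",
             paste(utils::head(missing, 5), collapse = ", "))
  called_dir <- ifelse(de_sirolimus$called, de_sirolimus$direction, 0L)
  names(called_dir) <- de_sirolimus$gene_id

  up <- signature$gene_id[signature$direction == 1L]
  down <- signature$gene_id[signature$direction == -1L]
  up_rev <- up[called_dir[up] == -1L]
  down_rev <- down[called_dir[down] == 1L]
  pct <- function(n, N) if (N == 0) NA_integer_ else round_half_up(100 * n / N)
  structure(list(
    n_up_in_ko = length(up), n_up_reversed = length(up_rev),
    pct_up_reversed = pct(length(up_rev), length(up)),
    n_down_in_ko = length(down), n_down_reversed = length(down_rev),
    pct_down_reversed = pct(length(down_rev), length(down)),
    up_reversed = up_rev, down_reversed = down_rev),
    class = "correction_report")
}

#' @export
print.correction_report <- function(x, ...) {
  cat(sprintf("sirolimus reversal: up-in-KO %d/%d reversed (%s%%); down-in-KO %d/%d reversed (%s%%)\n",
              x$n_up_reversed, x$n_up_in_ko, x$pct_up_reversed,
              x$n_down_reversed, x$n_down_in_ko, x$pct_down_reversed))
  invisible(x)
}

#' Fraction of one call set shared with another
#'
#' Computes the rounded percentage of `de_a`'s called genes of a given
#' direction that are also called with the same direction in `de_b`.
#' `de_a` is the putative subset side (e.g. the WT sirolimus response when
#' asking how much of it is contained in the KO response).
#'
#' @param de_a,de_b `tsc_de` results over the same gene universe.
#' @param direction +1 or -1.
#' @return integer percentage, or `NA` (with attribute `reason`) if `de_a`
#'   calls no genes in that direction.
#' @export
common_gene_fraction <- function(de_a, de_b, direction) {
  stopifnot(direction %in% c(-1L, 1L))
  missing <- setdiff(de_a$gene_id, de_b$gene_id)
  if (length(missing))
    stop_tsc("gene universe mismatch, e.g.: ",
             paste(utils::head(missing, 5), collapse = ", "))
  a <- de_a$gene_id[de_a$called & de_a$direction == direction]
  b <- de_b$gene_id[de_b$called & de_b$direction == direction]
  if (!length(a))
    return(structure(NA_integer_, reason = "no called genes in de_a for this direction"))
  round_half_up(100 * length(intersect(a, b)) / length(a))
}

#' Screen genes for membership in all required annotation categories
#'
#' Local stand-in for an ontology over-representation portal: keeps the
#' genes whose category set contains every required category, preserving the
#' input order.  Genes absent from the annotation table have no categories.
#'
#' @param genes character vector of candidate genes.
#' @param annotations data.frame with columns `gene_id`, `category` (one row
#'   per pair), as from [read_annotation_table()].
#' @param required_categories non-empty character vector.
#' @return character vector of retained genes.
#' @examples
#' ann <- data.frame(gene_id = c("Lgals3", "Lgals3", "Vegfa"),
#'                   category = c("extracellular region", "signaling",
#'                                "signaling"))
#' annotate_candidates(c("Lgals3", "Vegfa"), ann,
#'                     c("extracellular region", "signaling"))
#' @export
annotate_candidates <- function(genes, annotations, required_categories) {
  if (!length(required_categories)) stop_tsc("required_categories must be non-empty")
  keep <- vapply(genes, function(g) {
    cats <- annotations$category[annotations$gene_id == g]
    all(required_categories %in% cats)
  }, logical(1))
  genes[keep]
}
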