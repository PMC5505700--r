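# Expression matrices: genes in rows, samples in columns, with an explicit
# scale tag distinguishing raw abundances (FPKM / normalized RSEM style,
# non-negative) from log2(x + 1) transformed values.

#' Construct an expression matrix
#'
#' Wraps a numeric genes x samples matrix together with a scale tag and
#' validates the container invariants: unique gene and sample identifiers,
#' finite values, and non-negativity on the raw scale.
#'
#' @param values numeric matrix with gene identifiers as rownames and sample
#'   identifiers as colnames.
#' @param scale `"raw"` for untransformed non-negative abundances or
#'   `"log2p1"` for values already on the log2(x + 1) scale.
#' @return an `ExpressionMatrix` object (a list with elements `values` and
#'   `scale`).
#' @examples
#' m <- matrix(c(0, 1, 3, 7), 2, 2,
#'             dimnames = list(c("Lgals3", "Tsc2"), c("s1", "s2")))
#' expression_matrix(m, "raw")
#' @export
expression_matrix <- function(values, scale = c("raw", "log2p1")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop_tsc("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_tsc("`values` must carry gene rownames and sample colnames")
  x <- structure(list(values = values, scale = scale),
                 class = "ExpressionMatrix")
  validate_expression_matrix(x)
  x
}

validate_expression_matrix <- function(x) {
  v <- x$values
  dup_g <- rownames(v)[duplicated(rownames(v))]
  if (length(dup_g))
    stop_tsc("duplicate gene identifier(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(v)[duplicated(colnames(v))]
  if (length(dup_s))
    stop_tsc("duplicate sample identifier(s): ", paste(unique(dup_s), collapse = ", "))
  bad <- which(!is.finite(v), arr.ind = TRUE)
  if (nrow(bad))
    stop_tsc("non-finite value at gene '", rownames(v)[bad[1, 1]],
             "', sample '", colnames(v)[bad[1, 2]], "'")
  if (x$scale == "raw") {
    neg <- which(v < 0, arr.ind = TRUE)
    if (nrow(neg))
      stop_tsc("negative raw expression value at gene '",
               rownames(v)[neg[1, 1]], "', sample '", colnames(v)[neg[1, 2]], "'")
  }
  invisible(x)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (scale: %s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' Expects a tab-delimited file whose first column holds gene identifiers and
#' whose remaining columns (one per sample, named in the header) hold numeric
#' expression values.  Row and column order are preserved.
#'
#' @param path file path.
#' @param scale scale tag of the stored values (see [expression_matrix()]).
#' @return an `ExpressionMatrix`.
#' @export
read_expression_matrix <- function(path, scale = c("raw", "log2p1")) {
  scale <- match.arg(scale)
  df <- read_tsv_strict(path, colClasses = "character")
  if (ncol(df) < 2)
    stop_tsc("expression TSV needs a gene-id column plus >= 1 sample column: ", path)
  gene_ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop_tsc("non-numeric cell '", vals[bad[1, 1], bad[1, 2]], "' at gene '",
             gene_ids[bad[1, 1]], "', sample '", colnames(vals)[bad[1, 2]], "'")
  dimnames(num) <- list(gene_ids, colnames(vals))
  expression_matrix(num, scale)
}

#' Write an expression matrix to TSV
#'
#' @param x an `ExpressionMatrix`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
}

#' Apply the log2(x + 1) transform
#'
#' Every analysis stage operates on `log2(x + 1)` transformed abundances;
#' this converts a raw-scale matrix and retags it.  Applying it to an
#' already-transformed matrix is an error so the transform cannot be stacked
#' silently.
#'
#' @param x a raw-scale `ExpressionMatrix`.
#' @return the transformed `ExpressionMatrix` with scale `"log2p1"`.
#' @examples
#' m <- matrix(c(0, 1, 3, 7), 2, 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' log_transform(expression_matrix(m, "raw"))$values
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "raw")
    stop_tsc("matrix is already on the log2(x + 1) scale")
  expression_matrix(log2(x$values + 1), "log2p1")
}
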