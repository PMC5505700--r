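# Readers and writers for the tabular artifacts around the expression matrix:
# sample metadata, MAF-dialect mutation tables, signatures, ortholog maps and
# gene-annotation tables.  All are strict TSV.

#' Read a sample metadata table
#'
#' Columns: `sample_id`, `genotype` (WT/KO), `treatment` (vehicle/sirolimus)
#' and optionally `pair_id` linking the vehicle and sirolimus members of the
#' same cell line.
#'
#' @param path file path.
#' @param expression optional `ExpressionMatrix`; when given, every sample_id
#'   must be a column of the matrix.
#' @return a data.frame of sample metadata.
#' @export
read_sample_table <- function(path, expression = NULL) {
  df <- read_tsv_strict(path, colClasses = "character")
  need <- c("sample_id", "genotype", "treatment")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_tsc("sample table missing column(s): ", paste(miss, collapse = ", "))
  if (!"pair_id" %in% names(df)) df$pair_id <- NA_character_
  validate_sample_table(df, expression)
  df
}

#' Validate a sample metadata table
#'
#' Checks identifier uniqueness, the genotype/treatment vocabularies, and
#' (optionally) that every sample is a column of an expression matrix.
#'
#' @param df sample table data.frame.
#' @param expression optional `ExpressionMatrix` companion.
#' @return the table, invisibly; errors describe the first violation.
#' @export
validate_sample_table <- function(df, expression = NULL) {
  if (anyDuplicated(df$sample_id))
    stop_tsc("duplicate sample_id in sample table")
  bad_g <- setdiff(unique(df$genotype), c("WT", "KO"))
  if (length(bad_g))
    stop_tsc("unknown genotype value(s): ", paste(bad_g, collapse = ", "))
  bad_t <- setdiff(unique(df$treatment), c("vehicle", "sirolimus"))
  if (length(bad_t))
    stop_tsc("unknown treatment value(s): ", paste(bad_t, collapse = ", "))
  if (!is.null(expression)) {
    miss <- setdiff(df$sample_id, colnames(expression$values))
    if (length(miss))
      stop_tsc("sample(s) absent from expression matrix: ",
               paste(miss, collapse = ", "))
  }
  invisible(df)
}

#' Read a MAF-dialect mutation table
#'
#' Needs three columns: tumor identifier, gene symbol and variant
#' classification.  Standard MAF column names
#' (`Tumor_Sample_Barcode`, `Hugo_Symbol`, `Variant_Classification`) are
#' accepted by default alongside plain synonyms; extra columns are ignored
#' and unknown classification strings are preserved verbatim.
#'
#' @param path file path.
#' @param synonyms named list giving accepted header names for the three
#'   fields `tumor_id`, `gene_symbol` and `variant_classification`.
#' @return a data.frame with columns `tumor_id`, `gene_symbol`,
#'   `variant_classification`, one row per mutation record.
#' @export
read_mutation_table <- function(path, synonyms = list(
    tumor_id = c("tumor_id", "Tumor_Sample_Barcode"),
    gene_symbol = c("gene_symbol", "Hugo_Symbol"),
    variant_classification = c("variant_classification", "Variant_Classification"))) {
  df <- read_tsv_strict(path, colClasses = "character")
  pick <- function(field) {
    hit <- intersect(synonyms[[field]], names(df))
    if (!length(hit))
      stop_tsc("mutation table missing a column for '", field,
               "' (accepted names: ", paste(synonyms[[field]], collapse = ", "), ")")
    df[[hit[1]]]
  }
  out <- data.frame(tumor_id = pick("tumor_id"),
                    gene_symbol = pick("gene_symbol"),
                    variant_classification = pick("variant_classification"),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$tumor_id)) || any(!nzchar(out$gene_symbol)))
    stop_tsc("mutation table contains empty tumor_id or gene_symbol")
  out
}

#' Construct a directional gene signature
#'
#' A signature is an ordered map from gene identifier to direction: +1 for
#' genes up in the Tsc2-deficient (KO) state, -1 for genes down.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param direction integer vector of +1/-1, recycled if length 1.
#' @param meta optional list of provenance metadata (source comparison, FDR
#'   target, per-direction counts).
#' @return a `tsc_signature` data.frame.
#' @export
signature_set <- function(gene_id, direction, meta = list()) {
  if (length(direction) == 1L) direction <- rep(direction, length(gene_id))
  if (length(gene_id) != length(direction))
    stop_tsc("gene_id and direction lengths differ")
  if (anyDuplicated(gene_id))
    stop_tsc("duplicate gene_id in signature: ",
             paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (length(direction) && !all(direction %in% c(-1L, 1L)))
    stop_tsc("signature directions must be +1 or -1")
  structure(data.frame(gene_id = as.character(gene_id),
                       direction = as.integer(direction),
                       stringsAsFactors = FALSE),
            meta = meta, class = c("tsc_signature", "data.frame"))
}

#' Read a signature TSV
#'
#' Two columns: `gene_id` and `direction`, with direction encoded as
#' `up`/`down` or `+1`/`-1`.  A header-only file yields an empty signature
#' with a warning.
#'
#' @param path file path.
#' @return a `tsc_signature`.
#' @export
read_signature <- function(path) {
  df <- read_tsv_strict(path, colClasses = "character")
  miss <- setdiff(c("gene_id", "direction"), names(df))
  if (length(miss))
    stop_tsc("signature file missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) {
    warning("empty signature file: ", path, call. = FALSE)
    return(signature_set(character(), integer()))
  }
  tok <- df$direction
  dir <- ifelse(tok %in% c("up", "+1", "1"), 1L,
                ifelse(tok %in% c("down", "-1"), -1L, NA_integer_))
  if (anyNA(dir))
    stop_tsc("bad direction token(s): ",
             paste(unique(tok[is.na(dir)]), collapse = ", "),
             " (accepted: up, down, +1, -1)")
  signature_set(df$gene_id, dir)
}

#' Write a signature TSV
#'
#' Round-trip stable with [read_signature()].
#'
#' @param sig a `tsc_signature`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "tsc_signature"))
  df <- data.frame(gene_id = sig$gene_id,
                   direction = ifelse(sig$direction > 0, "up", "down"),
                   stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
}

#' Read a two-column mouse-to-human ortholog map
#'
#' @param path TSV with columns `mouse_gene` and `human_gene`.
#' @return a data.frame; duplicate mouse genes are an error (the map must be
#'   resolved to at most one human symbol per mouse gene before use).
#' @export
read_ortholog_map <- function(path) {
  df <- read_tsv_strict(path, colClasses = "character")
  miss <- setdiff(c("mouse_gene", "human_gene"), names(df))
  if (length(miss))
    stop_tsc("ortholog map missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$mouse_gene))
    stop_tsc("ortholog map has duplicate mouse_gene entries: ",
             paste(unique(df$mouse_gene[duplicated(df$mouse_gene)]), collapse = ", "))
  df
}

#' Read a gene-annotation table
#'
#' One row per gene-category pair (columns `gene_id`, `category`), as used by
#' the local annotation-category candidate screen.
#'
#' @param path file path.
#' @return a data.frame with columns `gene_id` and `category`.
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv_strict(path, colClasses = "character")
  miss <- setdiff(c("gene_id", "category"), names(df))
  if (length(miss))
    stop_tsc("annotation table missing column(s): ", paste(miss, collapse = ", "))
  if (any(!nzchar(df$category)))
    stop_tsc("annotation table contains empty category strings")
  df
}
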