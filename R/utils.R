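# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero to the nearest integer
#'
#' Planted-set sizes and reported percentages use commercial ("half up")
#' rounding rather than R's banker's rounding, so counts like
#' `round_half_up(0.5) == 1` are reproducible across platforms.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4))
#' @export
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Strict TSV writer: tab-delimited, "." decimal, no quoting, UTF-8.
write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_strict <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8", ...)
}

# Deterministic per-stage seed derived from the global seed and a stage name.
# Keeps derived seeds in the 32-bit integer range.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

stop_tsc <- function(...) stop(..., call. = FALSE)
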