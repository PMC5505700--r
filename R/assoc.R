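# Clinical association statistics: Pearson and one-covariate partial
# correlation with t-based two-sided p-values, factorial simple main
# effects, and group percent changes.

#' Pearson correlation with a two-sided t-based p-value
#'
#' Standard product-moment correlation; `p` from
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3, nonzero variance).
#' @return list of class `correlation_result`: `r`, `p_value`, `n`, `df`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop_tsc("x and y lengths differ")
  n <- length(x)
  if (n < 3) stop_tsc("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_tsc("zero variance in x or y")
  r <- stats::cor(x, y)
  p <- cor_p(r, df = n - 2)
  structure(list(r = r, p_value = p, n = n, df = n - 2, type = "pearson"),
            class = "correlation_result")
}

cor_p <- function(r, df) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t), df)
}

#' Partial correlation adjusting for one covariate
#'
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, with a
#' two-sided p from t on `n - 3` degrees of freedom.
#'
#' @param x,y numeric vectors; `z` the covariate (all equal length, n >= 4).
#' @return list of class `correlation_result`.
#' @export
partial_cor <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop_tsc("x, y, z lengths differ")
  if (n < 4) stop_tsc("need n >= 4")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop_tsc("covariate is collinear with x or y; partial correlation degenerate")
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  structure(list(r = r, p_value = cor_p(r, df = n - 3), n = n, df = n - 3,
                 type = "partial"),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.4f, p = %.4g (n = %d, df = %d)\n",
              x$type, x$r, x$p_value, x$n, x$df))
  invisible(x)
}

#' Two-way factorial ANOVA with simple main effects
#'
#' Fits the full two-factor interaction model, reports Type III omnibus
#' tests (sum-to-zero contrasts), and estimates the simple main effect of
#' `factor_a` at each level of `factor_b` as a contrast of cell means with
#' the pooled residual variance of the full model.
#'
#' @param value numeric response.
#' @param factor_a,factor_b binary factors/characters aligned with `value`;
#'   all four cells must be non-empty.
#' @return list of class `simple_effects`: `omnibus` (Type III table) and
#'   `simple` (one row per level of `factor_b`: estimate, se, t, df, p).
#' @export
two_way_simple_effects <- function(value, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  if (nlevels(a) != 2 || nlevels(b) != 2)
    stop_tsc("both factors must have exactly two levels")
  counts <- table(a, b)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop_tsc("empty cell: ", levels(a)[bad[1]], " x ", levels(b)[bad[2]])
  }
  df <- data.frame(value = value, a = a, b = b)
  fit3 <- stats::lm(value ~ a * b, data = df,
                    contrasts = list(a = "contr.sum", b = "contr.sum"))
  # omnibus is undefined when the cells are fit exactly (zero residuals)
  omni <- tryCatch(car::Anova(fit3, type = 3), error = function(e) NULL)

  fit_cells <- stats::lm(value ~ 0 + a:b, data = df)
  sigma2 <- sum(stats::residuals(fit_cells)^2) / stats::df.residual(fit_cells)
  cell_mean <- tapply(df$value, list(df$a, df$b), mean)
  simple <- do.call(rbind, lapply(levels(b), function(lb) {
    n1 <- counts[1, lb]; n2 <- counts[2, lb]
    est <- cell_mean[2, lb] - cell_mean[1, lb]
    se <- sqrt(sigma2 * (1 / n1 + 1 / n2))
    tval <- est / se
    dfr <- stats::df.residual(fit_cells)
    data.frame(level_b = lb,
               estimate = est, se = se, t = tval, df = dfr,
               p_value = 2 * stats::pt(-abs(tval), dfr),
               stringsAsFactors = FALSE)
  }))
  rownames(simple) <- NULL
  structure(list(omnibus = omni, simple = simple), class = "simple_effects")
}

#' Percent change between group means
#'
#' `100 * (mean_alt - mean_ref) / mean_ref`, reported alongside the rounded
#' integer value and a Welch t p-value.
#'
#' @param group_ref,group_alt numeric vectors; the reference mean must be
#'   nonzero.
#' @return list: `pct_change` (exact), `pct_change_rounded`, `p_value`,
#'   `means`.
#' @export
percent_change <- function(group_ref, group_alt) {
  m_ref <- mean(group_ref); m_alt <- mean(group_alt)
  if (m_ref == 0) stop_tsc("reference group mean is zero")
  pct <- 100 * (m_alt - m_ref) / m_ref
  p <- if (length(group_ref) > 1 && length(group_alt) > 1)
    stats::t.test(group_alt, group_ref)$p.value else NA_real_
  list(pct_change = pct, pct_change_rounded = round_half_up(pct),
       p_value = p, means = c(ref = m_ref, alt = m_alt))
}
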