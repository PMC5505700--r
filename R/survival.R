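# Kaplan-Meier estimation and the two-group log-rank test, via the survival
# package, with the median convention fixed as the smallest observed time at
# which S(t) drops to 0.5 or below.

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive event/censoring times.
#' @param events logical (or 0/1) event indicators; censored records are
#'   `FALSE`.
#' @return list of class `km_curve`: `time`, `n_risk`, `n_event`, `surv`
#'   (the step function evaluated at the observed times) and `median`
#'   (smallest time with `S(t) <= 0.5`, `NA` if the curve never reaches 0.5).
#' @export
km_estimate <- function(times, events) {
  if (any(times <= 0)) stop_tsc("survival times must be positive")
  if (length(times) != length(events)) stop_tsc("times and events lengths differ")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  # tolerance: the product-limit estimate of an exact 0.5 step can land a few
  # ulps above 0.5, which would otherwise shift the median to the next event
  at_half <- fit$surv <= 0.5 + 1e-9
  med <- if (any(at_half)) min(fit$time[at_half]) else NA_real_
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 surv = fit$surv, median = med),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve over %d time points; median = %s\n",
              length(x$time),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param times positive event/censoring times.
#' @param events event indicators (censored = FALSE/0).
#' @param groups vector with exactly two distinct labels.
#' @return list: `chi_square` (1 df) and `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  if (length(unique(groups)) != 2)
    stop_tsc("log-rank test needs exactly two groups")
  if (any(times <= 0)) stop_tsc("survival times must be positive")
  sd <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ g,
                           data = data.frame(times = times, events = events,
                                             g = factor(groups)))
  chi <- unname(sd$chisq)
  list(chi_square = chi, p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}
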