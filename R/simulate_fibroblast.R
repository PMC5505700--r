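# Synthetic stand-in for the mouse fibroblast RNA-seq experiment: WT and
# Tsc2-KO neonatal dermal fibroblast lines, each profiled under vehicle and
# sirolimus, with planted KO-responsive genes of which a stated fraction is
# reversed by sirolimus.  All data are generated on the log2(x + 1) scale the
# analysis operates on and back-transformed to raw abundances.

#' Simulate a fibroblast KO/sirolimus experiment
#'
#' Generates a raw-scale expression matrix over `4 * n_lines` samples:
#' `n_lines` WT and `n_lines` KO lines, each with a vehicle and a sirolimus
#' sample (paired within line).  Planted KO-up and KO-down genes receive
#' `+/- effect_size_logfc` in KO samples; for the "reversed" subset the KO
#' effect is removed in KO + sirolimus samples.  A configurable shared set of
#' sirolimus-responsive genes shifts in all sirolimus samples (emulating the
#' treatment response seen in WT cells, largely a subset of the KO response),
#' and an additional KO-only sirolimus-responsive set shifts only in
#' KO + sirolimus samples.
#'
#' @param n_genes number of genes.
#' @param n_lines cell lines per genotype (>= 2; the study design uses 3).
#' @param frac_up_in_ko,frac_down_in_ko proportions of genes planted up/down
#'   in KO (must sum to <= 1).
#' @param effect_size_logfc planted KO effect in log2 units.
#' @param frac_reversed_up,frac_reversed_down fractions of the planted up and
#'   down genes whose KO effect is removed by sirolimus (defaults 0.92 and
#'   0.80, the reversal fractions the analysis is designed to detect).
#' @param frac_sir_shared_down,frac_sir_shared_up fractions of background
#'   genes down-/up-shifted by sirolimus in both genotypes.
#' @param frac_sir_ko_only_down fraction of background genes down-shifted by
#'   sirolimus only in KO cells (the KO treatment response exceeds the WT
#'   response).
#' @param sirolimus_effect_logfc magnitude of the treatment shifts above.
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @param line_sd sd of the per-line random intercept shared by the vehicle
#'   and sirolimus samples of a line (makes pairing informative).
#' @param baseline_log_mean,baseline_log_sd per-gene baseline distribution on
#'   the log2 scale.
#' @param seed integer seed; equal seeds give byte-identical outputs.
#' @return a list with elements `expression` (raw-scale
#'   [expression_matrix()]), `samples` (sample table with `sample_id`,
#'   `genotype`, `treatment`, `pair_id`) and `truth` (planted gene sets,
#'   reversal flags and the echoed parameters).
#' @export
simulate_fibroblast_experiment <- function(n_genes = 2000,
                                           n_lines = 3,
                                           frac_up_in_ko = 0.10,
                                           frac_down_in_ko = 0.05,
                                           effect_size_logfc = 2,
                                           frac_reversed_up = 0.92,
                                           frac_reversed_down = 0.80,
                                           frac_sir_shared_down = 0.10,
                                           frac_sir_shared_up = 0.01,
                                           frac_sir_ko_only_down = 0.10,
                                           sirolimus_effect_logfc = effect_size_logfc,
                                           noise_sd = 0.5,
                                           line_sd = 0.2,
                                           baseline_log_mean = 3,
                                           baseline_log_sd = 1.5,
                                           seed = 1) {
  if (n_lines < 2) stop_tsc("n_lines must be >= 2 (the paired design is undefined otherwise)")
  props <- c(frac_up_in_ko, frac_down_in_ko, frac_reversed_up, frac_reversed_down,
             frac_sir_shared_down, frac_sir_shared_up, frac_sir_ko_only_down)
  if (any(props < 0 | props > 1)) stop_tsc("all fractions must lie in [0, 1]")
  if (frac_up_in_ko + frac_down_in_ko > 1)
    stop_tsc("frac_up_in_ko + frac_down_in_ko must be <= 1")
  set.seed(as.integer(seed))

  genes <- sprintf("mgene_%05d", seq_len(n_genes))
  n_up <- round_half_up(frac_up_in_ko * n_genes)
  n_down <- round_half_up(frac_down_in_ko * n_genes)
  up_genes <- genes[seq_len(n_up)]
  down_genes <- genes[n_up + seq_len(n_down)]
  background <- setdiff(genes, c(up_genes, down_genes))

  n_rev_up <- round_half_up(frac_reversed_up * n_up)
  n_rev_down <- round_half_up(frac_reversed_down * n_down)
  rev_up <- up_genes[seq_len(n_rev_up)]
  rev_down <- down_genes[seq_len(n_rev_down)]

  n_shared_down <- round_half_up(frac_sir_shared_down * length(background))
  n_shared_up <- round_half_up(frac_sir_shared_up * length(background))
  n_ko_only_down <- round_half_up(frac_sir_ko_only_down * length(background))
  sir_shared_down <- background[seq_len(n_shared_down)]
  sir_shared_up <- background[n_shared_down + seq_len(n_shared_up)]
  sir_ko_only_down <- background[n_shared_down + n_shared_up + seq_len(n_ko_only_down)]

  samples <- data.frame(
    sample_id = c(sprintf("WT_veh_L%d", seq_len(n_lines)),
                  sprintf("KO_veh_L%d", seq_len(n_lines)),
                  sprintf("WT_sir_L%d", seq_len(n_lines)),
                  sprintf("KO_sir_L%d", seq_len(n_lines))),
    genotype = rep(c("WT", "KO", "WT", "KO"), each = n_lines),
    treatment = rep(c("vehicle", "sirolimus"), each = 2 * n_lines),
    pair_id = c(sprintf("WT_L%d", seq_len(n_lines)), sprintf("KO_L%d", seq_len(n_lines)),
                sprintf("WT_L%d", seq_len(n_lines)), sprintf("KO_L%d", seq_len(n_lines))),
    stringsAsFactors = FALSE)

  baseline <- stats::rnorm(n_genes, baseline_log_mean, baseline_log_sd)
  ko_eff <- numeric(n_genes)
  names(ko_eff) <- genes
  ko_eff[up_genes] <- effect_size_logfc
  ko_eff[down_genes] <- -effect_size_logfc
  reversed <- genes %in% c(rev_up, rev_down)
  names(reversed) <- genes

  sir_shift <- numeric(n_genes)
  names(sir_shift) <- genes
  sir_shift[sir_shared_down] <- -sirolimus_effect_logfc
  sir_shift[sir_shared_up] <- sirolimus_effect_logfc
  sir_ko_shift <- numeric(n_genes)
  names(sir_ko_shift) <- genes
  sir_ko_shift[sir_ko_only_down] <- -sirolimus_effect_logfc

  line_ids <- unique(samples$pair_id)
  line_eff <- stats::rnorm(length(line_ids), 0, line_sd)
  names(line_eff) <- line_ids

  y <- matrix(0, n_genes, nrow(samples), dimnames = list(genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    s <- samples[j, ]
    mu <- baseline + line_eff[[s$pair_id]]
    if (s$genotype == "KO") {
      eff <- ko_eff
      if (s$treatment == "sirolimus") eff[reversed] <- 0
      mu <- mu + eff
      if (s$treatment == "sirolimus") mu <- mu + sir_shift + sir_ko_shift
    } else if (s$treatment == "sirolimus") {
      mu <- mu + sir_shift
    }
    y[, j] <- mu + stats::rnorm(n_genes, 0, noise_sd)
  }
  raw <- pmax(2^y - 1, 0)

  truth <- list(up_in_ko = up_genes, down_in_ko = down_genes,
                reversed_up = rev_up, reversed_down = rev_down,
                sirolimus_shared_down = sir_shared_down,
                sirolimus_shared_up = sir_shared_up,
                sirolimus_ko_only_down = sir_ko_only_down,
                log_matrix = y,
                params = list(n_genes = n_genes, n_lines = n_lines,
                              frac_up_in_ko = frac_up_in_ko,
                              frac_down_in_ko = frac_down_in_ko,
                              effect_size_logfc = effect_size_logfc,
                              frac_reversed_up = frac_reversed_up,
                              frac_reversed_down = frac_reversed_down,
                              noise_sd = noise_sd, line_sd = line_sd,
                              baseline_log_mean = baseline_log_mean,
                              baseline_log_sd = baseline_log_sd,
                              seed = seed))
  list(expression = expression_matrix(raw, "raw"),
       samples = samples,
       truth = truth)
}
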