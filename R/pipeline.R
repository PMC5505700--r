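# End-to-end orchestration: simulate the fibroblast experiment, run the
# three SAM comparisons, build the signature and its reversal report,
# simulate and score the tumor cohort, and compare score distributions by
# mutation status.  Every artifact is written as TSV/JSON with a checksum
# manifest; a single global seed fans out to per-stage derived seeds.

#' Default pipeline configuration
#'
#' A flat, namespaced key-value set covering all module parameters.  Every
#' key has a default; unknown keys are rejected by [validate_config()].
#'
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1,
    fib.n_genes = 2000, fib.n_lines = 3,
    fib.frac_up = 0.10, fib.frac_down = 0.05,
    fib.effect_size_logfc = 2,
    fib.frac_reversed_up = 0.92, fib.frac_reversed_down = 0.80,
    fib.noise_sd = 0.5, fib.line_sd = 0.2,
    fib.baseline_log_mean = 3, fib.baseline_log_sd = 1.5,
    sam.fdr_target = 0.10, sam.s0_mode = "auto", sam.fdr_stat = "mean",
    sam.max_exhaustive_perms = 5000, sam.n_sampled_perms = 1000,
    sam.n_delta = 50,
    cohort.n_tumors = 391, cohort.frac_mutant = 43 / 391,
    cohort.mutant_shift_logfc = 0.5, cohort.noise_sd = 1,
    cohort.n_background_genes = 1000,
    score.test = "mann_whitney")
}

#' Validate and resolve a pipeline configuration
#'
#' Reads a YAML key-value file (or takes a list), fills defaults, rejects
#' unknown keys with a nearest-match suggestion, and type-checks values
#' against the defaults.
#'
#' @param config path to a YAML file, a named list of overrides, or `NULL`
#'   for pure defaults.
#' @return resolved named list.
#' @export
validate_config <- function(config = NULL) {
  defaults <- pipeline_defaults()
  over <- if (is.null(config)) list()
  else if (is.character(config)) yaml::read_yaml(config) %||% list()
  else if (is.list(config)) config
  else stop_tsc("config must be a file path, a list, or NULL")
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    sugg <- vapply(unknown, function(k) {
      dist <- utils::adist(k, names(defaults))
      names(defaults)[which.min(dist)]
    }, character(1))
    stop_tsc("unknown config key(s): ",
             paste(sprintf("'%s' (did you mean '%s'?)", unknown, sugg),
                   collapse = ", "))
  }
  out <- utils::modifyList(defaults, over)
  for (k in names(out)) {
    want_num <- is.numeric(defaults[[k]])
    if (want_num && !is.numeric(out[[k]]))
      stop_tsc("config key '", k, "' must be numeric, got: ", out[[k]])
    if (!want_num && !is.character(out[[k]]))
      stop_tsc("config key '", k, "' must be a string, got class ",
               class(out[[k]])[1])
  }
  out
}

#' Run the full analysis pipeline
#'
#' Stages: fibroblast simulation; SAM differential expression for KO vs WT
#' (vehicle, unpaired) and sirolimus vs vehicle within KO and within WT
#' (paired); signature construction; sirolimus reversal report and
#' common-gene fractions; tumor cohort simulation; ortholog mapping;
#' per-tumor scoring; mutant-vs-wildtype comparison.  All artifacts plus a
#' checksum manifest and a readable summary are written to `outdir`.
#' Identical configurations produce byte-identical artifacts.
#'
#' @param config see [validate_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_full_pipeline <- function(config = NULL, outdir) {
  cfg <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  art <- function(name) file.path(outdir, name)
  written <- character()
  log_info <- function(...) message("[tsc2sig] ", ...)

  log_info("stage 1/6: simulating fibroblast experiment")
  fib <- simulate_fibroblast_experiment(
    n_genes = cfg$fib.n_genes, n_lines = cfg$fib.n_lines,
    frac_up_in_ko = cfg$fib.frac_up, frac_down_in_ko = cfg$fib.frac_down,
    effect_size_logfc = cfg$fib.effect_size_logfc,
    frac_reversed_up = cfg$fib.frac_reversed_up,
    frac_reversed_down = cfg$fib.frac_reversed_down,
    noise_sd = cfg$fib.noise_sd, line_sd = cfg$fib.line_sd,
    baseline_log_mean = cfg$fib.baseline_log_mean,
    baseline_log_sd = cfg$fib.baseline_log_sd,
    seed = derive_seed(cfg$seed, "fibroblast"))
  write_expression_matrix(fib$expression, art("fibroblast_expression.tsv"))
  write_tsv_strict(fib$samples, art("fibroblast_samples.tsv"))
  written <- c(written, "fibroblast_expression.tsv", "fibroblast_samples.tsv")

  log_info("stage 2/6: SAM differential expression (3 comparisons)")
  scfg <- sam_config(fdr_target = cfg$sam.fdr_target,
                     s0_mode = cfg$sam.s0_mode,
                     fdr_stat = cfg$sam.fdr_stat,
                     max_exhaustive_perms = cfg$sam.max_exhaustive_perms,
                     n_sampled_perms = cfg$sam.n_sampled_perms,
                     n_delta = cfg$sam.n_delta,
                     seed = derive_seed(cfg$seed, "sam"))
  de_ko <- differential_expression(fib$expression, fib$samples,
                                   "ko_vs_wt_vehicle", scfg)
  de_sir_ko <- differential_expression(fib$expression, fib$samples,
                                       "sir_vs_veh_in_ko", scfg)
  de_sir_wt <- differential_expression(fib$expression, fib$samples,
                                       "sir_vs_veh_in_wt", scfg)
  write_de_table(de_ko, art("de_ko_vs_wt.tsv"))
  write_de_table(de_sir_ko, art("de_sirolimus_in_ko.tsv"))
  write_de_table(de_sir_wt, art("de_sirolimus_in_wt.tsv"))
  written <- c(written, "de_ko_vs_wt.tsv", "de_sirolimus_in_ko.tsv",
               "de_sirolimus_in_wt.tsv")

  log_info("stage 3/6: signature and sirolimus reversal")
  sig <- build_signature(de_ko)
  write_signature(sig, art("signature_mouse.tsv"))
  corr <- sirolimus_correction(sig, de_sir_ko)
  corr_df <- data.frame(direction = c("up_in_ko", "down_in_ko"),
                        n_signature = c(corr$n_up_in_ko, corr$n_down_in_ko),
                        n_reversed = c(corr$n_up_reversed, corr$n_down_reversed),
                        pct_reversed = c(corr$pct_up_reversed, corr$pct_down_reversed))
  write_tsv_strict(corr_df, art("correction_report.tsv"))
  common <- data.frame(
    direction = c("up", "down"),
    pct_wt_in_ko = c(as.integer(common_gene_fraction(de_sir_wt, de_sir_ko, 1L)),
                     as.integer(common_gene_fraction(de_sir_wt, de_sir_ko, -1L))))
  write_tsv_strict(common, art("common_gene_fractions.tsv"))
  written <- c(written, "signature_mouse.tsv", "correction_report.tsv",
               "common_gene_fractions.tsv")

  log_info("stage 4/6: ortholog mapping")
  omap <- data.frame(mouse_gene = sig$gene_id,
                     human_gene = toupper(sig$gene_id),
                     stringsAsFactors = FALSE)
  write_tsv_strict(omap, art("ortholog_map.tsv"))
  sig_h <- if (nrow(sig)) map_orthologs(sig, omap) else sig
  write_signature(sig_h, art("signature_human.tsv"))
  written <- c(written, "ortholog_map.tsv", "signature_human.tsv")

  log_info("stage 5/6: simulating and scoring the tumor cohort")
  if (!nrow(sig_h))
    stop_tsc("pipeline aborted at stage 5 (cohort): signature is empty")
  cohort <- simulate_tumor_cohort(
    sig_h, n_tumors = cfg$cohort.n_tumors,
    frac_mutant = cfg$cohort.frac_mutant,
    mutant_shift_logfc = cfg$cohort.mutant_shift_logfc,
    noise_sd = cfg$cohort.noise_sd,
    n_background_genes = cfg$cohort.n_background_genes,
    seed = derive_seed(cfg$seed, "cohort"))
  write_expression_matrix(cohort$expression, art("tumor_expression.tsv"))
  write_tsv_strict(cohort$mutations, art("tumor_mutations.tsv"))
  scores <- score_tumors(cohort$expression, sig_h)
  status <- classify_mutants(cohort$mutations, scores$tumor_id)
  scores$mutation_status <- unname(status[scores$tumor_id])
  write_tsv_strict(scores, art("tumor_scores.tsv"))
  written <- c(written, "tumor_expression.tsv", "tumor_mutations.tsv",
               "tumor_scores.tsv")

  log_info("stage 6/6: group comparison and manifest")
  cmp <- compare_groups(scores$score, scores$mutation_status,
                        test = cfg$score.test)
  jsonlite::write_json(list(test = cmp$test, statistic = cmp$statistic,
                            p_value = cmp$p_value, n = as.list(cmp$n),
                            means = as.list(cmp$means)),
                       art("score_comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  written <- c(written, "score_comparison.json")

  summary_lines <- c(
    sprintf("signature: %d genes (%d up, %d down) at FDR target %.2f",
            nrow(sig), sum(sig$direction == 1), sum(sig$direction == -1),
            cfg$sam.fdr_target),
    sprintf("sirolimus reversal: up %d/%d (%s%%), down %d/%d (%s%%)",
            corr$n_up_reversed, corr$n_up_in_ko, corr$pct_up_reversed,
            corr$n_down_reversed, corr$n_down_in_ko, corr$pct_down_reversed),
    sprintf("cohort: %d tumors, %d mutant; score comparison p = %.4g",
            nrow(scores), sum(scores$mutation_status == "mutant"), cmp$p_value))
  writeLines(summary_lines, art("summary.txt"))
  written <- c(written, "summary.txt")

  manifest <- list(
    seed = cfg$seed, config = cfg,
    artifacts = lapply(written, function(f)
      list(file = f, md5 = unname(tools::md5sum(art(f))))))
  jsonlite::write_json(manifest, art("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(config = cfg, signature = sig, signature_human = sig_h,
                 de_ko_vs_wt = de_ko, de_sirolimus_in_ko = de_sir_ko,
                 de_sirolimus_in_wt = de_sir_wt,
                 correction = corr, scores = scores, comparison = cmp,
                 outdir = outdir, manifest = manifest))
}
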