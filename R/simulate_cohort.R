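# Synthetic stand-in for a human tumor cohort with TSC1/TSC2 mutation calls:
# ~391 tumors of which ~11% carry a non-silent TSC1 or TSC2 mutation, with
# signature genes shifted along their directions in mutant tumors.

#' Default MAF variant classes treated as non-silent
#'
#' The protein-altering or regulatory classes that define TSC1/TSC2 mutant
#' status: missense, nonsense, frameshift (ins/del), splice site, in-frame
#' insertion/deletion, nonstop, translation start site and 5'UTR variants.
#'
#' @return character vector of MAF `Variant_Classification` strings.
#' @export
default_nonsilent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
    "Frame_Shift_Ins", "Splice_Site", "In_Frame_Del", "In_Frame_Ins",
    "Nonstop_Mutation", "Translation_Start_Site", "5'UTR")
}

#' Simulate a tumor cohort carrying a signature shift in mutants
#'
#' Tumors with a planted non-silent TSC1/TSC2 mutation have every signature
#' gene shifted by `direction * mutant_shift_logfc` on the log2 scale;
#' wild-type tumors may instead carry a silent TSC1/TSC2 record or a decoy
#' mutation in an unrelated gene, exercising the non-silent classification.
#'
#' @param signature a `tsc_signature` in human gene space (non-empty).
#' @param n_tumors cohort size (default 391).
#' @param frac_mutant fraction of tumors with a non-silent TSC1/TSC2 mutation
#'   (default 43/391); counts are rounded half up.
#' @param mutant_shift_logfc planted shift in log2 units.
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @param n_background_genes extra genes with no planted effect.
#' @param frac_silent fraction of wild-type tumors given a silent TSC1/TSC2
#'   record.
#' @param frac_decoy fraction of tumors given a non-silent record in a
#'   non-target gene.
#' @param baseline_log_mean,baseline_log_sd per-gene baseline distribution.
#' @param seed integer seed.
#' @return list with `expression` (raw [expression_matrix()]), `mutations`
#'   (MAF-style data.frame), and `truth` (mutant tumor ids and echoed
#'   parameters).
#' @export
simulate_tumor_cohort <- function(signature,
                                  n_tumors = 391,
                                  frac_mutant = 43 / 391,
                                  mutant_shift_logfc = 0.5,
                                  noise_sd = 1,
                                  n_background_genes = 1000,
                                  frac_silent = 0.10,
                                  frac_decoy = 0.30,
                                  baseline_log_mean = 5,
                                  baseline_log_sd = 1.5,
                                  seed = 1) {
  stopifnot(inherits(signature, "tsc_signature"))
  if (!nrow(signature)) stop_tsc("signature must be non-empty")
  if (frac_mutant <= 0 || frac_mutant >= 1) stop_tsc("frac_mutant must lie in (0, 1)")
  n_mut <- round_half_up(frac_mutant * n_tumors)
  if (n_mut == 0) stop_tsc("frac_mutant yields zero mutant tumors at this cohort size")
  set.seed(as.integer(seed))

  tumors <- sprintf("TUMOR_%04d", seq_len(n_tumors))
  mutant_ids <- sort(sample(tumors, n_mut))
  genes <- c(signature$gene_id,
             sprintf("BGGENE_%05d", seq_len(n_background_genes)))
  if (anyDuplicated(genes)) stop_tsc("signature gene ids collide with background gene ids")

  baseline <- stats::rnorm(length(genes), baseline_log_mean, baseline_log_sd)
  y <- baseline + matrix(stats::rnorm(length(genes) * n_tumors, 0, noise_sd),
                         length(genes), n_tumors)
  dimnames(y) <- list(genes, tumors)
  shift <- numeric(length(genes))
  names(shift) <- genes
  shift[signature$gene_id] <- signature$direction * mutant_shift_logfc
  y[, mutant_ids] <- y[, mutant_ids] + shift
  raw <- pmax(2^y - 1, 0)

  nonsilent <- default_nonsilent_classes()
  recs <- data.frame(tumor_id = mutant_ids,
                     gene_symbol = sample(c("TSC1", "TSC2"), n_mut, replace = TRUE),
                     variant_classification = sample(nonsilent, n_mut, replace = TRUE),
                     stringsAsFactors = FALSE)
  wt_ids <- setdiff(tumors, mutant_ids)
  n_silent <- round_half_up(frac_silent * length(wt_ids))
  if (n_silent > 0) {
    sil <- sort(sample(wt_ids, n_silent))
    recs <- rbind(recs, data.frame(
      tumor_id = sil,
      gene_symbol = sample(c("TSC1", "TSC2"), n_silent, replace = TRUE),
      variant_classification = "Silent", stringsAsFactors = FALSE))
  }
  n_decoy <- round_half_up(frac_decoy * n_tumors)
  if (n_decoy > 0) {
    dec <- sort(sample(tumors, n_decoy))
    recs <- rbind(recs, data.frame(
      tumor_id = dec,
      gene_symbol = sample(c("TP53", "FGFR3", "PIK3CA"), n_decoy, replace = TRUE),
      variant_classification = sample(nonsilent, n_decoy, replace = TRUE),
      stringsAsFactors = FALSE))
  }
  recs <- recs[order(recs$tumor_id, recs$gene_symbol), , drop = FALSE]
  rownames(recs) <- NULL

  list(expression = expression_matrix(raw, "raw"),
       mutations = recs,
       truth = list(mutant_tumors = mutant_ids,
                    params = list(n_tumors = n_tumors, frac_mutant = frac_mutant,
                                  mutant_shift_logfc = mutant_shift_logfc,
                                  noise_sd = noise_sd, seed = seed)))
}
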