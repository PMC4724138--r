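#' Run the full candidate-SNP analysis pipeline
#'
#' Chains the stages on one cohort: phenotype derivation (BMI, BMI-SDS,
#' weight class when not already present), genotype QC, differentiation
#' screen against the discovery frequencies, per-SNP association for
#' obese vs normal-weight, overweight vs normal-weight, and BMI-SDS,
#' the unweighted GRS with its shift test and cumulative effects,
#' variance explained, and the nested ROC comparison. When `out_dir`
#' is given, each stage table is written as TSV alongside a run log
#' with the counts and thresholds used.
#'
#' @param genotypes Dosage matrix (subjects x SNPs).
#' @param phenotypes Phenotype data.frame with `subject_id`, `sex`,
#'   `age`, `study_group` and either `weight_class` + `bmi_sds` or
#'   `height_cm` + `weight_kg` (derived via the references).
#' @param panel SNP panel, see [load_panel()].
#' @param cutoffs,lms References used only when classes/SDS must be
#'   derived.
#' @param alpha Family-wise level for Bonferroni control (default
#'   0.05; the per-test threshold divides by the number of passing
#'   SNPs).
#' @param grs_policy Missing-dosage policy for the score.
#' @param roc_mode `"grs"` (GRS as a single added predictor, default)
#'   or `"snps"` (all passing dosages added individually).
#' @param out_dir Optional output directory for stage TSVs and the run
#'   log.
#' @return List of class `pipeline_result` with elements `qc`, `fst`,
#'   `association` (list per outcome), `grs`, `grs_shift`,
#'   `grs_effects`, `variance`, `roc`, `bonferroni_threshold`,
#'   `counts`.
#' @export
run_pipeline <- function(genotypes, phenotypes, panel,
                         cutoffs = load_bmi_cutoffs(), lms = NULL,
                         alpha = 0.05,
                         grs_policy = c("mean_impute", "complete_case"),
                         roc_mode = c("grs", "snps"), out_dir = NULL) {
  grs_policy <- match.arg(grs_policy)
  roc_mode <- match.arg(roc_mode)
  ph <- phenotypes
  if (!"bmi" %in% names(ph)) ph$bmi <- compute_bmi(ph$weight_kg, ph$height_cm)
  if (!"weight_class" %in% names(ph)) {
    ph$weight_class <- classify_weight(ph$bmi, ph$sex, ph$age, cutoffs)
  }
  if (!"bmi_sds" %in% names(ph)) {
    if (is.null(lms)) stop("BMI-SDS analyses need an LMS reference (lms = ...)")
    ph$bmi_sds <- bmi_sds(ph$bmi, ph$sex, ph$age, lms)
  }
  common <- intersect(ph$subject_id, rownames(genotypes))
  if (!length(common)) stop("no subjects shared between phenotypes and genotypes")
  ph <- ph[match(common, ph$subject_id), ]
  g <- genotypes[common, , drop = FALSE]
  attr(g, "n_alleles") <- attr(genotypes, "n_alleles")

  nw_ids <- ph$subject_id[ph$weight_class == "normal"]
  qc <- run_qc(g, panel, normal_weight_ids = nw_ids)
  passing <- qc_passing(qc)
  if (!length(passing)) stop("no SNP survives QC")
  thr <- bonferroni_threshold(alpha, length(passing))

  eaf_obs <- stats::setNames(qc$eaf_observed, qc$snp_id)[passing]
  fst_tab <- differentiation_table(panel[panel$snp_id %in% passing, ], eaf_obs)

  design <- covariate_design(ph$age, ph$sex, ph$study_group)
  is_ob <- ph$weight_class == "obese"
  is_ow <- ph$weight_class == "overweight"
  is_nw <- ph$weight_class == "normal"
  scan_for <- function(mask_case, mask_ctrl, label) {
    sel <- mask_case | mask_ctrl
    association_scan(g[sel, , drop = FALSE], as.numeric(mask_case[sel]),
                     design[sel, , drop = FALSE], snp_ids = passing,
                     outcome_label = label, type = "logistic", alpha = alpha)
  }
  assoc <- list(
    obese_vs_normal = scan_for(is_ob, is_nw, "obese_vs_normal"),
    overweight_vs_normal = scan_for(is_ow, is_nw, "overweight_vs_normal"),
    bmi_sds = association_scan(g, ph$bmi_sds, design, snp_ids = passing,
                               outcome_label = "bmi_sds", type = "linear",
                               alpha = alpha))
  if ("discovery_or" %in% names(panel)) {
    disc <- stats::setNames(panel$discovery_or, panel$snp_id)[passing]
    dc <- direction_consistency(assoc$obese_vs_normal$or_value, disc)
    assoc$obese_vs_normal$direction_consistent <- dc$consistent
  }

  grs <- compute_grs(g, snp_ids = passing, policy = grs_policy)
  gsub <- stats::setNames(grs$grs, grs$subject_id)
  ph_g <- ph[ph$subject_id %in% grs$subject_id, ]
  score <- gsub[ph_g$subject_id]
  d_g <- covariate_design(ph_g$age, ph_g$sex, ph_g$study_group)
  ob_g <- ph_g$weight_class == "obese"; nw_g <- ph_g$weight_class == "normal"
  sel <- ob_g | nw_g
  shift <- grs_shift_test(score[ob_g], score[nw_g])
  grs_effects <- list(
    obesity = grs_cumulative_effect(score[sel], as.numeric(ob_g[sel]),
                                    d_g[sel, , drop = FALSE], type = "logistic"),
    bmi_sds = grs_cumulative_effect(score, ph_g$bmi_sds, d_g, type = "linear"))
  variance <- variance_explained(g[ph$subject_id %in% grs$subject_id, passing,
                                   drop = FALSE],
                                 ph_g$bmi_sds, d_g)

  base <- d_g[sel, , drop = FALSE]
  added <- if (roc_mode == "grs") cbind(GRS = score[sel]) else {
    gm <- g[ph_g$subject_id[sel], passing, drop = FALSE]
    # ROC needs complete predictors; mean-impute residual missing dosages
    for (j in seq_len(ncol(gm))) {
      gm[is.na(gm[, j]), j] <- 2 * estimate_eaf(gm[, j])
    }
    gm
  }
  roc <- compare_nested_models(as.numeric(ob_g[sel]), base, cbind(base, added))

  counts <- c(n_subjects = nrow(ph), n_obese = sum(is_ob),
              n_overweight = sum(is_ow), n_normal = sum(is_nw),
              n_snps_panel = nrow(panel), n_snps_pass = length(passing),
              n_grs_subjects = nrow(grs))
  out <- list(qc = qc, fst = fst_tab, association = assoc, grs = grs,
              grs_shift = shift, grs_effects = grs_effects,
              variance = variance, roc = roc,
              bonferroni_threshold = thr, counts = counts)
  class(out) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

# fixed-precision stage tables + run log; full precision stays in the
# returned object
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_qc_report(result$qc, file.path(out_dir, "qc_report.tsv"))
  f <- result$fst
  utils::write.table(
    data.frame(snp = f$snp_id, eaf_discovery = f$p1, eaf_study = f$p2,
               fst = sprintf("%.3f", f$fst),
               flag = ifelse(f$large_differentiation, "large", "")),
    file.path(out_dir, "fst_table.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(result$association)) {
    a <- result$association[[nm]]
    tab <- data.frame(snp = a$snp_id,
                      estimate = round_half_up(
                        ifelse(is.na(a$or_value), a$effect, a$or_value), 2),
                      ci_low = round_half_up(a$ci_low, 2),
                      ci_high = round_half_up(a$ci_high, 2),
                      p = ifelse(a$p_two_sided < 0.001,
                                 sprintf("%.2e", a$p_two_sided),
                                 sprintf("%.3f", a$p_two_sided)),
                      n = a$n_used,
                      bonferroni = a$bonferroni_significant)
    if ("direction_consistent" %in% names(a)) {
      tab$direction_consistent <- a$direction_consistent
    }
    utils::write.table(tab, file.path(out_dir, paste0("assoc_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.csv(result$grs, file.path(out_dir, "grs.csv"), row.names = FALSE)
  log <- c(paste0("subjects: ", result$counts[["n_subjects"]]),
           paste0("obese/overweight/normal: ",
                  paste(result$counts[c("n_obese", "n_overweight", "n_normal")],
                        collapse = "/")),
           paste0("panel SNPs: ", result$counts[["n_snps_panel"]],
                  ", passing QC: ", result$counts[["n_snps_pass"]]),
           paste0("bonferroni threshold: ", result$bonferroni_threshold),
           paste0("GRS subjects: ", result$counts[["n_grs_subjects"]]),
           paste0("GRS shift test: chi2 = ",
                  round_half_up(result$grs_shift$chi2, 2), ", df = ",
                  result$grs_shift$df, ", p = ",
                  signif(result$grs_shift$p, 3)),
           paste0("variance explained (delta R2): ",
                  round_half_up(100 * result$variance$r2_delta, 2), "%"),
           paste0("AUC base/full: ", round_half_up(result$roc$auc_base, 3),
                  "/", round_half_up(result$roc$auc_full, 3),
                  ", DeLong p = ", signif(result$roc$p_diff, 4)))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Candidate-SNP pipeline result\n")
  cat(sprintf("  subjects: %d (%d obese / %d overweight / %d normal)\n",
              x$counts[["n_subjects"]], x$counts[["n_obese"]],
              x$counts[["n_overweight"]], x$counts[["n_normal"]]))
  cat(sprintf("  SNPs passing QC: %d of %d (Bonferroni threshold %.3g)\n",
              x$counts[["n_snps_pass"]], x$counts[["n_snps_panel"]],
              x$bonferroni_threshold))
  s <- attr(x$fst, "summary")
  cat(sprintf("  F_ST: max %.3f, %d flagged >= %.2f\n", s$max, s$n_flagged,
              s$threshold))
  or <- x$grs_effects$obesity
  cat(sprintf("  GRS per-allele OR (obesity): %.2f (%.2f-%.2f), p = %.3g\n",
              or$or_value, or$ci_low, or$ci_high, or$p_two_sided))
  be <- x$grs_effects$bmi_sds
  cat(sprintf("  GRS per-allele beta (BMI-SDS): %.3f (%.3f-%.3f), p = %.3g\n",
              be$effect, be$ci_low, be$ci_high, be$p_two_sided))
  cat(sprintf("  variance explained by panel (delta R2): %.2f%%\n",
              100 * x$variance$r2_delta))
  cat(sprintf("  AUC %.3f -> %.3f (diff %.3f, DeLong p = %.3g)\n",
              x$roc$auc_base, x$roc$auc_full, x$roc$auc_diff, x$roc$p_diff))
  invisible(x)
}
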