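#' AUC by the rank-sum (Mann-Whitney) formulation
#'
#' The area under the ROC curve equals the probability that a randomly
#' chosen case outscores a randomly chosen control, with ties counted
#' one half — computed from the rank sum of the case scores in the
#' pooled sample.
#'
#' @param scores_cases,scores_controls Numeric prediction scores.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_mann_whitney(c(0.9, 0.8), c(0.7, 0.6))  # 1
#' auc_mann_whitney(c(0.9, 0.5), c(0.5, 0.1))  # 0.875
#' @export
auc_mann_whitney <- function(scores_cases, scores_controls) {
  n1 <- length(scores_cases); n0 <- length(scores_controls)
  if (!n1 || !n0) stop("both groups must be non-empty")
  r <- rank(c(scores_cases, scores_controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare the AUCs of two nested prediction models
#'
#' Fits the base (covariates-only) and full (covariates + genetic term)
#' logistic models on the same subjects, takes the fitted probabilities
#' as prediction scores, and compares the two apparent (in-sample) AUCs
#' with the DeLong test for correlated ROC curves; AUC confidence
#' intervals use the DeLong variance. The genetic term may be the GRS
#' as one column or the full dosage set. Differing subject sets between
#' the two designs are an error — nested comparison requires identical
#' subjects, and a silent intersection would bias the apparent gain.
#'
#' @param outcome Binary 0/1 case indicator.
#' @param design_base Covariate matrix of the base model.
#' @param design_full Matrix of the full model (base columns plus the
#'   added predictors), same rows as `design_base`.
#' @return List of class `roc_comparison`: `auc_base`, `auc_full` (each
#'   with `ci`), `auc_diff`, `p_diff`, `n_cases`, `n_controls`, and the
#'   two score vectors.
#' @export
compare_nested_models <- function(outcome, design_base, design_full) {
  y <- as.numeric(outcome)
  if (nrow(design_base) != nrow(design_full) || nrow(design_base) != length(y)) {
    stop("base and full designs must cover the identical subject set")
  }
  keep <- stats::complete.cases(design_base) & stats::complete.cases(design_full) & !is.na(y)
  if (!all(keep)) {
    stop(sum(!keep), " subject(s) incomplete in one design: ",
         "supply identical complete subject sets (no silent intersection)")
  }
  if (!all(colnames(design_base) %in% colnames(design_full))) {
    stop("full model must nest the base model (base columns missing)")
  }
  score <- function(X) {
    dat <- data.frame(y = y, X[, setdiff(colnames(X), "(Intercept)"),
                               drop = FALSE], check.names = FALSE)
    stats::glm(y ~ ., data = dat, family = stats::binomial())$fitted.values
  }
  s_base <- score(design_base)
  s_full <- score(design_full)
  roc_of <- function(s) pROC::roc(response = y, predictor = s,
                                  levels = c(0, 1), direction = "<",
                                  quiet = TRUE)
  r_base <- roc_of(s_base); r_full <- roc_of(s_full)
  auc_base <- as.numeric(pROC::auc(r_base))
  auc_full <- as.numeric(pROC::auc(r_full))
  p_diff <- if (isTRUE(all.equal(s_base, s_full))) 1 else {
    as.numeric(pROC::roc.test(r_base, r_full, method = "delong",
                              paired = TRUE)$p.value)
  }
  out <- list(auc_base = auc_base,
              ci_base = as.numeric(pROC::ci.auc(r_base, method = "delong"))[c(1, 3)],
              auc_full = auc_full,
              ci_full = as.numeric(pROC::ci.auc(r_full, method = "delong"))[c(1, 3)],
              auc_diff = auc_full - auc_base, p_diff = p_diff,
              n_cases = sum(y == 1), n_controls = sum(y == 0),
              scores_base = s_base, scores_full = s_full)
  class(out) <- "roc_comparison"
  out
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("AUC base  %.3f (95%% CI %.3f-%.3f)\n", x$auc_base,
              x$ci_base[1], x$ci_base[2]))
  cat(sprintf("AUC full  %.3f (95%% CI %.3f-%.3f)\n", x$auc_full,
              x$ci_full[1], x$ci_full[2]))
  cat(sprintf("Difference %.3f, DeLong p = %.4g (%d cases, %d controls)\n",
              x$auc_diff, x$p_diff, x$n_cases, x$n_controls))
  invisible(x)
}

#' ROC curve points
#'
#' False- and true-positive rates at every score threshold, for
#' plotting or export.
#'
#' @param scores Prediction scores.
#' @param outcome Binary 0/1 case indicator.
#' @return Data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, outcome) {
  y <- as.numeric(outcome)
  r <- pROC::roc(response = y, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  data.frame(threshold = r$thresholds, fpr = 1 - r$specificities,
             tpr = r$sensitivities)
}
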