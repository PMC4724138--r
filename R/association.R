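#' Covariate design matrix for adjusted association models
#'
#' Builds the standard adjustment set for paediatric obesity
#' association: intercept, age, age squared (constructed from the same
#' age column, never supplied separately), a male indicator, and
#' reference-coded indicators for the study group.
#'
#' @param age Age in years.
#' @param sex `"male"`/`"female"` (or M/F).
#' @param study_group Group labels (factor or character); the first
#'   level is the reference.
#' @return Numeric matrix with named columns, one row per subject.
#' @export
covariate_design <- function(age, sex, study_group) {
  sex <- normalize_sex(sex)
  grp <- factor(study_group)
  n <- length(age)
  if (length(sex) != n || length(grp) != n) stop("covariate lengths differ")
  X <- cbind(`(Intercept)` = 1, age = age, age_sq = age^2,
             sex_male = as.numeric(sex == "male"))
  if (nlevels(grp) > 1) {
    G <- stats::model.matrix(~grp)[, -1, drop = FALSE]
    colnames(G) <- paste0("group_", levels(grp)[-1])
    X <- cbind(X, G)
  }
  X
}

# shared scaffolding for both regression arms
new_association_result <- function(snp_id, outcome, effect, se, n_used,
                                   logistic, conf_level = 0.95) {
  effect <- unname(effect); se <- unname(se)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- effect + c(-1, 1) * z * se
  res <- list(snp_id = snp_id, outcome = outcome, effect = effect, se = se,
              ci_low = if (logistic) exp(ci[1]) else ci[1],
              ci_high = if (logistic) exp(ci[2]) else ci[2],
              or_value = if (logistic) exp(effect) else NA_real_,
              p_two_sided = 2 * stats::pnorm(-abs(effect / se)),
              n_used = n_used, conf_level = conf_level)
  class(res) <- "association_result"
  res
}

#' @export
print.association_result <- function(x, ...) {
  est <- if (!is.na(x$or_value)) sprintf("OR = %.2f", x$or_value)
         else sprintf("beta = %.3f", x$effect)
  cat(sprintf("%s [%s]: %s (95%% CI %.2f-%.2f), p = %.3g, n = %d\n",
              x$snp_id, x$outcome, est, x$ci_low, x$ci_high,
              x$p_two_sided, x$n_used))
  invisible(x)
}

#' Per-allele logistic association under the additive model
#'
#' Fits `outcome ~ dosage + covariates` by maximum likelihood
#' (iteratively reweighted least squares) and reports the per-allele
#' odds ratio with a Wald 95% CI and two-sided Wald p-value. Subjects
#' with a missing dosage are dropped for this SNP (complete-case per
#' test); `n_used` records the analysed count.
#'
#' @param dosage Effect-allele dosage 0/1/2 (NA = missing).
#' @param outcome Binary 0/1 (or logical) case indicator.
#' @param design Covariate matrix from [covariate_design()], or `NULL`
#'   for an unadjusted (intercept-only) fit.
#' @param snp_id,outcome_label Labels carried into the result.
#' @param p_method `"wald"` (default) or `"lrt"` for a likelihood-ratio
#'   p-value on the dosage term.
#' @return An `association_result`: `effect` (log-OR per allele), `se`,
#'   `or_value`, `ci_low`/`ci_high` (OR scale), `p_two_sided`, `n_used`.
#' @export
fit_logistic_additive <- function(dosage, outcome, design = NULL,
                                  snp_id = "snp", outcome_label = "obese_vs_normal",
                                  p_method = c("wald", "lrt")) {
  p_method <- match.arg(p_method)
  outcome <- as.numeric(outcome)
  keep <- !is.na(dosage) & !is.na(outcome)
  if (!is.null(design)) keep <- keep & stats::complete.cases(design)
  d <- dosage[keep]; y <- outcome[keep]
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  if (stats::var(d) == 0) stop("constant dosage: no per-allele effect estimable")
  X <- if (is.null(design)) matrix(1, length(d), 1,
                                   dimnames = list(NULL, "(Intercept)"))
       else design[keep, , drop = FALSE]
  dat <- data.frame(y = y, d = d, X[, setdiff(colnames(X), "(Intercept)"),
                                    drop = FALSE], check.names = FALSE)
  fit <- stats::glm(y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 50))
  co <- summary(fit)$coefficients
  if (!fit$converged || any(abs(stats::coef(fit)) > 15) ||
      co["d", "Std. Error"] > 100) {
    stop("logistic fit for ", snp_id, " did not converge cleanly ",
         "(complete or quasi-complete separation likely); ",
         "consider a penalized (Firth-type) fit")
  }
  res <- new_association_result(snp_id, outcome_label,
                                effect = co["d", "Estimate"],
                                se = co["d", "Std. Error"],
                                n_used = length(d), logistic = TRUE)
  if (p_method == "lrt") {
    fit0 <- stats::update(fit, . ~ . - d)
    res$p_two_sided <- stats::pchisq(fit0$deviance - fit$deviance, df = 1,
                                     lower.tail = FALSE)
  }
  res
}

#' Per-allele linear association with BMI-SDS under the additive model
#'
#' Ordinary least squares of the quantitative outcome on dosage plus
#' covariates; Wald 95% CI and a two-sided p from the normal
#' approximation (consistent with the logistic arm).
#'
#' @param dosage Effect-allele dosage 0/1/2 (NA = missing).
#' @param bmi_sds Quantitative outcome (BMI-SDS).
#' @inheritParams fit_logistic_additive
#' @return An `association_result` with `effect` = beta per allele (in
#'   outcome units).
#' @export
fit_linear_additive <- function(dosage, bmi_sds, design = NULL,
                                snp_id = "snp", outcome_label = "bmi_sds") {
  keep <- !is.na(dosage) & !is.na(bmi_sds)
  if (!is.null(design)) keep <- keep & stats::complete.cases(design)
  d <- dosage[keep]; y <- bmi_sds[keep]
  X <- if (is.null(design)) matrix(1, length(d), 1,
                                   dimnames = list(NULL, "(Intercept)"))
       else design[keep, , drop = FALSE]
  M <- cbind(X, d = d)
  if (nrow(M) <= ncol(M)) stop("fewer subjects than parameters")
  q <- qr(M)
  if (q$rank < ncol(M)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(M)[q$pivot[(q$rank + 1):ncol(M)]], collapse = ", "))
  }
  fit <- stats::lm.fit(M, y)
  sigma2 <- sum(fit$residuals^2) / (nrow(M) - ncol(M))
  XtX_inv <- chol2inv(qr.R(q))[order(q$pivot), order(q$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(XtX_inv))[ncol(M)]
  new_association_result(snp_id, outcome_label, effect = fit$coefficients["d"],
                         se = se, n_used = nrow(M), logistic = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level in (0, 1).
#' @param k Number of tests (>= 1).
#' @return `alpha / k`.
#' @examples
#' bonferroni_threshold(0.05, 32)  # 0.0015625, printed as 0.00156
#' @export
bonferroni_threshold <- function(alpha, k) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.numeric(k) || k < 1 || k != as.integer(k)) stop("k must be an integer >= 1")
  alpha / k
}

#' Direction consistency of study effects against discovery effects
#'
#' A study effect is directionally consistent when its log odds ratio
#' has the same sign as the discovery study's. An OR of exactly 1 sits
#' on the boundary: it is counted as inconsistent and flagged
#' indeterminate.
#'
#' @param study_or Per-allele odds ratios estimated in the study.
#' @param discovery_or Odds ratios reported by the discovery studies
#'   (NA where unavailable; those SNPs return NA).
#' @return A data.frame with `consistent` (logical) and `indeterminate`
#'   (OR exactly 1 on either side); the count of consistent SNPs in
#'   `attr(, "n_consistent")`.
#' @export
direction_consistency <- function(study_or, discovery_or) {
  check_positive(study_or, "study_or")
  s1 <- sign(log(study_or)); s2 <- sign(log(discovery_or))
  indet <- !is.na(s2) & (s1 == 0 | s2 == 0)
  cons <- ifelse(is.na(s2), NA, s1 == s2 & s1 != 0)
  out <- data.frame(consistent = cons, indeterminate = indet)
  attr(out, "n_consistent") <- sum(cons, na.rm = TRUE)
  out
}

#' Panel-wide association scan
#'
#' Runs the additive-model fit for every passing SNP of a panel against
#' one outcome contrast, applying Bonferroni control across the panel.
#'
#' @param genotypes Dosage matrix.
#' @param outcome Binary indicator (logistic) or numeric (linear).
#' @param design Covariate matrix from [covariate_design()].
#' @param snp_ids SNPs to test (default: all genotype columns).
#' @param outcome_label Contrast label stored per row.
#' @param type `"logistic"` or `"linear"`.
#' @param alpha Family-wise level; the per-test threshold is
#'   `alpha / length(snp_ids)`.
#' @return Data.frame, one row per SNP: estimate, CI, p, n, and
#'   `bonferroni_significant`.
#' @export
association_scan <- function(genotypes, outcome, design, snp_ids = colnames(genotypes),
                             outcome_label = "obese_vs_normal",
                             type = c("logistic", "linear"), alpha = 0.05) {
  type <- match.arg(type)
  thr <- bonferroni_threshold(alpha, length(snp_ids))
  rows <- lapply(snp_ids, function(s) {
    r <- if (type == "logistic") {
      fit_logistic_additive(genotypes[, s], outcome, design, snp_id = s,
                            outcome_label = outcome_label)
    } else {
      fit_linear_additive(genotypes[, s], outcome, design, snp_id = s,
                          outcome_label = outcome_label)
    }
    data.frame(snp_id = s, outcome = outcome_label, effect = r$effect,
               se = r$se, or_value = r$or_value, ci_low = r$ci_low,
               ci_high = r$ci_high, p_two_sided = r$p_two_sided,
               n_used = r$n_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bonferroni_significant <- out$p_two_sided < thr
  attr(out, "bonferroni_threshold") <- thr
  out
}
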