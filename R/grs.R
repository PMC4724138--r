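#' Unweighted genetic risk score
#'
#' Sums effect-allele dosages over the panel SNPs for each subject. The
#' score is deliberately unweighted: each risk allele counts 1. Missing
#' dosages are handled by policy: `"mean_impute"` (default) substitutes
#' the SNP's expected dosage `2 * EAF` estimated from the non-missing
#' subjects, keeping every subject in the analysis; `"complete_case"`
#' drops subjects with any missing dosage, yielding integer scores.
#' Subjects missing every SNP are excluded with a warning under either
#' policy.
#'
#' @param genotypes Dosage matrix (subjects x SNPs).
#' @param snp_ids SNPs entering the score (default: all columns).
#' @param policy `"mean_impute"` or `"complete_case"`.
#' @return Data.frame with `subject_id`, `grs`, `n_missing`; the policy
#'   in `attr(, "policy")`.
#' @examples
#' g <- rbind(a = c(0, 1, 2, 1), b = c(2, 2, 2, 2))
#' colnames(g) <- paste0("rs", 1:4)
#' compute_grs(g)$grs  # 4 and 8
#' @export
compute_grs <- function(genotypes, snp_ids = colnames(genotypes),
                        policy = c("mean_impute", "complete_case")) {
  policy <- match.arg(policy)
  g <- genotypes[, snp_ids, drop = FALSE]
  n_missing <- rowSums(is.na(g))
  all_missing <- n_missing == ncol(g)
  if (any(all_missing)) {
    warning(sum(all_missing), " subject(s) missing every panel SNP excluded from GRS")
    g <- g[!all_missing, , drop = FALSE]
    n_missing <- n_missing[!all_missing]
  }
  if (policy == "complete_case") {
    keep <- n_missing == 0
    g <- g[keep, , drop = FALSE]
    n_missing <- n_missing[keep]
    score <- rowSums(g)
  } else {
    eaf <- apply(g, 2, estimate_eaf)
    imp <- matrix(rep(2 * eaf, each = nrow(g)), nrow = nrow(g))
    gi <- ifelse(is.na(g), imp, g)
    score <- rowSums(gi)
  }
  out <- data.frame(subject_id = rownames(g) %||% as.character(seq_len(nrow(g))),
                    grs = unname(score), n_missing = unname(n_missing),
                    stringsAsFactors = FALSE)
  attr(out, "policy") <- policy
  out
}

#' Risk-allele distribution shift between two groups
#'
#' Contingency chi-square comparing the risk-allele-count histograms of
#' two groups (e.g. obese vs normal-weight). Scores are binned at
#' integer resolution (floored), and adjacent bins are merged inward
#' from the distribution tails until every expected cell count reaches
#' 5, the usual validity rule for the Pearson approximation; degrees of
#' freedom are `bins - 1`.
#'
#' @param grs_a,grs_b Numeric score vectors for the two groups.
#' @param min_expected Minimum expected cell count before merging stops
#'   (default 5).
#' @return List: `chi2`, `df`, `p`, `bins` (merged bin labels), and the
#'   merged `counts` matrix (bin x group).
#' @export
grs_shift_test <- function(grs_a, grs_b, min_expected = 5) {
  if (!length(grs_a) || !length(grs_b)) stop("both groups must be non-empty")
  bins <- sort(unique(floor(c(grs_a, grs_b))))
  if (length(bins) < 2) stop("fewer than 2 score bins: no distribution to compare")
  counts <- cbind(a = tabulate(match(floor(grs_a), bins), length(bins)),
                  b = tabulate(match(floor(grs_b), bins), length(bins)))
  labels <- as.character(bins)
  repeat {
    expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    if (all(expected >= min_expected) || nrow(counts) <= 2) break
    # merge the tail whose boundary bin is sparser
    first <- min(expected[1, ]); last <- min(expected[nrow(counts), ])
    if (first <= last) {
      counts[2, ] <- counts[2, ] + counts[1, ]
      labels[2] <- paste0("<=", sub("^[<>]=", "", labels[2]))
      counts <- counts[-1, , drop = FALSE]; labels <- labels[-1]
    } else {
      k <- nrow(counts)
      counts[k - 1, ] <- counts[k - 1, ] + counts[k, ]
      labels[k - 1] <- paste0(">=", sub("^[<>]=", "", labels[k - 1]))
      counts <- counts[-k, , drop = FALSE]; labels <- labels[-k]
    }
  }
  if (nrow(counts) < 2) stop("fewer than 2 score bins after merging")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  chi2 <- sum((counts - expected)^2 / expected)
  df <- nrow(counts) - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE),
       bins = labels, counts = counts)
}

#' Cumulative per-allele effect of the risk score
#'
#' Treats the GRS as the exposure in the adjusted additive model: a
#' logistic fit gives the odds ratio per additional risk allele, a
#' linear fit the BMI-SDS increase per allele.
#'
#' @param grs Numeric score vector.
#' @param outcome Binary indicator (logistic) or numeric BMI-SDS
#'   (linear).
#' @param design Covariate matrix from [covariate_design()].
#' @param type `"logistic"` or `"linear"`.
#' @return An `association_result` (exposure labelled `"GRS"`).
#' @export
grs_cumulative_effect <- function(grs, outcome, design = NULL,
                                  type = c("logistic", "linear")) {
  type <- match.arg(type)
  if (stats::var(grs, na.rm = TRUE) == 0) stop("constant GRS: no effect estimable")
  if (type == "logistic") {
    fit_logistic_additive(grs, outcome, design, snp_id = "GRS",
                          outcome_label = "obese_vs_normal")
  } else {
    fit_linear_additive(grs, outcome, design, snp_id = "GRS",
                        outcome_label = "bmi_sds")
  }
}

#' Variance in a quantitative trait explained by the panel
#'
#' Incremental R-squared of the SNP dosages over the covariate model:
#' both nested OLS fits use the identical complete-case subject set, so
#' the increment is non-negative by construction. Reported for the full
#' dosage set and, optionally, for the GRS as a single predictor.
#'
#' @param genotypes Dosage matrix (the predictor set).
#' @param bmi_sds Quantitative outcome.
#' @param design Covariate matrix, or `NULL` for unadjusted R-squared.
#' @param snp_ids SNPs entering the full model.
#' @return List: `r2_delta` (increment), `r2_full`, `r2_base`, `n_used`.
#' @export
variance_explained <- function(genotypes, bmi_sds, design = NULL,
                               snp_ids = colnames(genotypes)) {
  G <- genotypes[, snp_ids, drop = FALSE]
  X <- if (is.null(design)) matrix(1, length(bmi_sds), 1,
                                   dimnames = list(NULL, "(Intercept)"))
       else design
  keep <- stats::complete.cases(G) & !is.na(bmi_sds) & stats::complete.cases(X)
  G <- G[keep, , drop = FALSE]; y <- bmi_sds[keep]; X <- X[keep, , drop = FALSE]
  if (length(y) <= ncol(X) + ncol(G)) stop("too few complete cases for nested fits")
  r2 <- function(M) {
    res <- stats::lm.fit(M, y)$residuals
    1 - sum(res^2) / sum((y - mean(y))^2)
  }
  r2_base <- r2(X)
  r2_full <- r2(cbind(X, G))
  list(r2_delta = r2_full - r2_base, r2_full = r2_full, r2_base = r2_base,
       n_used = length(y))
}

#' Histogram counts of risk-allele scores by group
#'
#' Numeric companion to the usual risk-allele histogram figure: integer
#' score bins with the per-group counts.
#'
#' @param grs Numeric score vector.
#' @param group Group label per subject.
#' @return Data.frame `score` x one count column per group.
#' @export
grs_histogram <- function(grs, group) {
  bins <- sort(unique(floor(grs)))
  tab <- table(factor(floor(grs), levels = bins), group)
  out <- data.frame(score = bins)
  for (g in colnames(tab)) out[[g]] <- as.vector(tab[, g])
  out
}
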