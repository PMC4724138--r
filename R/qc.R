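#' Hardy-Weinberg chi-square test from genotype counts
#'
#' Pearson chi-square with 1 df and no continuity correction: expected
#' genotype counts `n(p^2, 2pq, q^2)` from the estimated allele
#' frequency, p-value from the upper chi-square tail. A monomorphic
#' sample carries no information about HWE and returns statistic 0,
#' p = 1 and `degenerate = TRUE`.
#'
#' @param n_hom_effect,n_het,n_hom_other Genotype counts (effect-allele
#'   homozygote, heterozygote, other homozygote).
#' @return List with `chi2`, `p`, `df = 1`, `degenerate`.
#' @examples
#' hwe_chisq(25, 50, 25)  # exact HWE proportions: chi2 = 0, p = 1
#' hwe_chisq(10, 10, 10)
#' @export
hwe_chisq <- function(n_hom_effect, n_het, n_hom_other) {
  counts <- c(n_hom_effect, n_het, n_hom_other)
  if (any(counts < 0) || sum(counts) == 0) stop("counts must be >= 0 and sum > 0")
  n <- sum(counts)
  p <- (2 * n_hom_effect + n_het) / (2 * n)
  if (p == 0 || p == 1) {
    return(list(chi2 = 0, p = 1, df = 1L, degenerate = TRUE))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L, degenerate = FALSE)
}

#' Exact Hardy-Weinberg test (conditional on allele counts)
#'
#' Enumerates all heterozygote counts compatible
#' with the observed allele counts, computes their probabilities under
#' the conditional (hypergeometric-type) HWE distribution, and sums the
#' probabilities of outcomes no more likely than the observed one.
#' Offered as an alternative to [hwe_chisq()] for small samples.
#'
#' @inheritParams hwe_chisq
#' @return List with `p` and `degenerate`.
#' @export
hwe_exact <- function(n_hom_effect, n_het, n_hom_other) {
  counts <- c(n_hom_effect, n_het, n_hom_other)
  if (any(counts < 0) || sum(counts) == 0) stop("counts must be >= 0 and sum > 0")
  n <- sum(counts)
  n_a <- 2 * n_hom_effect + n_het      # minor or major, symmetry below
  n_b <- 2 * n_hom_other + n_het
  rare <- min(n_a, n_b)
  if (rare == 0) return(list(p = 1, degenerate = TRUE))
  hets <- seq(rare %% 2, rare, by = 2)  # feasible heterozygote counts
  # conditional probability up to a constant in h (normalised below)
  logp <- vapply(hets, function(h) {
    ha <- (n_a - h) / 2; hb <- (n_b - h) / 2
    h * log(2) - lgamma(ha + 1) - lgamma(h + 1) - lgamma(hb + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- match(n_het, hets)
  list(p = min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)])), degenerate = FALSE)
}

#' Genotype quality control over a SNP panel
#'
#' Applies the exclusion ledger in fixed order per SNP: call rate below
#' threshold, then triallelic (more than two observed alleles), then
#' monomorphic, then minor allele frequency below threshold. SNPs that
#' survive are tested for Hardy-Weinberg equilibrium in the
#' normal-weight (control) subset only; HWE failures are *flagged*, not
#' excluded, unless `exclude_hwe = TRUE` — a nominally significant HWE
#' deviation in a modest sample is weak evidence of genotyping error on
#' its own, so the default leaves the call to the analyst.
#'
#' @param genotypes Dosage matrix from [read_genotypes_tsv()] /
#'   [read_genotypes_vcf()] (optionally with an `"n_alleles"` attribute).
#' @param panel SNP panel data.frame; rows are matched to genotype
#'   columns by `snp_id`.
#' @param normal_weight_ids Subject ids forming the HWE reference group;
#'   empty set skips HWE with a warning.
#' @param call_rate_min,maf_min,hwe_alpha QC thresholds (defaults 0.95,
#'   0.01, 0.05).
#' @param exclude_hwe If `TRUE`, `flag_hwe` SNPs are treated as failures
#'   by [qc_passing()].
#' @param hwe_method `"chisq"` (default) or `"exact"`.
#' @return A data.frame of class `qc_report`: one row per panel SNP with
#'   `call_rate`, `eaf_observed`, `maf`, `hwe_p`, `hwe_flag`, `status`;
#'   exclusion-class counts in `attr(, "counts")`.
#' @export
run_qc <- function(genotypes, panel, normal_weight_ids = character(),
                   call_rate_min = 0.95, maf_min = 0.01, hwe_alpha = 0.05,
                   exclude_hwe = FALSE, hwe_method = c("chisq", "exact")) {
  hwe_method <- match.arg(hwe_method)
  snp_ids <- panel$snp_id
  missing_snps <- setdiff(snp_ids, colnames(genotypes))
  if (length(missing_snps)) {
    stop("panel SNP(s) absent from genotype matrix: ",
         paste(missing_snps, collapse = ", "))
  }
  n_alleles <- attr(genotypes, "n_alleles")
  nw <- intersect(normal_weight_ids, rownames(genotypes))
  if (!length(nw) && length(snp_ids)) {
    warning("empty normal-weight subset: HWE screening skipped")
  }
  rep <- data.frame(snp_id = snp_ids, call_rate = NA_real_,
                    eaf_observed = NA_real_, maf = NA_real_,
                    hwe_p = NA_real_, hwe_flag = FALSE,
                    status = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_along(snp_ids)) {
    d <- genotypes[, snp_ids[j]]
    cr <- mean(!is.na(d))
    rep$call_rate[j] <- cr
    eaf <- if (any(!is.na(d))) estimate_eaf(d) else NA_real_
    rep$eaf_observed[j] <- eaf
    rep$maf[j] <- if (is.na(eaf)) NA_real_ else min(eaf, 1 - eaf)
    tri <- !is.null(n_alleles) && !is.na(n_alleles[snp_ids[j]]) &&
      n_alleles[snp_ids[j]] > 2L
    rep$status[j] <- if (cr < call_rate_min) "fail_callrate"
      else if (tri) "fail_triallelic"
      else if (is.na(eaf) || rep$maf[j] == 0) "fail_monomorphic"
      else if (rep$maf[j] < maf_min) "fail_maf"
      else "pass"
    if (rep$status[j] == "pass" && length(nw)) {
      dn <- d[nw]; dn <- dn[!is.na(dn)]
      if (length(dn)) {
        h <- if (hwe_method == "chisq") {
          hwe_chisq(sum(dn == 2), sum(dn == 1), sum(dn == 0))
        } else {
          hwe_exact(sum(dn == 2), sum(dn == 1), sum(dn == 0))
        }
        rep$hwe_p[j] <- h$p
        rep$hwe_flag[j] <- !h$degenerate && h$p < hwe_alpha
      }
    }
  }
  counts <- table(factor(rep$status, levels = c("pass", "fail_callrate",
                                                "fail_triallelic",
                                                "fail_monomorphic", "fail_maf")))
  attr(rep, "counts") <- counts
  attr(rep, "exclude_hwe") <- exclude_hwe
  attr(rep, "thresholds") <- c(call_rate_min = call_rate_min,
                               maf_min = maf_min, hwe_alpha = hwe_alpha)
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' SNPs surviving QC
#'
#' @param report A `qc_report` from [run_qc()].
#' @return Character vector of passing SNP ids (HWE-flagged SNPs are
#'   dropped only when the report was built with `exclude_hwe = TRUE`).
#' @export
qc_passing <- function(report) {
  keep <- report$status == "pass"
  if (isTRUE(attr(report, "exclude_hwe"))) keep <- keep & !report$hwe_flag
  report$snp_id[keep]
}

#' Write a QC report as TSV
#'
#' Columns: snp, call_rate, eaf, maf, hwe_p, status (HWE-flagged SNPs
#' get status `pass;flag_hwe`).
#'
#' @param report A `qc_report`.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  out <- data.frame(snp = report$snp_id,
                    call_rate = round_half_up(report$call_rate, 4),
                    eaf = round_half_up(report$eaf_observed, 4),
                    maf = round_half_up(report$maf, 4),
                    hwe_p = signif(report$hwe_p, 3),
                    status = ifelse(report$hwe_flag,
                                    paste0(report$status, ";flag_hwe"),
                                    report$status))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
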