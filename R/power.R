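#' Analytic power for the per-allele case-control test
#'
#' Under the log-additive (multiplicative) penetrance model with the
#' risk allele at population frequency `maf` in Hardy-Weinberg
#' proportions, case genotypes remain in HWE at the enriched frequency
#' \deqn{p_1 = \frac{p\,OR}{1 - p + p\,OR},}
#' while controls carry the population frequency `p`. The per-allele
#' test then reduces to a two-proportion comparison of allele
#' frequencies on `2 n_cases` vs `2 n_controls` alleles; power is the
#' two-sided normal tail probability of the Wald statistic at the
#' alternative,
#' \deqn{\Phi(\lambda - z_{1-\alpha/2}) + \Phi(-\lambda - z_{1-\alpha/2}),}
#' with noncentrality \eqn{\lambda = (p_1 - p) / SE_1} and `SE_1` the
#' binomial standard error under the alternative. A null `or = 1` gives
#' power equal to `alpha` exactly.
#'
#' @param n_cases,n_controls Group sizes.
#' @param maf Risk-allele frequency in (0, 0.5].
#' @param or Allelic odds ratio (> 0).
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`. Vectorised over `maf` and `or`.
#' @examples
#' power_case_control(705, 607, maf = 0.11, or = 1.5)  # about 0.94
#' @export
power_case_control <- function(n_cases, n_controls, maf, or, alpha = 0.05) {
  check_positive(n_cases, "n_cases"); check_positive(n_controls, "n_controls")
  check_positive(or, "or")
  if (any(maf <= 0) || any(maf > 0.5)) stop("'maf' must be in (0, 0.5]")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  p0 <- maf
  p1 <- p0 * or / (1 - p0 + p0 * or)
  m1 <- 2 * n_cases; m0 <- 2 * n_controls
  se1 <- sqrt(p1 * (1 - p1) / m1 + p0 * (1 - p0) / m0)
  lambda <- (p1 - p0) / se1
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(abs(lambda) - z) + stats::pnorm(-abs(lambda) - z)
}

#' Analytic power for a per-allele effect on a quantitative trait
#'
#' For an additive per-allele effect `beta` on a trait with residual
#' standard deviation `sd` and a SNP at frequency `maf` in HWE (dosage
#' variance `2 maf (1 - maf)`), the Wald noncentrality in a sample of
#' `n` is \eqn{\lambda = \beta \sqrt{n \cdot 2\,maf(1-maf)} / sd}; power
#' is the two-sided normal tail as in [power_case_control()].
#'
#' @param n Total sample size.
#' @param maf Allele frequency in (0, 0.5].
#' @param beta Per-allele effect in trait units (BMI-SDS).
#' @param sd Residual standard deviation of the trait (default 1, the
#'   natural unit for an SDS outcome).
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`. Vectorised over `maf` and `beta`.
#' @examples
#' power_quantitative(2030, maf = 0.11, beta = 0.10)  # about 0.51
#' @export
power_quantitative <- function(n, maf, beta, sd = 1, alpha = 0.05) {
  check_positive(n, "n"); check_positive(sd, "sd")
  if (any(maf <= 0) || any(maf > 0.5)) stop("'maf' must be in (0, 0.5]")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  lambda <- beta * sqrt(n * 2 * maf * (1 - maf)) / sd
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(abs(lambda) - z) + stats::pnorm(-abs(lambda) - z)
}

#' Simulation cross-check of case-control power
#'
#' Draws case genotypes from HWE at the enriched frequency and control
#' genotypes from HWE at the population frequency (the same generative
#' model as the analytic formula), applies the per-allele score (trend)
#' test to each replicate, and reports the rejection fraction. Runs
#' vectorised over replicates from multinomial genotype counts, so the
#' default 10,000 replicates take well under a second.
#'
#' @inheritParams power_case_control
#' @param n_rep Number of simulation replicates.
#' @return Estimated power (rejection fraction).
#' @export
simulate_power_cc <- function(n_cases, n_controls, maf, or, alpha = 0.05,
                              n_rep = 10000) {
  p0 <- maf
  p1 <- p0 * or / (1 - p0 + p0 * or)
  gfreq <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)
  cases <- stats::rmultinom(n_rep, n_cases, gfreq(p1))       # rows: dosage 0/1/2
  ctrls <- stats::rmultinom(n_rep, n_controls, gfreq(p0))
  # Cochran-Armitage trend (score) statistic per replicate, dosage weights 0/1/2
  n1 <- n_cases; n0 <- n_controls; n <- n1 + n0
  tot <- cases + ctrls
  s_case <- colSums(cases * c(0, 1, 2))
  s_tot <- colSums(tot * c(0, 1, 2))
  s2_tot <- colSums(tot * c(0, 1, 4))
  num <- s_case - n1 * s_tot / n
  varn <- n1 * n0 / n^2 * (s2_tot - s_tot^2 / n) * n / (n - 1)
  z2 <- num^2 / varn
  mean(stats::pchisq(z2, df = 1, lower.tail = FALSE) < alpha)
}

#' Power table over a SNP panel
#'
#' Evaluates case-control and/or quantitative power over the panel's
#' discovery allele frequencies (folded to minor allele frequencies)
#' for grids of effect sizes and alpha levels.
#'
#' @param panel SNP panel data.frame with `eaf_discovery`.
#' @param n_cases,n_controls Case-control arm sizes.
#' @param n_quant Sample size of the quantitative arm.
#' @param or_grid Allelic odds ratios for the binary arm.
#' @param beta_grid Per-allele effects for the quantitative arm.
#' @param alpha_grid Two-sided alpha levels.
#' @return Long-format data.frame: snp_id, maf, outcome, effect, alpha,
#'   power.
#' @export
power_table <- function(panel, n_cases, n_controls, n_quant,
                        or_grid = c(1.2, 1.5), beta_grid = c(0.05, 0.10),
                        alpha_grid = c(0.05, bonferroni_threshold(0.05, nrow(panel)))) {
  maf <- pmin(panel$eaf_discovery, 1 - panel$eaf_discovery)
  rows <- list()
  for (a in alpha_grid) {
    for (or in or_grid) {
      rows[[length(rows) + 1]] <- data.frame(
        snp_id = panel$snp_id, maf = maf, outcome = "binary",
        effect = or, alpha = a,
        power = power_case_control(n_cases, n_controls, maf, or, a))
    }
    for (b in beta_grid) {
      rows[[length(rows) + 1]] <- data.frame(
        snp_id = panel$snp_id, maf = maf, outcome = "quantitative",
        effect = b, alpha = a,
        power = power_quantitative(n_quant, maf, b, alpha = a))
    }
  }
  do.call(rbind, rows)
}
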