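#' Two-population allele-frequency differentiation index
#'
#' For an allele with frequency `p1` in the discovery population and
#' `p2` in the study sample,
#' \deqn{F_{ST} = \frac{(p_1 - p_2)^2}{(p_1 + p_2)\,(2 - (p_1 + p_2))}.}
#' The denominator is `2 p̄ (1 - p̄)` scaled by 4 with `p̄` the mean
#' frequency, so the index is symmetric in the two populations and
#' invariant to relabelling the allele (`p -> 1 - p` in both). Values
#' at or above 0.10 are conventionally read as large genetic
#' differentiation. The degenerate fixed-allele case `p1 = p2 = 0` or
#' `1` is defined as 0 (the limit of identical frequencies).
#'
#' @param p1 Allele frequency in the discovery population, in `[0, 1]`.
#' @param p2 Allele frequency in the study sample, in `[0, 1]`.
#' @return F_ST in `[0, 1)`. Vectorised.
#' @examples
#' fst(0.42, 0.13)  # 0.105 to 3 dp
#' fst(0.61, 0.92)  # 0.134
#' @export
fst <- function(p1, p2) {
  check_frequency(p1, "p1"); check_frequency(p2, "p2")
  s <- p1 + p2
  out <- ifelse(s == 0 | s == 2, 0, (p1 - p2)^2 / (s * (2 - s)))
  unname(out)
}

#' Differentiation screen of a SNP panel against its discovery studies
#'
#' Computes F_ST per SNP between the discovery effect-allele frequency
#' stored in the panel and the observed study frequency, flags large
#' differentiation at the (unrounded) 0.10 threshold, and summarises.
#' Flagging happens on full precision; the reported `fst` column is
#' rounded to 3 decimals, matching how such tables are printed — a
#' value printing as 0.099 or 0.100 is flagged by its exact value, not
#' its rounded one.
#'
#' @param panel SNP panel data.frame with `snp_id`, `eaf_discovery` and
#'   (optionally) `ancestry`/`discovery_study` columns.
#' @param observed_eaf Named numeric vector of study effect-allele
#'   frequencies (names = snp_id), e.g. from [run_qc()]'s
#'   `eaf_observed`, or the panel's own `eaf_study` column when `NULL`.
#' @param threshold Large-differentiation threshold (default 0.10).
#' @return A data.frame of class `fst_table` with columns `snp_id`,
#'   `p1`, `p2`, `fst` (3 dp), `fst_exact`, `large_differentiation`;
#'   summary list in `attr(, "summary")` (`min`, `max`, `n_flagged`,
#'   `by_study` counts of flagged/unflagged per discovery study).
#' @export
differentiation_table <- function(panel, observed_eaf = NULL, threshold = 0.10) {
  if (is.null(observed_eaf)) {
    if (!"eaf_study" %in% names(panel)) {
      stop("supply observed_eaf or a panel with an 'eaf_study' column")
    }
    observed_eaf <- stats::setNames(panel$eaf_study, panel$snp_id)
  }
  keep <- !is.na(panel$eaf_discovery) & panel$snp_id %in% names(observed_eaf)
  dropped <- panel$snp_id[!keep]
  if (length(dropped)) {
    warning("SNP(s) without frequency pair omitted from F_ST table: ",
            paste(dropped, collapse = ", "))
  }
  pan <- panel[keep, ]
  p1 <- pan$eaf_discovery
  p2 <- unname(observed_eaf[pan$snp_id])
  f <- fst(p1, p2)
  out <- data.frame(snp_id = pan$snp_id, p1 = p1, p2 = p2,
                    fst = round_half_up(f, 3), fst_exact = f,
                    large_differentiation = f >= threshold,
                    stringsAsFactors = FALSE)
  if ("gene" %in% names(pan)) out$gene <- pan$gene
  by_study <- NULL
  grp <- pan$discovery_study %||% NULL
  if (!is.null(grp)) {
    by_study <- as.data.frame(table(study = grp, flagged = out$large_differentiation))
  }
  attr(out, "summary") <- list(min = min(f), max = max(f),
                               n_flagged = sum(out$large_differentiation),
                               by_study = by_study, threshold = threshold)
  class(out) <- c("fst_table", "data.frame")
  out
}
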