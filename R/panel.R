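#' Load a SNP panel file
#'
#' A panel is a TSV with one row per candidate locus: `snp_id`, `gene`,
#' `chr`, `position`, `effect_allele`, `other_allele`, `eaf_discovery`
#' (effect-allele frequency in the discovery population), and
#' optionally `eaf_study`, `hwe_p_normal`, `fst_printed`,
#' `discovery_study`, `ancestry`, `is_proxy`, `discovery_or`. For proxy
#' SNPs the stored discovery frequency is the proxy's own frequency in
#' the discovery population (taken from a reference database upstream);
#' no live lookup is performed.
#'
#' @param path TSV path; the default is the bundled 32-SNP childhood
#'   obesity panel (GWAS-derived loci with discovery frequencies, study
#'   frequencies and ancestry labels).
#' @return Validated data.frame of class `snp_panel`.
#' @examples
#' panel <- load_panel()
#' nrow(panel)          # 32
#' sum(panel$is_proxy)  # 4 proxy SNPs in the analysed panel
#' @export
load_panel <- function(path = system.file("extdata", "snp_panel_cn32.tsv",
                                          package = "riskallele")) {
  pan <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (!nrow(pan)) stop("empty panel file: ", path)
  need <- c("snp_id", "effect_allele", "other_allele", "eaf_discovery")
  miss <- setdiff(need, names(pan))
  if (length(miss)) stop("panel misses column(s): ", paste(miss, collapse = ", "))
  dup <- pan$snp_id[duplicated(pan$snp_id)]
  if (length(dup)) stop("duplicated rsID(s) in panel: ", paste(unique(dup), collapse = ", "))
  bases <- c("A", "C", "G", "T")
  bad <- !(pan$effect_allele %in% bases) | !(pan$other_allele %in% bases) |
    pan$effect_allele == pan$other_allele
  if (any(bad)) {
    stop("malformed alleles for SNP(s): ", paste(pan$snp_id[bad], collapse = ", "))
  }
  for (col in intersect(c("eaf_discovery", "eaf_study"), names(pan))) {
    v <- pan[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("column ", col, " outside [0, 1] for SNP(s): ",
           paste(pan$snp_id[!is.na(v) & (v < 0 | v > 1)], collapse = ", "))
    }
  }
  if (!"is_proxy" %in% names(pan)) pan$is_proxy <- FALSE
  pan$is_proxy <- as.logical(pan$is_proxy)
  class(pan) <- c("snp_panel", "data.frame")
  pan
}
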