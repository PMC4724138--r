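#' Read a subjects-by-SNPs dosage table
#'
#' Tab-separated file: first column `subject_id`, remaining columns one
#' per SNP (header = rsID), entries the effect-allele dosage 0/1/2,
#' empty or `NA` for a missing call. The file is expected to be coded
#' relative to the panel's effect alleles already.
#'
#' @param path TSV path.
#' @return Numeric matrix (subjects x SNPs) with dimnames, values in
#'   `{0, 1, 2, NA}`.
#' @export
read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "subject_id") stop("first column must be 'subject_id'")
  ids <- as.character(tab$subject_id)
  if (anyDuplicated(ids)) stop("duplicated subject_id in genotype file")
  g <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- ids
  bad <- !is.na(g) & !(g %in% c(0, 1, 2))
  if (any(bad)) stop("dosages must be 0, 1, 2 or missing; found other values")
  g
}

#' Read genotypes from a VCF against a SNP panel
#'
#' Extracts GT fields with \pkg{vcfR} and codes each record as the count
#' of the panel's effect allele. Records whose REF/ALT do not match the
#' panel alleles raise an error; records matching only after base
#' complementation are accepted with a strand warning (no silent
#' flipping). A record with more than one ALT allele is kept, coded
#' `NA`, and reported in the `"n_alleles"` attribute so QC can fail it
#' as triallelic.
#'
#' @param path VCF (v4.x) path, plain text or bgzipped.
#' @param panel SNP panel data.frame, see [load_panel()].
#' @return Dosage matrix as in [read_genotypes_tsv()], with an
#'   `"n_alleles"` attribute (named integer: observed allele count per
#'   panel SNP).
#' @export
read_genotypes_vcf <- function(path, panel) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  gt <- vcfR::extract.gt(v, element = "GT")
  subjects <- colnames(gt)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- matrix(NA_real_, nrow = length(subjects), ncol = nrow(panel),
                dimnames = list(subjects, panel$snp_id))
  n_alleles <- setNames(rep(NA_integer_, nrow(panel)), panel$snp_id)
  for (j in seq_len(nrow(panel))) {
    k <- match(panel$snp_id[j], ids)
    if (is.na(k)) next
    ref <- fix[k, "REF"]; alt <- fix[k, "ALT"]
    alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
    n_alleles[j] <- 1L + length(alts)
    if (length(alts) > 1L) next  # triallelic: leave NA, QC flags it
    pair <- c(panel$effect_allele[j], panel$other_allele[j])
    if (!setequal(c(ref, alts), pair)) {
      if (setequal(c(comp[ref], comp[alts]), pair)) {
        warning("SNP ", panel$snp_id[j],
                ": VCF alleles match the panel only after complementation; ",
                "coding on the complement strand")
        ref <- comp[[ref]]; alts <- comp[[alts]]
      } else {
        stop("SNP ", panel$snp_id[j], ": VCF alleles ", ref, "/", alt,
             " match neither panel allele (", pair[1], "/", pair[2], ")")
      }
    }
    calls <- gt[k, ]
    alleles <- strsplit(gsub("\\|", "/", calls), "/", fixed = FALSE)
    eff_is_alt <- identical(unname(alts), panel$effect_allele[j])
    out[, j] <- vapply(alleles, function(a) {
      if (length(a) != 2L || any(a == ".") || any(is.na(a))) return(NA_real_)
      n_alt <- sum(a == "1")
      if (eff_is_alt) n_alt else 2 - n_alt
    }, numeric(1))
  }
  attr(out, "n_alleles") <- n_alleles
  out
}

#' Effect-allele frequency from dosages
#'
#' @param dosages Numeric vector of effect-allele dosages 0/1/2 with
#'   `NA` for missing calls.
#' @param snp_id Optional label used in error messages.
#' @return Frequency in `[0, 1]` over non-missing subjects.
#' @examples
#' estimate_eaf(c(0, 1, 2))            # 0.5
#' estimate_eaf(c(0, 0, 1, 1, 2, NA))  # 0.4
#' @export
estimate_eaf <- function(dosages, snp_id = NULL) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) {
    stop("all dosages missing", if (!is.null(snp_id)) paste0(" for SNP ", snp_id))
  }
  sum(d) / (2 * length(d))
}
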