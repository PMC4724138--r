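# Programmatic fixtures shared across test files.

test_panel <- function() load_panel()

# Deterministic 40-SNP QC fixture: 32 clean SNPs, 1 monomorphic,
# 1 triallelic, 6 rare (0 < MAF < 1%). 2000 subjects.
make_qc_fixture <- function(n = 2000) {
  good <- function(i) rep_len(c(0, 1, 2, 1, 0, 1), n)      # MAF well above 1%
  rare <- function() c(rep(1, 10), rep(0, n - 10))          # MAF 10/(2n) = 0.25%
  cols <- list()
  for (i in 1:32) cols[[paste0("ok", i)]] <- good(i)
  cols[["mono"]] <- rep(0, n)
  cols[["tri"]] <- rep_len(c(0, 1, 2), n)
  for (i in 1:6) cols[[paste0("rare", i)]] <- rare()
  g <- do.call(cbind, cols)
  rownames(g) <- paste0("S", seq_len(n))
  n_alleles <- setNames(rep(2L, ncol(g)), colnames(g))
  n_alleles["tri"] <- 3L
  attr(g, "n_alleles") <- n_alleles
  panel <- data.frame(snp_id = colnames(g),
                      effect_allele = "A", other_allele = "G",
                      eaf_discovery = 0.3, stringsAsFactors = FALSE)
  list(genotypes = g, panel = panel)
}

# small two-group phenotype frame with known classes
make_small_cohort <- function(seed = 42, n_per_class = 120) {
  panel <- test_panel()
  simulate_cohort(panel,
                  groups = list(G1 = list(quota = c(normal = n_per_class,
                                                    overweight = n_per_class,
                                                    obese = n_per_class),
                                          female_fraction = 0.5,
                                          age_mean = 12.5, age_sd = 2.5)),
                  seed = seed)
}
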