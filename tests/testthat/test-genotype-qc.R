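test_that("effect-allele frequency estimation handles missing calls", {
  expect_equal(estimate_eaf(c(0, 1, 2)), 0.5)
  expect_equal(estimate_eaf(c(2, 2, 2, 2)), 1)
  expect_equal(estimate_eaf(c(0, 0, 1, 1, 2, NA)), 0.4)
  expect_error(estimate_eaf(c(NA, NA), snp_id = "rs1"), "rs1")
})

test_that("EAF of the recoded allele is the complement", {
  set.seed(101)
  for (i in 1:20) {
    d <- rbinom(30, 2, runif(1, 0.05, 0.95))
    d[sample(30, 5)] <- NA
    if (all(is.na(d))) next
    expect_equal(estimate_eaf(d) + estimate_eaf(2 - d), 1)
  }
})

test_that("HWE chi-square matches hand-computed values", {
  h <- hwe_chisq(25, 50, 25)
  expect_equal(h$chi2, 0)
  expect_equal(h$p, 1)
  # p-hat = 0.5, expected (7.5, 15, 7.5): chi2 = 10/3
  h <- hwe_chisq(10, 10, 10)
  expect_equal(h$chi2, 10 / 3)
  expect_equal(h$p, pchisq(10 / 3, 1, lower.tail = FALSE))
  h <- hwe_chisq(0, 0, 100)
  expect_true(h$degenerate)
  expect_equal(h$p, 1)
})

test_that("HWE chi-square is invariant under homozygote swap", {
  set.seed(7)
  for (i in 1:50) {
    cnt <- rmultinom(1, 200, c(0.2, 0.5, 0.3))
    a <- hwe_chisq(cnt[1], cnt[2], cnt[3])
    b <- hwe_chisq(cnt[3], cnt[2], cnt[1])
    expect_equal(a$chi2, b$chi2)
    expect_equal(a$p, b$p)
  }
})

test_that("HWE flag rate under true HWE is the nominal 5%", {
  set.seed(2024)
  n_rep <- 2000
  counts <- rmultinom(n_rep, 500, c(0.49, 0.42, 0.09))  # HWE at p = 0.7
  p <- vapply(seq_len(n_rep),
              function(i) hwe_chisq(counts[1, i], counts[2, i], counts[3, i])$p,
              numeric(1))
  rate <- mean(p < 0.05)
  # 3.5 binomial SDs around 0.05 for 2000 replicates is about +/- 0.017
  expect_gt(rate, 0.033)
  expect_lt(rate, 0.067)
})

test_that("exact HWE test agrees with the chi-square in large balanced samples", {
  ex <- hwe_exact(300, 500, 200)
  ch <- hwe_chisq(300, 500, 200)
  expect_lt(abs(ex$p - ch$p), 0.06)
  expect_true(hwe_exact(0, 0, 50)$degenerate)
  # tiny sample where the exact null distribution is enumerable by hand:
  # n_a = 2, n_b = 2 -> het in {0, 2} with probs (1/3, 2/3)
  expect_equal(hwe_exact(1, 0, 1)$p, 1 / 3)
})

test_that("QC ledger partitions the panel and applies the fixed order", {
  fx <- make_qc_fixture()
  rep <- run_qc(fx$genotypes, fx$panel,
                normal_weight_ids = rownames(fx$genotypes)[1:500])
  counts <- attr(rep, "counts")
  expect_equal(sum(counts), nrow(fx$panel))
  expect_equal(unname(counts["pass"]), 32)
  expect_equal(unname(counts["fail_monomorphic"]), 1)
  expect_equal(unname(counts["fail_triallelic"]), 1)
  expect_equal(unname(counts["fail_maf"]), 6)
  expect_equal(length(qc_passing(rep)), 32)
  expect_equal(rep$status[rep$snp_id == "mono"], "fail_monomorphic")
})

test_that("call-rate failures are caught and HWE flags do not exclude", {
  g <- cbind(lowcall = c(rep(NA, 12), rbinom(88, 2, 0.3)),
             offhwe = c(rep(1, 100)))   # all heterozygous: extreme HWE deviation
  rownames(g) <- paste0("S", 1:100)
  panel <- data.frame(snp_id = colnames(g), effect_allele = "A",
                      other_allele = "G", eaf_discovery = 0.3)
  rep <- run_qc(g, panel, normal_weight_ids = rownames(g))
  expect_equal(rep$status[1], "fail_callrate")
  expect_equal(rep$status[2], "pass")
  expect_true(rep$hwe_flag[2])
  expect_true("offhwe" %in% qc_passing(rep))
  rep2 <- run_qc(g, panel, normal_weight_ids = rownames(g), exclude_hwe = TRUE)
  expect_false("offhwe" %in% qc_passing(rep2))
  expect_warning(run_qc(g, panel, normal_weight_ids = character()),
                 "HWE screening skipped")
})

test_that("dosage TSV round-trips through the reader", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\trs1\trs2", "a\t0\t2", "b\t1\tNA", "c\t2\t1"), path)
  g <- read_genotypes_tsv(path)
  expect_equal(dim(g), c(3L, 2L))
  expect_equal(g["b", "rs2"], NA_real_)
  expect_equal(estimate_eaf(g[, "rs1"]), 0.5)
  writeLines(c("subject_id\trs1", "a\t3"), path)
  expect_error(read_genotypes_tsv(path), "dosages")
})

test_that("VCF genotypes are coded against the panel effect allele", {
  panel <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                      effect_allele = c("A", "G", "C"),
                      other_allele = c("G", "T", "T"),
                      eaf_discovery = 0.3, stringsAsFactors = FALSE)
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
           # rs1: REF is the effect allele -> dosage counts REF copies
           "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1|1",
           # rs2: ALT is the effect allele
           "1\t200\trs2\tT\tG\t.\tPASS\t.\tGT\t0/1\t1/1\t./.",
           # rs3: triallelic record
           "1\t300\trs3\tC\tT,G\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  g <- read_genotypes_vcf(path, panel)
  expect_equal(unname(g[, "rs1"]), c(2, 1, 0))
  expect_equal(unname(g[, "rs2"]), c(1, 2, NA))
  expect_true(all(is.na(g[, "rs3"])))
  expect_equal(unname(attr(g, "n_alleles")["rs3"]), 3L)
  # alleles matching only after complementation warn but code correctly
  panel2 <- panel[1, ]; panel2$effect_allele <- "T"; panel2$other_allele <- "C"
  expect_warning(g2 <- read_genotypes_vcf(path, panel2), "complement")
  expect_equal(unname(g2[, "rs1"]), c(2, 1, 0))
  # alleles matching neither way are an error
  panel3 <- panel[1, ]; panel3$effect_allele <- "A"; panel3$other_allele <- "C"
  expect_error(read_genotypes_vcf(path, panel3), "neither")
})
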