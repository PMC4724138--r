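test_that("unweighted score sums effect alleles with missing-data policies", {
  g <- rbind(a = rep(2, 32), b = rep(c(0, 1, 2, 1), 8))
  colnames(g) <- paste0("rs", 1:32)
  grs <- compute_grs(g, policy = "complete_case")
  expect_equal(grs$grs[grs$subject_id == "a"], 64)
  expect_equal(grs$grs[grs$subject_id == "b"], 32)
  # one missing SNP mean-imputed at 2 * EAF
  g2 <- rbind(a = c(2, 2, 2, 2, 2), b = c(2, 2, 2, 2, NA),
              c = c(0, 0, 0, 0, 0), d = c(0, 0, 0, 0, 1))
  colnames(g2) <- paste0("rs", 1:5)
  # EAF of rs5 over non-missing subjects (2, 0, 1)/6 = 0.5 -> impute 1
  grs2 <- compute_grs(g2, policy = "mean_impute")
  expect_equal(grs2$grs[grs2$subject_id == "b"], 8 + 2 * 0.5)
  expect_equal(grs2$n_missing[grs2$subject_id == "b"], 1)
  # complete-case drops subject b and yields integers
  grs3 <- compute_grs(g2, policy = "complete_case")
  expect_false("b" %in% grs3$subject_id)
  expect_true(all(grs3$grs == floor(grs3$grs)))
  g2["b", ] <- NA
  expect_warning(compute_grs(g2), "missing every panel SNP")
})

test_that("complete-case GRS equals the dosage row sum", {
  set.seed(21)
  g <- simulate_genotypes(50, setNames(runif(10, 0.2, 0.8), paste0("rs", 1:10)))
  grs <- compute_grs(g, policy = "complete_case")
  expect_equal(grs$grs, unname(rowSums(g)))
})

test_that("distribution shift test behaves at both extremes", {
  same <- rep(c(28, 29, 30, 31, 32), each = 40)
  out <- grs_shift_test(same, same)
  expect_equal(out$chi2, 0)
  expect_equal(out$p, 1)
  # symmetric in group order
  set.seed(31)
  a <- rpois(300, 30); b <- rpois(300, 31)
  expect_equal(grs_shift_test(a, b)$chi2, grs_shift_test(b, a)$chi2)
  # deterministic +4 shift is overwhelming evidence
  set.seed(32)
  base <- rbinom(500, 64, 0.45)
  out <- grs_shift_test(base + 4, base)
  expect_lt(out$p, 0.001)
  # matches the first-principles contingency oracle on the merged table
  expect_equal(out$chi2, oracle_chisq(out$counts))
  expect_error(grs_shift_test(rep(30, 50), rep(30, 50)), "fewer than 2")
})

test_that("tail merging enforces the minimum expected count", {
  set.seed(33)
  a <- c(rbinom(200, 64, 0.45), 2, 63)  # sparse extreme bins
  b <- rbinom(200, 64, 0.45)
  out <- grs_shift_test(a, b)
  expected <- outer(rowSums(out$counts), colSums(out$counts)) / sum(out$counts)
  expect_true(all(expected >= 5) || nrow(out$counts) == 2)
  expect_equal(out$df, nrow(out$counts) - 1)
})

test_that("cumulative GRS effect recovers a known liability slope", {
  # parameter recovery under the liability generator without
  # ascertainment distortion: proportional quotas, single group
  panel <- test_panel()
  beta_true <- 0.05
  beta <- setNames(rep(beta_true, nrow(panel)), panel$snp_id)
  hits <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(panel,
                          groups = list(G = list(quota = c(normal = 400),
                                                 female_fraction = 0.5,
                                                 age_mean = 12.5, age_sd = 2.5)),
                          beta = beta, seed = 5000 + r,
                          thresholds = c(overweight = 20, obese = 21))
    # thresholds far above reach: plain random sample, class "normal"
    grs <- compute_grs(co$genotypes)
    fit <- fit_linear_additive(grs$grs, co$phenotypes$bmi_sds)
    if (fit$ci_low <= beta_true && beta_true <= fit$ci_high) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.93)
})

test_that("constant and null scores are handled", {
  set.seed(41)
  y <- rbinom(200, 1, 0.5)
  expect_error(grs_cumulative_effect(rep(30, 200), y), "constant GRS")
  g <- rnorm(200, 30, 3)
  fit <- grs_cumulative_effect(g, y, type = "logistic")
  expect_lt(abs(fit$effect), 3 * fit$se)
})

test_that("variance explained is a non-negative nested-model increment", {
  set.seed(55)
  n <- 10000
  d <- rbinom(n, 2, 0.5)
  # construct a signal fraction of 10%: var(0.447 * d) ~ 0.1 of total
  b <- sqrt(0.1 / 0.9 / var(d))
  y <- b * d + rnorm(n)
  g <- cbind(rs1 = d)
  rownames(g) <- paste0("S", 1:n)
  out <- variance_explained(g, y)
  expect_lt(abs(out$r2_delta - 0.10), 0.01)
  # null SNPs explain nothing
  g0 <- cbind(rs1 = rbinom(n, 2, 0.3)); rownames(g0) <- rownames(g)
  out0 <- variance_explained(g0, rnorm(n))
  expect_lt(out0$r2_delta, 0.005)
  expect_gte(out0$r2_delta, -1e-12)
  # covariates fully explaining the outcome leave zero increment
  age <- runif(n, 7, 18)
  X <- cbind(`(Intercept)` = 1, age = age)
  outc <- variance_explained(g0, 2 * age, X)
  expect_equal(outc$r2_delta, 0, tolerance = 1e-12)
})

test_that("histogram counts reconcile with group sizes", {
  set.seed(61)
  grs <- rbinom(300, 64, 0.45)
  grp <- rep(c("obese", "normal"), 150)
  h <- grs_histogram(grs, grp)
  expect_equal(sum(h$obese) + sum(h$normal), 300)
  expect_equal(sum(h$obese), 150)
})
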