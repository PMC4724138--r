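test_that("saturated two-by-two logistic fit matches the cross-product oracle", {
  # genotype coded 0/2 only; genotype OR = (10*10)/(5*5) = 4, so the
  # per-allele OR over the 2-unit coding is sqrt(4) = 2
  d <- c(rep(2, 10), rep(0, 5), rep(2, 5), rep(0, 10))
  y <- c(rep(1, 15), rep(0, 15))
  r <- fit_logistic_additive(d, y)
  expect_equal(r$or_value, 2, tolerance = 1e-6)
  expect_equal(r$n_used, 30)
})

test_that("logistic fit equals an independent Newton-Raphson oracle", {
  set.seed(314)
  for (i in 1:200) {
    inst <- draw_logistic_instance()
    design <- cbind(`(Intercept)` = 1, x = inst$x)
    r <- fit_logistic_additive(inst$d, inst$y, design)
    expect_equal(r$effect, inst$oracle$coef[2], tolerance = 1e-6)
    expect_equal(r$se, inst$oracle$se[2], tolerance = 1e-6)
  }
})

test_that("null dosage gives OR near 1 and missing dosages are dropped", {
  set.seed(9)
  n <- 4000
  d <- rbinom(n, 2, 0.4)
  y <- rbinom(n, 1, 0.5)
  r <- fit_logistic_additive(d, y)
  expect_lt(abs(r$effect), 3 * r$se)
  d[1:100] <- NA
  r2 <- fit_logistic_additive(d, y)
  expect_equal(r2$n_used, n - 100)
  expect_error(fit_logistic_additive(rep(1, n), y), "constant dosage")
  expect_error(fit_logistic_additive(d, rep(1, n)), "both outcome classes")
})

test_that("separation raises an informative error", {
  d <- c(rep(0, 20), rep(2, 20))
  y <- c(rep(0, 20), rep(1, 20))
  # glm itself warns about fitted probabilities of 0/1 on the way to the
  # separation diagnosis
  suppressWarnings(expect_error(fit_logistic_additive(d, y), "separation"))
})

test_that("allele recoding inverts the odds ratio exactly", {
  set.seed(77)
  for (i in 1:20) {
    inst <- draw_logistic_instance()
    design <- cbind(`(Intercept)` = 1, x = inst$x)
    a <- fit_logistic_additive(inst$d, inst$y, design)
    b <- fit_logistic_additive(2 - inst$d, inst$y, design)
    expect_equal(a$effect, -b$effect, tolerance = 1e-8)
    expect_equal(a$or_value, 1 / b$or_value, tolerance = 1e-8)
    expect_equal(sort(c(a$ci_low, a$ci_high)),
                 sort(1 / c(b$ci_low, b$ci_high)), tolerance = 1e-8)
  }
})

test_that("shifting age leaves the SNP effect untouched", {
  set.seed(5)
  n <- 500
  age <- runif(n, 7, 18)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  grp <- sample(c("A", "B"), n, replace = TRUE)
  d <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.5 + 0.3 * d + 0.05 * age))
  r1 <- fit_logistic_additive(d, y, covariate_design(age, sex, grp))
  r2 <- fit_logistic_additive(d, y, covariate_design(age + 5, sex, grp))
  expect_equal(r1$effect, r2$effect, tolerance = 1e-6)
  expect_equal(r1$se, r2$se, tolerance = 1e-6)
})

test_that("linear fit matches the closed-form normal-equations oracle", {
  set.seed(123)
  for (i in 1:200) {
    n <- 50
    d <- rbinom(n, 2, runif(1, 0.2, 0.8))
    x <- rnorm(n)
    y <- 0.1 + 0.3 * d - 0.2 * x + rnorm(n)
    if (var(d) == 0) next
    design <- cbind(`(Intercept)` = 1, x = x)
    r <- fit_linear_additive(d, y, design)
    o <- oracle_ols(cbind(1, x, d), y)
    expect_equal(r$effect, o$coef[3], tolerance = 1e-8)
    expect_equal(r$se, o$se[3], tolerance = 1e-8)
  }
})

test_that("deterministic linear signal is recovered exactly", {
  d <- rep(c(0, 1, 2), 20)
  r <- fit_linear_additive(d, 0.5 * d)
  expect_equal(r$effect, 0.5, tolerance = 1e-12)
  expect_lt(r$se, 1e-12)
  expect_error(fit_linear_additive(d, 0.5 * d,
                                   cbind(`(Intercept)` = 1, d2 = d)),
               "collinear")
})

test_that("covariate design enforces the age-squared construction", {
  X <- covariate_design(c(8, 10), c("M", "F"), c("A", "B"))
  expect_equal(X[, "age_sq"], X[, "age"]^2)
  expect_equal(unname(X[, "sex_male"]), c(1, 0))
  expect_true("group_B" %in% colnames(X))
  expect_error(covariate_design(c(8, 10), "M", c("A", "B", "C")), "lengths")
})

test_that("Bonferroni threshold is alpha over k", {
  expect_equal(bonferroni_threshold(0.05, 32), 0.0015625)
  expect_equal(signif(bonferroni_threshold(0.05, 32), 3), 0.00156)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
  expect_error(bonferroni_threshold(1.2, 4), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "k")
})

test_that("direction consistency compares signs of log odds ratios", {
  out <- direction_consistency(c(1.31, 0.90, 1.00, 1.2),
                               c(1.39, 1.10, 1.10, NA))
  expect_equal(out$consistent[1:3], c(TRUE, FALSE, FALSE))
  expect_true(out$indeterminate[3])
  expect_true(is.na(out$consistent[4]))
  expect_equal(attr(out, "n_consistent"), 1)
})

test_that("per-SNP type-I error under null cohorts is nominal", {
  # 1000 seeded null cohorts (all liability effects zero), two panel
  # SNPs tested per cohort with the full covariate adjustment
  panel <- test_panel()[1:2, ]
  groups <- list(G = list(quota = c(normal = 60, obese = 60),
                          female_fraction = 0.5, age_mean = 12.5, age_sd = 2.5))
  pvals <- unlist(lapply(1:1000, function(s) {
    co <- simulate_cohort(panel, groups = groups, seed = 10000 + s)
    ph <- co$phenotypes
    y <- as.numeric(ph$weight_class == "obese")
    X <- covariate_design(ph$age, ph$sex, rep(c("A", "B"), length.out = nrow(ph)))
    vapply(panel$snp_id, function(s2) {
      tryCatch(fit_logistic_additive(co$genotypes[, s2], y, X)$p_two_sided,
               error = function(e) NA_real_)
    }, numeric(1))
  }))
  pvals <- pvals[!is.na(pvals)]
  expect_gt(length(pvals), 1800)
  rate <- mean(pvals < 0.05)
  # 3.5 binomial SDs around 0.05 at ~2000 draws
  expect_gt(rate, 0.033)
  expect_lt(rate, 0.067)
})
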