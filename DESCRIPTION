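Package: riskallele
Title: Candidate-SNP Case-Control Association and Unweighted Genetic Risk
    Scores for Childhood Obesity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for candidate-SNP case-control studies of
    childhood obesity: BMI and BMI-SDS phenotyping against age- and
    sex-specific references (LMS transform and cutoff tables), genotype
    quality control (call rate, monomorphic/triallelic exclusion, minor
    allele frequency, Hardy-Weinberg screening in the control group),
    two-population allele-frequency differentiation (F_ST) screening,
    per-SNP additive-model logistic and linear association with
    covariate adjustment and Bonferroni control, unweighted genetic risk
    scores with distribution-shift and cumulative-effect tests, ROC/AUC
    comparison of nested prediction models with the DeLong test,
    analytic and simulation-based power calculations, and a synthetic
    cohort generator with liability-threshold ascertainment for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pROC,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
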