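#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Draws independent SNPs with dosage probabilities
#' `((1-p)^2, 2p(1-p), p^2)` at each SNP's effect-allele frequency and
#' applies per-SNP missingness at the configured rate. Uses the current
#' RNG state; call `set.seed()` (or go through [simulate_cohort()])
#' for reproducibility.
#'
#' @param n Number of subjects.
#' @param eaf Named vector of effect-allele frequencies (names become
#'   SNP column names).
#' @param missingness Per-SNP missing-call probability (scalar or
#'   vector; default 0).
#' @param subject_ids Optional row names (default `S1..Sn`).
#' @return Dosage matrix (subjects x SNPs) with NA for missing calls.
#' @export
simulate_genotypes <- function(n, eaf, missingness = 0, subject_ids = NULL) {
  check_frequency(eaf, "eaf")
  if (any(missingness < 0 | missingness >= 1)) stop("missingness must be in [0, 1)")
  k <- length(eaf)
  missingness <- rep_len(missingness, k)
  ids <- subject_ids %||% paste0("S", seq_len(n))
  g <- matrix(NA_real_, n, k,
              dimnames = list(ids, names(eaf) %||% paste0("snp", seq_len(k))))
  for (j in seq_len(k)) {
    g[, j] <- stats::rbinom(n, 2, eaf[j])
    if (missingness[j] > 0) {
      g[stats::runif(n) < missingness[j], j] <- NA_real_
    }
  }
  g
}

#' Default group specification for the bundled study design
#'
#' Two school-based study groups with the per-class quotas of the
#' emulated two-group design: group ALIR contributes 151 normal-weight,
#' 400 overweight and 386 obese children; group CPOOA contributes 456,
#' 318 and 319. Ages are drawn Normal(12.9, 2.7) truncated to
#' `[7, 19)` years (the coverage of the screening reference) and the
#' female fraction is 0.40, matching the pooled cohort.
#'
#' @return List of per-group specs consumed by [simulate_cohort()].
#' @export
default_group_spec <- function() {
  list(
    ALIR = list(quota = c(normal = 151, overweight = 400, obese = 386),
                female_fraction = 0.40, age_mean = 12.9, age_sd = 2.7),
    CPOOA = list(quota = c(normal = 456, overweight = 318, obese = 319),
                 female_fraction = 0.40, age_mean = 12.9, age_sd = 2.7)
  )
}

#' Simulate an ascertained case-control cohort
#'
#' Liability-threshold generator: each child's BMI-SDS is
#' \deqn{z = \sum_j \beta_j d_j + \gamma_{age} (age - \bar{age}) +
#'       \gamma_{sex} 1[male] + \epsilon,\quad \epsilon \sim N(0, sd),}
#' with per-allele liability effects `beta` on the panel dosages.
#' Weight class is assigned by thresholds on the liability score
#' (defaults 1.645 for obese and 1.036 for overweight — the normal
#' quantiles of the 95th and 85th percentiles; normal-weight spans
#' (-1.036, 1.036), the 15th-85th band). Candidates are drawn in
#' batches and accepted until every (group x class) quota is filled,
#' reproducing outcome-dependent (case-control) ascertainment: with all
#' `beta = 0` the accepted genotypes are unrelated to class, while
#' positive effects enrich risk alleles among the obese.
#'
#' Height is drawn from an age-linear normal model and weight is
#' back-computed so that BMI reproduces the subject's BMI-SDS under the
#' bundled synthetic LMS reference, keeping the anthropometry round-trip
#' consistent for pipeline tests.
#'
#' @param panel SNP panel data.frame; simulation frequencies come from
#'   its `eaf_study` column (fall-back `eaf_discovery`).
#' @param groups Per-group spec list, see [default_group_spec()].
#' @param beta Named per-allele liability effects in BMI-SDS units
#'   (default all 0); names must be panel SNP ids.
#' @param covariate_effects List with `age` (per year, centred at the
#'   group mean) and `sex_male` liability effects (defaults 0).
#' @param residual_sd Liability residual SD (default 1).
#' @param missingness Per-SNP missing-call rate applied after
#'   ascertainment (default 0).
#' @param thresholds Liability thresholds `c(overweight =, obese =)`.
#' @param seed Integer seed; the same configuration and seed yield an
#'   identical cohort.
#' @param max_batches Attempt budget: error if quotas are still open
#'   after this many candidate batches (guards unreachable quotas).
#' @return List of class `sim_cohort`: `phenotypes` (subject_id, sex,
#'   age, height_cm, weight_kg, study_group, bmi, bmi_sds,
#'   weight_class), `genotypes` (dosage matrix), `config` (the full
#'   generating configuration, for provenance).
#' @export
simulate_cohort <- function(panel, groups = default_group_spec(),
                            beta = NULL, covariate_effects = list(),
                            residual_sd = 1, missingness = 0,
                            thresholds = c(overweight = 1.036, obese = 1.645),
                            seed = 1, max_batches = 200) {
  set.seed(seed)
  eaf <- panel$eaf_study %||% panel$eaf_discovery
  if (is.null(eaf) || any(is.na(eaf))) eaf <- panel$eaf_discovery
  eaf <- stats::setNames(eaf, panel$snp_id)
  check_frequency(eaf, "panel simulation EAF", open = TRUE)
  b <- stats::setNames(rep(0, nrow(panel)), panel$snp_id)
  if (!is.null(beta)) {
    unknown <- setdiff(names(beta), panel$snp_id)
    if (length(unknown)) stop("beta names not in panel: ", paste(unknown, collapse = ", "))
    b[names(beta)] <- beta
  }
  g_age <- covariate_effects$age %||% 0
  g_sex <- covariate_effects$sex_male %||% 0
  lms <- load_lms_reference()
  classes <- c("normal", "overweight", "obese")

  pheno <- list(); geno <- list(); counter <- 0L
  for (gname in names(groups)) {
    spec <- groups[[gname]]
    open <- stats::setNames(rep(0, length(classes)), classes)
    open[intersect(names(spec$quota), classes)] <-
      spec$quota[intersect(names(spec$quota), classes)]
    batch_size <- max(200L, 4L * sum(open))
    batches <- 0L
    while (any(open > 0)) {
      batches <- batches + 1L
      if (batches > max_batches) {
        stop("quota unreachable for group ", gname, " after ", max_batches,
             " batches; open: ",
             paste(names(open[open > 0]), open[open > 0], collapse = ", "))
      }
      G <- simulate_genotypes(batch_size, eaf)
      age <- pmin(pmax(stats::rnorm(batch_size, spec$age_mean, spec$age_sd), 7), 18.99)
      sex <- ifelse(stats::runif(batch_size) < spec$female_fraction, "female", "male")
      z <- as.vector(G %*% b) + g_age * (age - spec$age_mean) +
        g_sex * (sex == "male") + stats::rnorm(batch_size, 0, residual_sd)
      cls <- ifelse(z >= thresholds[["obese"]], "obese",
                    ifelse(z >= thresholds[["overweight"]], "overweight",
                           ifelse(z > -thresholds[["overweight"]], "normal", "below")))
      for (cl in classes) {
        if (open[[cl]] == 0) next
        idx <- which(cls == cl)
        take <- idx[seq_len(min(length(idx), open[[cl]]))]
        if (!length(take)) next
        open[[cl]] <- open[[cl]] - length(take)
        ids <- paste0("S", counter + seq_along(take))
        counter <- counter + length(take)
        bmi <- mapply(function(zz, s, a) {
          row <- lms[lms$sex == s, ]
          row <- row[which.min(abs(row$age - a)), ]
          lms_z_inverse(zz, row$L, row$M, row$S)
        }, z[take], sex[take], age[take])
        height <- 110 + 4.5 * age[take] + stats::rnorm(length(take), 0, 6)
        pheno[[length(pheno) + 1]] <- data.frame(
          subject_id = ids, sex = sex[take], age = age[take],
          height_cm = height, weight_kg = bmi * (height / 100)^2,
          study_group = gname, bmi = bmi, bmi_sds = z[take],
          weight_class = cl, stringsAsFactors = FALSE)
        gm <- G[take, , drop = FALSE]
        rownames(gm) <- ids
        geno[[length(geno) + 1]] <- gm
      }
    }
  }
  phenotypes <- do.call(rbind, pheno)
  genotypes <- do.call(rbind, geno)
  if (any(missingness > 0)) {
    miss <- rep_len(missingness, ncol(genotypes))
    for (j in seq_len(ncol(genotypes))) {
      genotypes[stats::runif(nrow(genotypes)) < miss[j], j] <- NA_real_
    }
  }
  out <- list(phenotypes = phenotypes, genotypes = genotypes,
              config = list(groups = groups, beta = b,
                            covariate_effects = list(age = g_age, sex_male = g_sex),
                            residual_sd = residual_sd, missingness = missingness,
                            thresholds = thresholds, seed = seed,
                            eaf = eaf))
  class(out) <- "sim_cohort"
  out
}

#' Simulate a case-control dataset under a direct logistic disease model
#'
#' Alternative to the liability generator for odds-ratio recovery
#' experiments: control genotypes are drawn from HWE at the population
#' frequencies and case genotypes from HWE at the enriched frequencies
#' implied by per-SNP allelic odds ratios, so the generating per-allele
#' OR of each SNP is known exactly.
#'
#' @param n_cases,n_controls Group sizes.
#' @param eaf Named population effect-allele frequencies.
#' @param or Named allelic odds ratios (default 1 for all SNPs).
#' @param seed Integer seed.
#' @return List: `genotypes` (cases stacked above controls), `outcome`
#'   (1 = case), `subject_id`.
#' @export
simulate_case_control <- function(n_cases, n_controls, eaf, or = NULL, seed = 1) {
  set.seed(seed)
  check_frequency(eaf, "eaf", open = TRUE)
  o <- stats::setNames(rep(1, length(eaf)), names(eaf))
  if (!is.null(or)) o[names(or)] <- or
  p_case <- eaf * o / (1 - eaf + eaf * o)
  g_case <- simulate_genotypes(n_cases, p_case,
                               subject_ids = paste0("case", seq_len(n_cases)))
  g_ctrl <- simulate_genotypes(n_controls, eaf,
                               subject_ids = paste0("ctrl", seq_len(n_controls)))
  list(genotypes = rbind(g_case, g_ctrl),
       outcome = c(rep(1, n_cases), rep(0, n_controls)),
       subject_id = c(rownames(g_case), rownames(g_ctrl)))
}

#' Write a simulated cohort to the pipeline's input formats
#'
#' Emits the phenotype CSV, the genotype dosage TSV and a provenance
#' sidecar recording the generating configuration (including the seed).
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- file.path(dir, "phenotypes.csv")
  gt <- file.path(dir, "genotypes.tsv")
  pv <- file.path(dir, "provenance.txt")
  utils::write.csv(cohort$phenotypes[, c("subject_id", "sex", "age",
                                         "height_cm", "weight_kg", "study_group")],
                   ph, row.names = FALSE, quote = FALSE)
  g <- data.frame(subject_id = rownames(cohort$genotypes),
                  cohort$genotypes, check.names = FALSE)
  utils::write.table(g, gt, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  lines <- c(paste0("seed: ", cfg$seed),
             paste0("residual_sd: ", cfg$residual_sd),
             paste0("thresholds: overweight=", cfg$thresholds[["overweight"]],
                    " obese=", cfg$thresholds[["obese"]]),
             paste0("beta: ", paste(names(cfg$beta), cfg$beta, sep = "=",
                                    collapse = " ")),
             paste0("eaf: ", paste(names(cfg$eaf), cfg$eaf, sep = "=",
                                   collapse = " ")))
  writeLines(lines, pv)
  invisible(c(phenotypes = ph, genotypes = gt, provenance = pv))
}
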