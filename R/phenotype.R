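#' Body mass index from weight and height
#'
#' BMI is weight in kilograms divided by the squared height in metres.
#' Height is taken in centimetres, the unit used on paediatric
#' anthropometry forms.
#'
#' @param weight_kg Body weight in kg (positive).
#' @param height_cm Standing height in cm (positive).
#' @return BMI in kg/m^2. Vectorised over both arguments.
#' @examples
#' compute_bmi(47.09, 156.2)
#' compute_bmi(100, 200)
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  check_positive(weight_kg, "weight_kg")
  check_positive(height_cm, "height_cm")
  weight_kg / (height_cm / 100)^2
}

#' Load a BMI cutoff table for weight-status screening
#'
#' Reads a CSV with columns `sex` (male/female), `age_band` (integer
#' years), `overweight_cutoff` and `obesity_cutoff` (kg/m^2), and
#' optionally `normal_lower_cutoff`. The bundled table
#' `bmi_cutoffs_cn.csv` is the Chinese school-age screening reference
#' (ages 7-18) used for case/control definition: BMI at or above the
#' age- and sex-specific 95th-percentile cutoff is obese, between the
#' 85th and 95th is overweight.
#'
#' @param path CSV path; defaults to the bundled Chinese reference.
#' @return A data.frame of class `bmi_cutoff_table`.
#' @export
load_bmi_cutoffs <- function(path = system.file("extdata", "bmi_cutoffs_cn.csv",
                                                package = "riskallele")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_band", "overweight_cutoff", "obesity_cutoff")
  if (!all(need %in% names(tab))) {
    stop("cutoff table must have columns: ", paste(need, collapse = ", "))
  }
  tab$sex <- normalize_sex(tab$sex)
  if (any(tab$overweight_cutoff >= tab$obesity_cutoff)) {
    stop("overweight cutoff must be below obesity cutoff in every row")
  }
  # screening cutoffs rise with age within sex; a violation signals a typo
  for (s in unique(tab$sex)) {
    rows <- tab[tab$sex == s, ]
    rows <- rows[order(rows$age_band), ]
    if (is.unsorted(rows$overweight_cutoff) || is.unsorted(rows$obesity_cutoff)) {
      warning("cutoffs are not non-decreasing in age for sex ", s)
    }
  }
  class(tab) <- c("bmi_cutoff_table", "data.frame")
  tab
}

#' Assign weight class from BMI and an age/sex cutoff table
#'
#' Ages are floored to integer bands `[k, k+1)`; ages above the oldest
#' band reuse its cutoffs, ages below the youngest cannot be screened
#' and come back `"unclassified"` with a warning. A BMI exactly equal to
#' a cutoff goes to the higher class. When the table carries a
#' `normal_lower_cutoff` column, BMI below it is also `"unclassified"`
#' (the underweight tail is not a study class).
#'
#' @param bmi BMI in kg/m^2.
#' @param sex `"male"`/`"female"` (or `"M"`/`"F"`).
#' @param age Age in years (decimal).
#' @param cutoffs A `bmi_cutoff_table`, see [load_bmi_cutoffs()].
#' @return Character vector: `"normal"`, `"overweight"`, `"obese"` or
#'   `"unclassified"`.
#' @examples
#' cuts <- load_bmi_cutoffs()
#' classify_weight(23.0, "male", 10, cuts)   # obese
#' classify_weight(22.0, "female", 12, cuts) # overweight
#' @export
classify_weight <- function(bmi, sex, age, cutoffs = load_bmi_cutoffs()) {
  sex <- normalize_sex(sex)
  n <- max(length(bmi), length(sex), length(age))
  bmi <- rep_len(bmi, n); sex <- rep_len(sex, n); age <- rep_len(age, n)
  bands <- floor(age)
  out <- rep("unclassified", n)
  min_band <- min(cutoffs$age_band)
  max_band <- max(cutoffs$age_band)
  low <- bands < min_band
  if (any(low)) {
    warning(sum(low), " subject(s) below age ", min_band,
            " left unclassified")
  }
  bands <- pmin(bands, max_band)
  idx <- match(paste(sex, bands), paste(cutoffs$sex, cutoffs$age_band))
  has_floor <- "normal_lower_cutoff" %in% names(cutoffs)
  for (i in seq_len(n)) {
    if (low[i] || is.na(idx[i]) || !is.finite(bmi[i])) next
    row <- cutoffs[idx[i], ]
    out[i] <- if (bmi[i] >= row$obesity_cutoff) "obese"
      else if (bmi[i] >= row$overweight_cutoff) "overweight"
      else if (has_floor && !is.na(row$normal_lower_cutoff) &&
               bmi[i] < row$normal_lower_cutoff) "unclassified"
      else "normal"
  }
  out
}

#' Load an LMS growth reference
#'
#' Reads a CSV with columns `sex`, `age`, `L`, `M`, `S`. `M` is the
#' median BMI (kg/m^2), `S` the coefficient of variation and `L` the
#' Box-Cox power of the reference at that sex and age. Growth-reference
#' tables (e.g. the WHO 5-19y BMI-for-age reference) are external data
#' supplied by the user; the bundled
#' `lms_reference_synthetic.csv` is a smooth synthetic stand-in for
#' tests and examples only, not a published reference.
#'
#' @param path CSV path; defaults to the bundled synthetic table.
#' @return A data.frame of class `lms_reference`.
#' @export
load_lms_reference <- function(path = system.file("extdata",
                                                  "lms_reference_synthetic.csv",
                                                  package = "riskallele")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age", "L", "M", "S")
  if (!all(need %in% names(tab))) {
    stop("LMS reference must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$S <= 0) || any(tab$M <= 0)) stop("LMS reference needs S > 0 and M > 0")
  class(tab) <- c("lms_reference", "data.frame")
  tab
}

#' BMI standard deviation score via the LMS transform
#'
#' Converts BMI to an age- and sex-standardised z-score using the LMS
#' (Box-Cox) parameters of a growth reference:
#' \deqn{z = \frac{(BMI/M)^L - 1}{L\,S}} for `L != 0` and
#' \eqn{z = \log(BMI/M)/S} at `L = 0`. Reference rows are matched on
#' sex and nearest tabulated age; an age outside the table's coverage
#' is an error naming the offending subject.
#'
#' @param bmi BMI in kg/m^2.
#' @param sex `"male"`/`"female"` (or `"M"`/`"F"`).
#' @param age Age in years.
#' @param lms An `lms_reference`, see [load_lms_reference()].
#' @return Numeric BMI-SDS vector.
#' @export
bmi_sds <- function(bmi, sex, age, lms = load_lms_reference()) {
  sex <- normalize_sex(sex)
  n <- max(length(bmi), length(sex), length(age))
  bmi <- rep_len(bmi, n); sex <- rep_len(sex, n); age <- rep_len(age, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    rows <- lms[lms$sex == sex[i], ]
    if (!nrow(rows) || age[i] < min(rows$age) - 0.5 || age[i] > max(rows$age) + 0.5) {
      stop(sprintf("age %.2f (subject %d) outside LMS reference coverage [%s, %s]",
                   age[i], i, min(rows$age), max(rows$age)))
    }
    row <- rows[which.min(abs(rows$age - age[i])), ]
    out[i] <- lms_z(bmi[i], row$L, row$M, row$S)
  }
  out
}

# The LMS transform itself, on scalar parameters (exported for direct use
# with ad-hoc L/M/S values).
#' @rdname bmi_sds
#' @param L,M,S Box-Cox power, median and coefficient of variation.
#' @export
lms_z <- function(bmi, L, M, S) {
  check_positive(bmi, "bmi"); check_positive(M, "M"); check_positive(S, "S")
  if (abs(L) < .Machine$double.eps^0.5) log(bmi / M) / S
  else ((bmi / M)^L - 1) / (L * S)
}

# invert lms_z: BMI that maps to z under (L, M, S); used by the cohort
# simulator to realise anthropometry from a liability z-score
lms_z_inverse <- function(z, L, M, S) {
  if (abs(L) < .Machine$double.eps^0.5) M * exp(S * z)
  else M * (1 + L * S * z)^(1 / L)
}

#' Read a phenotype table
#'
#' Expects a header CSV with columns `subject_id`, `sex` (M/F or
#' male/female), `age` (years), `height_cm`, `weight_kg`,
#' `study_group`. Derives `bmi` and, when references are supplied,
#' `bmi_sds` and `weight_class`.
#'
#' @param path CSV path.
#' @param cutoffs Optional `bmi_cutoff_table` for weight classification.
#' @param lms Optional `lms_reference` for BMI-SDS.
#' @return A data.frame, one row per subject.
#' @export
read_phenotypes <- function(path, cutoffs = NULL, lms = NULL) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age", "height_cm", "weight_kg", "study_group")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("phenotype file misses column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ph$subject_id)) stop("duplicated subject_id in phenotype file")
  ph$sex <- normalize_sex(ph$sex)
  ph$bmi <- compute_bmi(ph$weight_kg, ph$height_cm)
  if (!is.null(lms)) ph$bmi_sds <- bmi_sds(ph$bmi, ph$sex, ph$age, lms)
  if (!is.null(cutoffs)) ph$weight_class <- classify_weight(ph$bmi, ph$sex, ph$age, cutoffs)
  ph
}

normalize_sex <- function(sex) {
  out <- c(m = "male", male = "male", f = "female", female = "female")[tolower(as.character(sex))]
  if (any(is.na(out))) stop("sex must be one of M/F/male/female")
  unname(out)
}
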