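## clinical_records: ingest raw survey rows, apply exclusion rules, and
## compute derived clinical measures (BMI, LDL, HOMA-IR).

#' Canonical cohort column names
#'
#' One row per subject.  Units: age in years; weight kg; height m; waist cm;
#' sbp/dbp mmHg; fpg (fasting plasma glucose), tg, hdl, tc, ldl_direct in
#' mg/dL; insulin in uU/mL (numerically identical to mU/L, the scale the
#' HOMA constant 405 is defined for).  `sex` is "male"/"female"; the three
#' flags are logical.  `ldl_direct` is the directly assayed LDL, present
#' only for some subjects.
#'
#' @export
cohort_columns <- function() {
  c("subject_id", "age", "sex", "weight", "height", "waist", "sbp", "dbp",
    "fpg", "insulin", "tg", "hdl", "tc", "ldl_direct",
    "diabetes_history", "antihypertensive_med", "pregnant")
}

#' Body-mass index
#'
#' BMI is weight (kg) divided by height (m) squared.
#'
#' @param weight weight in kg, strictly positive.
#' @param height height in m, strictly positive.
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(81, 1.8)   # 25
#' @export
compute_bmi <- function(weight, height) {
  if (any(is.na(weight)) || any(is.na(height)) ||
      any(weight <= 0) || any(height <= 0))
    abort("compute_bmi: weight and height must be present and strictly positive",
          "homacut_invalid_measurement")
  weight / height^2
}

#' HOMA-IR insulin-resistance score
#'
#' Homeostasis model assessment of insulin resistance:
#' fasting insulin (uU/mL) x fasting glucose (mg/dL) / 405.
#'
#' @param insulin fasting insulin in uU/mL, non-negative.
#' @param glucose fasting plasma glucose in mg/dL, non-negative.
#' @return unitless HOMA-IR score.
#' @examples
#' compute_homa_ir(10, 81)  # 2
#' @export
compute_homa_ir <- function(insulin, glucose) {
  if (any(is.na(insulin)) || any(is.na(glucose)))
    abort("compute_homa_ir: insulin and glucose must both be present",
          "homacut_missing_lab")
  if (any(insulin < 0) || any(glucose < 0))
    abort("compute_homa_ir: inputs must be non-negative",
          "homacut_invalid_measurement")
  insulin * glucose / 405
}

#' LDL-cholesterol, Friedewald or direct
#'
#' For triglycerides at or below 400 mg/dL, LDL is estimated by the
#' Friedewald formula TC - HDL - TG/5 (all mg/dL).  Above 400 mg/dL the
#' formula is invalid and the directly assayed value is used; if that is
#' absent, `NA` is returned (the record is retained — LDL enters no
#' metabolic-syndrome rule).
#'
#' @param tc total cholesterol, mg/dL.
#' @param hdl HDL-cholesterol, mg/dL.
#' @param tg triglycerides, mg/dL.
#' @param ldl_direct directly assayed LDL, mg/dL, or `NA`.
#' @return LDL-cholesterol in mg/dL, `NA` where undeterminable.
#' @examples
#' compute_ldl(200, 50, 150)            # 120
#' compute_ldl(250, 40, 450, 130)       # 130 (direct branch)
#' @export
compute_ldl <- function(tc, hdl, tg, ldl_direct = NA_real_) {
  if (any(is.na(tc)) || any(is.na(hdl)) || any(is.na(tg)))
    abort("compute_ldl: tc, hdl and tg must be present", "homacut_missing_lab")
  n <- max(length(tc), length(hdl), length(tg), length(ldl_direct))
  tc <- rep_len(tc, n); hdl <- rep_len(hdl, n)
  tg <- rep_len(tg, n); ldl_direct <- rep_len(as.numeric(ldl_direct), n)
  ifelse(tg <= 400, tc - hdl - tg / 5, ldl_direct)
}

#' Apply cohort exclusion rules
#'
#' Drops pregnant subjects, subjects with any missing lab among
#' triglycerides, HDL, total cholesterol, fasting glucose and fasting
#' insulin, and subjects outside the 25-64 year age range (both bounds
#' retained).  Each excluded record gets exactly one reason code, the first
#' match in the fixed order pregnancy, missing-lab, age-range, so the log
#' is deterministic.
#'
#' @param records data frame with the columns of [cohort_columns()].
#' @return list with `retained` (data frame) and `excluded` (data frame with
#'   `subject_id` and `reason`).
#' @export
apply_exclusions <- function(records) {
  check_columns(records,
                c("subject_id", "age", "pregnant",
                  "tg", "hdl", "tc", "fpg", "insulin"),
                "apply_exclusions")
  preg <- !is.na(records$pregnant) & records$pregnant
  labs_missing <- is.na(records$tg) | is.na(records$hdl) | is.na(records$tc) |
    is.na(records$fpg) | is.na(records$insulin)
  age_out <- is.na(records$age) | records$age < 25 | records$age > 64
  reason <- rep(NA_character_, nrow(records))
  reason[age_out] <- "age-range"
  reason[labs_missing] <- "missing-lab"
  reason[preg] <- "pregnancy"
  drop <- !is.na(reason)
  retained <- records[!drop, , drop = FALSE]
  if (nrow(retained) == 0L)
    abort("apply_exclusions: no records remain after exclusions",
          "homacut_empty_cohort")
  rownames(retained) <- NULL
  list(retained = retained,
       excluded = data.frame(subject_id = records$subject_id[drop],
                             reason = reason[drop],
                             stringsAsFactors = FALSE))
}

#' Add derived clinical measures to a cohort
#'
#' Appends `bmi`, `ldl` and `homa_ir` columns.  Intended to run after
#' [apply_exclusions()], so the labs feeding HOMA-IR and LDL are present;
#' BMI is `NA` where weight or height is missing and an error is raised for
#' non-positive anthropometry.
#'
#' @param records data frame of retained survey records.
#' @return the data frame with three derived columns appended.
#' @export
derive_clinical <- function(records) {
  check_columns(records, c("weight", "height", "tc", "hdl", "tg",
                           "fpg", "insulin"), "derive_clinical")
  ld <- if ("ldl_direct" %in% names(records))
    as.numeric(records$ldl_direct) else NA_real_
  ok <- !is.na(records$weight) & !is.na(records$height)
  if (any(records$weight[ok] <= 0) || any(records$height[ok] <= 0))
    abort("derive_clinical: non-positive weight or height",
          "homacut_invalid_measurement")
  bmi <- rep(NA_real_, nrow(records))
  bmi[ok] <- compute_bmi(records$weight[ok], records$height[ok])
  records$bmi <- bmi
  records$ldl <- compute_ldl(records$tc, records$hdl, records$tg, ld)
  records$homa_ir <- compute_homa_ir(records$insulin, records$fpg)
  records
}

#' Read a survey cohort from delimited text
#'
#' Expects a header row with the canonical column names of
#' [cohort_columns()]; comma-separated by default, tab accepted.  Missing
#' values are empty fields or `NA`.  Inputs in SI units (mmol/L) are
#' rejected, not converted: a glucose column whose median is below 25
#' cannot be mg/dL.
#'
#' @param path file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return data frame of survey records.
#' @export
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path))
    abort(sprintf("read_cohort: no such file: %s", path), "homacut_io")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  check_columns(df, setdiff(cohort_columns(), "ldl_direct"), "read_cohort")
  if (!"ldl_direct" %in% names(df)) df$ldl_direct <- NA_real_
  for (col in c("diabetes_history", "antihypertensive_med", "pregnant"))
    df[[col]] <- as.logical(df[[col]])
  bad_sex <- !df$sex %in% c("male", "female")
  if (any(bad_sex))
    abort("read_cohort: sex must be 'male' or 'female'", "homacut_bad_value")
  med_fpg <- stats::median(df$fpg, na.rm = TRUE)
  if (is.finite(med_fpg) && med_fpg < 25)
    abort("read_cohort: fpg looks like mmol/L; inputs must be mg/dL (no unit conversion is performed)",
          "homacut_bad_units")
  df[cohort_columns()]
}

#' Write a cohort (or any result table) as delimited text
#'
#' @param df data frame.
#' @param path output path.
#' @param sep field separator.
#' @export
write_cohort <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}
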