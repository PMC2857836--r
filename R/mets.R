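## mets_classification: ATPIII / IDF metabolic-syndrome rules, component
## counts, metabolically-normal subjects, diabetes stratum.
##
## All threshold operators follow the printed rule sets exactly:
## ATPIII waist >=102 (men) / >=88 (women); IDF waist strictly >90 (both
## sexes, Iranian cut-off); tg >=150; HDL <40 (men) / <50 (women);
## BP >=130 systolic or >=85 diastolic or on antihypertensive medication;
## fpg >=100 or diabetic.  The normal-subject rule uses tc <=200 and
## bmi <=25 inclusive.

#' Diabetes stratum assignment
#'
#' The survey records self-reported diabetes history; a fasting glucose of
#' 126 mg/dL or more is the conventional biochemical diagnosis.  The
#' default rule combines the two; `"history_only"` uses the interview flag
#' alone.
#'
#' @param records data frame with `diabetes_history` (and `fpg` for the
#'   default rule).
#' @param rule `"history_or_fpg126"` (default) or `"history_only"`.
#' @return character vector, `"diabetic"` or `"nondiabetic"` per record.
#' @export
diabetes_stratum <- function(records,
                             rule = c("history_or_fpg126", "history_only")) {
  rule <- match.arg(rule)
  check_columns(records, "diabetes_history", "diabetes_stratum")
  if (any(is.na(records$diabetes_history)))
    abort("diabetes_stratum: diabetes_history has missing values",
          "homacut_incomplete_record")
  dm <- records$diabetes_history
  if (rule == "history_or_fpg126") {
    check_columns(records, "fpg", "diabetes_stratum")
    if (any(is.na(records$fpg)))
      abort("diabetes_stratum: fpg has missing values",
            "homacut_incomplete_record")
    dm <- dm | records$fpg >= 126
  }
  ifelse(dm, "diabetic", "nondiabetic")
}

#' ATPIII component flags and count
#'
#' Returns the five ATPIII risk components as logical columns plus their
#' sum: abdominal obesity (sex-specific waist), high triglycerides, low
#' HDL (sex-specific), high blood pressure (either pressure at threshold
#' or on antihypertensive medication), and high fasting glucose (at
#' threshold or diabetic).
#'
#' @param records data frame of survey records.
#' @param diabetic logical vector, the diabetes stratum (see
#'   [diabetes_stratum()]); defaults to the package's default rule.
#' @return data frame with columns `abdominal_obesity_atpiii`, `high_tg`,
#'   `low_hdl`, `high_bp`, `high_fpg`, `atpiii_count`.
#' @export
atpiii_components <- function(records, diabetic = NULL) {
  need <- c("sex", "waist", "tg", "hdl", "sbp", "dbp", "fpg",
            "antihypertensive_med")
  check_columns(records, need, "atpiii_components")
  if (anyNA(records[need]))
    abort("atpiii_components: missing component inputs",
          "homacut_incomplete_record")
  if (is.null(diabetic))
    diabetic <- diabetes_stratum(records) == "diabetic"
  male <- records$sex == "male"
  waist_flag <- ifelse(male, records$waist >= 102, records$waist >= 88)
  tg_flag  <- records$tg >= 150
  hdl_flag <- ifelse(male, records$hdl < 40, records$hdl < 50)
  bp_flag  <- records$sbp >= 130 | records$dbp >= 85 |
    records$antihypertensive_med
  fpg_flag <- records$fpg >= 100 | diabetic
  data.frame(abdominal_obesity_atpiii = waist_flag,
             high_tg = tg_flag, low_hdl = hdl_flag,
             high_bp = bp_flag, high_fpg = fpg_flag,
             atpiii_count = as.integer(waist_flag) + tg_flag + hdl_flag +
               bp_flag + fpg_flag)
}

#' ATPIII metabolic-syndrome label
#'
#' True when three or more of the five ATPIII components are present.
#'
#' @inheritParams atpiii_components
#' @return logical vector.
#' @export
classify_atpiii <- function(records, diabetic = NULL) {
  atpiii_components(records, diabetic)$atpiii_count >= 3L
}

#' IDF metabolic-syndrome label
#'
#' Central obesity (waist strictly greater than 90 cm, both sexes —
#' population-specific cut-off) is mandatory, plus any two of high
#' triglycerides, low HDL, high blood pressure, high fasting glucose
#' (same component definitions as ATPIII).
#'
#' @inheritParams atpiii_components
#' @return logical vector.
#' @export
classify_idf <- function(records, diabetic = NULL) {
  comp <- atpiii_components(records, diabetic)
  central <- records$waist > 90
  secondary <- as.integer(comp$high_tg) + comp$low_hdl + comp$high_bp +
    comp$high_fpg
  central & secondary >= 2L
}

#' Metabolically normal subjects
#'
#' A subject without any metabolic abnormality: tg < 150, sex-specific HDL
#' at or above 40 (men) / 50 (women), fpg < 100, sbp < 130, dbp < 85, total
#' cholesterol <= 200 and BMI <= 25, and not on antihypertensive medication
#' (medication use implies abnormality).
#'
#' @param records data frame including the derived `bmi` column.
#' @return logical vector.
#' @export
is_metabolically_normal <- function(records) {
  need <- c("sex", "tg", "hdl", "fpg", "sbp", "dbp", "tc", "bmi",
            "antihypertensive_med")
  check_columns(records, need, "is_metabolically_normal")
  if (anyNA(records[need]))
    abort("is_metabolically_normal: missing inputs",
          "homacut_incomplete_record")
  male <- records$sex == "male"
  records$tg < 150 &
    ifelse(male, records$hdl >= 40, records$hdl >= 50) &
    records$fpg < 100 & records$sbp < 130 & records$dbp < 85 &
    records$tc <= 200 & records$bmi <= 25 &
    !records$antihypertensive_med
}

#' Full metabolic-syndrome assessment table
#'
#' One row per subject: component flags, ATPIII count, MetS labels under
#' both rule sets, metabolically-normal flag and diabetes stratum.
#'
#' @param records derived cohort (see [derive_clinical()]).
#' @param diabetes_rule passed to [diabetes_stratum()].
#' @return data frame, one row per input record.
#' @export
assess_mets <- function(records, diabetes_rule = "history_or_fpg126") {
  stratum <- diabetes_stratum(records, diabetes_rule)
  diabetic <- stratum == "diabetic"
  comp <- atpiii_components(records, diabetic)
  out <- data.frame(subject_id = records$subject_id, comp,
                    central_obesity_idf = records$waist > 90)
  out$mets_atpiii <- comp$atpiii_count >= 3L
  out$mets_idf <- classify_idf(records, diabetic)
  out$metabolically_normal <- is_metabolically_normal(records)
  ## belt-and-braces: the normal definition is strictly stronger than
  ## "no MetS" under both rule sets
  stopifnot(!any(out$metabolically_normal & (out$mets_atpiii | out$mets_idf)))
  out$stratum <- stratum
  out
}
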