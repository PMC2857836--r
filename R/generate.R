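## synthetic_survey: cohorts with a known latent structure.
##
## One latent insulin-resistance factor Z ~ N(0,1) drives insulin, glucose,
## waist, triglycerides, HDL (negatively), blood pressure and BMI, with
## age/sex effects and a location shift for diabetic subjects in glucose,
## insulin, waist, triglycerides, blood pressure and BMI.  This is the
## simplest mechanism that yields a tunable HOMA-IR-vs-MetS AUC together
## with realistic co-occurrence of the syndrome components, and it lets
## every downstream stage be tested against ground truth.

default_sample_strata <- function() {
  ## the survey oversamples older subjects and women relative to census
  age <- c("25-34" = 0.30, "35-44" = 0.27, "45-54" = 0.24, "55-64" = 0.19)
  sex <- c(male = 0.45, female = 0.55)
  out <- expand.grid(age_band = names(age), sex = names(sex),
                     stringsAsFactors = FALSE)
  out$proportion <- age[out$age_band] * sex[out$sex]
  out
}

#' Default census strata table
#'
#' Age-decade x sex population proportions used for post-stratification
#' when no census file is supplied.  These are synthetic stand-in margins
#' with the young-skewed age structure typical of a rapidly grown
#' population (they are not an official census extract); the same table
#' ships as `inst/extdata/census_strata_synthetic.csv`.
#'
#' @return data frame with `age_band`, `sex`, `proportion`.
#' @export
default_census <- function() {
  age <- c("25-34" = 0.36, "35-44" = 0.27, "45-54" = 0.21, "55-64" = 0.16)
  sex <- c(male = 0.50, female = 0.50)
  out <- expand.grid(age_band = names(age), sex = names(sex),
                     stringsAsFactors = FALSE)
  out$proportion <- age[out$age_band] * sex[out$sex]
  out
}

#' Synthetic survey generator configuration
#'
#' The defaults are the package's frozen "survey-like" preset: a cohort of
#' 4,233 pre-exclusion subjects aged 25-64 with ~12% diabetic subjects,
#' log-normal insulin/glucose/triglycerides, metabolic-syndrome prevalence
#' near one third and a latent-factor dependence placing the HOMA-IR
#' versus MetS AUC in the high-0.6 band.  `loadings` are the latent-factor
#' coefficients per variable (log scale for the log-normal variables);
#' `diabetic_shift` the location shifts for diabetic subjects;
#' `age_effect_scale` multiplies every age trend (0 switches them off);
#' `missing_rates` the per-lab missingness applied last.
#'
#' @param n cohort size before exclusions.
#' @param seed integer seed (`NULL` for the session RNG).
#' @param sample_strata sampling proportions per age-band x sex stratum.
#' @param loadings named numeric latent-factor loadings.
#' @param marginals named list of marginal location/scale parameters.
#' @param diabetic_fraction proportion of diabetic subjects.
#' @param diabetic_shift named numeric location shifts for diabetics.
#' @param age_effect_scale multiplier on all age trends.
#' @param missing_rates named missingness probabilities per lab field.
#' @param pregnancy_rate pregnancy probability among women aged 45 or less.
#' @param history_rate probability a diabetic subject reports a history.
#' @return an object of class `"survey_config"`.
#' @export
survey_config <- function(n = 4233, seed = NULL,
                          sample_strata = default_sample_strata(),
                          loadings = c(insulin = 0.25, glucose = 0.04,
                                       waist = 5.5, tg = 0.30, hdl = 4.0,
                                       sbp = 6.0, dbp = 3.5, bmi = 1.8),
                          marginals = list(
                            insulin = c(meanlog = log(7.6), sdlog = 0.52),
                            glucose = c(meanlog = log(89), sdlog = 0.075),
                            waist = c(male = 92.5, female = 91, sd = 7),
                            tg = c(meanlog = log(150), sdlog = 0.38),
                            hdl = c(male = 42, female = 48, sd = 8),
                            sbp = c(mean = 120, sd = 11),
                            dbp = c(mean = 75, sd = 7),
                            bmi = c(mean = 25.5, female_shift = 1, sd = 3),
                            ldl = c(mean = 115, sd = 28),
                            height = c(male = 1.71, female = 1.59,
                                       male_sd = 0.07, female_sd = 0.065)),
                          diabetic_fraction = 0.12,
                          diabetic_shift = c(insulin = 0.32, glucose = 0.58,
                                             waist = 3, tg = 0.10, sbp = 4,
                                             bmi = 1),
                          age_effect_scale = 1,
                          missing_rates = c(insulin = 0.12, fpg = 0.04,
                                            tg = 0.04, hdl = 0.04,
                                            tc = 0.04),
                          pregnancy_rate = 0.03,
                          history_rate = 0.75) {
  if (n <= 0) abort("survey_config: n must be positive",
                    "homacut_invalid_argument")
  if (diabetic_fraction < 0 || diabetic_fraction > 1 ||
      pregnancy_rate < 0 || pregnancy_rate > 1 ||
      any(missing_rates < 0) || any(missing_rates > 1))
    abort("survey_config: proportions must lie in [0, 1]",
          "homacut_invalid_argument")
  if (any(vapply(marginals, function(m) any(m[grepl("sd", names(m))] <= 0),
                 logical(1))))
    abort("survey_config: scales must be positive", "homacut_invalid_argument")
  structure(list(n = as.integer(n), seed = seed,
                 sample_strata = sample_strata, loadings = loadings,
                 marginals = marginals,
                 diabetic_fraction = diabetic_fraction,
                 diabetic_shift = diabetic_shift,
                 age_effect_scale = age_effect_scale,
                 missing_rates = missing_rates,
                 pregnancy_rate = pregnancy_rate,
                 history_rate = history_rate),
            class = "survey_config")
}

#' Independence (null) generator configuration
#'
#' The preset with every score-label dependence channel switched off: all
#' latent loadings zero, no diabetic subjects (the diabetic location shift
#' is a second dependence channel) and no age trends (age is a shared
#' covariate of the score and the syndrome components).  Under this
#' configuration HOMA-IR carries essentially no information about MetS and
#' the AUC sits at chance, up to the small residual induced by fasting
#' glucose appearing in both the score and the glucose component.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @param ... further overrides passed to [survey_config()].
#' @return a `"survey_config"` object.
#' @export
null_config <- function(n = 4233, seed = NULL, ...) {
  survey_config(n = n, seed = seed,
                loadings = c(insulin = 0, glucose = 0, waist = 0, tg = 0,
                             hdl = 0, sbp = 0, dbp = 0, bmi = 0),
                diabetic_fraction = 0, age_effect_scale = 0, ...)
}

#' Generate a synthetic survey cohort
#'
#' Draws a cohort from a [survey_config()]: stratum, age, sex, diabetic
#' status, latent factor, then each clinical variable as a marginal
#' transform of the latent factor plus age/sex/diabetes effects and
#' independent noise.  Measurements are rounded to realistic instrument
#' precision (so score ties occur, as in real assay data); missingness and
#' pregnancy are applied last.  Deterministic given the config seed.
#'
#' @param config a `"survey_config"` object.
#' @return data frame with the columns of [cohort_columns()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n
  st <- cfg$sample_strata
  idx <- sample.int(nrow(st), n, replace = TRUE, prob = st$proportion)
  band <- st$age_band[idx]
  sex <- st$sex[idx]
  lo <- c("25-34" = 25, "35-44" = 35, "45-54" = 45, "55-64" = 55)[band]
  age <- as.integer(lo + floor(stats::runif(n) * 10))
  female <- sex == "female"
  a <- (age - 45) / 10 * cfg$age_effect_scale
  D <- stats::runif(n) < cfg$diabetic_fraction
  Z <- stats::rnorm(n)
  lam <- cfg$loadings; mg <- cfg$marginals; sh <- cfg$diabetic_shift
  rn <- function() stats::rnorm(n)

  insulin <- exp(mg$insulin["meanlog"] + 0.05 * a + lam["insulin"] * Z +
                 sh["insulin"] * D + mg$insulin["sdlog"] * rn())
  fpg <- exp(mg$glucose["meanlog"] + 0.02 * a + lam["glucose"] * Z +
             sh["glucose"] * D + mg$glucose["sdlog"] * rn())
  waist <- ifelse(female, mg$waist["female"], mg$waist["male"]) + 2.2 * a +
    lam["waist"] * Z + sh["waist"] * D + mg$waist["sd"] * rn()
  tg <- exp(mg$tg["meanlog"] + 0.05 * a + lam["tg"] * Z + sh["tg"] * D +
            mg$tg["sdlog"] * rn())
  hdl <- ifelse(female, mg$hdl["female"], mg$hdl["male"]) -
    lam["hdl"] * Z + mg$hdl["sd"] * rn()
  e_bp <- rn()
  sbp <- mg$sbp["mean"] + 4.5 * a + lam["sbp"] * Z + sh["sbp"] * D +
    mg$sbp["sd"] * e_bp
  dbp <- mg$dbp["mean"] + 1.8 * a + lam["dbp"] * Z + 0.5 * sh["sbp"] * D +
    mg$dbp["sd"] * (0.6 * e_bp + 0.8 * rn())
  bmi <- mg$bmi["mean"] + mg$bmi["female_shift"] * female + 1.0 * a +
    lam["bmi"] * Z + sh["bmi"] * D + mg$bmi["sd"] * rn()
  bmi <- pmax(bmi, 15)
  height <- ifelse(female,
                   mg$height["female"] + mg$height["female_sd"] * rn(),
                   mg$height["male"] + mg$height["male_sd"] * rn())
  height <- pmax(height, 1.3)
  weight <- bmi * height^2
  ldl_comp <- mg$ldl["mean"] + 2 * a + mg$ldl["sd"] * rn()
  tc <- pmax(hdl + ldl_comp + tg / 5, 80)
  hdl <- pmax(hdl, 10); waist <- pmax(waist, 50)
  sbp <- pmax(sbp, 70); dbp <- pmax(dbp, 40)

  diabetes_history <- D & stats::runif(n) < cfg$history_rate
  med <- stats::runif(n) <
    stats::plogis(-3.4 + 0.045 * (sbp - 120) + 0.8 * D)
  pregnant <- female & age <= 45 & stats::runif(n) < cfg$pregnancy_rate

  df <- data.frame(
    subject_id = sprintf("S%06d", seq_len(n)),
    age = age, sex = sex,
    weight = round(weight, 1), height = round(height, 2),
    waist = round(waist / 0.5) * 0.5,
    sbp = round(sbp), dbp = round(dbp),
    fpg = round(fpg), insulin = round(insulin, 1),
    tg = round(tg), hdl = round(hdl), tc = round(tc),
    ldl_direct = NA_real_,
    diabetes_history = diabetes_history,
    antihypertensive_med = med, pregnant = pregnant,
    stringsAsFactors = FALSE)

  high_tg <- df$tg > 400
  direct_avail <- high_tg & stats::runif(n) < 0.9
  df$ldl_direct[direct_avail] <-
    round(pmax(ldl_comp[direct_avail] + 5 * stats::rnorm(sum(direct_avail)),
               30))

  mr <- cfg$missing_rates
  for (col in names(mr))
    df[[col]][stats::runif(n) < mr[[col]]] <- NA_real_
  df
}

#' Ground truth implied by a generator configuration
#'
#' Reference values for the estimands the pipeline targets — weighted MetS
#' prevalence under both definitions, the HOMA-IR versus MetS AUC, and the
#' criterion-optimal cut-offs per diabetes stratum — obtained by a large
#' Monte-Carlo run of the generator itself under a fixed internal seed
#' (missingness and pregnancy are switched off: they are random filters
#' that do not move the estimands).  Recomputable from the configuration
#' alone.
#'
#' @param config a `"survey_config"` object.
#' @param n Monte-Carlo population size (default one million).
#' @param census census table for the weighted estimands.
#' @return an object of class `"planted_truth"`: list with `n`,
#'   `prevalence` (named, ATPIII/IDF, weighted), `auc` (overall and per
#'   stratum, ATPIII and IDF), `cutoff` (per stratum x definition x
#'   criterion), and the config echo.
#' @export
planted_truth <- function(config, n = 1e6, census = default_census()) {
  stopifnot(inherits(config, "survey_config"))
  cfg <- config
  cfg$n <- as.integer(n)
  cfg$seed <- 880427L            # fixed internal reference seed
  cfg$missing_rates[] <- 0
  cfg$pregnancy_rate <- 0
  cohort <- derive_clinical(generate_cohort(cfg))
  mets <- assess_mets(cohort)
  w <- poststratification_weights(cohort, census)
  res <- list(config = config, n = cfg$n)
  res$prevalence <- c(atpiii = weighted_prevalence(mets$mets_atpiii, w),
                      idf = weighted_prevalence(mets$mets_idf, w))
  res$auc <- list()
  res$cutoff <- list()
  for (def in c("atpiii", "idf")) {
    lab <- mets[[paste0("mets_", def)]]
    res$auc[[paste0(def, "_overall")]] <- auc(cohort$homa_ir, lab, w)
    for (strat in c("nondiabetic", "diabetic")) {
      i <- mets$stratum == strat
      if (length(unique(lab[i])) < 2L) next
      r <- wroc(cohort$homa_ir[i], lab[i], w[i])
      res$auc[[paste0(def, "_", strat)]] <- auc(r)
      for (m in c("youden", "distance"))
        res$cutoff[[paste(def, strat, m, sep = "_")]] <-
          optimal_cutpoint(r, m)$threshold
    }
  }
  structure(res, class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("Planted truth (Monte-Carlo reference, n = %d)\n", x$n))
  cat(sprintf("  MetS prevalence: ATPIII %s, IDF %s (weighted)\n",
              fmt_num(x$prevalence["atpiii"]), fmt_num(x$prevalence["idf"])))
  for (nm in names(x$auc))
    cat(sprintf("  AUC %-18s %s\n", nm, fmt_num(x$auc[[nm]], 4)))
  for (nm in names(x$cutoff))
    cat(sprintf("  cut-off %-28s %s\n", nm, fmt_num(x$cutoff[[nm]])))
  invisible(x)
}
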