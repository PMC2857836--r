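## cli_pipeline: end-to-end orchestration — ingest or generate, exclude,
## derive, classify, weight, and emit the full report bundle as delimited
## text plus a JSON manifest.  All randomness flows from one top-level
## seed via substream derivation.

#' Pipeline configuration
#'
#' @param input path to a cohort file, or `NULL` to generate from the
#'   frozen survey-like preset.
#' @param census path to a census strata table, or `NULL` for
#'   [default_census()].
#' @param criteria MetS definitions to analyse.
#' @param score score column, `"homa_ir"` (default) or `"insulin"` (the
#'   pipeline runs unchanged with fasting insulin as the score).
#' @param strata diabetes strata to analyse.
#' @param diabetes_rule passed to [diabetes_stratum()].
#' @param p_grid percentile grid for threshold tables.
#' @param B bootstrap replicates for the AUC interval.
#' @param seed top-level integer seed.
#' @param outdir output directory (created if absent).
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, census = NULL,
                            criteria = c("atpiii", "idf"),
                            score = c("homa_ir", "insulin"),
                            strata = c("nondiabetic", "diabetic"),
                            diabetes_rule = "history_or_fpg126",
                            p_grid = seq(50, 95, by = 5),
                            B = 500, seed = 1L, outdir = "homacut-output") {
  score <- match.arg(score)
  criteria <- match.arg(criteria, several.ok = TRUE)
  strata <- match.arg(strata, several.ok = TRUE)
  if (any(p_grid < 0 | p_grid > 100))
    abort("pipeline_config: percentile grid must lie in [0, 100]",
          "homacut_invalid_argument")
  if (!is.null(input) && !file.exists(input))
    abort(sprintf("pipeline_config: input not found: %s", input),
          "homacut_io")
  if (!is.null(census) && is.character(census) && !file.exists(census))
    abort(sprintf("pipeline_config: census table not found: %s", census),
          "homacut_io")
  structure(list(input = input, census = census, criteria = criteria,
                 score = score, strata = strata,
                 diabetes_rule = diabetes_rule, p_grid = p_grid,
                 B = as.integer(B), seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Run the full cut-point analysis pipeline
#'
#' Stages: (1) load or generate the cohort; (2) apply exclusions and
#' derive BMI/LDL/HOMA-IR; (3) classify MetS and assign strata; (4)
#' post-stratify to the census margins; (5) per stratum x definition, fit
#' the weighted ROC, select cut-offs under both criteria, bootstrap the
#' AUC, and tabulate percentile thresholds and PLR curves.  Writes a
#' bundle of delimited-text outputs and a JSON manifest; identical inputs
#' and seed give a byte-identical bundle.  A stratum whose label has a
#' single class is skipped with a warning.
#'
#' @param config a `"pipeline_config"` object.
#' @param quiet suppress per-stage log lines?
#' @return (invisibly) a list with the cohort, assessment, weights, fits
#'   and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_line <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  ## stage 1: cohort
  if (is.null(config$input)) {
    gen_seed <- substream_seed(config$seed, "generator")
    raw <- generate_cohort(survey_config(seed = gen_seed))
    source_desc <- sprintf("generated (preset, substream seed %d)", gen_seed)
  } else {
    sep <- if (grepl("\\.tsv$", config$input)) "\t" else ","
    raw <- read_cohort(config$input, sep = sep)
    source_desc <- config$input
  }
  log_line("cohort: %d records from %s", nrow(raw), source_desc)

  ## stage 2: exclusions + derived measures
  excl <- apply_exclusions(raw)
  cohort <- derive_clinical(excl$retained)
  log_line("exclusions: %d retained, %d excluded (%s)",
           nrow(cohort), nrow(excl$excluded),
           paste(sprintf("%s=%d", names(table(excl$excluded$reason)),
                         table(excl$excluded$reason)), collapse = ", "))

  ## stage 3: MetS assessment
  mets <- assess_mets(cohort, config$diabetes_rule)
  log_line("classification: ATPIII prevalence %.1f%%, IDF %.1f%% (unweighted)",
           100 * mean(mets$mets_atpiii), 100 * mean(mets$mets_idf))

  ## stage 4: weights
  census <- if (is.null(config$census)) default_census()
            else if (is.character(config$census)) read_census(config$census)
            else validate_census(config$census)
  w <- poststratification_weights(cohort, census)
  log_line("weighting: %d strata, weight range [%.3f, %.3f]",
           length(unique(attr(w, "stratum"))), min(w), max(w))

  score <- cohort[[config$score]]

  ## report: cohort characteristics by sex (weighted mean +/- SEM)
  chars <- cohort_characteristics(cohort, mets, w)
  write_cohort(chars, file.path(config$outdir, "cohort_characteristics.csv"))
  write_cohort(excl$excluded, file.path(config$outdir, "exclusions.csv"))
  write_cohort(cohort, file.path(config$outdir, "cohort_derived.csv"))
  write_cohort(mets, file.path(config$outdir, "mets_assessment.csv"))

  ## reference score percentiles among metabolically normal subjects
  nrm <- mets$metabolically_normal
  if (any(nrm)) {
    pn <- data.frame(percentile = config$p_grid,
                     threshold = weighted_percentile(score[nrm], w[nrm],
                                                     config$p_grid))
    write_cohort(pn, file.path(config$outdir,
                               "score_percentiles_normal_subjects.csv"))
  }

  ## stage 5: ROC / cut-points per stratum x definition
  fits <- list()
  cp_rows <- list()
  skipped <- character()
  boot_seed <- substream_seed(config$seed, "bootstrap")
  for (def in config$criteria) {
    lab_all <- mets[[paste0("mets_", def)]]
    for (strat in config$strata) {
      i <- mets$stratum == strat
      key <- paste(def, strat, sep = "_")
      if (sum(i) < 2L || length(unique(lab_all[i])) < 2L) {
        warn(sprintf("stratum %s has a single class for %s; skipped",
                     strat, def), "homacut_single_class")
        skipped <- c(skipped, key)
        next
      }
      d <- data.frame(label = lab_all[i], score = score[i])
      fit <- cutpoint(label ~ score, d, weights = w[i],
                      boot = TRUE, B = config$B,
                      seed = substream_seed(boot_seed, key),
                      p_grid = config$p_grid)
      fits[[key]] <- fit
      rc <- fit$roc
      write_cohort(data.frame(threshold = rc$thresholds,
                              sensitivity = rc$sensitivity,
                              specificity = rc$specificity),
                   file.path(config$outdir, sprintf("roc_%s.csv", key)))
      write_cohort(criterion_curves(rc),
                   file.path(config$outdir,
                             sprintf("criterion_curves_%s.csv", key)))
      write_cohort(fit$table,
                   file.path(config$outdir,
                             sprintf("percentile_table_%s.csv", key)))
      for (m in names(fit$cutpoints)) {
        cp <- fit$cutpoints[[m]]
        cp_rows[[paste(key, m)]] <- data.frame(
          definition = def, stratum = strat, method = m,
          n = fit$n, threshold = cp$threshold,
          sensitivity = cp$sensitivity, specificity = cp$specificity,
          youden_j = cp$youden_j,
          youden_paper_scale = cp$youden_paper_scale,
          distance_sq = cp$distance_sq, plr = cp$plr,
          percentile = cp$percentile_of_threshold,
          plateau_low = cp$plateau["low"], plateau_high = cp$plateau["high"],
          auc = fit$auc, auc_low = fit$auc_ci[1], auc_high = fit$auc_ci[2])
      }
      log_line("cutpoint [%s]: AUC %.3f, youden threshold %.4g", key,
               fit$auc, fit$cutpoints[["youden"]]$threshold)
    }
  }
  cp_summary <- do.call(rbind, c(cp_rows, make.row.names = FALSE))
  if (!is.null(cp_summary))
    write_cohort(cp_summary, file.path(config$outdir, "cutpoints.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("homacut")),
    seed = config$seed, score = config$score,
    criteria = config$criteria, strata = config$strata,
    diabetes_rule = config$diabetes_rule, bootstrap_B = config$B,
    input = if (is.null(config$input)) "preset-generator" else config$input,
    n_input = nrow(raw), n_retained = nrow(cohort),
    n_excluded = nrow(excl$excluded),
    exclusion_reasons = as.list(table(excl$excluded$reason)),
    skipped_strata = skipped,
    outputs = sort(setdiff(list.files(config$outdir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, exclusions = excl$excluded, mets = mets,
                 weights = w, fits = fits, cutpoints = cp_summary,
                 manifest = manifest))
}

## Table-S1-style summary: weighted mean +/- SEM of the main clinical
## variables by sex, plus weighted prevalences.
cohort_characteristics <- function(cohort, mets, w) {
  vars <- c("age", "bmi", "waist", "sbp", "dbp", "fpg", "insulin",
            "homa_ir", "tg", "hdl", "tc")
  rows <- list()
  for (sx in c("male", "female")) {
    i <- cohort$sex == sx
    for (v in vars) {
      ok <- i & !is.na(cohort[[v]])
      ms <- weighted_mean_sem(cohort[[v]][ok], w[ok])
      ms_u <- weighted_mean_sem(cohort[[v]][ok])
      rows[[paste(sx, v)]] <- data.frame(
        sex = sx, variable = v, n = sum(ok),
        mean = ms["mean"], sem = ms["sem"],
        mean_unweighted = ms_u["mean"], sem_unweighted = ms_u["sem"])
    }
    for (lab in c("mets_atpiii", "mets_idf", "metabolically_normal")) {
      rows[[paste(sx, lab)]] <- data.frame(
        sex = sx, variable = paste0("prevalence_", lab), n = sum(i),
        mean = weighted_prevalence(mets[[lab]][i], w[i]), sem = NA_real_,
        mean_unweighted = mean(mets[[lab]][i]), sem_unweighted = NA_real_)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
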