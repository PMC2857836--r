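## survey_weighting: post-stratification to census age-decade x sex margins
## and weighted summary statistics.

AGE_BANDS <- c("25-34", "35-44", "45-54", "55-64")

#' Age-decade band of an age in years
#'
#' @param age integer ages, 25-64.
#' @return factor with levels `25-34`, `35-44`, `45-54`, `55-64`.
#' @export
age_band <- function(age) {
  cut(age, breaks = c(25, 35, 45, 55, 65), right = FALSE,
      labels = AGE_BANDS)
}

#' Read a census strata table
#'
#' Delimited text with columns `age_band`, `sex`, `proportion`: population
#' proportion of each age-decade x sex stratum.  Proportions must be
#' strictly positive and sum to 1 (tolerance 1e-9).
#'
#' @param path file path.
#' @param sep field separator.
#' @return validated data frame.
#' @export
read_census <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_census(df)
}

validate_census <- function(df) {
  check_columns(df, c("age_band", "sex", "proportion"), "census table")
  if (any(df$proportion <= 0))
    abort("census table: proportions must be strictly positive",
          "homacut_bad_census")
  if (abs(sum(df$proportion) - 1) > 1e-9)
    abort("census table: proportions must sum to 1", "homacut_bad_census")
  if (anyDuplicated(paste(df$age_band, df$sex)))
    abort("census table: duplicated strata", "homacut_bad_census")
  df
}

#' Post-stratification weights against census margins
#'
#' Each record is assigned to its age-decade x sex stratum; the stratum
#' weight is the census proportion divided by the sample proportion, then
#' rescaled so the weights average 1 over the cohort (weighted and
#' unweighted cohort sizes stay comparable).  Census strata with no sample
#' members are dropped from the normalization with a warning.
#'
#' @param records data frame with `age` and `sex`.
#' @param census census strata table (see [read_census()]).
#' @return numeric weight vector, one per record, with a `"stratum"`
#'   attribute giving each record's stratum key.
#' @export
poststratification_weights <- function(records, census) {
  census <- validate_census(census)
  check_columns(records, c("age", "sex"), "poststratification_weights")
  key <- paste(as.character(age_band(records$age)), records$sex, sep = ":")
  ckey <- paste(census$age_band, census$sex, sep = ":")
  if (any(is.na(key)) || !all(key %in% ckey))
    abort("poststratification_weights: record outside the census strata",
          "homacut_bad_stratum")
  present <- ckey %in% key
  if (!all(present))
    warn(sprintf("census strata absent from the sample, omitted: %s",
                 paste(ckey[!present], collapse = ", ")),
         "homacut_empty_stratum")
  prop_census <- census$proportion[present] / sum(census$proportion[present])
  names(prop_census) <- ckey[present]
  n <- length(key)
  prop_sample <- table(key) / n
  w <- as.numeric(prop_census[key] / prop_sample[key])
  w <- w / mean(w)
  attr(w, "stratum") <- key
  w
}

#' Weighted mean and its standard error
#'
#' Mean is the weight-normalized sum; the standard error uses the weighted
#' variance with Kish's effective sample size
#' n_eff = (sum w)^2 / sum w^2.  With equal weights this reduces to the
#' ordinary mean and s/sqrt(n).
#'
#' @param x numeric values.
#' @param w positive weights (default equal).
#' @return named numeric vector `c(mean, sem, n_eff)`.
#' @export
weighted_mean_sem <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(x) == length(w), all(w > 0))
  if (length(x) < 2L)
    abort("weighted_mean_sem: need at least two observations",
          "homacut_insufficient_data")
  m <- sum(w * x) / sum(w)
  n_eff <- sum(w)^2 / sum(w^2)
  v <- sum(w * (x - m)^2) / sum(w) * n_eff / (n_eff - 1)
  c(mean = m, sem = sqrt(v / n_eff), n_eff = n_eff)
}

#' Weighted percentile
#'
#' Quantile of the weighted empirical distribution.  Ties are merged;
#' distinct values sit at the midpoints of their cumulative-weight blocks
#' and the quantile is linearly interpolated between adjacent distinct
#' values (clamped to the minimum below the first midpoint and the maximum
#' above the last).  With equal weights on `{1,2,3}` the 50th percentile is
#' 2; integer weights reproduce the percentile of the expanded multiset.
#'
#' @param x numeric values.
#' @param w positive weights (default equal).
#' @param p percentile(s) in \[0, 100\].
#' @return numeric vector, one value per element of `p`.
#' @export
weighted_percentile <- function(x, w = NULL, p) {
  if (length(x) == 0L)
    abort("weighted_percentile: empty sample", "homacut_insufficient_data")
  if (any(is.na(p)) || any(p < 0) || any(p > 100))
    abort("weighted_percentile: p must be in [0, 100]",
          "homacut_invalid_argument")
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(x) == length(w), all(w > 0), !anyNA(x))
  o <- order(x)
  xs <- x[o]; ws <- w[o]
  grp <- cumsum(!duplicated(xs))
  v <- xs[!duplicated(xs)]
  wv <- as.numeric(rowsum(ws, grp))
  wv <- wv / sum(wv)
  cum <- cumsum(wv)
  pos <- cum - wv / 2
  if (length(v) == 1L) return(rep(v, length(p)))
  stats::approx(pos, v, xout = p / 100, rule = 2, ties = "ordered")$y
}

#' Weighted prevalence of a binary label
#'
#' @param labels logical vector.
#' @param w positive weights (default equal).
#' @return weighted proportion in \[0, 1\].
#' @export
weighted_prevalence <- function(labels, w = NULL) {
  if (length(labels) == 0L)
    abort("weighted_prevalence: empty sample", "homacut_insufficient_data")
  if (is.null(w)) w <- rep(1, length(labels))
  stopifnot(length(labels) == length(w), all(w > 0), !anyNA(labels))
  sum(w * labels) / sum(w)
}

#' Weighted Pearson correlation
#'
#' Weighted covariance over the product of weighted standard deviations.
#' With equal weights this is the ordinary product-moment correlation.
#'
#' @param x,y numeric vectors.
#' @param w positive weights (default equal).
#' @return correlation in \[-1, 1\].
#' @export
weighted_pearson <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(x) == length(y), length(x) == length(w), all(w > 0))
  if (length(x) < 3L)
    abort("weighted_pearson: need at least three observations",
          "homacut_insufficient_data")
  mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - mx)^2); syy <- sum(w * (y - my)^2)
  if (sxx == 0 || syy == 0)
    abort("weighted_pearson: constant input", "homacut_degenerate_input")
  sum(w * (x - mx) * (y - my)) / sqrt(sxx * syy)
}
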