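## roc_cutpoint: weighted empirical ROC curves, AUC with bootstrap CI,
## Youden / distance-to-(0,1) / PLR criteria, optimal cut-offs and
## percentile threshold tables.
##
## Positivity rule throughout: a subject tests positive when
## score >= threshold (higher score, more likely disease).

#' Weighted empirical ROC curve
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' observed scores, bracketed by -Inf and +Inf sentinels.  At each
#' threshold, sensitivity is the weighted fraction of positives with score
#' at or above it and specificity the weighted fraction of negatives below
#' it.  Sensitivity is non-increasing and specificity non-decreasing in
#' the threshold; the sentinels give the (1, 0) and (0, 1) corners.
#'
#' @param score numeric scores (e.g. HOMA-IR).
#' @param label logical (or 0/1) disease labels; `TRUE` is the positive
#'   class.
#' @param weights positive subject weights (default equal).
#' @return an object of class `"wroc"`: list with `thresholds` (ascending),
#'   `sensitivity`, `specificity`, `pos_weight`, `neg_weight`, `n`.
#' @examples
#' r <- wroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' auc(r)  # 1
#' @export
wroc <- function(score, label, weights = NULL) {
  label <- as.logical(label)
  if (is.null(weights)) weights <- rep(1, length(score))
  stopifnot(length(score) == length(label),
            length(score) == length(weights))
  if (anyNA(score) || anyNA(label) || anyNA(weights) || any(weights <= 0))
    abort("wroc: scores, labels and weights must be complete, weights positive",
          "homacut_invalid_argument")
  P <- sum(weights[label]); N <- sum(weights[!label])
  if (P == 0 || N == 0)
    abort("wroc: both classes must be present with positive weight",
          "homacut_degenerate_labels")
  o <- order(score)
  s <- score[o]; l <- label[o]; w <- weights[o]
  new <- !duplicated(s)
  grp <- cumsum(new)
  v <- s[new]                                   # distinct ascending scores
  wp <- as.numeric(rowsum(w * l, grp))          # positive weight per value
  wn <- as.numeric(rowsum(w * !l, grp))         # negative weight per value
  k <- length(v)
  thr <- c(-Inf, if (k > 1) (v[-k] + v[-1]) / 2, Inf)
  ## threshold i sits above the first (i-1) distinct values
  sens <- c(1, 1 - cumsum(wp) / P)
  spec <- c(0, cumsum(wn) / N)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 pos_weight = P, neg_weight = N, n = length(score)),
            class = "wroc")
}

#' Area under a ROC curve
#'
#' @param x a `"wroc"` object (or, for the default method, scores).
#' @param ... further arguments for methods.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(x, ...) UseMethod("auc")

#' @describeIn auc trapezoidal area in (1 - specificity, sensitivity)
#'   space; identical to the weighted pairwise concordance probability with
#'   half credit for score ties.
#' @export
auc.wroc <- function(x, ...) {
  fpr <- 1 - x$specificity
  sens <- x$sensitivity
  ## thresholds ascend, so fpr descends; integrate left-to-right
  sum((fpr[-length(fpr)] - fpr[-1]) * (sens[-length(sens)] + sens[-1]) / 2)
}

#' @describeIn auc convenience: builds the curve from `score`, `label`
#'   and `weights`.
#' @param label,weights see [wroc()].
#' @export
auc.default <- function(x, label, weights = NULL, ...) {
  auc(wroc(x, label, weights))
}

## Fast weighted concordance used by the bootstrap: same quantity as
## auc.wroc but computed from a pre-sorted tie-block structure so that
## replicates (which only reweight subjects) avoid re-sorting.
roc_blocks <- function(score, label) {
  o <- order(score)
  grp <- cumsum(!duplicated(score[o]))
  list(order = o, grp = grp, label = label[o])
}

wauc_blocks <- function(blocks, weights) {
  w <- weights[blocks$order]
  wp <- as.numeric(rowsum(w * blocks$label, blocks$grp))
  wn <- as.numeric(rowsum(w * !blocks$label, blocks$grp))
  P <- sum(wp); N <- sum(wn)
  if (P == 0 || N == 0) return(NA_real_)
  below <- cumsum(wn) - wn
  sum(wp * (below + wn / 2)) / (P * N)
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Subjects are resampled with replacement (their weights travel with
#' them); the interval is the percentile interval of the replicate AUCs.
#' A replicate that loses one class entirely is redrawn (and counted).
#'
#' @param score,label,weights as in [wroc()].
#' @param B number of bootstrap replicates (at least 100).
#' @param level confidence level.
#' @param seed integer seed; the caller's RNG state is preserved.
#' @return numeric vector `c(low, high)` with attributes `point` (the
#'   full-sample AUC), `B`, `level` and `redrawn` (count of degenerate
#'   replicates redrawn).
#' @export
auc_bootstrap_ci <- function(score, label, weights = NULL, B = 2000,
                             level = 0.95, seed = NULL) {
  if (B < 100) abort("auc_bootstrap_ci: B must be at least 100",
                     "homacut_invalid_argument")
  label <- as.logical(label)
  n <- length(score)
  if (is.null(weights)) weights <- rep(1, n)
  blocks <- roc_blocks(score, label)
  point <- wauc_blocks(blocks, weights)
  if (is.na(point))
    abort("auc_bootstrap_ci: both classes must be present",
          "homacut_degenerate_labels")
  redrawn <- 0L
  reps <- numeric(B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        cnt <- stats::rmultinom(1L, n, rep.int(1 / n, n))[, 1L]
        a <- wauc_blocks(blocks, weights * cnt)
        if (!is.na(a)) break
        redrawn <- redrawn + 1L
      }
      reps[b] <- a
    }
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7))
  structure(ci, point = point, B = B, level = level, redrawn = redrawn)
}

#' Youden index
#'
#' J = sensitivity + specificity - 1.  The companion scale J + 1
#' (sensitivity + specificity) is returned alongside because published
#' cut-point tables in this literature often print Youden values on that
#' 1-offset scale; the two orderings are identical.
#'
#' @param sensitivity,specificity proportions in \[0, 1\].
#' @return named vector `c(j, paper_scale)`.
#' @export
youden <- function(sensitivity, specificity) {
  check_unit_interval(sensitivity, specificity, "youden")
  j <- sensitivity + specificity - 1
  c(j = j, paper_scale = j + 1)
}

#' Squared distance to the perfect-classification corner (0, 1)
#'
#' (1 - sensitivity)^2 + (1 - specificity)^2 in ROC space.  Minimized as
#' printed, without the square root (the argmin is the same either way);
#' [sqrt()] of the result gives the Euclidean distance.
#'
#' @param sensitivity,specificity proportions in \[0, 1\].
#' @return unitless squared distance in \[0, 2\].
#' @export
distance_sq <- function(sensitivity, specificity) {
  check_unit_interval(sensitivity, specificity, "distance_sq")
  (1 - sensitivity)^2 + (1 - specificity)^2
}

#' Positive likelihood ratio
#'
#' sensitivity / (1 - specificity): how much a positive result raises the
#' odds of disease.  `Inf` when specificity is exactly 1.
#'
#' @param sensitivity,specificity proportions in \[0, 1\].
#' @return unitless ratio, possibly `Inf`.
#' @export
plr <- function(sensitivity, specificity) {
  check_unit_interval(sensitivity, specificity, "plr")
  ifelse(specificity == 1, Inf, sensitivity / (1 - specificity))
}

check_unit_interval <- function(sensitivity, specificity, where) {
  if (anyNA(sensitivity) || anyNA(specificity) ||
      any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1))
    abort(sprintf("%s: sensitivity and specificity must lie in [0, 1]", where),
          "homacut_invalid_argument")
  invisible(TRUE)
}

#' Optimal cut-off on a ROC curve
#'
#' Selects the finite threshold maximizing the Youden index
#' (`method = "youden"`) or minimizing the squared distance to (0, 1)
#' (`method = "distance"`).  Ties within a criterion tolerance of 1e-12
#' form a plateau: the lowest threshold is chosen and the plateau interval
#' reported.
#'
#' @param roc a `"wroc"` object.
#' @param method `"youden"` or `"distance"`.
#' @param score,weights optionally, the original scores and weights, used
#'   to attach the weighted percentile rank of the chosen threshold.
#' @return an object of class `"cutpoint_result"`: list with `threshold`,
#'   `criterion`, `criterion_value`, `sensitivity`, `specificity`,
#'   `youden_j`, `youden_paper_scale`, `distance_sq`, `plr`,
#'   `percentile_of_threshold` (or `NA`), `plateau` (interval), `n_tied`.
#' @export
optimal_cutpoint <- function(roc, method = c("youden", "distance"),
                             score = NULL, weights = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(roc, "wroc"))
  fin <- is.finite(roc$thresholds)
  if (!any(fin))
    abort("optimal_cutpoint: no finite candidate threshold (all scores tied)",
          "homacut_no_cutpoint")
  thr <- roc$thresholds[fin]
  se <- roc$sensitivity[fin]
  sp <- roc$specificity[fin]
  crit <- if (method == "youden") se + sp - 1 else
    -((1 - se)^2 + (1 - sp)^2)          # maximize either way
  best <- max(crit)
  tied <- which(crit >= best - 1e-12)
  pick <- tied[1L]                      # lowest threshold wins
  pct <- if (!is.null(score)) {
    if (is.null(weights)) weights <- rep(1, length(score))
    100 * sum(weights[score < thr[pick]]) / sum(weights)
  } else NA_real_
  structure(list(
    threshold = thr[pick],
    criterion = method,
    criterion_value = if (method == "youden") best else -best,
    sensitivity = se[pick],
    specificity = sp[pick],
    youden_j = se[pick] + sp[pick] - 1,
    youden_paper_scale = se[pick] + sp[pick],
    distance_sq = (1 - se[pick])^2 + (1 - sp[pick])^2,
    plr = unname(plr(se[pick], sp[pick])),
    percentile_of_threshold = pct,
    plateau = c(low = thr[tied[1L]], high = thr[tied[length(tied)]]),
    n_tied = length(tied)), class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("Optimal cut-off (%s criterion): %g\n", x$criterion,
              x$threshold))
  cat(sprintf("  sensitivity %s, specificity %s, Youden J %s (1+J %s)\n",
              fmt_num(x$sensitivity), fmt_num(x$specificity),
              fmt_num(x$youden_j), fmt_num(x$youden_paper_scale)))
  cat(sprintf("  distance^2 to (0,1) %s, PLR %s\n",
              fmt_num(x$distance_sq), fmt_num(x$plr)))
  if (!is.na(x$percentile_of_threshold))
    cat(sprintf("  threshold at the %s-th weighted percentile of the score\n",
                fmt_num(x$percentile_of_threshold, 1)))
  if (x$n_tied > 1L)
    cat(sprintf("  criterion plateau: %d thresholds in [%g, %g]\n",
                x$n_tied, x$plateau["low"], x$plateau["high"]))
  invisible(x)
}

#' Percentile threshold table
#'
#' For each grid percentile of the weighted score distribution, the
#' corresponding threshold and its diagnostic performance: sensitivity and
#' specificity under the score-at-or-above-threshold positivity rule, and
#' the positive likelihood ratio.
#'
#' @param score,label,weights as in [wroc()].
#' @param p_grid percentiles, default 50 to 95 in steps of 5.
#' @return data frame with columns `percentile`, `threshold`,
#'   `sensitivity`, `specificity`, `plr`.
#' @export
percentile_table <- function(score, label, weights = NULL,
                             p_grid = seq(50, 95, by = 5)) {
  label <- as.logical(label)
  if (is.null(weights)) weights <- rep(1, length(score))
  thr <- weighted_percentile(score, weights, p_grid)
  P <- sum(weights[label]); N <- sum(weights[!label])
  if (P == 0 || N == 0)
    abort("percentile_table: both classes must be present",
          "homacut_degenerate_labels")
  se <- vapply(thr, function(t) sum(weights[label & score >= t]) / P,
               numeric(1))
  sp <- vapply(thr, function(t) sum(weights[!label & score < t]) / N,
               numeric(1))
  data.frame(percentile = p_grid, threshold = thr, sensitivity = se,
             specificity = sp, plr = plr(se, sp))
}

#' @export
print.wroc <- function(x, ...) {
  cat(sprintf("Weighted empirical ROC: %d subjects, %d thresholds\n",
              x$n, length(x$thresholds)))
  cat(sprintf("  positive weight %s, negative weight %s, AUC %s\n",
              fmt_num(x$pos_weight, 1), fmt_num(x$neg_weight, 1),
              fmt_num(auc(x), 4)))
  invisible(x)
}

#' @export
plot.wroc <- function(x, ...) {
  plot(1 - x$specificity, x$sensitivity, type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}
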