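## The user-facing model fit: label ~ score, optional survey weights,
## returning a classed object with the ROC curve, AUC (with optional
## bootstrap CI) and the optimal cut-offs under both criteria.

#' Fit an optimal diagnostic cut-point
#'
#' Builds the weighted empirical ROC curve of a continuous score for a
#' binary condition and selects the optimal threshold by the Youden index
#' and/or the distance-to-(0,1) criterion.
#'
#' @param formula a two-sided formula `label ~ score`, e.g.
#'   `mets_atpiii ~ homa_ir`.
#' @param data data frame holding both variables.
#' @param weights optional positive survey weights (e.g. from
#'   [poststratification_weights()]).
#' @param method criterion(s) to evaluate; default both.
#' @param boot logical: compute a percentile bootstrap CI for the AUC?
#' @param B bootstrap replicates.
#' @param conf.level confidence level for the AUC interval.
#' @param seed integer seed for the bootstrap.
#' @param p_grid percentile grid for the threshold table.
#' @return an object of class `"cutpoint"`: list with `roc` (a
#'   [wroc()] object), `auc`, `auc_ci` (or `NULL`), `cutpoints` (a named
#'   list of `"cutpoint_result"` objects), `table` (the percentile
#'   threshold table), `call`, `n`, `prevalence` (weighted).
#' @examples
#' d <- data.frame(score = c(0.5, 1, 1.5, 2, 2.5, 3),
#'                 dx = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE))
#' fit <- cutpoint(dx ~ score, d)
#' coef(fit)
#' @export
cutpoint <- function(formula, data, weights = NULL,
                     method = c("youden", "distance"),
                     boot = FALSE, B = 2000, conf.level = 0.95,
                     seed = NULL, p_grid = seq(50, 95, by = 5)) {
  method <- match.arg(method, several.ok = TRUE)
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  if (ncol(mf) != 2L)
    abort("cutpoint: formula must be label ~ score", "homacut_invalid_argument")
  label <- as.logical(mf[[1L]])
  score <- as.numeric(mf[[2L]])
  if (is.null(weights)) weights <- rep(1, nrow(mf)) else {
    if (length(weights) == nrow(data))
      weights <- weights[as.integer(rownames(mf))]
    stopifnot(length(weights) == nrow(mf))
  }
  roc <- wroc(score, label, weights)
  cps <- lapply(method, function(m)
    optimal_cutpoint(roc, m, score = score, weights = weights))
  names(cps) <- method
  ci <- if (boot)
    auc_bootstrap_ci(score, label, weights, B = B, level = conf.level,
                     seed = seed) else NULL
  structure(list(roc = roc, auc = auc(roc), auc_ci = ci, cutpoints = cps,
                 table = percentile_table(score, label, weights, p_grid),
                 call = match.call(), n = length(score),
                 prevalence = weighted_prevalence(label, weights),
                 score = score, label = label, weights = weights),
            class = "cutpoint")
}

#' @export
print.cutpoint <- function(x, ...) {
  cat("Diagnostic cut-point analysis\n")
  cat("Call: "); print(x$call)
  cat(sprintf("n = %d, weighted prevalence = %s, AUC = %s",
              x$n, fmt_num(x$prevalence), fmt_num(x$auc, 4)))
  if (!is.null(x$auc_ci))
    cat(sprintf(" (%d%% CI %s-%s)", round(100 * attr(x$auc_ci, "level")),
                fmt_num(x$auc_ci[1], 4), fmt_num(x$auc_ci[2], 4)))
  cat("\n\n")
  for (cp in x$cutpoints) print(cp)
  invisible(x)
}

#' @export
summary.cutpoint <- function(object, ...) {
  out <- do.call(rbind, lapply(names(object$cutpoints), function(m) {
    cp <- object$cutpoints[[m]]
    data.frame(method = m, threshold = cp$threshold,
               sensitivity = cp$sensitivity, specificity = cp$specificity,
               youden_j = cp$youden_j,
               youden_paper_scale = cp$youden_paper_scale,
               distance_sq = cp$distance_sq, plr = cp$plr,
               percentile = cp$percentile_of_threshold)
  }))
  structure(list(cutpoints = out, auc = object$auc, auc_ci = object$auc_ci,
                 n = object$n, prevalence = object$prevalence,
                 table = object$table), class = "summary.cutpoint")
}

#' @export
print.summary.cutpoint <- function(x, ...) {
  cat(sprintf("n = %d, weighted prevalence = %s, AUC = %s\n",
              x$n, fmt_num(x$prevalence), fmt_num(x$auc, 4)))
  cat("\nSelected cut-offs:\n")
  print(x$cutpoints, row.names = FALSE, digits = 4)
  cat("\nPercentile threshold table:\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.cutpoint <- function(object, method = NULL, ...) {
  if (is.null(method)) method <- names(object$cutpoints)[1L]
  cp <- object$cutpoints[[method]]
  c(threshold = cp$threshold, sensitivity = cp$sensitivity,
    specificity = cp$specificity, youden_j = cp$youden_j, plr = cp$plr)
}

#' @export
predict.cutpoint <- function(object, newdata = NULL, method = NULL, ...) {
  if (is.null(method)) method <- names(object$cutpoints)[1L]
  thr <- object$cutpoints[[method]]$threshold
  score <- if (is.null(newdata)) object$score else {
    v <- all.vars(object$call$formula)[2L]
    if (is.data.frame(newdata)) newdata[[v]] else as.numeric(newdata)
  }
  factor(ifelse(score >= thr, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' @export
plot.cutpoint <- function(x, which = c("roc", "criteria", "plr"), ...) {
  which <- match.arg(which)
  if (which == "roc") return(plot(x$roc, ...))
  if (which == "criteria") {
    cc <- criterion_curves(x$roc)
    fin <- is.finite(cc$threshold)
    graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(mfrow = c(1, 1)))
    plot(cc$threshold[fin], cc$youden_paper_scale[fin], type = "l",
         xlab = "threshold", ylab = "Youden index (1 + J)", ...)
    graphics::abline(v = x$cutpoints[[1L]]$threshold, lty = 3)
    plot(cc$threshold[fin], sqrt(cc$distance_sq[fin]), type = "l",
         xlab = "threshold", ylab = "distance to (0,1)", ...)
    graphics::abline(v = x$cutpoints[[1L]]$threshold, lty = 3)
  } else {
    tab <- x$table
    plot(tab$percentile, tab$plr, type = "b", xlab = "score percentile",
         ylab = "positive likelihood ratio", ...)
  }
  invisible(x)
}

#' @export
residuals.cutpoint <- function(object, method = NULL, ...) {
  ## classification residual: label minus the hard prediction at the
  ## chosen threshold
  pred <- predict(object, method = method) == "positive"
  as.numeric(object$label) - as.numeric(pred)
}

#' Criterion-versus-threshold curves
#'
#' The Youden index (both scales), squared distance to (0, 1) and PLR at
#' every candidate threshold of a ROC curve — the data behind cut-point
#' selection plots.
#'
#' @param roc a `"wroc"` object.
#' @return data frame with one row per threshold.
#' @export
criterion_curves <- function(roc) {
  stopifnot(inherits(roc, "wroc"))
  se <- roc$sensitivity; sp <- roc$specificity
  data.frame(threshold = roc$thresholds, sensitivity = se, specificity = sp,
             youden_j = se + sp - 1, youden_paper_scale = se + sp,
             distance_sq = (1 - se)^2 + (1 - sp)^2, plr = plr(se, sp))
}
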