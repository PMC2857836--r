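## Shared fixtures and independent brute-force oracles.

## A complete survey record with sensible healthy-adult defaults;
## override any field by name.
make_record <- function(...) {
  rec <- data.frame(
    subject_id = "T000001", age = 40L, sex = "male",
    weight = 75, height = 1.75, waist = 85, sbp = 115, dbp = 72,
    fpg = 88, insulin = 7, tg = 110, hdl = 48, tc = 180,
    ldl_direct = NA_real_, diabetes_history = FALSE,
    antihypertensive_med = FALSE, pregnant = FALSE,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

make_cohort <- function(...) {
  recs <- list(...)
  out <- do.call(rbind, recs)
  out$subject_id <- sprintf("T%06d", seq_len(nrow(out)))
  out
}

## O(n^2) pairwise weighted concordance: the AUC oracle.
brute_auc <- function(score, label, w = rep(1, length(score))) {
  pos <- which(label); neg <- which(!label)
  num <- 0
  for (i in pos) for (j in neg)
    num <- num + w[i] * w[j] *
      (if (score[i] > score[j]) 1 else if (score[i] == score[j]) 0.5 else 0)
  num / (sum(w[pos]) * sum(w[neg]))
}

## Exhaustive criterion search over every candidate threshold.
brute_best_criterion <- function(roc, method) {
  fin <- is.finite(roc$thresholds)
  se <- roc$sensitivity[fin]; sp <- roc$specificity[fin]
  if (method == "youden") max(se + sp - 1)
  else min((1 - se)^2 + (1 - sp)^2)
}

## Random weighted ROC fixture with both classes guaranteed.
random_roc_fixture <- function(n = NULL) {
  if (is.null(n)) n <- sample(4:50, 1)
  repeat {
    label <- runif(n) < runif(1, 0.2, 0.8)
    if (any(label) && !all(label)) break
  }
  score <- round(rnorm(n, mean = label), sample(0:2, 1))  # ties likely
  w <- runif(n, 0.2, 3)
  list(score = score, label = label, w = w, n = n)
}

## Component-flag fixtures: for a given sex, values that switch exactly one
## syndrome component on or off.
flag_values <- function(sex) {
  list(waist = if (sex == "male") c(on = 103, off = 95) else c(on = 89, off = 80),
       tg    = c(on = 160, off = 100),
       hdl   = if (sex == "male") c(on = 35, off = 45) else c(on = 45, off = 55),
       sbp   = c(on = 135, off = 120),
       fpg   = c(on = 105, off = 90))
}

combo_cohort <- function(sex) {
  fv <- flag_values(sex)
  grid <- expand.grid(waist = 0:1, tg = 0:1, hdl = 0:1, bp = 0:1, fpg = 0:1)
  recs <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    make_record(sex = sex,
                waist = fv$waist[[2 - g$waist]],
                tg = fv$tg[[2 - g$tg]],
                hdl = fv$hdl[[2 - g$hdl]],
                sbp = fv$sbp[[2 - g$bp]], dbp = 70,
                fpg = fv$fpg[[2 - g$fpg]])
  })
  list(cohort = do.call(make_cohort, recs),
       n_flags = rowSums(grid))
}
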