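#' @keywords internal
"_PACKAGE"

## Classed conditions so callers can distinguish user error from data error.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "homacut_error")))
}

warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "homacut_warning")))
}

## Evaluate expr with a local RNG state; the caller's .Random.seed is
## untouched.  All randomness in the package flows through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Derive a reproducible substream seed from a top-level seed
#'
#' Each pipeline stage draws its randomness from its own substream so that
#' partial reruns (e.g. regenerating only the bootstrap) are reproducible.
#' The derivation is a fixed affine-modular map of the top-level seed and a
#' stage label, kept strictly below 2^31.
#'
#' @param seed integer top-level seed.
#' @param stage character stage label, e.g. `"generator"`, `"bootstrap"`.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483399 + 1)
}

## Column presence check with a named-column error.
check_columns <- function(df, cols, where) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    abort(sprintf("%s: missing required column(s): %s", where,
                  paste(miss, collapse = ", ")),
          "homacut_missing_columns")
  invisible(TRUE)
}

fmt_num <- function(x, digits = 3) formatC(x, digits = digits, format = "f")
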