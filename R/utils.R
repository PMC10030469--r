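#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number stream seeded to `seed`,
#' restoring the caller's RNG state afterwards so that seeded package
#' functions do not perturb the user's session.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed from a master seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# TRUE for a numeric vector/column whose non-missing values are all 0 or 1
is_indicator <- function(x) {
  x <- x[!is.na(x)]
  length(x) > 0 && is.numeric(x) && all(x %in% c(0, 1))
}
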