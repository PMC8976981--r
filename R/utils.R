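#' @keywords internal
#' @useDynLib segxai, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a per-stage seed from a global seed; keeps results < 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

stop_sx <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_sx(fmt, ...)
  invisible(TRUE)
}

is_int_triple <- function(x) {
  is.numeric(x) && length(x) == 3L && all(x == round(x)) && all(x > 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
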